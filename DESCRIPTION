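Package: growl
Title: Group Outcome-Weighted Learning for Individualized Treatment Rules
    with Many Treatments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates a latent grouping of a large treatment space together
    with the optimal group-structured individualized treatment rule (ITR)
    from randomized or observational trial data.  Treatments with similar
    conditional effects are clustered into groups and a group-level decision
    rule is learned in a single optimization, using a weighted angle-based
    multicategory support vector machine (RAMSVM) surrogate loss solved by
    dual coordinate descent, with linear or Gaussian-kernel decision
    functions.  Includes greedy, genetic and exhaustive partition search,
    cross-validated tuning of the regularization parameter, a sample-splitting
    procedure that selects the number of treatment groups by a
    benefit/variability trade-off, inverse-probability-weighted value
    estimation, simulation scenario generators with oracle evaluation
    utilities, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    nnet,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
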