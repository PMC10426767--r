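#' Fit the treatment-free main effect s(X)
#'
#' Ordinary least squares of the outcome on `(1, X)`, used only to form
#' residuals `R - s(X)` before the weighted classification step.  Removing a
#' main effect that does not depend on the treatment leaves the decision
#' problem unchanged while shrinking the spread of the subject weights.
#' Falls back to a ridge-stabilized solve (with a warning) when the design
#' is rank deficient.
#'
#' @param dataset a [trial_dataset()].
#' @return an object of class `main_effect`: a list with `coef` (length
#'   `d + 1`, intercept first) and a callable `fun(Xnew)`.
#' @export
fit_main_effect <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  Xa <- cbind(1, dataset$X)
  qrx <- qr(Xa)
  if (qrx$rank < ncol(Xa)) {
    warning("rank-deficient design in main-effect fit; using ridge-stabilized solve")
    XtX <- crossprod(Xa)
    co <- solve(XtX + diag(1e-8 * (1 + mean(diag(XtX))), ncol(Xa)),
                crossprod(Xa, dataset$R))
    co <- drop(co)
  } else {
    co <- qr.coef(qrx, dataset$R)
  }
  co[!is.finite(co)] <- 0
  structure(
    list(coef = unname(co),
         fun = local({
           cf <- unname(co)
           function(Xnew) {
             Xnew <- as.matrix(Xnew)
             drop(cbind(1, Xnew) %*% cf)
           }
         })),
    class = "main_effect"
  )
}

#' Weighted classification records from residualized outcomes
#'
#' Converts a dataset and candidate partition into the weighted multicategory
#' classification records that the dual solver consumes.  With residual
#' `r_i = R_i - s(X_i)` and observed group propensity
#' `p_i = p(delta(A_i) | X_i)`:
#' \itemize{
#'   \item `r_i > 0`: one record with the observed group label and weight
#'     `r_i / p_i`;
#'   \item `r_i < 0`: the label is switched uniformly to one of the other
#'     `K - 1` groups with the weight inflated by `K - 1`.  In `"expand"`
#'     mode the uniform switch is replaced by its expectation: `K - 1`
#'     deterministic records, one per alternative group, each with weight
#'     `-r_i / p_i`.  In `"sample"` mode a single record is drawn (seeded).
#'   \item `r_i = 0`: no record.
#' }
#' Both modes give the same population objective; `"expand"` is deterministic
#' and is the default.
#'
#' @param dataset a [trial_dataset()].
#' @param partition a [treatment_partition()].
#' @param s a `main_effect` object, or `NULL` to skip residualization
#'   (`s(X) = 0`).
#' @param mode `"expand"` or `"sample"`.
#' @param seed integer seed, required for `"sample"` mode.
#' @return an object of class `weighted_records`: list with matrix `X`,
#'   integer `label`, numeric `weight`, integer `subject` (originating row)
#'   and `n_eff` (the original sample size used in the `1/n` scaling of the
#'   empirical objective).
#' @export
transform_residuals <- function(dataset, partition, s = NULL,
                                mode = c("expand", "sample"), seed = NULL) {
  stopifnot(inherits(dataset, "trial_dataset"),
            inherits(partition, "treatment_partition"))
  mode <- match.arg(mode)
  K <- partition$K
  res <- if (is.null(s)) dataset$R else dataset$R - s$fun(dataset$X)
  gp <- group_propensity(dataset, partition)
  obs_group <- partition$labels[dataset$A]
  p_obs <- gp[cbind(seq_len(dataset$n), obs_group)]

  if (mode == "sample") {
    if (is.null(seed)) stop_invalid("sample mode requires a seed")
    set.seed(seed)
  }

  pos <- which(res > 0)
  neg <- which(res < 0)
  # column g of alt_labels lists the K-1 groups other than g
  alt_labels <- matrix(unlist(lapply(seq_len(K), function(g) seq_len(K)[-g])),
                       nrow = K - 1L)
  if (mode == "expand") {
    neg_rows <- rep(neg, each = K - 1L)
    neg_labs <- as.vector(alt_labels[, obs_group[neg], drop = FALSE])
    neg_wts <- rep(-res[neg] / p_obs[neg], each = K - 1L)
  } else {
    neg_rows <- neg
    pick <- sample.int(K - 1L, length(neg), replace = TRUE)
    neg_labs <- alt_labels[cbind(pick, obs_group[neg])]
    neg_wts <- (K - 1L) * (-res[neg]) / p_obs[neg]
  }
  rows <- c(pos, neg_rows)
  weighted_records(
    X = dataset$X[rows, , drop = FALSE],
    label = c(obs_group[pos], neg_labs),
    weight = c(res[pos] / p_obs[pos], neg_wts),
    K = K,
    subject = rows,
    n_eff = dataset$n
  )
}

#' Construct weighted classification records directly
#'
#' Low-level constructor used by [transform_residuals()] and by tests that
#' build tiny hand-computable instances.
#'
#' @param X covariate matrix (one row per record; may have zero columns for
#'   intercept-only problems).
#' @param label integer group labels in `1..K`.
#' @param weight nonnegative record weights.
#' @param K number of groups.
#' @param subject originating subject index per record.
#' @param n_eff effective sample size for the `1/n` objective scaling;
#'   defaults to the number of records.
#' @return a `weighted_records` object.
#' @export
weighted_records <- function(X, label, weight, K,
                             subject = seq_along(label),
                             n_eff = length(label)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  label <- as.integer(label)
  weight <- as.numeric(weight)
  if (length(label) != nrow(X) || length(weight) != nrow(X)) {
    stop_invalid("X, label and weight must agree in length")
  }
  if (any(weight < 0)) stop_invalid("weights must be nonnegative")
  if (length(label) && any(label < 1L | label > K)) {
    stop_invalid("labels must lie in 1..K")
  }
  structure(list(X = X, label = label, weight = weight, K = as.integer(K),
                 subject = as.integer(subject), n_eff = n_eff),
            class = "weighted_records")
}
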