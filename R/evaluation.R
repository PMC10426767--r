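#' Oracle value of a group-structured rule on test covariates
#'
#' Expected outcome of the policy "recommend group `g(x)`, then sample a
#' treatment within the group proportionally to its propensities", computed
#' with the scenario's true mean-outcome function:
#' the mean over test rows of
#' `sum_{a in G_g(x)} p(a | x) / p(G_g(x) | x) * mu(a, x)`.
#'
#' @param spec a [scenario_spec()].
#' @param partition a [treatment_partition()] of the scenario's arms.
#' @param groups recommended group per test row (integer vector, or a
#'   function of the covariate matrix).
#' @param X_test covariate matrix of test rows.
#' @return the oracle value (scalar).
#' @export
test_value <- function(spec, partition, groups, X_test) {
  X_test <- as.matrix(X_test)
  if (is.function(groups)) groups <- groups(X_test)
  groups <- as.integer(groups)
  eff <- group_effect_matrix(spec, X_test, partition)
  mean(eff[cbind(seq_len(nrow(X_test)), groups)])
}

#' Group-based misclassification rate against the oracle
#'
#' Fraction of test rows at which the recommended group's conditional value
#' `sum_{a in G} p(a|x)/p(G|x) mu(a, x)` falls short of the best achievable
#' arm mean `max_a mu(a, x)` by more than `1e-9`.  Under exactly homogeneous
#' groups and the generating partition this coincides with the
#' individual-treatment misclassification rate.
#'
#' @inheritParams test_value
#' @return misclassification rate in `[0, 1]`.
#' @export
misclassification <- function(spec, partition, groups, X_test) {
  X_test <- as.matrix(X_test)
  if (is.function(groups)) groups <- groups(X_test)
  groups <- as.integer(groups)
  eff <- group_effect_matrix(spec, X_test, partition)
  chosen <- eff[cbind(seq_len(nrow(X_test)), groups)]
  mu <- oracle_mu(spec, X_test)
  best <- mu[cbind(seq_len(nrow(X_test)), max.col(mu, ties.method = "first"))]
  mean(best - chosen > 1e-9)
}

#' Replicated simulation benchmark
#'
#' Repeats, for `n_reps` independent replicates: generate a training set
#' from the scenario, fit the pipeline (or apply the oracle rule), generate
#' an independent test covariate sample, and record whether the estimated
#' partition matches the generating one, the oracle value of the fitted
#' rule, and its misclassification rate.  Aggregates the recovery `ratio`
#' and root-mean-square errors of the value and of the misclassification
#' rate.  The value error of a replicate is the mean regret on its test
#' sample — the empirical optimal value `mean(max_a mu(a, X))` minus the
#' empirical value of the fitted rule, both on the same covariate draw, so
#' that the covariate-sampling noise common to the two means cancels and
#' the error measures only the quality of the rule.
#'
#' @param spec a [scenario_spec()].
#' @param config a [growl_config()], or the string `"oracle"` to evaluate
#'   the generating partition with the Bayes group rule (plumbing check).
#' @param n_train,n_test training and test sample sizes.
#' @param n_reps number of replicates.
#' @param master_seed integer master seed; every replicate derives its own
#'   seeds from it.
#' @param v_opt pre-computed oracle optimal value (computed internally when
#'   `NULL`).
#' @return an object of class `replication_summary`: list with `ratio`,
#'   `rmse_value`, `rmse_misclass`, the oracle value `v_opt`, a per-rep
#'   data frame `reps`, and counts of failed replicates.
#' @export
run_replications <- function(spec, config, n_train, n_test = 10000L,
                             n_reps = 30L, master_seed = 1L, v_opt = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), n_reps >= 1)
  if (is.null(v_opt)) {
    v_opt <- oracle_optimal_value(spec, seed = derive_seed(master_seed, "vopt"))
  }
  rows <- vector("list", n_reps)
  failures <- 0L
  for (r in seq_len(n_reps)) {
    res <- tryCatch({
      set.seed(derive_seed(master_seed, "testX", r))
      X_test <- matrix(runif(n_test * spec$d, -1, 1), nrow = n_test)
      if (identical(config, "oracle")) {
        part <- spec$delta0
        groups <- oracle_group_rule(spec, X_test)
      } else {
        train <- generate_scenario(spec, n_train,
                                   seed = derive_seed(master_seed, "train", r))
        fit <- fit_growl(train, config, seed = derive_seed(master_seed, "fit", r))
        part <- fit$partition
        groups <- fit$rule(X_test)
      }
      recovered <- partitions_equal(part, spec$delta0)
      mu <- oracle_mu(spec, X_test)
      v_opt_rep <- mean(mu[cbind(seq_len(n_test),
                                 max.col(mu, ties.method = "first"))])
      data.frame(
        rep = r,
        recovered = recovered,
        value = test_value(spec, part, groups, X_test),
        v_opt_rep = v_opt_rep,
        misclass = misclassification(spec, part, groups, X_test)
      )
    }, error = function(e) {
      warning("replicate ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failures <- failures + 1L else rows[[r]] <- res
  }
  reps <- do.call(rbind, rows)
  if (is.null(reps) || nrow(reps) == 0) stop("all replicates failed")
  structure(list(
    scenario = spec$id, design = spec$design, n_train = n_train,
    n_reps = n_reps, n_failed = failures, v_opt = v_opt,
    ratio = mean(reps$recovered),
    rmse_value = sqrt(mean((reps$value - reps$v_opt_rep)^2)),
    rmse_misclass = sqrt(mean(reps$misclass^2)),
    reps = reps
  ), class = "replication_summary")
}

#' @export
print.replication_summary <- function(x, ...) {
  cat("Scenario ", x$scenario, " (", x$design, "), n_train = ", x$n_train,
      ", ", nrow(x$reps), "/", x$n_reps, " replicates\n", sep = "")
  cat(sprintf("  partition recovery ratio: %.3f\n", x$ratio))
  cat(sprintf("  value rmse (vs oracle %.3f): %.4f\n", x$v_opt, x$rmse_value))
  cat(sprintf("  misclassification rmse:   %.4f\n", x$rmse_misclass))
  invisible(x)
}
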