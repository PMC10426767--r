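#' Simulation scenario specifications
#'
#' Four benchmark data-generating processes with many treatment arms and a
#' latent group structure.  Covariates are `X1..X10 ~ U[-1, 1]` i.i.d. and
#' outcomes are Gaussian with unit standard deviation around
#' `mu(a, x) = 1 + 2 x1 + x2 + 0.5 x3 + T0(x, a)`:
#' \describe{
#'   \item{S1}{10 arms, 2 homogeneous groups `{1..5}, {6..10}`, linear
#'     interaction `T0 = 1.8 (0.2 - x1 - x2) * (-1 or +1)` by group.}
#'   \item{S2}{as S1 with the circular boundary
#'     `T0 = 3.5 (0.8 - x1^2 - x2^2) * (-1 or +1)`.}
#'   \item{S3}{15 arms, 3 homogeneous groups of 5 with linear group effects
#'     `5(-0.2 + x1 + 2 x2)`, `5(0.3 + 2 x1 + x2)`, `5(-0.2 + 3 x1)`.}
#'   \item{S4}{10 arms; S1's interaction with the group sign perturbed per
#'     arm to `-1 - a/theta` (arms 1..5) and `1 + (a-5)/theta` (arms 6..10),
#'     so the groups are only nearly homogeneous; `theta = Inf` recovers
#'     S1 exactly and smaller `theta` makes arms within a group more
#'     diverse.}
#' }
#' Propensities are covariate-independent: `1/M` per arm in the balanced
#' design, and a fixed unbalanced vector (smallest entry 1/20) otherwise.
#'
#' @param id one of `"S1"`, `"S2"`, `"S3"`, `"S4"`.
#' @param design `"balanced"` or `"unbalanced"`.
#' @param theta positive heterogeneity parameter for S4 (`Inf` allowed).
#' @return an object of class `scenario_spec` with fields `id`, `M`, `K0`,
#'   `delta0` (the generating [treatment_partition()]), `design`, `theta`,
#'   `d = 10`.
#' @export
scenario_spec <- function(id = c("S1", "S2", "S3", "S4"),
                          design = c("balanced", "unbalanced"),
                          theta = Inf) {
  id <- match.arg(id)
  design <- match.arg(design)
  if (id == "S4") {
    if (!is.numeric(theta) || theta <= 0) stop_invalid("theta must be > 0")
  }
  M <- if (id == "S3") 15L else 10L
  K0 <- if (id == "S3") 3L else 2L
  delta0 <- treatment_partition(rep(seq_len(K0), each = 5L), K0)
  structure(list(id = id, M = M, K0 = K0, delta0 = delta0,
                 design = design, theta = theta, d = 10L),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario", x$id, "(", x$design, "design ):", x$M, "arms,",
      x$K0, "generating groups")
  if (x$id == "S4") cat(", theta =", x$theta)
  cat("\n")
  invisible(x)
}

#' True mean-outcome function of a scenario
#'
#' Evaluates `E[R | A = a, X = x] = 1 + 2 x1 + x2 + 0.5 x3 + T0(x, a)` for
#' every arm at each covariate row.
#'
#' @param spec a [scenario_spec()].
#' @param X covariate matrix with `d = 10` columns (a single vector is
#'   accepted).
#' @param a optional single arm; if omitted the full `n x M` matrix of arm
#'   means is returned.
#' @return numeric vector (when `a` given) or `n x M` matrix.
#' @export
oracle_mu <- function(spec, X, a = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != spec$d) stop_invalid("X must have ", spec$d, " columns")
  main <- 1 + 2 * X[, 1] + X[, 2] + 0.5 * X[, 3]
  contrast <- switch(spec$id,
    S1 = ,
    S4 = 1.8 * (0.2 - X[, 1] - X[, 2]),
    S2 = 3.5 * (0.8 - X[, 1]^2 - X[, 2]^2),
    S3 = NULL
  )
  arm_mu <- function(arm) {
    if (arm < 1 || arm > spec$M) stop_invalid("arm must lie in 1..", spec$M)
    t0 <- switch(spec$id,
      S1 = contrast * ifelse(arm <= 5, -1, 1),
      S2 = contrast * ifelse(arm <= 5, -1, 1),
      S3 = 5 * (if (arm <= 5) (-0.2 + X[, 1] + 2 * X[, 2])
                else if (arm <= 10) (0.3 + 2 * X[, 1] + X[, 2])
                else (-0.2 + 3 * X[, 1])),
      S4 = {
        shift <- if (is.finite(spec$theta)) {
          if (arm <= 5) -1 - arm / spec$theta else 1 + (arm - 5) / spec$theta
        } else {
          if (arm <= 5) -1 else 1
        }
        contrast * shift
      }
    )
    main + t0
  }
  if (!is.null(a)) return(arm_mu(a))
  out <- vapply(seq_len(spec$M), arm_mu, numeric(nrow(X)))
  if (!is.matrix(out)) out <- matrix(out, nrow = 1)
  out
}

#' Treatment propensity vector of a scenario
#'
#' Covariate-independent assignment probabilities: `1/M` per arm for the
#' balanced design; the fixed unbalanced vectors (built from exact
#' fractions, summing to 1) otherwise.
#'
#' @param spec a [scenario_spec()].
#' @return numeric vector of length `M` summing to 1.
#' @export
propensity_vector <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$design == "balanced") return(rep(1 / spec$M, spec$M))
  if (spec$id == "S3") {
    c(1, 1, 1, 0, 0, 1, 1, 1, 0, 0, 1, 1, 0, 0, 0) / 20 +
      c(0, 0, 0, 11, 11, 0, 0, 0, 11, 11, 0, 0, 0, 0, 0) / 120 +
      c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 7, 7, 7) / 90
  } else {
    c(1 / 20, 1 / 20, 1 / 20, 3 / 20, 1 / 5,
      1 / 20, 1 / 20, 1 / 10, 1 / 10, 1 / 5)
  }
}

#' Generate a synthetic trial dataset from a scenario
#'
#' Draws `X ~ U[-1, 1]^10`, samples arms from the scenario's propensity
#' vector, and sets `R = mu(A, X) + N(0, 1)`.  The propensity matrix of the
#' returned dataset holds the exact generating probabilities.
#'
#' @param spec a [scenario_spec()].
#' @param n number of subjects.
#' @param seed integer seed.
#' @return a [trial_dataset()] with the scenario stored in attribute
#'   `"scenario"`.
#' @export
generate_scenario <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "scenario_spec"), n >= 1)
  set.seed(seed)
  X <- matrix(runif(n * spec$d, -1, 1), nrow = n)
  colnames(X) <- paste0("x", seq_len(spec$d))
  pvec <- propensity_vector(spec)
  A <- sample.int(spec$M, n, replace = TRUE, prob = pvec)
  mu <- oracle_mu(spec, X)
  R <- mu[cbind(seq_len(n), A)] + rnorm(n)
  ds <- trial_dataset(X, A, R, matrix(pvec, nrow = n, ncol = spec$M,
                                      byrow = TRUE), M = spec$M)
  attr(ds, "scenario") <- spec
  ds
}

# propensity-weighted within-group mean outcome for each group of a
# partition: E[R | A in G_k, X = x]; n x K matrix
group_effect_matrix <- function(spec, X, partition) {
  mu <- oracle_mu(spec, X)
  pvec <- propensity_vector(spec)
  K <- partition$K
  out <- matrix(0, nrow = nrow(mu), ncol = K)
  for (k in seq_len(K)) {
    arms <- which(partition$labels == k)
    w <- pvec[arms] / sum(pvec[arms])
    out[, k] <- mu[, arms, drop = FALSE] %*% w
  }
  out
}

#' Oracle group rule and oracle optimal value
#'
#' `oracle_group_rule` returns, for each covariate row, the generating-
#' partition group with the largest conditional group effect (the Bayes
#' group rule under `delta0`).  `oracle_optimal_value` is the Monte-Carlo
#' mean over the covariate distribution of the best achievable arm mean
#' `max_a mu(a, X)` — the value of the unrestricted optimal ITR, used as the
#' reference for value mean-squared errors.
#'
#' @param spec a [scenario_spec()].
#' @param X covariate matrix.
#' @return integer group labels.
#' @export
oracle_group_rule <- function(spec, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  eff <- group_effect_matrix(spec, X, spec$delta0)
  as.integer(max.col(eff, ties.method = "first"))
}

#' @rdname oracle_group_rule
#' @param n_mc Monte-Carlo sample size.
#' @param seed integer seed.
#' @export
oracle_optimal_value <- function(spec, n_mc = 2e5, seed = 1L) {
  set.seed(seed)
  X <- matrix(runif(n_mc * spec$d, -1, 1), nrow = n_mc)
  mu <- oracle_mu(spec, X)
  mean(mu[cbind(seq_len(n_mc), max.col(mu, ties.method = "first"))])
}
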