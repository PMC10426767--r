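#' RAMSVM surrogate loss
#'
#' The reinforced angle-based multicategory SVM loss: a convex combination of
#' a sum of hinges pushing `f(x)` away from the wrong vertices and a hinge
#' pulling it toward the labeled vertex,
#' \deqn{L_\phi(c, f) = (1-\gamma)\sum_{k \ne c}(1 + \langle W_k, f\rangle)_+
#'   + \gamma\,(K - 1 - \langle W_c, f\rangle)_+ .}
#'
#' @param group_label integer label in `1..K`.
#' @param f_value numeric vector of length `K - 1`.
#' @param gamma mixing weight in `[0, 1]`.
#' @param code a [simplex_code()].
#' @return nonnegative loss value.
#' @export
ramsvm_loss <- function(group_label, f_value, gamma, code) {
  stopifnot(inherits(code, "simplex_code"))
  check_scalar(gamma, "gamma", 0, 1)
  K <- code$K
  group_label <- as.integer(group_label)
  if (group_label < 1L || group_label > K) stop_invalid("label must lie in 1..K")
  if (length(f_value) != K - 1L) stop_invalid("f_value must have length K - 1")
  ip <- drop(code$W %*% f_value)
  wrong <- sum(pmax(1 + ip[-group_label], 0))
  right <- max(K - 1 - ip[group_label], 0)
  (1 - gamma) * wrong + gamma * right
}

# kernel matrix between row sets; kernel is "linear" or "rbf" with
# kappa(x, x') = exp(-sigma2 * ||x - x'||^2)
kernel_matrix <- function(X1, X2, kernel, sigma2 = NULL) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (kernel == "linear") return(tcrossprod(X1, X2))
  if (kernel != "rbf") stop_invalid("unknown kernel: ", kernel)
  if (is.null(sigma2) || sigma2 <= 0) stop_invalid("rbf kernel needs sigma2 > 0")
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  exp(-sigma2 * d2)
}

new_dual_state <- function(fit) {
  structure(list(alpha = fit$alpha, upper = fit$upper,
                 objective = fit$objective,
                 objective_trace = fit$objective_trace,
                 sweeps = fit$sweeps, max_kkt = fit$max_kkt,
                 converged = fit$converged),
            class = "dual_state")
}

#' Solve the linear RAMSVM dual by coordinate descent
#'
#' Minimizes the box-constrained dual quadratic program of the weighted
#' RAMSVM with linear decision functions `f_k(x) = x' beta_k` (covariates
#' augmented with a leading constant 1, so the intercept is part of the
#' penalized coefficient vector).  Each coordinate update is an exact 1-D
#' quadratic minimization clipped to its box, so the dual objective is
#' non-increasing; convergence is declared when every coordinate's box-KKT
#' residual is below `tol`.  The primal coefficients are recovered as
#' `beta_k = u_k / (n lambda)` from the optimal multipliers.
#'
#' @param records a [weighted_records()] object.
#' @param code a [simplex_code()] with `K` equal to the records' group count.
#' @param lambda positive regularization parameter.
#' @param gamma loss mixing weight, default 0.5.
#' @param tol KKT tolerance, default `1e-6`.
#' @param max_sweeps maximum number of cyclic sweeps, default 500.
#' @return a list with components `dual` (a `dual_state`) and `model`
#'   (a `linear_decision_model` with coefficient matrix `B` of size
#'   `(K-1) x (d+1)`).
#' @export
solve_dual_linear <- function(records, code, lambda, gamma = 0.5,
                              tol = 1e-6, max_sweeps = 500L) {
  stopifnot(inherits(records, "weighted_records"),
            inherits(code, "simplex_code"))
  if (!is.numeric(lambda) || lambda <= 0) stop_invalid("lambda must be > 0")
  check_scalar(gamma, "gamma", 0, 1)
  if (records$K != code$K) stop_invalid("records and code disagree on K")
  if (length(records$label) == 0) stop_invalid("records must be nonempty")
  Xa <- cbind(1, records$X)
  fit <- .cd_ramsvm_linear(Xa, records$label, records$weight, code$W,
                           records$n_eff, lambda, gamma, tol,
                           as.integer(max_sweeps))
  if (!fit$converged && fit$max_kkt > 1e-3) {
    # the dual state always records convergence; warn only when the
    # remaining KKT residual is material
    warning("coordinate descent did not reach tol ", tol, " after ",
            max_sweeps, " sweeps (max KKT residual ",
            format(fit$max_kkt, digits = 3), ")")
  }
  model <- structure(
    list(B = fit$B, K = code$K, d = ncol(records$X), code = code,
         lambda = lambda, gamma = gamma),
    class = c("linear_decision_model", "decision_model")
  )
  list(dual = new_dual_state(fit), model = model)
}

#' Solve the kernel RAMSVM dual by coordinate descent
#'
#' Kernel analogue of [solve_dual_linear()] for decision functions
#' `f_k(x) = theta_{k,0} + sum_i theta_{k,i} kappa(X_i, x)` in a product
#' RKHS.  The dual quadratic couples the multipliers through the Gram matrix
#' and, via an explicit intercept term, through the column sums; both the
#' kernel coefficients `theta_k` and the intercepts `theta_{k,0}` are
#' recovered in closed form from the optimal multipliers.  The Gram matrix
#' must be (numerically) invertible; a near-singular Gram matrix is
#' stabilized with a small diagonal jitter when `jitter = TRUE`, otherwise
#' it is an error.
#'
#' @inheritParams solve_dual_linear
#' @param kernel `"linear"` or `"rbf"`.
#' @param sigma2 RBF inverse-bandwidth parameter in
#'   `kappa(x, x') = exp(-sigma2 ||x - x'||^2)`; see [rbf_sigma()].
#' @param jitter add diagonal jitter `1e-8 * mean(diag(G))` (with a warning)
#'   when the Gram matrix is numerically singular, instead of erroring.
#' @return a list with `dual` and `model` (a `kernel_decision_model`).
#' @export
solve_dual_kernel <- function(records, code, kernel = c("rbf", "linear"),
                              sigma2 = NULL, lambda, gamma = 0.5,
                              tol = 1e-6, max_sweeps = 500L,
                              jitter = TRUE) {
  stopifnot(inherits(records, "weighted_records"),
            inherits(code, "simplex_code"))
  kernel <- match.arg(kernel)
  if (!is.numeric(lambda) || lambda <= 0) stop_invalid("lambda must be > 0")
  check_scalar(gamma, "gamma", 0, 1)
  if (records$K != code$K) stop_invalid("records and code disagree on K")
  if (length(records$label) == 0) stop_invalid("records must be nonempty")
  G <- kernel_matrix(records$X, records$X, kernel, sigma2)
  rc <- rcond(G)
  if (!is.finite(rc) || rc < 1e-12) {
    if (!jitter) {
      stop_invalid("Gram matrix is numerically singular ",
                   "(reciprocal condition number ", format(rc, digits = 3),
                   "); deduplicate covariate rows or allow jitter")
    }
    warning("Gram matrix numerically singular; adding diagonal jitter")
    G <- G + diag(1e-8 * mean(diag(G)), nrow(G))
    if (rcond(G) < 1e-14) stop_invalid("Gram matrix singular even after jitter")
  }
  fit <- .cd_ramsvm_kernel(G, records$label, records$weight, code$W,
                           records$n_eff, lambda, gamma, tol,
                           as.integer(max_sweeps))
  if (!fit$converged && fit$max_kkt > 1e-3) {
    warning("coordinate descent did not reach tol ", tol, " after ",
            max_sweeps, " sweeps (max KKT residual ",
            format(fit$max_kkt, digits = 3), ")")
  }
  model <- structure(
    list(kernel = kernel, sigma2 = sigma2, train_X = records$X,
         Theta = fit$Theta, intercepts = drop(fit$intercepts),
         G = G, K = code$K, d = ncol(records$X), code = code,
         lambda = lambda, gamma = gamma),
    class = c("kernel_decision_model", "decision_model")
  )
  list(dual = new_dual_state(fit), model = model)
}

#' Evaluate a decision model and assign treatment groups
#'
#' Evaluates the fitted decision function `f` at new covariate rows and
#' applies the angle-based rule `argmax_k <W_k, f(x)>` (smallest index on
#' ties).
#'
#' @param object a `linear_decision_model` or `kernel_decision_model`.
#' @param X_new numeric matrix of new covariate rows (unaugmented).
#' @param ... unused.
#' @return a list with `f_values` (`m x (K-1)`) and integer `groups`.
#' @export
predict.linear_decision_model <- function(object, X_new, ...) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != object$d) {
    stop_invalid("model expects ", object$d, " covariates, got ", ncol(X_new))
  }
  f <- cbind(1, X_new) %*% t(object$B)
  list(f_values = f, groups = decide_group(object$code, f))
}

#' @rdname predict.linear_decision_model
#' @export
predict.kernel_decision_model <- function(object, X_new, ...) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != object$d) {
    stop_invalid("model expects ", object$d, " covariates, got ", ncol(X_new))
  }
  Kx <- kernel_matrix(X_new, object$train_X, object$kernel, object$sigma2)
  f <- sweep(Kx %*% object$Theta, 2, -object$intercepts)
  list(f_values = f, groups = decide_group(object$code, f))
}

# squared function norm of a fitted model, matching the (lambda/2)||f||^2
# penalty the dual optimizes: sum_k beta_k'beta_k for linear models,
# sum_k theta_k' G theta_k + theta_{k,0}^2 for kernel models
model_norm2 <- function(model) {
  if (inherits(model, "linear_decision_model")) {
    sum(model$B^2)
  } else {
    sum(vapply(seq_len(model$K - 1L), function(k) {
      th <- model$Theta[, k]
      drop(crossprod(th, model$G %*% th)) + model$intercepts[k]^2
    }, numeric(1)))
  }
}

# Relabel a fitted decision model's groups by `perm` (perm[old] = new).
# The regular simplex is symmetric, so the vertex permutation W_k -> W_perm[k]
# extends to the linear map Q = ((K-1)/K) W' P W on f-space (W'W is
# (K/(K-1)) I because the rows are unit vectors with equal pairwise inner
# products summing to zero); transformed scores satisfy
# <W_perm[k], Q f> = <W_k, f> exactly.
permute_decision_model <- function(model, perm) {
  K <- model$K
  W <- model$code$W
  P <- matrix(0, K, K)
  P[cbind(perm, seq_len(K))] <- 1
  Q <- ((K - 1) / K) * t(W) %*% P %*% W
  if (inherits(model, "linear_decision_model")) {
    model$B <- Q %*% model$B
  } else {
    model$Theta <- model$Theta %*% t(Q)
    model$intercepts <- drop(Q %*% model$intercepts)
  }
  model
}
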