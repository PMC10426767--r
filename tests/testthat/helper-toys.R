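# Shared builders for small synthetic problems and the generic convex-QP
# reference solver used to validate the coordinate-descent duals.

# a tiny two-group trial with strong linear interaction: arms 1..M split
# into two homogeneous groups whose effect is +/- sgn * (x1 + offset)
toy_two_group <- function(n = 300, M = 4, effect = 3, noise = 0.5,
                          seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n * 2, -1, 1), n, 2)
  A <- sample.int(M, n, replace = TRUE)
  grp <- ifelse(A <= M / 2, -1, 1)
  R <- 1 + X[, 1] + effect * (0.1 - X[, 1] - X[, 2]) * grp +
    noise * rnorm(n)
  trial_dataset(X, A, R, matrix(1 / M, n, M))
}

toy_true_partition <- function(M = 4) {
  treatment_partition(rep(1:2, each = M / 2))
}

# explicit dual QP matrices of the linear RAMSVM dual for a record set:
# variables alpha_{ij} stacked record-major; returns H, linear coefficients
# and box bounds such that the dual is min 0.5 a'Ha - lin'a, 0 <= a <= up
linear_dual_qp <- function(records, code, lambda, gamma) {
  Xa <- cbind(1, records$X)
  m <- nrow(Xa)
  K <- code$K
  nv <- m * K
  Gmat <- matrix(0, (K - 1) * ncol(Xa), nv)
  lin <- numeric(nv)
  up <- numeric(nv)
  idx <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(K)) {
      idx <- idx + 1
      ci <- records$label[i]
      s <- if (j == ci) code$W[ci, ] else -code$W[j, ]
      Gmat[, idx] <- as.vector(outer(Xa[i, ], s))
      lin[idx] <- if (j == ci) K - 1 else 1
      up[idx] <- records$weight[i] * (if (j == ci) gamma else 1 - gamma)
    }
  }
  list(H = crossprod(Gmat) / (records$n_eff * lambda), lin = lin, up = up,
       Gmat = Gmat)
}

# explicit dual QP of the kernel RAMSVM dual (Gram + intercept coupling)
kernel_dual_qp <- function(records, code, G, lambda, gamma) {
  m <- nrow(G)
  K <- code$K
  nv <- m * K
  Cm <- matrix(0, m * (K - 1), nv)
  lin <- numeric(nv)
  up <- numeric(nv)
  idx <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(K)) {
      idx <- idx + 1
      ci <- records$label[i]
      s <- if (j == ci) code$W[ci, ] else -code$W[j, ]
      for (k in seq_len(K - 1)) Cm[(k - 1) * m + i, idx] <- s[k]
      lin[idx] <- if (j == ci) K - 1 else 1
      up[idx] <- records$weight[i] * (if (j == ci) gamma else 1 - gamma)
    }
  }
  Gblk <- kronecker(diag(K - 1), G + matrix(1, m, m))
  list(H = t(Cm) %*% Gblk %*% Cm / (records$n_eff * lambda), lin = lin,
       up = up)
}

# generic box-constrained convex-QP reference: projected quasi-Newton via
# L-BFGS-B on the explicit quadratic (independent of the coordinate-descent
# implementation under test)
qp_oracle <- function(H, lin, up) {
  fn <- function(a) 0.5 * sum(a * (H %*% a)) - sum(lin * a)
  gr <- function(a) drop(H %*% a) - lin
  o <- stats::optim(rep(0, length(lin)), fn, gr, method = "L-BFGS-B",
                    lower = 0, upper = up,
                    control = list(maxit = 5000, factr = 10))
  list(alpha = o$par, objective = o$value)
}

# two-point covariate problem with three homogeneous treatment groups and
# known conditional group effects; the Bayes group rule is group 1 at
# x = -1 and group 3 at x = +1
toy_two_point <- function(n = 1500, seed = 1, noise = 0) {
  set.seed(seed)
  x <- sample(c(-1, 1), n, replace = TRUE)
  mu <- cbind(2 - 2 * pmax(x, 0),      # group 1: 2 at x=-1, 0 at x=+1
              1,                       # group 2: 1 everywhere
              2 + 2 * pmin(x, 0))      # group 3: 0 at x=-1, 2 at x=+1
  A <- sample.int(3, n, replace = TRUE)
  R <- mu[cbind(seq_len(n), A)] + noise * rnorm(n)
  trial_dataset(matrix(x, ncol = 1), A, R, matrix(1 / 3, n, 3))
}
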