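test_that("RAMSVM loss matches hand-computed values", {
  s3 <- simplex_code(3)
  # all inner products zero: (1-g)*2*1 + g*(K-1)
  expect_equal(ramsvm_loss(1, c(0, 0), 0.5, s3), 2)
  expect_equal(ramsvm_loss(2, c(0, 0), 0.5, s3), 2)
  # f = (K-1) W_k: zero loss for label k
  for (k in 1:3) {
    expect_equal(ramsvm_loss(k, 2 * s3$W[k, ], 0.5, s3), 0, tolerance = 1e-12)
  }
  # binary hand evaluation
  s2 <- simplex_code(2)
  expect_equal(ramsvm_loss(1, -0.5, 0.5, s2), 1.5)
  expect_error(ramsvm_loss(1, c(0, 0), 1.2, s3),
               class = "growl_invalid_argument")
})

test_that("intercept-only single-record dual matches the closed form", {
  # objective reduces to s^2/(2 lambda) - s over s in [0, 1], minimized at
  # s = lambda: objective -lambda/2, recovered beta = 1
  rec <- weighted_records(X = matrix(0, 1, 0), label = 1, weight = 1, K = 2,
                          n_eff = 1)
  fit <- solve_dual_linear(rec, simplex_code(2), lambda = 0.25, gamma = 0.5)
  expect_equal(fit$dual$objective, -0.125, tolerance = 1e-10)
  expect_equal(drop(fit$model$B), 1, tolerance = 1e-10)
  expect_equal(sum(fit$dual$alpha), 0.25, tolerance = 1e-8)
})

test_that("degenerate inputs give zero solutions and argument errors", {
  rec0 <- weighted_records(matrix(rnorm(6), 3, 2), c(1, 2, 1), rep(0, 3),
                           K = 2, n_eff = 3)
  fit <- solve_dual_linear(rec0, simplex_code(2), lambda = 1)
  expect_equal(fit$model$B, matrix(0, 1, 3), ignore_attr = TRUE)
  expect_equal(fit$dual$objective, 0)
  kfit <- solve_dual_kernel(rec0, simplex_code(2), kernel = "rbf",
                            sigma2 = 1, lambda = 1)
  expect_equal(kfit$model$Theta, matrix(0, 3, 1), ignore_attr = TRUE)
  expect_equal(kfit$model$intercepts, 0)

  expect_error(solve_dual_linear(rec0, simplex_code(2), lambda = -1),
               class = "growl_invalid_argument")
})

test_that("coordinate descent matches a generic convex-QP reference", {
  # linear dual, several seeded instances with n_rec * K <= 60
  for (seed in c(7, 8)) {
    set.seed(seed)
    m <- 8; K <- 3
    rec <- weighted_records(matrix(rnorm(m * 2), m, 2),
                            sample.int(K, m, TRUE),
                            runif(m, 0.2, 2), K = K, n_eff = m)
    code <- simplex_code(K)
    lam <- 0.5; gam <- 0.4
    fit <- solve_dual_linear(rec, code, lambda = lam, gamma = gam,
                             tol = 1e-10, max_sweeps = 5000)
    qp <- linear_dual_qp(rec, code, lam, gam)
    orc <- qp_oracle(qp$H, qp$lin, qp$up)
    expect_lt(abs(fit$dual$objective - orc$objective), 1e-6)
    # primal recovery agrees with the oracle multipliers
    B_orc <- matrix(qp$Gmat %*% orc$alpha / (m * lam), nrow = K - 1,
                    byrow = TRUE)
    expect_lt(max(abs(fit$model$B - B_orc)), 1e-4)
  }

  # kernel dual (RBF), n_rec * K <= 60
  set.seed(11)
  m <- 6; K <- 2
  rec <- weighted_records(matrix(rnorm(m * 2), m, 2),
                          sample.int(K, m, TRUE),
                          runif(m, 0.3, 1.5), K = K, n_eff = m)
  code <- simplex_code(K)
  kfit <- solve_dual_kernel(rec, code, kernel = "rbf", sigma2 = 1,
                            lambda = 0.3, gamma = 0.5,
                            tol = 1e-10, max_sweeps = 5000)
  G <- exp(-as.matrix(dist(rec$X))^2)
  qpk <- kernel_dual_qp(rec, code, G, 0.3, 0.5)
  orck <- qp_oracle(qpk$H, qpk$lin, qpk$up)
  expect_lt(abs(kfit$dual$objective - orck$objective), 1e-6)
})

test_that("dual objective is non-increasing and box-KKT holds at exit", {
  set.seed(13)
  m <- 30; K <- 3
  rec <- weighted_records(matrix(rnorm(m * 4), m, 4),
                          sample.int(K, m, TRUE),
                          runif(m, 0, 2), K = K, n_eff = m)
  fit <- solve_dual_linear(rec, simplex_code(K), lambda = 0.2, gamma = 0.5,
                           tol = 1e-8, max_sweeps = 5000)
  tr <- fit$dual$objective_trace
  expect_true(all(diff(tr) <= 1e-10))
  expect_lt(fit$dual$max_kkt, 1e-6)
  # multipliers inside the box
  expect_true(all(fit$dual$alpha >= 0))
  expect_true(all(fit$dual$alpha <= fit$dual$upper + 1e-12))

  kfit <- solve_dual_kernel(rec, simplex_code(K), kernel = "rbf",
                            sigma2 = 0.5, lambda = 0.2, tol = 1e-8,
                            max_sweeps = 5000)
  expect_true(all(diff(kfit$dual$objective_trace) <= 1e-10))
  expect_lt(kfit$dual$max_kkt, 1e-6)
})

test_that("exactly singular Gram matrices error without jitter", {
  X <- matrix(rnorm(8), 4, 2)
  X[3, ] <- X[1, ] # duplicated covariate row -> singular linear Gram
  rec <- weighted_records(X, c(1, 2, 1, 2), rep(1, 4), K = 2, n_eff = 4)
  expect_error(
    solve_dual_kernel(rec, simplex_code(2), kernel = "linear", lambda = 1,
                      jitter = FALSE),
    class = "growl_invalid_argument"
  )
  # with jitter the solve proceeds under a warning
  expect_warning(
    fit <- solve_dual_kernel(rec, simplex_code(2), kernel = "linear",
                             lambda = 1, jitter = TRUE),
    "jitter"
  )
  expect_true(fit$dual$converged)
})

test_that("prediction applies the angle rule with the tie-break", {
  zero <- structure(
    list(B = matrix(0, 2, 4), K = 3L, d = 3L, code = simplex_code(3)),
    class = c("linear_decision_model", "decision_model"))
  pr <- predict(zero, matrix(rnorm(15), 5, 3))
  expect_equal(pr$groups, rep(1L, 5))
  expect_equal(pr$f_values, matrix(0, 5, 2))
  expect_error(predict(zero, matrix(0, 2, 2)),
               class = "growl_invalid_argument")

  # predictions invariant to positive rescaling of the coefficients
  set.seed(3)
  mod <- zero
  mod$B <- matrix(rnorm(8), 2, 4)
  Xn <- matrix(rnorm(60), 20, 3)
  mod2 <- mod
  mod2$B <- 7.3 * mod$B
  expect_equal(predict(mod, Xn)$groups, predict(mod2, Xn)$groups)
})

test_that("linear solver and linear-kernel solver give similar rules", {
  set.seed(17)
  ds <- toy_two_group(n = 120, M = 4, seed = 17)
  part <- toy_true_partition(4)
  s <- fit_main_effect(ds)
  rec <- transform_residuals(ds, part, s)
  code <- simplex_code(2)
  lin <- solve_dual_linear(rec, code, lambda = 0.1)
  ker <- solve_dual_kernel(rec, code, kernel = "linear", lambda = 0.1)
  grid <- matrix(runif(400, -1, 1), 200, 2)
  agree <- mean(predict(lin$model, grid)$groups ==
                  predict(ker$model, grid)$groups)
  # intercept handling differs between the two duals, so require soft
  # agreement rather than equality
  expect_gte(agree, 0.9)
})

test_that("relabeling a fitted model permutes its predictions exactly", {
  set.seed(19)
  for (K in c(2, 4)) {
    rec <- weighted_records(matrix(rnorm(90), 30, 3),
                            sample.int(K, 30, TRUE),
                            runif(30, 0.1, 2), K = K, n_eff = 30)
    fit <- solve_dual_linear(rec, simplex_code(K), lambda = 0.5)
    perm <- sample(K)
    m2 <- growl:::permute_decision_model(fit$model, perm)
    Xn <- matrix(rnorm(150), 50, 3)
    expect_equal(predict(m2, Xn)$groups, perm[predict(fit$model, Xn)$groups])
  }
})
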