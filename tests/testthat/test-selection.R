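test_that("normalized value estimator matches hand arithmetic", {
  # subjects: (R, p(obs group), match): (2,0.5,yes) (1,0.25,yes) (3,0.5,no)
  X <- matrix(0, 3, 1)
  prop <- matrix(c(0.5, 0.25, 0.25,
                   0.25, 0.5, 0.25,
                   0.5, 0.25, 0.25), 3, 3, byrow = TRUE)
  ds <- trial_dataset(X, c(1, 1, 1), c(2, 1, 3), prop, M = 3)
  part <- treatment_partition(1:3)
  # observed groups are all 1 with p = 0.5, 0.25, 0.5; rules match 1,1,no
  groups <- c(1L, 1L, 2L)
  expect_equal(estimate_value_group(ds, part, groups), 8 / 6)

  # constant outcomes: ratio self-normalizes to the constant
  dsc <- trial_dataset(X, c(1, 2, 3), rep(4.2, 3), prop, M = 3)
  expect_equal(estimate_value_group(dsc, part, c(1L, 2L, 3L)), 4.2)

  # K = 1 partition: sample mean of R (random recommendation value)
  one <- structure(list(labels = rep(1L, 3), K = 1L, M = 3L),
                   class = "treatment_partition")
  expect_equal(estimate_value_group(ds, one, rep(1L, 3)), 2)

  # no match at all: explicit condition, not NaN
  expect_error(estimate_value_group(ds, part, c(3L, 3L, 3L)),
               class = "growl_no_match")
})

test_that("value estimator is invariant to joint relabeling", {
  ds <- toy_two_group(n = 120, M = 4, seed = 61)
  part <- toy_true_partition(4)
  groups <- sample(1:2, 120, TRUE)
  v1 <- estimate_value_group(ds, part, groups)
  v2 <- estimate_value_group(ds, treatment_partition(3 - part$labels),
                             3L - groups)
  expect_equal(v1, v2)
})

test_that("median-heuristic bandwidth follows the printed rule", {
  # two points at distance 2: tau = 2, sigma2 = 1/8
  expect_equal(rbf_sigma(matrix(c(0, 2), 2, 1)), 1 / 8)
  # kernel value at distance 1 when tau = 1
  X <- matrix(c(0, 1), 2, 1)
  expect_equal(exp(-rbf_sigma(X) * 1^2), exp(-0.5))
  # identical rows are rejected
  expect_error(rbf_sigma(matrix(1, 3, 2)), class = "growl_invalid_argument")
  # duplicating a large sample leaves the median essentially unchanged
  set.seed(62)
  X <- matrix(runif(200), 100, 2)
  expect_equal(rbf_sigma(rbind(X, X)), rbf_sigma(X), tolerance = 0.02)
})

test_that("lambda selection respects the grid and its tie rules", {
  ds <- toy_two_group(n = 80, M = 4, seed = 63)
  cfg <- growl_config(lambda_grid = 0.5, K = 2)
  expect_equal(cv_select_lambda(ds, 2, cfg, seed = 1)$lambda, 0.5)

  # zero-signal outcomes: held-out values agree to within their standard
  # errors, so the guarded selection returns the smallest lambda
  set.seed(64)
  ds0 <- trial_dataset(matrix(runif(160, -1, 1), 80, 2),
                       sample(1:4, 80, TRUE), 1 + 0.1 * rnorm(80),
                       matrix(0.25, 80, 4))
  cfg0 <- growl_config(lambda_grid = c(0.5, 1, 2), n_folds = 4,
                       cv_search = "init", K = 2)
  sel0 <- suppressWarnings(cv_select_lambda(ds0, 2, cfg0, seed = 2))
  expect_equal(sel0$lambda, 0.5)
  expect_true(sel0$lambda %in% cfg0$lambda_grid)

  # deterministic given the seed
  cfg <- growl_config(lambda_grid = c(0.25, 1), n_folds = 4, K = 2)
  s1 <- suppressWarnings(cv_select_lambda(ds, 2, cfg, seed = 5))
  s2 <- suppressWarnings(cv_select_lambda(ds, 2, cfg, seed = 5))
  expect_equal(s1$lambda, s2$lambda)
  expect_equal(s1$mean_values, s2$mean_values)
})

test_that("the cross-validated lambda is no worse than the worst grid point", {
  ds <- toy_two_group(n = 200, M = 4, seed = 65)
  cfg <- growl_config(lambda_grid = c(0.0625, 16), n_folds = 5, K = 2)
  sel <- suppressWarnings(cv_select_lambda(ds, 2, cfg, seed = 3))
  vals <- sel$mean_values
  chosen <- vals[match(sel$lambda, cfg$lambda_grid)]
  expect_gte(chosen + sel$diagnostics$se[which.max(vals)],
             min(vals, na.rm = TRUE))
})

test_that("group-number selection has zero benefit at K = 1 and obeys ties", {
  ds <- toy_two_group(n = 300, M = 4, effect = 4, noise = 0.5, seed = 66)
  cfg <- growl_config(K_range = 2:3, T_splits = 8, lambda = 0.25)
  sel <- suppressWarnings(select_group_number(ds, cfg, seed = 7))
  expect_true(all(sel$trace[, 1] == 0))
  expect_true(sel$K %in% 2:3)
  expect_equal(dim(sel$trace), c(8L, 4L))
  # strong two-group signal: the bipartition should win
  expect_equal(sel$K, 2L)
})

test_that("full pipeline is reproducible and recovers the toy partition", {
  ds <- toy_two_group(n = 250, M = 4, effect = 4, seed = 67)
  cfg <- growl_config(K = 2, lambda_grid = c(0.0625, 0.25, 1), n_folds = 5)
  fit1 <- suppressWarnings(fit_growl(ds, cfg, seed = 8))
  fit2 <- suppressWarnings(fit_growl(ds, cfg, seed = 8))
  expect_true(partitions_equal(fit1$partition, toy_true_partition(4)))
  expect_equal(fit1$partition$labels, fit2$partition$labels)
  expect_equal(fit1$lambda, fit2$lambda)
  expect_equal(fit1$model$B, fit2$model$B)
  expect_type(fit1$rule, "closure")
  expect_equal(predict(fit1, ds$X), fit1$rule(ds$X))
})

test_that("fitting is equivariant to a relabeling of the treatments", {
  ds <- toy_two_group(n = 250, M = 4, effect = 4, seed = 68)
  perm <- c(3L, 1L, 4L, 2L)
  ds_perm <- trial_dataset(ds$X, perm[ds$A], ds$R, ds$prop[, order(perm)])
  cfg <- growl_config(K = 2, lambda = 0.25)
  f1 <- suppressWarnings(fit_growl(ds, cfg, seed = 9))
  f2 <- suppressWarnings(fit_growl(ds_perm, cfg, seed = 9))
  # permuting arm labels permutes the recovered partition accordingly
  expect_true(partitions_equal(
    treatment_partition(f1$partition$labels[order(perm)]),
    treatment_partition(f2$partition$labels)
  ))
})

test_that("degenerate all-zero outcomes give the trivial rule with warning", {
  X <- matrix(runif(80, -1, 1), 40, 2)
  ds <- trial_dataset(X, rep(1:4, 10), rep(0, 40), matrix(0.25, 40, 4))
  cfg <- growl_config(K = 2, lambda = 1)
  expect_warning(fit <- fit_growl(ds, cfg, seed = 10), "degenerate")
  expect_equal(fit$rule(X), rep(1L, 40))
})
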