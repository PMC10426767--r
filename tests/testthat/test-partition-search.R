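test_that("set-partition enumeration counts Stirling numbers", {
  expect_length(growl:::enumerate_partitions(2, 2), 1)  # {1},{2}
  expect_length(growl:::enumerate_partitions(4, 2), 7)  # S(4,2)
  expect_length(growl:::enumerate_partitions(5, 3), 25) # S(5,3)
  # canonical restricted-growth strings, no relabeling duplicates
  keys <- vapply(growl:::enumerate_partitions(4, 2), growl:::partition_key,
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("objective matches hand arithmetic in the flat-decision limit", {
  # two subjects with positive residuals 1 and 2 around s = 0, group
  # propensity 1/2 each, K = 2: at lambda -> infinity f̂ = 0, every loss is
  # K - 1 = 1, so J = (1/2)(2 + 4)*1 - (2/2)(2 + 4) = -3
  X <- matrix(c(0.3, -0.3), 2, 1)
  ds <- trial_dataset(X, c(1, 2), c(1, 2), matrix(0.5, 2, 2))
  s_zero <- structure(list(coef = c(0, 0),
                           fun = function(Xn) rep(0, nrow(Xn))),
                      class = "main_effect")
  res <- objective_for_partition(ds, treatment_partition(1:2),
                                 lambda = 1e8, gamma = 0.5, s = s_zero)
  expect_equal(res$objective, -3, tolerance = 1e-4)

  # zero residuals: zero model, objective 0
  ds0 <- trial_dataset(X, c(1, 2), c(0, 0), matrix(0.5, 2, 2))
  res0 <- objective_for_partition(ds0, treatment_partition(1:2),
                                  lambda = 1, s = s_zero)
  expect_null(res0$model)
  expect_equal(res0$objective, 0)
})

test_that("objective is invariant under group relabeling", {
  ds <- toy_two_group(n = 150, M = 4, seed = 31)
  s <- fit_main_effect(ds)
  for (labels in list(c(1, 1, 2, 2), c(1, 2, 2, 1))) {
    a <- objective_for_partition(ds, treatment_partition(labels), 0.5, s = s)
    b <- objective_for_partition(ds, treatment_partition(3 - labels), 0.5,
                                 s = s)
    expect_equal(a$objective, b$objective, tolerance = 1e-6)
  }
})

test_that("exhaustive search recovers the generating bipartition", {
  ds <- toy_two_group(n = 300, M = 4, seed = 41)
  pf <- exhaustive_search(ds, 2, lambda = 0.25)
  expect_true(partitions_equal(pf$partition, toy_true_partition(4)))
  expect_length(pf$trace, 7)
  # M = 2: single candidate
  ds2 <- toy_two_group(n = 60, M = 2, seed = 42)
  pf2 <- exhaustive_search(ds2, 2, lambda = 0.25)
  expect_equal(pf2$partition$labels, c(1L, 2L))
  # guard on the enumeration size
  expect_error(exhaustive_search(ds, 2, lambda = 0.25, max_candidates = 3),
               class = "growl_invalid_argument")
})

test_that("greedy search matches the exhaustive optimum from every init", {
  ds <- toy_two_group(n = 300, M = 4, seed = 41)
  s <- fit_main_effect(ds)
  best <- exhaustive_search(ds, 2, lambda = 0.25, s = s)
  for (labels in growl:::enumerate_partitions(4, 2)) {
    pf <- greedy_search(ds, 2, treatment_partition(labels), lambda = 0.25,
                        s = s)
    expect_true(partitions_equal(pf$partition, best$partition))
    # accepted moves never increase the objective
    init_obj <- objective_for_partition(ds, treatment_partition(labels),
                                        0.25, s = s)$objective
    expect_lte(pf$objective, init_obj + 1e-10)
  }
})

test_that("greedy with all-singleton groups has no legal moves", {
  ds <- toy_two_group(n = 100, M = 4, seed = 43)
  init <- treatment_partition(1:4)
  pf <- greedy_search(ds, 4, init, lambda = 0.5)
  expect_equal(pf$partition$labels, 1:4)
})

test_that("genetic search is seeded, reproducible and finds the optimum", {
  ds <- toy_two_group(n = 300, M = 4, seed = 41)
  s <- fit_main_effect(ds)
  best <- exhaustive_search(ds, 2, lambda = 0.25, s = s)
  ga1 <- genetic_search(ds, 2, lambda = 0.25, s = s, population = 20,
                        generations = 30, seed = 9)
  ga2 <- genetic_search(ds, 2, lambda = 0.25, s = s, population = 20,
                        generations = 30, seed = 9)
  expect_true(partitions_equal(ga1$partition, best$partition))
  expect_equal(ga1$partition$labels, ga2$partition$labels)
  expect_equal(ga1$objective, ga2$objective)
  # zero generations returns the best of the seeded initial population
  ga0 <- genetic_search(ds, 2, lambda = 0.25, s = s, population = 10,
                        generations = 0, seed = 9)
  expect_s3_class(ga0, "partition_fit")
  expect_error(genetic_search(ds, 2, lambda = 0.25, population = 3),
               class = "growl_invalid_argument")
})

test_that("search returns a model consistent with its canonical labels", {
  # run from an initial labeling whose canonical form permutes the groups
  # and check the fitted rule still recommends the high-outcome group
  ds <- toy_two_group(n = 300, M = 4, effect = 4, noise = 0.2, seed = 44)
  init <- treatment_partition(c(2, 2, 1, 1)) # canonicalizes to 1,1,2,2
  pf <- greedy_search(ds, 2, init, lambda = 0.0625)
  grid <- matrix(runif(300, -1, 1), 150, 2)
  pred <- predict(pf$model, grid)$groups
  # group 2 of the canonical partition (arms 3,4) is optimal where
  # 0.1 - x1 - x2 > 0
  want2 <- (0.1 - grid[, 1] - grid[, 2]) > 0.3
  want1 <- (0.1 - grid[, 1] - grid[, 2]) < -0.3
  expect_gt(mean(pred[want2] == 2L), 0.9)
  expect_gt(mean(pred[want1] == 1L), 0.9)
})

test_that("initial partitions cluster arms by fitted outcome profiles", {
  # noiseless homogeneous toy: arms within a group are identical
  ds <- toy_two_group(n = 400, M = 6, effect = 3, noise = 0, seed = 51)
  init <- init_partition(ds, 2, seed = 1)
  expect_true(partitions_equal(init, toy_true_partition(6)))
  # deterministic given the seed
  expect_equal(init_partition(ds, 2, seed = 1)$labels,
               init_partition(ds, 2, seed = 1)$labels)
  # M = 2, K = 2: always the two singletons
  ds2 <- toy_two_group(n = 80, M = 2, seed = 52)
  expect_equal(init_partition(ds2, 2, seed = 3)$labels, c(1L, 2L))
  # unobserved treatment is an error
  ds3 <- ds2
  ds3$A[ds3$A == 2] <- 1L
  expect_error(init_partition(ds3, 2, seed = 1),
               class = "growl_invalid_argument")
})
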