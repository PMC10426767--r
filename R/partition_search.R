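#' @keywords internal
#' @noRd
fit_decision <- function(records, code, lambda, gamma, kernel_spec,
                         tol = 1e-6, max_sweeps = 500L) {
  if (is.null(kernel_spec) || identical(kernel_spec$kernel, "linear")) {
    solve_dual_linear(records, code, lambda = lambda, gamma = gamma,
                      tol = tol, max_sweeps = max_sweeps)
  } else {
    solve_dual_kernel(records, code, kernel = "rbf",
                      sigma2 = kernel_spec$sigma2, lambda = lambda,
                      gamma = gamma, tol = tol, max_sweeps = max_sweeps)
  }
}

# vectorized RAMSVM loss over records at fitted f values
records_loss <- function(f_values, label, gamma, code) {
  m <- nrow(f_values)
  if (m == 0) return(numeric(0))
  scores <- f_values %*% t(code$W) # m x K
  K <- code$K
  hinge_wrong <- pmax(1 + scores, 0)
  idx <- cbind(seq_len(m), label)
  wrong <- rowSums(hinge_wrong) - hinge_wrong[idx]
  right <- pmax(K - 1 - scores[idx], 0)
  (1 - gamma) * wrong + gamma * right
}

#' Empirical objective of a candidate partition
#'
#' Fits the weighted RAMSVM decision function for the given partition and
#' evaluates the empirical generalized-risk objective that the partition
#' search minimizes,
#' \deqn{J(\delta) = \frac1n \sum_i \frac{R_i - s(X_i)}
#'   {p(\delta(A_i) \mid X_i)} \, L_\phi(\delta(A_i), \hat f(X_i))
#'   - \frac{K}{n} \sum_i \frac{R_i - s(X_i)}{p(\delta(A_i) \mid X_i)}
#'   + \frac{\lambda}{2} \|\hat f\|^2 ,}
#' with signed residual weights in both subject-level sums.  The decision
#' function itself is fitted from the label-switched transformed records
#' (whose population objective differs from the signed one only by a
#' constant on the region where the surrogate losses sum to a constant),
#' restoring convexity; but the partition comparison uses the signed form,
#' because replacing the signed sums by the nonnegative transformed-record
#' sums inflates the objective of partitions with small group propensities
#' (the `1/p` factors of a near-empty group grow without the sign
#' cancellation that bounds the signed sums) and biases the search toward
#' degenerate groupings.  Smaller is better.
#'
#' @param dataset a [trial_dataset()].
#' @param partition a [treatment_partition()].
#' @param lambda,gamma solver parameters.
#' @param kernel_spec `NULL` or `list(kernel = "linear")` for linear decision
#'   functions, `list(kernel = "rbf", sigma2 = ...)` for the Gaussian kernel.
#' @param s a pre-fitted [fit_main_effect()] result; by default refit on
#'   `dataset`.  Pass `NULL` to skip residualization.
#' @param mode,seed residual transform mode, see [transform_residuals()].
#' @return a list with `objective`, `model`, `dual`, `records`.
#' @export
objective_for_partition <- function(dataset, partition, lambda, gamma = 0.5,
                                    kernel_spec = NULL,
                                    s = fit_main_effect(dataset),
                                    mode = "expand", seed = NULL) {
  records <- transform_residuals(dataset, partition, s, mode = mode, seed = seed)
  code <- simplex_code(partition$K)
  n <- records$n_eff
  res <- if (is.null(s)) dataset$R else dataset$R - s$fun(dataset$X)
  gp <- group_propensity(dataset, partition)
  obs_group <- partition$labels[dataset$A]
  p_obs <- gp[cbind(seq_len(dataset$n), obs_group)]
  center <- partition$K * sum(res / p_obs) / n
  if (length(records$label) == 0 || all(records$weight == 0)) {
    return(list(objective = -center, model = NULL, dual = NULL,
                records = records))
  }
  fit <- fit_decision(records, code, lambda, gamma, kernel_spec)
  f_hat <- predict(fit$model, dataset$X)$f_values
  loss <- records_loss(f_hat, obs_group, gamma, code)
  obj <- sum(res / p_obs * loss) / n - center +
    lambda / 2 * model_norm2(fit$model)
  list(objective = obj, model = fit$model, dual = fit$dual, records = records)
}

# enumerate set partitions of M items into exactly K blocks as restricted
# growth strings (canonical label vectors, no relabeling duplicates)
enumerate_partitions <- function(M, K) {
  out <- list()
  rec <- function(labels, used) {
    i <- length(labels) + 1L
    if (i > M) {
      if (used == K) out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    remaining <- M - i + 1L
    for (g in seq_len(min(used + 1L, K))) {
      # prune: must still be able to open all K groups
      if (max(used, g) + remaining - 1L < K) next
      rec(c(labels, g), max(used, g))
    }
  }
  rec(integer(0), 0L)
  out
}

partition_key <- function(labels) {
  paste(canonicalize_partition(treatment_partition(labels))$labels,
        collapse = ",")
}

# memoizing objective evaluator shared by the search strategies
make_evaluator <- function(dataset, lambda, gamma, kernel_spec, s) {
  cache <- new.env(parent = emptyenv())
  trace <- list()
  eval_labels <- function(labels) {
    key <- partition_key(labels)
    if (!is.null(cache[[key]])) return(cache[[key]])
    part <- treatment_partition(labels)
    res <- objective_for_partition(dataset, part, lambda, gamma,
                                   kernel_spec, s = s)
    out <- list(partition = part, objective = res$objective,
                model = res$model)
    cache[[key]] <- out
    trace[[length(trace) + 1L]] <<- list(partition = part,
                                         objective = res$objective)
    out
  }
  list(eval = eval_labels, trace = function() trace)
}

partition_fit <- function(best, trace) {
  # canonicalize the labels and permute the fitted model to match, so the
  # returned (partition, model) pair stays consistent
  canon <- canonicalize_partition(best$partition)
  model <- best$model
  if (!is.null(model) && !identical(canon$labels, best$partition$labels)) {
    first_seen <- unique(best$partition$labels)
    perm <- integer(best$partition$K)
    perm[first_seen] <- seq_along(first_seen) # old group -> canonical group
    model <- permute_decision_model(model, perm)
  }
  structure(list(partition = canon, model = model,
                 objective = best$objective, trace = trace),
            class = "partition_fit")
}

#' @export
print.partition_fit <- function(x, ...) {
  cat("Partition fit, objective =", format(x$objective, digits = 6), "\n")
  print(x$partition)
  invisible(x)
}

#' Exhaustive partition search
#'
#' Evaluates the empirical objective for every set partition of the `M`
#' treatments into exactly `K` groups and returns the minimizer.  Feasible
#' for small treatment spaces only (the number of candidate partitions is
#' the Stirling number S(M, K)); serves as the exact reference for the
#' greedy and genetic strategies.  Ties are broken toward the
#' lexicographically smallest canonical label vector.
#'
#' @inheritParams objective_for_partition
#' @param K number of groups.
#' @param max_candidates guard on the enumeration size.
#' @return a `partition_fit` (partition, model, objective, search trace).
#' @export
exhaustive_search <- function(dataset, K, lambda, gamma = 0.5,
                              kernel_spec = NULL, s = fit_main_effect(dataset),
                              max_candidates = 1e5) {
  M <- dataset$M
  cands <- enumerate_partitions(M, K)
  if (length(cands) > max_candidates) {
    stop_invalid("search space has ", length(cands),
                 " partitions; use greedy_search() or genetic_search()")
  }
  ev <- make_evaluator(dataset, lambda, gamma, kernel_spec, s)
  best <- NULL
  for (labels in cands) { # enumeration order is lexicographic-canonical
    res <- ev$eval(labels)
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  partition_fit(best, ev$trace())
}

#' Greedy cyclic partition search
#'
#' Coordinate-descent-style search over partitions: cycling through the
#' treatments, each treatment's group assignment is switched to the best
#' improving alternative (moves that would empty a group are rejected),
#' until a full cycle makes no change.  The returned objective never
#' exceeds the initial partition's objective.
#'
#' @inheritParams exhaustive_search
#' @param init initial [treatment_partition()].
#' @param max_cycles maximum number of full cycles through the treatments.
#' @return a `partition_fit`.
#' @export
greedy_search <- function(dataset, K, init, lambda, gamma = 0.5,
                          kernel_spec = NULL, s = fit_main_effect(dataset),
                          max_cycles = 20L) {
  stopifnot(inherits(init, "treatment_partition"), init$K == K)
  ev <- make_evaluator(dataset, lambda, gamma, kernel_spec, s)
  current <- ev$eval(init$labels)
  labels <- init$labels
  for (cycle in seq_len(max_cycles)) {
    changed <- FALSE
    for (a in seq_len(dataset$M)) {
      if (sum(labels == labels[a]) == 1L) next # move would empty a group
      best_alt <- NULL
      for (g in setdiff(seq_len(K), labels[a])) {
        cand <- labels
        cand[a] <- g
        res <- ev$eval(cand)
        if (res$objective < current$objective - 1e-12 &&
            (is.null(best_alt) || res$objective < best_alt$objective)) {
          best_alt <- res
          best_labels <- cand
        }
      }
      if (!is.null(best_alt)) {
        current <- best_alt
        labels <- best_labels
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  partition_fit(current, ev$trace())
}

#' Genetic partition search
#'
#' Stochastic evolutionary search over group-label vectors: tournament
#' selection, uniform crossover, per-gene mutation, with offspring that
#' empty a group repaired by reassigning a random treatment from the largest
#' group.  Deterministic given `seed`; returns the best partition ever
#' evaluated.
#'
#' @inheritParams exhaustive_search
#' @param population population size (at least 4).
#' @param generations number of generations.
#' @param p_mutate per-gene mutation probability.
#' @param p_crossover probability of crossover (vs. cloning).
#' @param tournament tournament size for selection.
#' @param seed integer seed.
#' @param init optional [treatment_partition()] injected into the initial
#'   population.
#' @return a `partition_fit`.
#' @export
genetic_search <- function(dataset, K, lambda, gamma = 0.5,
                           kernel_spec = NULL, s = fit_main_effect(dataset),
                           population = 50L, generations = 100L,
                           p_mutate = 0.1, p_crossover = 0.8,
                           tournament = 3L, seed = 1L, init = NULL) {
  if (population < 4) stop_invalid("population must be at least 4")
  M <- dataset$M
  ev <- make_evaluator(dataset, lambda, gamma, kernel_spec, s)
  set.seed(derive_seed(seed, "ga"))

  repair <- function(labels) {
    missing <- setdiff(seq_len(K), unique(labels))
    for (g in missing) {
      counts <- tabulate(labels, K)
      from <- which(labels == which.max(counts))
      labels[if (length(from) == 1) from else sample(from, 1)] <- g
    }
    labels
  }
  random_individual <- function() repair(sample.int(K, M, replace = TRUE))

  pop <- replicate(population, random_individual(), simplify = FALSE)
  if (!is.null(init)) pop[[1]] <- init$labels
  fitness <- vapply(pop, function(l) ev$eval(l)$objective, numeric(1))
  best <- ev$eval(pop[[which.min(fitness)]])

  select_one <- function() {
    idx <- sample.int(population, tournament, replace = TRUE)
    pop[[idx[which.min(fitness[idx])]]]
  }
  for (gen in seq_len(generations)) {
    new_pop <- vector("list", population)
    new_pop[[1]] <- best$partition$labels # elitism
    for (i in 2:population) {
      p1 <- select_one()
      child <- if (runif(1) < p_crossover) {
        p2 <- select_one()
        mask <- runif(M) < 0.5
        ifelse(mask, p1, p2)
      } else p1
      mut <- runif(M) < p_mutate
      if (any(mut)) child[mut] <- sample.int(K, sum(mut), replace = TRUE)
      new_pop[[i]] <- repair(child)
    }
    pop <- new_pop
    fitness <- vapply(pop, function(l) ev$eval(l)$objective, numeric(1))
    gen_best <- ev$eval(pop[[which.min(fitness)]])
    if (gen_best$objective < best$objective) best <- gen_best
  }
  partition_fit(best, ev$trace())
}

#' Initial partition from clustered per-arm outcome fits
#'
#' Fits a (ridge-stabilized) linear model of the outcome on `(1, X)` within
#' each treatment arm, shrinking arms with fewer than `d + 1` observations
#' strongly toward the global fit, evaluates each arm's fitted values on the
#' full covariate sample, and k-means-clusters the resulting `M`
#' fitted-value profiles into `K` groups.  Arms with indistinguishable
#' conditional-outcome profiles land in the same initial group.
#'
#' @param dataset a [trial_dataset()].
#' @param K number of groups.
#' @param seed integer seed for k-means.
#' @return a [treatment_partition()].
#' @export
init_partition <- function(dataset, K, seed = 1L) {
  M <- dataset$M
  counts <- tabulate(dataset$A, M)
  if (any(counts == 0)) {
    stop_invalid("treatment(s) ", paste(which(counts == 0), collapse = ","),
                 " never observed")
  }
  d <- dataset$d
  Xa <- cbind(1, dataset$X)
  global <- fit_main_effect(dataset)$coef
  profiles <- matrix(0, nrow = M, ncol = dataset$n)
  for (a in seq_len(M)) {
    rows <- dataset$A == a
    Xa_a <- Xa[rows, , drop = FALSE]
    # ridge toward the global coefficients: a moderate fixed prior weight
    # keeps sparsely observed arms (n_a comparable to d) from producing
    # outlier profiles that k-means would isolate into singleton clusters,
    # and washes out as the arm sample grows
    ridge <- 2
    co <- solve(crossprod(Xa_a) + diag(ridge, d + 1),
                crossprod(Xa_a, dataset$R[rows]) + ridge * global)
    profiles[a, ] <- drop(Xa %*% co)
  }
  set.seed(derive_seed(seed, "init-kmeans"))
  uniq <- nrow(unique(round(profiles, 10)))
  if (uniq <= K) {
    # fewer distinct profiles than clusters: group identical profiles, then
    # split the largest groups until K groups exist
    labels <- as.integer(factor(apply(round(profiles, 10), 1, paste,
                                      collapse = ",")))
    while (length(unique(labels)) < K) {
      counts_g <- table(labels)
      big <- as.integer(names(counts_g)[which.max(counts_g)])
      member <- which(labels == big)
      labels[member[1]] <- max(labels) + 1L
    }
    labels <- as.integer(factor(labels))
  } else {
    labels <- kmeans(profiles, centers = K, nstart = 10)$cluster
  }
  canonicalize_partition(treatment_partition(labels, K))
}
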