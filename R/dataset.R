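#' Construct a trial dataset
#'
#' Bundles per-subject covariates, treatment labels, outcomes and treatment
#' propensities, validating the positivity assumption (all propensities
#' strictly positive, rows summing to one).
#'
#' @param X numeric matrix `n x d` of covariates.
#' @param A integer vector of treatment labels in `1..M`.
#' @param R numeric outcome vector (larger is better).
#' @param prop numeric matrix `n x M`; `prop[i, a]` is the propensity
#'   `p(a | X_i)` of subject `i` receiving treatment `a`.
#' @param M number of treatments; defaults to `ncol(prop)`.
#' @return an object of class `trial_dataset`.
#' @export
trial_dataset <- function(X, A, R, prop, M = ncol(prop)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  prop <- as.matrix(prop)
  A <- as.integer(A)
  R <- as.numeric(R)
  n <- nrow(X)
  if (n < 1 || ncol(X) < 1) stop_invalid("X must be a non-empty matrix")
  if (length(A) != n || length(R) != n || nrow(prop) != n) {
    stop_invalid("X, A, R and prop must describe the same n subjects")
  }
  if (M < 2) stop_invalid("at least 2 treatments are required")
  if (ncol(prop) != M) stop_invalid("prop must have M = ", M, " columns")
  if (any(A < 1L | A > M)) stop_invalid("treatment labels must lie in 1..", M)
  if (any(!is.finite(R)) || any(!is.finite(X)) || any(!is.finite(prop))) {
    stop_invalid("X, R and prop must be finite")
  }
  if (any(prop <= 0)) {
    stop_invalid("positivity violated: all propensities must be > 0")
  }
  rs <- rowSums(prop)
  if (any(abs(rs - 1) > 1e-8)) {
    bad <- which(abs(rs - 1) > 1e-8)[1]
    stop_invalid("propensity row ", bad, " sums to ", format(rs[bad]),
                 ", not 1")
  }
  structure(
    list(X = X, A = A, R = R, prop = prop, n = n, d = ncol(X), M = as.integer(M)),
    class = "trial_dataset"
  )
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("Trial dataset: n =", x$n, "subjects, d =", x$d,
      "covariates, M =", x$M, "treatments\n")
  cat("  arm counts:", paste(tabulate(x$A, x$M), collapse = " "), "\n")
  invisible(x)
}

#' Construct a treatment partition
#'
#' A partition assigns each of the `M` treatments to one of `K` non-empty
#' groups.  Partitions are identified only up to relabeling of the groups;
#' use [canonicalize_partition()] / [partitions_equal()] to compare them.
#'
#' @param labels integer vector of length `M`; `labels[a]` is the group of
#'   treatment `a`.
#' @param K number of groups; defaults to `max(labels)`.
#' @return an object of class `treatment_partition`.
#' @export
#' @examples
#' treatment_partition(c(1, 1, 2, 2))
treatment_partition <- function(labels, K = max(labels)) {
  labels <- as.integer(labels)
  K <- as.integer(K)
  if (length(labels) < K) stop_invalid("need at least K treatments")
  if (any(labels < 1L | labels > K)) {
    stop_invalid("group labels must lie in 1..K = ", K)
  }
  if (length(unique(labels)) != K) {
    stop_invalid("every group in 1..", K, " must be non-empty")
  }
  structure(list(labels = labels, K = K, M = length(labels)),
            class = "treatment_partition")
}

#' @export
print.treatment_partition <- function(x, ...) {
  groups <- split(seq_len(x$M), x$labels)
  cat("Partition of", x$M, "treatments into", x$K, "groups:\n")
  for (k in seq_along(groups)) {
    cat("  G", k, " = {", paste(groups[[k]], collapse = ","), "}\n", sep = "")
  }
  invisible(x)
}

#' Canonical form of a partition
#'
#' Relabels the groups in order of each group's smallest treatment, giving a
#' unique representative of the equivalence class of partitions under group
#' relabeling.  Idempotent.
#'
#' @param partition a [treatment_partition()].
#' @return a `treatment_partition` in canonical form.
#' @export
canonicalize_partition <- function(partition) {
  stopifnot(inherits(partition, "treatment_partition"))
  first_seen <- unique(partition$labels)
  relabel <- match(partition$labels, first_seen)
  treatment_partition(relabel, partition$K)
}

#' Compare two partitions up to group relabeling
#'
#' @param a,b [treatment_partition()] objects.
#' @return `TRUE` if the partitions induce the same grouping.
#' @export
partitions_equal <- function(a, b) {
  if (a$M != b$M || a$K != b$K) return(FALSE)
  identical(canonicalize_partition(a)$labels, canonicalize_partition(b)$labels)
}

#' Group-level propensity scores
#'
#' Sums the per-treatment propensities within each group of a partition:
#' `p(delta(a) | x) = sum over a' in the group of a of p(a' | x)`.
#'
#' @param dataset a [trial_dataset()].
#' @param partition a [treatment_partition()] over the dataset's treatments.
#' @return numeric `n x K` matrix of group propensities; rows sum to 1.
#' @export
group_propensity <- function(dataset, partition) {
  stopifnot(inherits(dataset, "trial_dataset"),
            inherits(partition, "treatment_partition"))
  if (partition$M != dataset$M) {
    stop_invalid("partition covers ", partition$M,
                 " treatments but dataset has ", dataset$M)
  }
  K <- partition$K
  out <- matrix(0, nrow = dataset$n, ncol = K)
  for (k in seq_len(K)) {
    cols <- which(partition$labels == k)
    out[, k] <- rowSums(dataset$prop[, cols, drop = FALSE])
  }
  out
}
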