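#' Angle-based simplex coding of treatment groups
#'
#' Encodes `K` treatment groups as the `K` vertices of a regular simplex in
#' `(K-1)`-dimensional space.  Row `k` of the matrix `W` is the code vector
#' of group `k`:
#' \deqn{W_1 = (K-1)^{-1/2}\,\mathbf{1}_{K-1}, \qquad
#'       W_k = -\frac{1+\sqrt{K}}{(K-1)^{3/2}}\,\mathbf{1}_{K-1}
#'             + \sqrt{\frac{K}{K-1}}\, e_{k-1}, \quad k = 2,\dots,K.}
#' Every vertex has unit norm, distinct vertices have inner product
#' \eqn{-1/(K-1)}, and the vertices sum to zero, so all groups are treated
#' symmetrically.  For `K = 2` this reduces to the usual \eqn{\pm 1} binary
#' coding.
#'
#' @param K integer number of treatment groups, at least 2.
#' @return an object of class `simplex_code`: a list with elements `K` and
#'   the `K x (K-1)` code matrix `W`.
#' @export
#' @examples
#' simplex_code(3)$W
simplex_code <- function(K) {
  if (!is.numeric(K) || length(K) != 1 || K != round(K) || K < 2) {
    stop_invalid("K must be an integer >= 2")
  }
  K <- as.integer(K)
  W <- matrix(0, nrow = K, ncol = K - 1L)
  W[1, ] <- (K - 1)^(-1 / 2)
  if (K >= 2) {
    for (k in 2:K) {
      W[k, ] <- -(1 + sqrt(K)) / (K - 1)^(3 / 2)
      W[k, k - 1L] <- W[k, k - 1L] + sqrt(K / (K - 1))
    }
  }
  structure(list(K = K, W = W), class = "simplex_code")
}

#' @export
print.simplex_code <- function(x, ...) {
  cat("Simplex code for", x$K, "treatment groups (vertices in",
      x$K - 1, "dims)\n")
  print(round(x$W, 5))
  invisible(x)
}

#' Assign a group from a decision-function value
#'
#' Returns the group whose simplex code vector has the largest inner product
#' with the decision-function value `f(x)`; ties are broken toward the
#' smallest group index so predictions are deterministic.
#'
#' @param code a [simplex_code()] object.
#' @param f_value numeric vector of length `K - 1`, or a matrix with `K - 1`
#'   columns (one row per observation).
#' @return integer group label(s) in `1..K`.
#' @export
decide_group <- function(code, f_value) {
  stopifnot(inherits(code, "simplex_code"))
  if (is.null(dim(f_value))) {
    f_value <- matrix(f_value, nrow = 1)
  }
  if (ncol(f_value) != code$K - 1L) {
    stop_invalid("f_value must have length/ncol K - 1 = ", code$K - 1L)
  }
  scores <- f_value %*% t(code$W) # m x K
  out <- max.col(scores, ties.method = "first")
  as.integer(out)
}
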