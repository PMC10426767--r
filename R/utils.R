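#' Derive a reproducible child seed from a master seed
#'
#' All randomness in the package (data generation, cross-validation folds,
#' sample splits, the genetic search, sample-mode label switching) flows from
#' a single master seed through this deterministic map, so that independent
#' components receive decorrelated but reproducible streams.
#'
#' @param master integer master seed.
#' @param ... character or integer tags naming the consumer (e.g. `"folds"`,
#'   a replicate index).
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "folds", 3)
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  tags <- list(...)
  h <- (abs(master) %% 2147483647)
  for (tag in tags) {
    bytes <- if (is.character(tag)) {
      utf8ToInt(paste(tag, collapse = "|"))
    } else {
      as.integer(tag)
    }
    for (b in bytes) {
      # 31-bit multiplicative mix, kept in double-safe range
      h <- (h * 69069 + as.double(b) + 1) %% 2147483647
    }
    h <- (h * 7919 + 104729) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(
    class = c("growl_invalid_argument", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    stop_invalid(name, " must be a finite scalar in [", lower, ", ", upper, "]")
  }
  x
}
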