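#' Read a trial dataset from delimited text
#'
#' Expects a header with covariate columns `x1..xd`, a treatment column `a`,
#' an outcome column `r`, and either `p` (propensity of the received arm —
#' only accepted together with `arm_levels` so the full matrix can be
#' reconstructed is NOT supported; see Details) or the full propensity
#' columns `p1..pM`.  Arm labels may be arbitrary strings; they are mapped
#' to `1..M` in order of first appearance (or of `arm_levels`) and the map
#' is kept in the returned dataset's `"label_map"` attribute.
#'
#' Rows with missing values are rejected with their line numbers, as are
#' non-positive propensities and propensity rows that do not sum to 1
#' (tolerance `1e-6`).  When no propensity columns are present, propensities
#' are estimated with [estimate_propensities()].
#'
#' @param path file path of the delimited text file.
#' @param sep field separator, default comma.
#' @param arm_levels optional character vector fixing the arm-label order.
#' @return a [trial_dataset()] with attribute `"label_map"`.
#' @export
read_dataset <- function(path, sep = ",", arm_levels = NULL) {
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  nm <- names(df)
  xcols <- grep("^x[0-9]+$", nm, value = TRUE)
  xcols <- xcols[order(as.integer(sub("^x", "", xcols)))]
  if (length(xcols) == 0) stop("no covariate columns x1..xd found")
  for (req in c("a", "r")) {
    if (!req %in% nm) stop("missing required column '", req, "'")
  }
  bad <- which(!stats::complete.cases(df[c(xcols, "a", "r")]))
  if (length(bad)) {
    stop("missing values in data row(s) ", paste(bad, collapse = ", "),
         " (file line(s) ", paste(bad + 1L, collapse = ", "), ")")
  }
  a_raw <- df[["a"]]
  levels_a <- arm_levels %||% unique(as.character(a_raw))
  A <- match(as.character(a_raw), levels_a)
  if (anyNA(A)) stop("arm label(s) not covered by arm_levels")
  M <- length(levels_a)
  pcols <- grep("^p[0-9]+$", nm, value = TRUE)
  X <- as.matrix(df[xcols])
  if (length(pcols) > 0) {
    pcols <- pcols[order(as.integer(sub("^p", "", pcols)))]
    if (length(pcols) != M) {
      stop("found ", length(pcols), " propensity columns but ", M, " arms")
    }
    prop <- as.matrix(df[pcols])
    if (any(is.na(prop))) stop("missing values in propensity columns")
    if (any(prop <= 0)) {
      stop("non-positive propensity in data row(s) ",
           paste(which(rowSums(prop <= 0) > 0), collapse = ", "))
    }
    rs <- rowSums(prop)
    bad <- which(abs(rs - 1) > 1e-6)
    if (length(bad)) {
      stop("propensity row(s) ", paste(bad, collapse = ", "),
           " do not sum to 1 (e.g. row ", bad[1], " sums to ",
           format(rs[bad[1]]), ")")
    }
    prop <- prop / rs
  } else {
    prop <- estimate_propensities(X, A, M)
  }
  ds <- trial_dataset(X, A, df[["r"]], prop, M = M)
  attr(ds, "label_map") <- levels_a
  ds
}

#' Write a trial dataset as delimited text
#'
#' Inverse of [read_dataset()]: writes `x1..xd`, `a`, `r`, `p1..pM`.
#'
#' @param dataset a [trial_dataset()].
#' @param path output file path.
#' @export
write_dataset <- function(dataset, path) {
  lab <- attr(dataset, "label_map")
  a_out <- if (is.null(lab)) dataset$A else lab[dataset$A]
  df <- data.frame(dataset$X, a = a_out, r = dataset$R, dataset$prop)
  names(df) <- c(paste0("x", seq_len(dataset$d)), "a", "r",
                 paste0("p", seq_len(dataset$M)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Estimate treatment propensities by multinomial logistic regression
#'
#' Maximum-likelihood multinomial logistic fit of the arm label on `(1, X)`.
#' Fitted probabilities are floored at `1e-6` and renormalized to guard the
#' inverse-probability weights.  If the fit does not converge (e.g. under
#' separation) it is refit with a small ridge penalty (weight decay) and a
#' warning.
#'
#' @param X covariate matrix (or a [trial_dataset()], whose propensity
#'   matrix is then replaced).
#' @param A integer arm labels in `1..M`.
#' @param M number of arms.
#' @return an `n x M` matrix of fitted propensities, rows summing to 1.
#' @export
estimate_propensities <- function(X, A = NULL, M = NULL) {
  if (inherits(X, "trial_dataset")) {
    A <- X$A; M <- X$M; X <- X$X
  }
  X <- as.matrix(X)
  M <- M %||% max(A)
  counts <- tabulate(A, M)
  if (any(counts < 2)) {
    stop("every arm needs at least 2 observations to estimate propensities")
  }
  yf <- factor(A, levels = seq_len(M))
  fit <- suppressWarnings(
    nnet::multinom(yf ~ X, trace = FALSE, maxit = 200)
  )
  if (!isTRUE(fit$convergence == 0)) {
    warning("multinomial fit did not converge; refitting with ridge penalty")
    fit <- suppressWarnings(
      nnet::multinom(yf ~ X, trace = FALSE, maxit = 500, decay = 1e-2)
    )
  }
  p <- predict(fit, type = "probs")
  if (is.null(dim(p))) p <- cbind(1 - p, p) # two-arm case returns a vector
  p <- pmax(p, 1e-6)
  unname(p / rowSums(p))
}

#' Serialize a fitted model to structured text
#'
#' Writes a fitted [fit_growl()] result (or a bare decision model) as JSON:
#' kernel specification, coefficients, partition, and the simplex dimension.
#' The file is plain text, diffable, and reloadable with [read_model()] to a
#' model producing identical predictions.
#'
#' @param fit a `growl_fit` or `decision_model`.
#' @param path output path.
#' @export
write_model <- function(fit, path) {
  if (inherits(fit, "growl_fit")) {
    model <- fit$model
    partition <- fit$partition$labels
  } else {
    model <- fit
    partition <- NULL
  }
  if (is.null(model)) stop("degenerate fit has no serializable model")
  obj <- list(
    format = "growl-model",
    version = as.character(packageVersion("growl")),
    K = model$K,
    d = model$d,
    partition = partition,
    kernel = if (inherits(model, "linear_decision_model")) "linear"
             else model$kernel,
    sigma2 = if (inherits(model, "kernel_decision_model")) model$sigma2,
    B = if (inherits(model, "linear_decision_model")) model$B,
    Theta = if (inherits(model, "kernel_decision_model")) model$Theta,
    intercepts = if (inherits(model, "kernel_decision_model"))
      model$intercepts,
    train_X = if (inherits(model, "kernel_decision_model")) model$train_X
  )
  jsonlite::write_json(obj[!vapply(obj, is.null, logical(1))], path,
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @return `read_model` returns a list with `model` (a decision model) and
#'   `partition` (a [treatment_partition()] or `NULL`).
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "growl-model")) stop("not a growl model file")
  code <- simplex_code(obj$K)
  model <- if (identical(obj$kernel, "linear") && !is.null(obj$B)) {
    structure(list(B = as.matrix(obj$B), K = obj$K, d = obj$d, code = code),
              class = c("linear_decision_model", "decision_model"))
  } else {
    train_X <- as.matrix(obj$train_X)
    G <- kernel_matrix(train_X, train_X, obj$kernel, obj$sigma2)
    structure(list(kernel = obj$kernel, sigma2 = obj$sigma2,
                   train_X = train_X, Theta = as.matrix(obj$Theta),
                   intercepts = as.numeric(obj$intercepts), G = G,
                   K = obj$K, d = obj$d, code = code),
              class = c("kernel_decision_model", "decision_model"))
  }
  partition <- if (!is.null(obj$partition)) {
    treatment_partition(obj$partition)
  }
  list(model = model, partition = partition)
}

# reproducibility manifest written next to every CLI output
write_manifest <- function(path, command, args, seed, inputs = character(0),
                           outputs = character(0)) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else NULL
  obj <- list(
    command = command,
    arguments = args,
    seed = seed,
    package_version = as.character(packageVersion("growl")),
    r_version = as.character(getRversion()),
    input_md5 = digests,
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(obj[!vapply(obj, is.null, logical(1))], path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
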