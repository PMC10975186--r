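# Core containers of the nonparametric representation: a discrete mixing
# distribution over parameter-space support points, and per-subject data.

#' Default parameter ranges per model type
#'
#' The packaged piperacillin posterior ranges used both as the adaptive-grid
#' search box and as the generation bounds for quasi-models:
#' \describe{
#'   \item{1c}{K 0.10–0.75 1/h, V 10–100 L}
#'   \item{2c}{K 0.10–1.70, KCP 0.05–5.00, KPC 0.05–5.00 1/h, Vc 5–35 L}
#'   \item{1c_crcl}{KI 0.005–0.100, KS 0.001–0.006 1/h per mL/min, V 15–80 L}
#'   \item{2c_crcl}{KI 0.00–0.35, KS 0.0005–0.0250, KCP 0.2–6.0,
#'     KPC 0.2–6.0 1/h, Vc 5–25 L}
#' }
#'
#' @param model_type model type string, see [param_names()].
#' @return a 2-row matrix (`low`, `high`) with one column per parameter.
#' @export
default_ranges <- function(model_type) {
  model_type <- match.arg(model_type, MODEL_TYPES)
  r <- switch(model_type,
    "1c" = list(K = c(0.10, 0.75), V = c(10, 100)),
    "2c" = list(K = c(0.10, 1.70), KCP = c(0.05, 5.00), KPC = c(0.05, 5.00),
                Vc = c(5, 35)),
    "1c_crcl" = list(KI = c(0.005, 0.100), KS = c(0.001, 0.006),
                     V = c(15, 80)),
    "2c_crcl" = list(KI = c(0.00, 0.35), KS = c(0.0005, 0.0250),
                     KCP = c(0.2, 6.0), KPC = c(0.2, 6.0), Vc = c(5, 25)))
  out <- vapply(r, identity, numeric(2))
  rownames(out) <- c("low", "high")
  out[, param_names(model_type), drop = FALSE]
}

check_ranges <- function(ranges, model_type) {
  pn <- param_names(model_type)
  if (!is.matrix(ranges) || nrow(ranges) != 2L ||
      !all(pn %in% colnames(ranges)))
    stop(sprintf("`ranges` must be a 2-row matrix with columns %s",
                 paste(pn, collapse = ", ")), call. = FALSE)
  ranges <- ranges[, pn, drop = FALSE]
  if (any(!is.finite(ranges)) || any(ranges[1, ] >= ranges[2, ]))
    stop("each parameter range must be finite with low < high", call. = FALSE)
  rownames(ranges) <- c("low", "high")
  ranges
}

#' Construct a discrete mixing distribution (set of support points)
#'
#' The nonparametric population representation: `n` support points, each a
#' parameter vector with a probability; probabilities must sum to 1 within
#' 1e-10 and every coordinate must lie inside the declared ranges.
#'
#' @param points numeric matrix, one row per support point, columns named as
#'   [param_names()] of `model_type`.
#' @param prob probabilities, one per point.
#' @param ranges 2-row (`low`, `high`) bounds matrix, cf. [default_ranges()].
#' @param model_type model type string.
#' @return an object of class `discrete_mixture`.
#' @export
discrete_mixture <- function(points, prob, ranges, model_type) {
  model_type <- match.arg(model_type, MODEL_TYPES)
  ranges <- check_ranges(ranges, model_type)
  pn <- param_names(model_type)
  points <- as.matrix(points)
  if (!all(pn %in% colnames(points)))
    stop("`points` must have one column per model parameter", call. = FALSE)
  points <- points[, pn, drop = FALSE]
  if (nrow(points) < 1L) stop("a mixture needs at least one support point", call. = FALSE)
  if (length(prob) != nrow(points) || any(prob < 0))
    stop("`prob` must be nonnegative with one value per point", call. = FALSE)
  if (abs(sum(prob) - 1) > 1e-10)
    stop(sprintf("probabilities must sum to 1 (off by %g)", sum(prob) - 1),
         call. = FALSE)
  tol <- 1e-9 * (ranges[2, ] - ranges[1, ])
  low_ok  <- sweep(points, 2, ranges[1, ] - tol, `>=`)
  high_ok <- sweep(points, 2, ranges[2, ] + tol, `<=`)
  if (!all(low_ok) || !all(high_ok))
    stop("all support points must lie within the declared ranges", call. = FALSE)
  structure(list(points = points, prob = as.numeric(prob), ranges = ranges,
                 model_type = model_type),
            class = "discrete_mixture")
}

#' @export
print.discrete_mixture <- function(x, ...) {
  cat("Discrete mixture (", x$model_type, "): ", nrow(x$points),
      " support points\n", sep = "")
  means <- colSums(x$prob * x$points)
  cat("  weighted means:",
      paste(sprintf("%s=%.4g", names(means), means), collapse = ", "), "\n")
  invisible(x)
}

#' Mean and variance of each parameter under a discrete mixture
#' @param mixture a `discrete_mixture`.
#' @return list with `mean` and `var`, named per parameter.
#' @export
mixture_moments <- function(mixture) {
  stopifnot(inherits(mixture, "discrete_mixture"))
  m <- colSums(mixture$prob * mixture$points)
  v <- colSums(mixture$prob * sweep(mixture$points, 2, m)^2)
  list(mean = m, var = v)
}

#' Per-subject modeling data
#'
#' Bundles one subject's dosing history, sampling times, observed
#' concentrations and covariates.
#'
#' @param id subject identifier.
#' @param reg a `regimen`.
#' @param times sampling times, hours, strictly increasing.
#' @param observations observed concentrations, mg/L, same length as `times`.
#' @param covariates named list of covariates (e.g. `CRCL` in mL/min).
#' @return an object of class `subject_data`.
#' @export
subject_data <- function(id, reg, times, observations, covariates = list()) {
  check_regimen(reg)
  times <- check_times(times)
  if (length(times) < 1L) stop("at least one observation is required", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop(sprintf("subject %s: sampling times must be strictly increasing", id),
         call. = FALSE)
  if (length(observations) != length(times))
    stop(sprintf("subject %s: observations and times differ in length", id),
         call. = FALSE)
  if (anyNA(observations) || any(!is.finite(observations)))
    stop(sprintf("subject %s: observations must be finite", id), call. = FALSE)
  structure(list(id = id, regimen = reg, times = times,
                 observations = as.numeric(observations),
                 covariates = covariates),
            class = "subject_data")
}

subject_crcl <- function(subject) {
  cr <- subject$covariates$CRCL
  if (is.null(cr)) NULL else cr
}

n_obs <- function(subjects) sum(vapply(subjects, function(s) length(s$times), 0L))

#' Read and write discrete mixtures as plain-text tables
#'
#' The serialization is a CSV of one row per support point (parameter
#' columns plus `prob`), preceded by `#`-comment header lines recording the
#' model type and ranges, so a mixture file is self-describing.
#'
#' @param mixture a `discrete_mixture`.
#' @param path file path.
#' @return `read_mixture()` returns a `discrete_mixture`;
#'   `write_mixture()` its path, invisibly.
#' @export
write_mixture <- function(mixture, path) {
  stopifnot(inherits(mixture, "discrete_mixture"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# model_type: %s", mixture$model_type), con)
  for (p in colnames(mixture$ranges))
    writeLines(sprintf("# range: %s %.17g %.17g", p,
                       mixture$ranges[1, p], mixture$ranges[2, p]), con)
  df <- as.data.frame(mixture$points)
  df$prob <- mixture$prob
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mixture
#' @export
read_mixture <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  mt <- sub("^# model_type: *", "", grep("^# model_type:", hdr, value = TRUE))
  if (!length(mt)) stop("mixture file lacks a '# model_type:' header", call. = FALSE)
  rng_lines <- grep("^# range:", hdr, value = TRUE)
  parts <- strsplit(sub("^# range: *", "", rng_lines), " +")
  ranges <- vapply(parts, function(p) as.numeric(p[2:3]), numeric(2))
  colnames(ranges) <- vapply(parts, `[[`, "", 1L)
  df <- utils::read.csv(textConnection(grep("^#", lines, value = TRUE,
                                            invert = TRUE)))
  discrete_mixture(as.matrix(df[setdiff(names(df), "prob")]), df$prob,
                   ranges, mt)
}
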