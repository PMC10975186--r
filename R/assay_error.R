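# Assay error model: a polynomial mapping concentration to the measurement
# standard deviation (the fixed-effect error component), fitted by
# unweighted least squares on nominal-concentration / replicate-SD pairs.

#' Construct an assay error polynomial
#'
#' `SD(c) = c0 + c1 c + c2 c^2 + c3 c^3` maps a concentration (mg/L) to its
#' measurement standard deviation (mg/L).
#'
#' @param coefficients numeric vector `(c0, ..., c_degree)`, constant term first.
#' @param r_squared determination coefficient of the fit, if known.
#' @return an object of class `error_polynomial`.
#' @seealso [piperacillin_error_poly()] for the packaged piperacillin
#'   HPLC-UV error model.
#' @export
error_polynomial <- function(coefficients, r_squared = NA_real_) {
  if (!is.numeric(coefficients) || !length(coefficients) ||
      length(coefficients) > 4L || anyNA(coefficients))
    stop("`coefficients` must be 1 to 4 finite numbers (c0..c3)", call. = FALSE)
  structure(list(coefficients = as.numeric(coefficients),
                 degree = length(coefficients) - 1L,
                 r_squared = r_squared),
            class = "error_polynomial")
}

#' @export
print.error_polynomial <- function(x, ...) {
  terms <- sprintf("%+g*c^%d", x$coefficients, seq_along(x$coefficients) - 1L)
  terms[1] <- sprintf("%g", x$coefficients[1])
  cat("Assay error polynomial (degree ", x$degree, "):\n  SD(c) = ",
      paste(terms, collapse = " "), "\n", sep = "")
  if (!is.na(x$r_squared)) cat("  r-squared:", format(x$r_squared), "\n")
  invisible(x)
}

#' Default piperacillin assay error polynomial
#'
#' The experimentally determined third-degree polynomial for the piperacillin
#' HPLC-UV assay:
#' `SD = 0.255056 + 0.049873 c - 0.000361 c^2 + 0.000001 c^3` (r^2 = 0.9564).
#' This polynomial is monotone increasing for c >= 0, so SD never falls
#' below its intercept.
#'
#' @return an `error_polynomial`.
#' @export
piperacillin_error_poly <- function() {
  error_polynomial(c(0.255056, 0.049873, -0.000361, 0.000001),
                   r_squared = 0.9564)
}

#' Evaluate the assay SD at a concentration
#'
#' @param poly an `error_polynomial`.
#' @param conc concentration(s), mg/L, >= 0. Evaluation outside the
#'   calibrated range is permitted; a nonpositive SD is an error because it
#'   signals use of the polynomial where it is not a valid error model.
#' @return SD(s) in mg/L.
#' @export
sd_at <- function(poly, conc) {
  stopifnot(inherits(poly, "error_polynomial"))
  if (!is.numeric(conc) || anyNA(conc) || any(conc < 0))
    stop("`conc` must be nonnegative concentrations (mg/L)", call. = FALSE)
  s <- outer(conc, seq_along(poly$coefficients) - 1L, `^`) %*% poly$coefficients
  s <- drop(s)
  if (any(s <= 0))
    stop(sprintf(
      "error polynomial yields nonpositive SD at c = %g mg/L; polynomial is not a valid error model there",
      conc[which(s <= 0)[1]]), call. = FALSE)
  s
}

#' Fit assay error polynomials of degree 1..max_degree
#'
#' Unweighted least-squares polynomial regression of replicate-measurement
#' SDs on nominal concentrations, one fit per degree; the fit with the
#' highest r-squared is flagged as selected. This mirrors the standard way
#' assay error models are elaborated for nonparametric PK software: spike a
#' drug at many levels, measure replicates, regress SD on concentration.
#'
#' @param conc nominal concentrations, mg/L.
#' @param sd per-level SDs of replicate measurements, mg/L, >= 0.
#' @param max_degree highest polynomial degree to try (1, 2 or 3).
#' @return list with `fits` (one `error_polynomial` per degree) and
#'   `selected`, the highest-r-squared fit.
#' @export
fit_error_polynomial <- function(conc, sd, max_degree = 3) {
  if (length(conc) != length(sd))
    stop("`conc` and `sd` must have equal length", call. = FALSE)
  if (any(sd < 0)) stop("SDs must be >= 0", call. = FALSE)
  max_degree <- as.integer(max_degree)
  if (max_degree < 1L || max_degree > 3L)
    stop("`max_degree` must be 1, 2 or 3", call. = FALSE)
  n_levels <- length(unique(conc))
  if (n_levels < max_degree + 2L)
    stop(sprintf(
      "underdetermined fit: %d distinct levels but degree %d needs at least %d",
      n_levels, max_degree, max_degree + 2L), call. = FALSE)

  degenerate <- stats::var(sd) == 0
  if (degenerate)
    warning("all SDs identical: r-squared is undefined and reported as 0",
            call. = FALSE)

  fits <- lapply(seq_len(max_degree), function(deg) {
    fit <- stats::lm(sd ~ stats::poly(conc, deg, raw = TRUE))
    # summary.lm warns on an essentially perfect fit; exact calibration
    # data is a legitimate input here
    r2 <- if (degenerate) 0 else suppressWarnings(summary(fit)$r.squared)
    error_polynomial(unname(stats::coef(fit)), r_squared = r2)
  })
  names(fits) <- paste0("degree", seq_len(max_degree))
  best <- which.max(vapply(fits, function(f) f$r_squared, 0))
  list(fits = fits, selected = fits[[best]])
}

#' Observation noise settings
#'
#' Additional proportional noise components of the clinical observation
#' model: dosing error, model misspecification and sample-timing error, each
#' a fraction of the predicted concentration. The defaults are the study
#' settings (0.01 each); use `noise_settings(0, 0, 0)` to reduce the
#' observation model to the pure assay polynomial.
#'
#' @param dosing_error,model_misspecification,timing_error fractions, >= 0.
#' @return a `noise_settings` object.
#' @export
noise_settings <- function(dosing_error = 0.01, model_misspecification = 0.01,
                           timing_error = 0.01) {
  for (v in c(dosing_error, model_misspecification, timing_error))
    check_scalar(v, "noise fraction", nonneg = TRUE)
  structure(list(dosing_error = dosing_error,
                 model_misspecification = model_misspecification,
                 timing_error = timing_error),
            class = "noise_settings")
}

#' Total observation variance at a predicted concentration
#'
#' Composes the assay polynomial with the proportional noise settings in
#' quadrature and applies a multiplicative inflation `gamma`:
#' `var = gamma^2 * (SD(c)^2 + (de*c)^2 + (mm*c)^2 + (te*c)^2)`.
#' With all noise terms 0 and `gamma = 1` this is exactly `sd_at(poly, c)^2`.
#' The quadrature composition of the three clinical settings is a package
#' convention (their exact semantics inside clinical dosing software are not
#' public); it is switchable off via `noise = NULL`.
#'
#' @param poly an `error_polynomial`.
#' @param predicted_c predicted concentration(s), mg/L, >= 0.
#' @param noise a [noise_settings()] object, or `NULL` for assay-only variance.
#' @param gamma multiplicative SD inflation, >= 1 conventionally.
#' @return variance(s), (mg/L)^2.
#' @export
observation_variance <- function(poly, predicted_c, noise = NULL, gamma = 1) {
  check_scalar(gamma, "gamma", positive = TRUE)
  v <- sd_at(poly, predicted_c)^2
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_settings"))
    v <- v + (noise$dosing_error * predicted_c)^2 +
      (noise$model_misspecification * predicted_c)^2 +
      (noise$timing_error * predicted_c)^2
  }
  gamma^2 * v
}
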