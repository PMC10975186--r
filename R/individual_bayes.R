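# Nonparametric MAP Bayesian analysis: reweight a discrete prior by one
# subject's data likelihood, yielding an individual posterior over the same
# support points.

#' Individual nonparametric posterior
#'
#' Bayes' rule on a discrete prior: posterior weight of point `j` is
#' `w_j L_j / sum_k w_k L_k`, with `L_j` the subject's data likelihood under
#' support point `j`. The fitted (predicted) curve is the posterior-weighted
#' average of the per-point predicted curves, matching the multi-point
#' posteriors a nonparametric prior can produce; the MAP point (maximal
#' posterior weight, ties to the first) and the posterior-mean parameter
#' vector are both reported.
#'
#' @param prior a `discrete_mixture`.
#' @param subject a `subject_data` with at least one observation.
#' @param error an [error_model()].
#' @return an object of class `individual_posterior`: list with
#'   `posterior` (the reweighted `discrete_mixture`), `posterior_weights`,
#'   `map_index`, `map_point`, `posterior_mean`, `predictions` (at the
#'   subject's sampling times), `mse`, `observed`, `times` and `id`.
#' @export
posterior <- function(prior, subject, error = error_model()) {
  stopifnot(inherits(prior, "discrete_mixture"),
            inherits(subject, "subject_data"))
  ll <- loglik_points(prior$points, subject, prior$model_type, error)
  scale <- max(ll)
  if (!is.finite(scale))
    stop(sprintf("degenerate posterior: subject %s has zero likelihood under every support point",
                 subject$id), call. = FALSE)
  wl <- prior$prob * exp(ll - scale)
  pw <- wl / sum(wl)
  post_mix <- discrete_mixture(prior$points, pw, prior$ranges,
                               prior$model_type)
  preds <- predict_matrix(prior$points, prior$model_type, subject$regimen,
                          subject$times, crcl = subject_crcl(subject))
  pred <- colSums(pw * preds)
  map_index <- which.max(pw)
  structure(list(
    posterior = post_mix,
    posterior_weights = pw,
    map_index = map_index,
    map_point = prior$points[map_index, ],
    posterior_mean = colSums(pw * prior$points),
    predictions = pred,
    mse = mse(subject$observations, pred),
    observed = subject$observations,
    times = subject$times,
    id = subject$id),
    class = "individual_posterior")
}

#' @export
print.individual_posterior <- function(x, ...) {
  cat(sprintf("Individual posterior for subject %s (MSE %.4g)\n", x$id, x$mse))
  cat("  posterior mean:",
      paste(sprintf("%s=%.4g", names(x$posterior_mean), x$posterior_mean),
            collapse = ", "), "\n")
  cat("  MAP point (weight ", sprintf("%.3f", x$posterior_weights[x$map_index]),
      "): ", paste(sprintf("%s=%.4g", names(x$map_point), x$map_point),
                   collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Mean squared prediction error
#'
#' `sum((c_obs - c_pred)^2) / n_dp`, the per-subject prediction quality
#' measure used to rank candidate priors (in the reference rich-sampling
#' design, `n_dp = 6` samples per subject).
#'
#' @param observed,predicted equal-length concentration vectors.
#' @return MSE in (mg/L)^2.
#' @export
mse <- function(observed, predicted) {
  if (length(observed) != length(predicted) || !length(observed))
    stop("`observed` and `predicted` must be equal nonzero length",
         call. = FALSE)
  mean((observed - predicted)^2)
}

#' Ratio comparison of two individual estimates
#'
#' Compares two `individual_posterior` objects for the same subject and
#' model type: the MSE ratio `a$mse / b$mse` (a ratio in 0.01–1.00 reads as
#' better performance of `a`, 1.00 as equivalence, > 1.00 as better
#' performance of `b`), elementwise ratios of the parameter point estimates,
#' and — for two-compartment types — the ratio of the KCP/KPC ratios.
#'
#' @param a,b `individual_posterior` objects.
#' @param estimate which point estimate to ratio: the posterior mean
#'   (default) or the MAP point.
#' @return list with `mse_ratio`, `param_ratios` and (two-compartment only)
#'   `kcp_kpc_ratio_ratio`; ratios with a zero denominator are `NaN`/`Inf`
#'   and flagged in `undefined`.
#' @export
compare_estimates <- function(a, b, estimate = c("posterior_mean", "map")) {
  stopifnot(inherits(a, "individual_posterior"),
            inherits(b, "individual_posterior"))
  if (!identical(a$posterior$model_type, b$posterior$model_type))
    stop("estimates compare only within one model type", call. = FALSE)
  if (!identical(as.character(a$id), as.character(b$id)))
    stop("estimates compare only within one subject", call. = FALSE)
  estimate <- match.arg(estimate)
  pa <- if (estimate == "map") a$map_point else a$posterior_mean
  pb <- if (estimate == "map") b$map_point else b$posterior_mean
  out <- list(mse_ratio = a$mse / b$mse, param_ratios = pa / pb)
  if (grepl("^2c", a$posterior$model_type))
    out$kcp_kpc_ratio_ratio <-
      (pa[["KCP"]] / pa[["KPC"]]) / (pb[["KCP"]] / pb[["KPC"]])
  undef <- c(mse_ratio = b$mse == 0, pb == 0)
  out$undefined <- names(undef)[undef]
  out
}
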