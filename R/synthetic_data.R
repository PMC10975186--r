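# Synthetic cohorts with known ground truth, emulating the reference study
# design: 4 g q6h 3-h infusions, six post-infusion samples at
# 0.25/0.5/1/1.5/2/2.5 h, observational noise drawn from the assay error
# polynomial evaluated at the noise-free prediction.

#' Generate a synthetic cohort
#'
#' Draws each subject's true parameters uniformly within `ranges`, computes
#' noise-free concentration curves with the closed-form models, and perturbs
#' each observation with `Normal(0, SD(pred))` noise from the assay error
#' polynomial. Negative draws are truncated at 0 (and counted in
#' `n_truncated`) since concentrations are strictly nonnegative. The truth
#' is always returned beside the data, never hidden.
#'
#' @param n_subjects cohort size (default 12, the reference design).
#' @param model_type model type string ("1c" or "2c"; for covariate types
#'   use [generate_covariate_cohort()]).
#' @param ranges truth-generation bounds, default [default_ranges()].
#' @param reg dosing regimen template, default [piperacillin_regimen()].
#' @param sampling_offsets hours after the last infusion's end.
#' @param error_poly assay [error_polynomial()] used to scale the noise.
#' @param seed integer seed; the cohort is deterministic given the seed.
#' @param noise set `FALSE` for noise-free observations.
#' @return object of class `synthetic_cohort`: list with `subjects` (list of
#'   `subject_data`), `truth` (data frame, one row per subject),
#'   `n_truncated` and `config`.
#' @export
generate_cohort <- function(n_subjects = 12, model_type = "1c",
                            ranges = default_ranges(model_type),
                            reg = piperacillin_regimen(),
                            sampling_offsets = c(0.25, 0.5, 1, 1.5, 2, 2.5),
                            error_poly = piperacillin_error_poly(),
                            seed = 1, noise = TRUE) {
  model_type <- match.arg(model_type, c("1c", "2c"))
  ranges <- check_ranges(ranges, model_type)
  build_cohort(n_subjects, model_type, ranges, reg, sampling_offsets,
               error_poly, seed, noise, crcl_range = NULL)
}

#' Generate a synthetic cohort with a creatinine-clearance covariate
#'
#' As [generate_cohort()], but for the covariate model types: each subject
#' additionally receives a CRCL drawn uniformly in `crcl_range` (mL/min) and
#' eliminates with `K = KI + KS * CRCL`.
#'
#' @inheritParams generate_cohort
#' @param crcl_range (low, high) creatinine clearance bounds, mL/min, > 0.
#' @return a `synthetic_cohort`; `truth` carries the CRCL column.
#' @export
generate_covariate_cohort <- function(n_subjects = 12, model_type = "1c_crcl",
                                      ranges = default_ranges(model_type),
                                      reg = piperacillin_regimen(),
                                      sampling_offsets = c(0.25, 0.5, 1, 1.5, 2, 2.5),
                                      error_poly = piperacillin_error_poly(),
                                      crcl_range = c(30, 150),
                                      seed = 1, noise = TRUE) {
  model_type <- match.arg(model_type, c("1c_crcl", "2c_crcl"))
  ranges <- check_ranges(ranges, model_type)
  if (length(crcl_range) != 2L || any(crcl_range <= 0) ||
      crcl_range[1] >= crcl_range[2])
    stop("`crcl_range` must be positive with low < high", call. = FALSE)
  build_cohort(n_subjects, model_type, ranges, reg, sampling_offsets,
               error_poly, seed, noise, crcl_range = crcl_range)
}

build_cohort <- function(n_subjects, model_type, ranges, reg,
                         sampling_offsets, error_poly, seed, noise,
                         crcl_range) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stop("`n_subjects` must be >= 1", call. = FALSE)
  check_regimen(reg)
  times <- sampling_times(reg, sampling_offsets)
  pn <- param_names(model_type)
  set.seed(seed)
  truth <- vapply(pn, function(p)
    stats::runif(n_subjects, ranges[1, p], ranges[2, p]),
    numeric(n_subjects))
  truth <- matrix(truth, nrow = n_subjects, dimnames = list(NULL, pn))
  crcl <- if (!is.null(crcl_range))
    stats::runif(n_subjects, crcl_range[1], crcl_range[2]) else NULL

  n_trunc <- 0L
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    pred <- predict_conc(truth[i, ], model_type, reg, times,
                         crcl = if (is.null(crcl)) NULL else crcl[i])
    obs <- if (noise) pred + stats::rnorm(length(pred),
                                          sd = sd_at(error_poly, pred))
           else pred
    trunc <- obs < 0
    n_trunc <- n_trunc + sum(trunc)
    obs[trunc] <- 0
    covs <- if (is.null(crcl)) list() else list(CRCL = crcl[i])
    subjects[[i]] <- subject_data(id = i, reg = reg, times = times,
                                  observations = obs, covariates = covs)
  }
  truth_df <- as.data.frame(truth)
  truth_df <- cbind(id = seq_len(n_subjects), truth_df)
  if (!is.null(crcl)) truth_df$CRCL <- crcl
  structure(list(
    subjects = subjects, truth = truth_df, n_truncated = n_trunc,
    config = list(n_subjects = n_subjects, model_type = model_type,
                  ranges = ranges, sampling_offsets = sampling_offsets,
                  seed = seed, noise = noise, crcl_range = crcl_range,
                  error_poly = error_poly$coefficients)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d subjects x %d observations (%s, seed %s)\n",
    length(x$subjects), length(x$subjects[[1]]$times),
    x$config$model_type, x$config$seed))
  if (x$n_truncated > 0)
    cat("  ", x$n_truncated, "negative noise draws truncated at 0\n")
  invisible(x)
}
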