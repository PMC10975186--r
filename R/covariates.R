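# Creatinine clearance from paired serum creatinine values via the
# unstable-renal-function mass balance of Jelliffe: daily creatinine
# production equals excretion plus the change in the body creatinine pool,
#   0.4 * BW * (c2 - c1) / T = P_adj - ((c1 + c2) / 2) * CCR * 1440
# with BW in kg, c1/c2 in mg/dL, T in days, P_adj in mg/day and CCR in
# hundreds of mL/min (1440 = minutes per day fixes the time base to days).

#' Jelliffe creatinine clearance for unstable renal function
#'
#' Solves the creatinine mass-balance equation for the clearance:
#' `CCR = (P_adj - 0.4 BW (c2 - c1) / T) / (1440 (c1 + c2) / 2)`.
#' At steady state (`c1 == c2`) this reduces to `P_adj / (1440 * c)`.
#'
#' @param body_weight kg, > 0.
#' @param c1,c2 first and second serum creatinine, mg/dL, > 0.
#' @param interval_T time between the two creatinine samples, in days
#'   (use [hours_to_days()] if needed); > 0.
#' @param p_adj adjusted daily creatinine production, mg/day
#'   (see [adjusted_production()]); > 0.
#' @return list with `ccr_hundred_ml_min` (the equation's native scale,
#'   hundreds of mL/min) and `ccr_ml_min` (mL/min, the scale consumed by
#'   [effective_K()] by default).
#' @export
jelliffe_crcl <- function(body_weight, c1, c2, interval_T, p_adj) {
  check_scalar(body_weight, "body_weight", positive = TRUE)
  check_scalar(c1, "c1", positive = TRUE)
  check_scalar(c2, "c2", positive = TRUE)
  check_scalar(interval_T, "interval_T", positive = TRUE)
  check_scalar(p_adj, "p_adj", positive = TRUE)
  ccr <- (p_adj - 0.4 * body_weight * (c2 - c1) / interval_T) /
    (1440 * (c1 + c2) / 2)
  if (ccr < 0)
    stop(sprintf(
      "nonphysical creatinine clearance (%g): inputs are inconsistent (creatinine rising faster than production allows)",
      ccr), call. = FALSE)
  list(ccr_hundred_ml_min = ccr, ccr_ml_min = 100 * ccr)
}

#' Convert hours to the day time base of the clearance equation
#' @param hours a duration in hours.
#' @return days.
#' @export
hours_to_days <- function(hours) hours / 24

#' Default constants for adjusted creatinine production
#'
#' The classic sex-specific linear-in-age excretion estimates
#' (mg/day per kg of body weight): males `29.3 - 0.203 * age`, females
#' `25.1 - 0.175 * age`, optionally corrected for unstable renal function by
#' the factor `1.035 - 0.0337 * mean serum creatinine`. All constants live
#' here so they can be overridden wholesale.
#'
#' @return a named list of constants.
#' @export
jelliffe_production_constants <- function() {
  list(male = c(intercept = 29.3, age_slope = 0.203),
       female = c(intercept = 25.1, age_slope = 0.175),
       correction = c(intercept = 1.035, scr_slope = 0.0337))
}

#' Adjusted daily creatinine production
#'
#' Estimated creatinine production in mg/day: proportional to body weight,
#' decreasing linearly in age, sex-specific, with an optional correction for
#' a non-steady-state mean serum creatinine.
#'
#' @param age years, > 0.
#' @param body_weight kg, > 0.
#' @param sex `"male"` or `"female"`.
#' @param mean_scr optional mean serum creatinine (mg/dL) for the
#'   unstable-renal-function correction; `NULL` skips the correction.
#' @param constants constants table, see [jelliffe_production_constants()].
#' @return P_adj in mg/day.
#' @export
adjusted_production <- function(age, body_weight, sex = c("male", "female"),
                                mean_scr = NULL,
                                constants = jelliffe_production_constants()) {
  check_scalar(age, "age", positive = TRUE)
  check_scalar(body_weight, "body_weight", positive = TRUE)
  sex <- match.arg(sex)
  k <- constants[[sex]]
  p <- body_weight * (k[["intercept"]] - k[["age_slope"]] * age)
  if (!is.null(mean_scr)) {
    check_scalar(mean_scr, "mean_scr", positive = TRUE)
    corr <- constants$correction
    p <- p * max(corr[["intercept"]] - corr[["scr_slope"]] * mean_scr, 0.1)
  }
  if (p <= 0)
    stop("adjusted production must be positive; age outside the supported range",
         call. = FALSE)
  p
}
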