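# Closed-form concentration predictions for IV-infusion compartment models.
# Units throughout: time h, amount mg, volume L, concentration mg/L,
# rate constants 1/h. Multi-dose regimens are handled by full-history
# superposition (the kinetics are linear); no steady-state shortcut.

#' Construct an infusion dose event
#'
#' A dose event is a constant-rate intravenous infusion defined by its start
#' time (hours from the subject's first dose), its duration (hours) and the
#' amount infused (mg).
#'
#' @param start_time infusion start, hours (>= 0 by convention, checked >= finite).
#' @param duration infusion length in hours; must be > 0 (bolus dosing is not
#'   modeled — use a short duration).
#' @param amount dose in mg, >= 0.
#' @return a one-row `regimen`.
#' @export
dose_event <- function(start_time, duration, amount) {
  check_scalar(start_time, "start_time")
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(amount, "amount", nonneg = TRUE)
  if (!is.finite(amount / duration))
    stop("infusion rate amount/duration must be finite", call. = FALSE)
  out <- data.frame(start = start_time, duration = duration, amount = amount)
  class(out) <- c("regimen", "data.frame")
  out
}

#' Combine dose events into a regimen
#'
#' Events are sorted by start time; overlapping infusions are legal and are
#' handled by superposition.
#'
#' @param ... `regimen` objects (e.g. from [dose_event()]) to concatenate.
#' @return a `regimen` data frame with columns `start`, `duration`, `amount`.
#' @export
regimen <- function(...) {
  events <- list(...)
  if (!length(events)) stop("a regimen needs at least one dose event", call. = FALSE)
  out <- do.call(rbind, lapply(events, function(e) {
    if (!inherits(e, "regimen")) stop("all arguments must be regimen objects", call. = FALSE)
    as.data.frame(e)
  }))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("regimen", "data.frame")
  out
}

#' The study dosing regimen: repeated 3-h piperacillin infusions every 6 h
#'
#' Builds the reference regimen of the modeled study design: 4000 mg
#' piperacillin every 6 h as a 3-h infusion. Sampling takes place after the
#' end of the last infusion; the number of infusions administered before the
#' sampled one is patient-history dependent and is therefore an argument
#' (default 4, i.e. at least 24 h of q6h therapy before sampling).
#'
#' @param dose per-infusion dose, mg.
#' @param interval dosing interval, h.
#' @param duration infusion duration, h.
#' @param n_prior_doses infusions given before the sampled one.
#' @return a `regimen` with `n_prior_doses + 1` events starting at t = 0.
#' @export
piperacillin_regimen <- function(dose = 4000, interval = 6, duration = 3,
                                 n_prior_doses = 4) {
  check_scalar(n_prior_doses, "n_prior_doses", nonneg = TRUE)
  starts <- seq(0, by = interval, length.out = n_prior_doses + 1)
  do.call(regimen, lapply(starts, dose_event, duration = duration, amount = dose))
}

#' Post-infusion sampling times for a regimen
#'
#' @param reg a `regimen`.
#' @param offsets hours after the end of the last infusion; defaults to the
#'   rich design 0.25, 0.5, 1, 1.5, 2, 2.5 h.
#' @return sampling times in hours from the first dose.
#' @export
sampling_times <- function(reg, offsets = c(0.25, 0.5, 1, 1.5, 2, 2.5)) {
  stopifnot(inherits(reg, "regimen"))
  last <- which.max(reg$start + reg$duration)
  reg$start[last] + reg$duration[last] + offsets
}

check_regimen <- function(reg) {
  if (!inherits(reg, "regimen")) stop("`regimen` must be a regimen object", call. = FALSE)
  invisible(reg)
}

# One-exponential infusion/washout kernel, vectorized over times:
# (1 - exp(-lambda * te)) * exp(-lambda * tw) / lambda, where te is the
# exposure (time spent inside the infusion window) and tw the washout time.
infusion_kernel <- function(lambda, te, tw) {
  (1 - exp(-lambda * te)) * exp(-lambda * tw) / lambda
}

# Repeated-eigenvalue limiting kernel for the two-compartment model:
# integral over u in [tw, tw + te] of exp(-lambda u) (1 + a u) du.
infusion_kernel_repeated <- function(lambda, a, te, tw) {
  anti <- function(u) -exp(-lambda * u) * (1 / lambda + a * (u / lambda + 1 / lambda^2))
  anti(tw + te) - anti(tw)
}

#' Predict concentrations from a one-compartment infusion model
#'
#' Closed-form solution of `dA/dt = input(t) - K A`, `c = A/V`, superposed
#' over all dose events of the regimen. For a single infusion at rate R0 the
#' concentration is `R0/(K V) (1 - exp(-K t))` during the infusion and decays
#' mono-exponentially afterwards.
#'
#' @param params list or named vector with `K` (elimination rate constant,
#'   1/h, > 0) and `V` (apparent volume of distribution, L, > 0).
#' @param reg a `regimen`.
#' @param times sampling times, hours >= 0.
#' @return concentrations in mg/L, one per time.
#' @export
predict_1c <- function(params, reg, times) {
  K <- check_scalar(params[["K"]], "K", positive = TRUE)
  V <- check_scalar(params[["V"]], "V", positive = TRUE)
  check_regimen(reg)
  times <- check_times(times)
  conc <- numeric(length(times))
  for (i in seq_len(nrow(reg))) {
    s <- reg$start[i]; d <- reg$duration[i]
    r0 <- reg$amount[i] / d
    te <- pmin(pmax(times - s, 0), d)
    tw <- pmax(times - s - d, 0)
    conc <- conc + (r0 / V) * infusion_kernel(K, te, tw)
  }
  conc
}

# Eigenstructure of the two-compartment micro-constant system.
# alpha + beta = K + KCP + KPC, alpha * beta = K * KPC; the discriminant is
# (K - KPC)^2 + KCP^2 + 2 KCP (K + KPC) >= 0 for admissible parameters.
two_cmt_eigen <- function(K, KCP, KPC) {
  s <- K + KCP + KPC
  disc <- s^2 - 4 * K * KPC
  disc <- max(disc, 0)
  alpha <- (s + sqrt(disc)) / 2
  beta  <- (s - sqrt(disc)) / 2
  list(alpha = alpha, beta = beta)
}

#' Predict concentrations from a two-compartment infusion model
#'
#' Central-compartment concentration from the standard bi-exponential
#' solution with micro rate constants `K` (elimination from central), `KCP`
#' and `KPC` (central-to-peripheral and back transfer) and central volume
#' `Vc`, superposed over the regimen's dose events. When the two eigenvalues
#' coincide within a relative gap of 1e-10 the l'Hopital limiting
#' (critically damped) form is used instead of the bi-exponential.
#'
#' @param params list or named vector with `K`, `KCP`, `KPC` (1/h) and `Vc` (L).
#'   `KCP = 0` is allowed (and reduces exactly to the one-compartment model);
#'   `KPC` must be > 0 whenever `KCP` > 0.
#' @inheritParams predict_1c
#' @return central concentrations in mg/L.
#' @export
predict_2c <- function(params, reg, times) {
  K   <- check_scalar(params[["K"]], "K", positive = TRUE)
  KCP <- check_scalar(params[["KCP"]], "KCP", nonneg = TRUE)
  KPC <- check_scalar(params[["KPC"]], "KPC", nonneg = TRUE)
  Vc  <- check_scalar(params[["Vc"]], "Vc", positive = TRUE)
  if (KCP > 0 && KPC <= 0)
    stop("KPC must be > 0 when KCP > 0 (drug would be trapped peripherally)",
         call. = FALSE)
  check_regimen(reg)
  times <- check_times(times)
  if (KCP == 0)  # peripheral compartment never populated
    return(predict_1c(list(K = K, V = Vc), reg, times))

  eig <- two_cmt_eigen(K, KCP, KPC)
  alpha <- eig$alpha; beta <- eig$beta
  repeated <- (alpha - beta) < 1e-10 * alpha

  conc <- numeric(length(times))
  for (i in seq_len(nrow(reg))) {
    s <- reg$start[i]; d <- reg$duration[i]
    r0 <- reg$amount[i] / d
    te <- pmin(pmax(times - s, 0), d)
    tw <- pmax(times - s - d, 0)
    if (repeated) {
      lam <- (alpha + beta) / 2
      conc <- conc + (r0 / Vc) * infusion_kernel_repeated(lam, lam - KPC, te, tw)
    } else {
      c1 <- (alpha - KPC) / (alpha - beta)
      c2 <- (KPC - beta) / (alpha - beta)
      conc <- conc + (r0 / Vc) *
        (c1 * infusion_kernel(alpha, te, tw) + c2 * infusion_kernel(beta, te, tw))
    }
  }
  conc
}

#' Covariate-driven elimination rate constant
#'
#' Renal-function parameterization of elimination:
#' `K = KI + KS * CRCL`, with `KI` the non-renal and `KS` the renal
#' elimination rate component. `CRCL` is creatinine clearance in mL/min
#' (the package-wide default scale; see [jelliffe_crcl()]).
#'
#' @param KI non-renal elimination rate constant, 1/h, >= 0.
#' @param KS renal elimination rate constant per mL/min of clearance, >= 0.
#' @param crcl creatinine clearance, mL/min, >= 0.
#' @return elimination rate constant, 1/h.
#' @export
effective_K <- function(KI, KS, crcl) {
  check_scalar(KI, "KI", nonneg = TRUE)
  check_scalar(KS, "KS", nonneg = TRUE)
  check_scalar(crcl, "crcl", nonneg = TRUE)
  K <- KI + KS * crcl
  if (K <= 0)
    stop(sprintf("effective K = KI + KS * CRCL must be > 0 (got %g)", K),
         call. = FALSE)
  K
}

# ---- model-type plumbing -------------------------------------------------

MODEL_TYPES <- c("1c", "2c", "1c_crcl", "2c_crcl")

#' Parameter names of a model type
#'
#' Model types: `"1c"` (K, V), `"2c"` (K, KCP, KPC, Vc), `"1c_crcl"`
#' (KI, KS, V) and `"2c_crcl"` (KI, KS, KCP, KPC, Vc). The `_crcl` variants
#' use `K = KI + KS * CRCL`.
#'
#' @param model_type one of `"1c"`, `"2c"`, `"1c_crcl"`, `"2c_crcl"`.
#' @return character vector of random-effect parameter names, in canonical order.
#' @export
param_names <- function(model_type) {
  switch(match.arg(model_type, MODEL_TYPES),
         "1c" = c("K", "V"),
         "2c" = c("K", "KCP", "KPC", "Vc"),
         "1c_crcl" = c("KI", "KS", "V"),
         "2c_crcl" = c("KI", "KS", "KCP", "KPC", "Vc"))
}

model_uses_crcl <- function(model_type) grepl("_crcl$", model_type)

#' Predict concentrations for any supported model type
#'
#' Dispatches a named parameter vector to [predict_1c()] or [predict_2c()],
#' resolving the covariate parameterization (`K = KI + KS * CRCL`) when the
#' model type requires a creatinine clearance.
#'
#' @param theta named numeric vector with the parameters of `model_type`
#'   (see [param_names()]).
#' @param model_type model type string.
#' @param reg a `regimen`.
#' @param times sampling times, h.
#' @param crcl creatinine clearance in mL/min; required by the `_crcl` types.
#' @return concentrations, mg/L.
#' @export
predict_conc <- function(theta, model_type, reg, times, crcl = NULL) {
  model_type <- match.arg(model_type, MODEL_TYPES)
  if (model_uses_crcl(model_type)) {
    if (is.null(crcl))
      stop(sprintf("model type '%s' requires a CRCL covariate", model_type),
           call. = FALSE)
    K <- effective_K(theta[["KI"]], theta[["KS"]], crcl)
  } else {
    K <- theta[["K"]]
  }
  if (model_type %in% c("1c", "1c_crcl")) {
    predict_1c(list(K = K, V = theta[["V"]]), reg, times)
  } else {
    predict_2c(list(K = K, KCP = theta[["KCP"]], KPC = theta[["KPC"]],
                    Vc = theta[["Vc"]]), reg, times)
  }
}

# Predictions for a matrix of support points (rows) at common times.
# Vectorized over points for the 1-compartment types, where the kernel is a
# scalar function of K only; loops for the 2-compartment types.
predict_matrix <- function(thetas, model_type, reg, times, crcl = NULL) {
  model_type <- match.arg(model_type, MODEL_TYPES)
  n <- nrow(thetas)
  if (model_type %in% c("1c", "1c_crcl")) {
    K <- if (model_uses_crcl(model_type)) {
      if (is.null(crcl)) stop("CRCL covariate required", call. = FALSE)
      thetas[, "KI"] + thetas[, "KS"] * crcl
    } else thetas[, "K"]
    V <- thetas[, "V"]
    if (any(K <= 0) || any(V <= 0))
      stop("all support points must have K > 0 and V > 0", call. = FALSE)
    out <- matrix(0, n, length(times))
    for (i in seq_len(nrow(reg))) {
      s <- reg$start[i]; d <- reg$duration[i]
      r0 <- reg$amount[i] / d
      te <- pmin(pmax(times - s, 0), d)
      tw <- pmax(times - s - d, 0)
      # outer over (points, times)
      ek <- exp(-outer(K, te))
      ew <- exp(-outer(K, tw))
      out <- out + (r0 / (K * V)) * (1 - ek) * ew
    }
    out
  } else {
    t(vapply(seq_len(n), function(j)
      predict_conc(thetas[j, ], model_type, reg, times, crcl),
      numeric(length(times))))
  }
}
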