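# Nonparametric maximum-likelihood estimation of the population mixing
# distribution on an adaptively refined grid of support points, and the
# population-level fit diagnostics.

#' Bundle the observation error model
#'
#' Combines an assay [error_polynomial()], optional proportional
#' [noise_settings()] and a multiplicative inflation `gamma` into the single
#' object consumed by the likelihood machinery. The default is the pure
#' piperacillin assay polynomial (no extra noise, gamma 1), which is the
#' error model under which the population fits are run; the clinical noise
#' settings belong to individual-level dosing software conventions.
#'
#' @param poly an `error_polynomial`.
#' @param noise a `noise_settings` object or `NULL`.
#' @param gamma multiplicative SD inflation, > 0.
#' @return an `error_model` object.
#' @export
error_model <- function(poly = piperacillin_error_poly(), noise = NULL,
                        gamma = 1) {
  stopifnot(inherits(poly, "error_polynomial"))
  check_scalar(gamma, "gamma", positive = TRUE)
  structure(list(poly = poly, noise = noise, gamma = gamma),
            class = "error_model")
}

# Log-likelihood of one subject's observations under each support point
# (rows of `thetas`); Gaussian observation model with variance from the
# error model evaluated at the predicted concentration.
loglik_points <- function(thetas, subject, model_type, error) {
  stopifnot(inherits(error, "error_model"))
  preds <- predict_matrix(thetas, model_type, subject$regimen, subject$times,
                          crcl = subject_crcl(subject))
  v <- observation_variance(error$poly, as.vector(preds), error$noise,
                            error$gamma)
  ll <- stats::dnorm(rep(subject$observations, each = nrow(preds)),
                     mean = as.vector(preds), sd = sqrt(v), log = TRUE)
  rowSums(matrix(ll, nrow = nrow(preds)))
}

#' Per-subject likelihood matrix over a mixture's support points
#'
#' `L[i, j] = p(subject i's observations | theta_j)` as a product of normal
#' densities. Computed in log space; each row is rescaled by its maximum to
#' avoid underflow, and the log of that scaling constant is returned in
#' `log_scale` so that the exact log-likelihood of weights `w` is
#' `sum(log(L %*% w) + log_scale)`.
#'
#' @param subjects list of `subject_data`.
#' @param mixture a `discrete_mixture` (only its support points are used).
#' @param error an [error_model()].
#' @return object of class `likelihood_matrix`: list with `L` (scaled
#'   likelihoods), `log_scale` (per subject) and `ids`.
#' @export
likelihood_matrix <- function(subjects, mixture, error = error_model()) {
  stopifnot(inherits(mixture, "discrete_mixture"))
  M <- t(vapply(subjects, function(s)
    loglik_points(mixture$points, s, mixture$model_type, error),
    numeric(nrow(mixture$points))))
  M <- matrix(M, nrow = length(subjects))  # guard the 1-point edge case
  log_scale <- apply(M, 1, max)
  bad <- !is.finite(log_scale)
  if (any(bad))
    stop(sprintf(
      "degenerate likelihood: subject %s cannot be explained by any support point",
      subjects[[which(bad)[1]]]$id), call. = FALSE)
  structure(list(L = exp(M - log_scale), log_scale = log_scale,
                 ids = vapply(subjects, function(s) as.character(s$id), "")),
            class = "likelihood_matrix")
}

#' Maximum-likelihood mixture weights on a fixed grid
#'
#' Maximizes `sum_i log sum_j w_j L[i, j]` over the probability simplex by
#' the multiplicative (EM) update
#' `w_j <- w_j * mean_i (L[i, j] / sum_k w_k L[i, k])`, which increases the
#' log-likelihood at every iteration. Iteration stops when the gain drops
#' below `tol` or at `max_iter` (with a warning, not a failure).
#'
#' @param lmat a [likelihood_matrix()] (or a plain nonnegative matrix, in
#'   which case the scaling constants are taken as 0).
#' @param initial starting weights; default uniform.
#' @param tol log-likelihood gain convergence threshold.
#' @param max_iter iteration cap.
#' @return list with `weights`, `logLik`, `iterations`, `converged` and
#'   `trace` (log-likelihood per iteration; non-decreasing).
#' @export
optimize_weights <- function(lmat, initial = NULL, tol = 1e-8,
                             max_iter = 5000) {
  if (inherits(lmat, "likelihood_matrix")) {
    L <- lmat$L; log_scale <- lmat$log_scale
  } else {
    L <- as.matrix(lmat); log_scale <- rep(0, nrow(L))
  }
  if (any(L < 0)) stop("likelihoods must be nonnegative", call. = FALSE)
  if (any(rowSums(L) == 0))
    stop("likelihood matrix has an all-zero row", call. = FALSE)
  J <- ncol(L)
  w <- if (is.null(initial)) rep(1 / J, J) else {
    if (length(initial) != J || any(initial < 0) || sum(initial) <= 0)
      stop("invalid initial weights", call. = FALSE)
    initial / sum(initial)
  }
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    denom <- as.vector(L %*% w)
    ll <- sum(log(denom) + log_scale)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
    w <- w * colMeans(L / denom)
    w <- w / sum(w)
  }
  if (!converged)
    warning(sprintf(
      "weight optimization stopped at %d iterations (last gain %.3g > tol %.3g)",
      max_iter, ll - ll_old, tol), call. = FALSE)
  # directional derivative of the log-likelihood toward each vertex of the
  # simplex; at the optimum D_j = 1 exactly on the support, < 1 elsewhere
  D <- colMeans(L / as.vector(L %*% w))
  list(weights = w, logLik = trace[length(trace)], iterations = length(trace),
       converged = converged, trace = trace, support_criterion = D)
}

# Perturbation directions for grid refinement: all sign vectors with one or
# two nonzero coordinates (2d axis moves plus 4*choose(d,2) pair diagonals).
refinement_directions <- function(d) {
  dirs <- list()
  for (i in seq_len(d)) for (s in c(-1, 1)) {
    v <- numeric(d); v[i] <- s
    dirs[[length(dirs) + 1L]] <- v
  }
  if (d >= 2) for (i in seq_len(d - 1)) for (j in (i + 1):d)
    for (si in c(-1, 1)) for (sj in c(-1, 1)) {
      v <- numeric(d); v[i] <- si; v[j] <- sj
      dirs[[length(dirs) + 1L]] <- v
    }
  dirs
}

# Greedy merge of near-duplicate support points: points whose every
# coordinate differs by less than `tol_rel` of the parameter range are
# collapsed onto the heavier point, probabilities summed. Heavier points
# absorb lighter ones, so the kept set is weight-ordered greedy maximal.
merge_points <- function(points, prob, ranges, tol_rel = 1e-4) {
  width <- ranges[2, ] - ranges[1, ]
  z <- sweep(points, 2, width, `/`)  # range-scaled coordinates
  ord <- order(prob, decreasing = TRUE)
  p <- ncol(points)
  keep <- integer(0)
  for (j in ord) {
    if (length(keep)) {
      zk <- z[keep, , drop = FALSE]
      gap <- abs(zk[, 1] - z[j, 1])
      for (c in seq_len(p)[-1]) gap <- pmax(gap, abs(zk[, c] - z[j, c]))
      hit <- which(gap < tol_rel)
      if (length(hit)) {
        k <- keep[hit[1]]
        prob[k] <- prob[k] + prob[j]
        next
      }
    }
    keep <- c(keep, j)
  }
  keep <- sort(keep)
  list(points = points[keep, , drop = FALSE], prob = prob[keep] / sum(prob[keep]))
}

#' Adaptive-grid nonparametric maximum-likelihood fit
#'
#' Estimates the discrete population mixing distribution by iterating:
#' (1) maximum-likelihood weighting of the current candidate grid
#' ([optimize_weights()]); (2) condensation — dropping points with weight
#' below `1e-8` of the maximum and merging points closer, in every
#' coordinate, than the grid's current working resolution (a quarter of the
#' active perturbation size, floored at `1e-4` of each parameter's range;
#' without the scale-aware merge, near-duplicate points split their weight
#' and escape the relative drop threshold); (3) refinement —
#' adding, for every surviving point and every dimension, the two
#' `±delta` perturbations clipped to the ranges, with `delta` starting at
#' 20% of each range. Whenever a cycle's log-likelihood gain falls below
#' `tol`, `delta` contracts by `refinement_shrink`; the fit terminates when
#' the gain is below `tol` with `delta` already at its floor `delta_min`
#' (or at `max_cycles`). Contraction-before-termination lets the grid walk
#' along curved likelihood ridges that axis-aligned perturbations at a
#' single scale cannot improve on.
#' The initial grid is a seeded randomly-shifted Halton set.
#'
#' @param subjects list of `subject_data`.
#' @param model_type model type string.
#' @param ranges parameter bounds; default [default_ranges()].
#' @param error an [error_model()].
#' @param n_initial initial grid size.
#' @param refinement_shrink multiplicative contraction of the perturbation
#'   size on a stalled cycle, in (0, 1).
#' @param tol stopping threshold on the per-cycle log-likelihood gain.
#' @param delta_min smallest perturbation size (as a fraction of each
#'   parameter range) at which a stalled cycle terminates the fit.
#' @param max_cycles cycle cap.
#' @param seed integer seed for the randomized initial grid.
#' @param metrics if `TRUE`, also compute the [fit_metrics()] report.
#' @return list with `mixture` (a `discrete_mixture`), `logLik`, `cycles`,
#'   `cycle_logLik` (per-cycle trace) and, if requested, `report`.
#' @export
adaptive_grid_fit <- function(subjects, model_type,
                              ranges = default_ranges(model_type),
                              error = error_model(),
                              n_initial = 100, refinement_shrink = 0.5,
                              tol = 0.01, delta_min = 1e-4, max_cycles = 400,
                              seed = 1, metrics = TRUE) {
  model_type <- match.arg(model_type, MODEL_TYPES)
  ranges <- check_ranges(ranges, model_type)
  if (!length(subjects)) stop("at least one subject is required", call. = FALSE)
  pn <- param_names(model_type)
  width <- ranges[2, ] - ranges[1, ]

  set.seed(seed)
  u <- (halton(n_initial, length(pn)) +
          matrix(stats::runif(length(pn)), n_initial, length(pn),
                 byrow = TRUE)) %% 1
  grid <- sweep(sweep(u, 2, width, `*`), 2, ranges[1, ], `+`)
  colnames(grid) <- pn

  delta <- 0.2
  prev_ll <- -Inf
  cycle_ll <- numeric(0)
  best <- NULL
  for (cycle in seq_len(max_cycles)) {
    mix <- discrete_mixture(grid, rep(1 / nrow(grid), nrow(grid)), ranges,
                            model_type)
    lmat <- likelihood_matrix(subjects, mix, error)
    opt <- suppressWarnings(optimize_weights(lmat))
    ll <- opt$logLik
    cycle_ll <- c(cycle_ll, ll)

    # condense: the relative weight threshold plus the support-criterion
    # purge (points with D_j measurably below 1 are provably off-support at
    # the optimum; EM alone only decays their weight geometrically slowly)
    keep <- opt$weights > 1e-8 * max(opt$weights) &
      opt$support_criterion > 1 - 1e-6
    keep[which.max(opt$weights)] <- TRUE
    if (!any(keep))
      stop("internal consistency error: grid empty after condensation",
           call. = FALSE)
    # merge at the resolution the grid is currently refined at (floor 1e-4):
    # near-duplicates at the working scale split their weight and would
    # otherwise defeat the relative drop threshold, inflating the grid
    merge_tol <- max(1e-4, 0.25 * delta)
    merged <- merge_points(grid[keep, , drop = FALSE],
                           opt$weights[keep] / sum(opt$weights[keep]), ranges,
                           tol_rel = merge_tol)
    best <- merged

    if (is.infinite(tol)) break
    if (ll - prev_ll < tol) {
      if (delta <= delta_min) break
      delta <- max(delta * refinement_shrink, delta_min)
    }
    prev_ll <- ll

    # refine: perturb each surviving point by +/- delta along every axis and
    # every pair diagonal (axis moves alone stall on coordinate-wise saddle
    # points of correlated parameters such as K and V), clipped to the box
    base <- merged$points
    new_pts <- do.call(rbind, lapply(refinement_directions(length(pn)),
                                     function(dir) {
      shift <- sweep(base, 2, delta * width * dir, `+`)
      shift <- pmin(pmax(shift, rep(ranges[1, ], each = nrow(shift))),
                    rep(ranges[2, ], each = nrow(shift)))
      shift
    }))
    cand <- rbind(base, new_pts)
    # deduplicate within the merge tolerance, preferring existing points
    dedup <- merge_points(cand, rep(1 / nrow(cand), nrow(cand)), ranges,
                          tol_rel = min(1e-4, 0.25 * delta))
    grid <- dedup$points
  }

  # final polish: converge the weights on the condensed support alone
  final_mix <- discrete_mixture(best$points, best$prob, ranges, model_type)
  final_opt <- suppressWarnings(optimize_weights(
    likelihood_matrix(subjects, final_mix, error), initial = best$prob))
  keep <- final_opt$weights > 1e-8 * max(final_opt$weights)
  mixture <- discrete_mixture(best$points[keep, , drop = FALSE],
                              final_opt$weights[keep] / sum(final_opt$weights[keep]),
                              ranges, model_type)
  out <- list(mixture = mixture, logLik = final_opt$logLik,
              cycles = length(cycle_ll), cycle_logLik = cycle_ll)
  if (metrics) out$report <- fit_metrics(subjects, mixture, error)
  out
}

#' Observed-versus-predicted regression diagnostics
#'
#' Ordinary least squares of observed on predicted concentrations; `r2` is
#' the squared Pearson correlation.
#'
#' @param observed,predicted equal-length concentration vectors (>= 3 pairs).
#' @return list with `slope`, `intercept`, `r2`.
#' @export
obs_pred_regression <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3L)
    stop("need >= 3 observed/predicted pairs", call. = FALSE)
  if (stats::var(predicted) == 0)
    stop("undefined regression: predicted values have zero variance",
         call. = FALSE)
  fit <- stats::lm(observed ~ predicted)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = stats::cor(observed, predicted)^2)
}

#' Small-sample-corrected AIC and BIC from a -2 log-likelihood
#'
#' `AICc = -2LL + 2P + 2P(P+1)/(N - P - 1)` and `BIC = -2LL + P ln N`, with
#' `N` the total number of observations and `P` the number of estimated
#' parameters (random-effect parameters plus one error parameter). The
#' small-sample correction is used because it reproduces the reference
#' piperacillin model comparison exactly; it converges to plain AIC as N
#' grows.
#'
#' @param neg2LL -2 log-likelihood.
#' @param P number of parameters.
#' @param N total number of observations; must exceed `P + 1` for the AICc
#'   correction term.
#' @return list with `AIC` and `BIC`.
#' @export
information_criteria <- function(neg2LL, P, N) {
  check_scalar(neg2LL, "neg2LL")
  check_scalar(P, "P", positive = TRUE)
  check_scalar(N, "N", positive = TRUE)
  if (N <= P + 1)
    stop("small-sample AIC correction requires N > P + 1", call. = FALSE)
  list(AIC = neg2LL + 2 * P + 2 * P * (P + 1) / (N - P - 1),
       BIC = neg2LL + P * log(N))
}

n_params <- function(model_type) length(param_names(model_type)) + 1L

#' Population-level fit diagnostics for a mixture
#'
#' Computes the standard nonparametric-fit report: -2 log-likelihood,
#' small-sample-corrected AIC, BIC ([information_criteria()] with
#' `P = #random-effect parameters + 1` error parameter), weighted prediction
#' error diagnostics (bias = mean of `(obs - pred_pop)/SD`, imprecision =
#' bias-adjusted mean square of the same), per-parameter shrinkage
#' (100 x mean posterior variance / population variance), and
#' observed-vs-predicted regressions for both population (prior-weighted)
#' and posterior (individually reweighted) predictions.
#'
#' @inheritParams likelihood_matrix
#' @return an object of class `fit_report` (a named list).
#' @export
fit_metrics <- function(subjects, mixture, error = error_model()) {
  stopifnot(inherits(mixture, "discrete_mixture"))
  lmat <- likelihood_matrix(subjects, mixture, error)
  N <- n_obs(subjects)
  P <- n_params(mixture$model_type)
  neg2LL <- -2 * sum(log(lmat$L %*% mixture$prob) + lmat$log_scale)
  ic <- information_criteria(neg2LL, P, N)

  pop_var <- mixture_moments(mixture)$var
  obs <- pred_pop <- pred_post <- numeric(0)
  wpe <- numeric(0)
  post_var <- matrix(0, length(subjects), ncol(mixture$points),
                     dimnames = list(NULL, colnames(mixture$points)))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    preds <- predict_matrix(mixture$points, mixture$model_type, s$regimen,
                            s$times, crcl = subject_crcl(s))
    pop_i <- colSums(mixture$prob * preds)
    post <- posterior(mixture, s, error)
    post_i <- post$predictions
    post_var[i, ] <- mixture_moments(post$posterior)$var
    sd_i <- sqrt(observation_variance(error$poly, pop_i, error$noise,
                                      error$gamma))
    obs <- c(obs, s$observations)
    pred_pop <- c(pred_pop, pop_i)
    pred_post <- c(pred_post, post_i)
    wpe <- c(wpe, (s$observations - pop_i) / sd_i)
  }
  bias <- mean(wpe)
  imprecision <- mean(wpe^2) - bias^2
  shrinkage <- 100 * colMeans(post_var) / pop_var

  structure(list(
    neg2LL = neg2LL, AIC = ic$AIC, BIC = ic$BIC, P = P, N = N,
    bias = bias, imprecision = imprecision, shrinkage = shrinkage,
    n_support = nrow(mixture$points),
    regression_population = obs_pred_regression(obs, pred_pop),
    regression_posterior = obs_pred_regression(obs, pred_post)),
    class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("Nonparametric fit report (N = %d observations, P = %d)\n",
              x$N, x$P))
  cat(sprintf("  -2LL %.1f  AIC %.1f  BIC %.1f  support points %d\n",
              x$neg2LL, x$AIC, x$BIC, x$n_support))
  cat(sprintf("  bias %.4f  imprecision %.4f\n", x$bias, x$imprecision))
  cat("  shrinkage (%):",
      paste(sprintf("%s=%.3g", names(x$shrinkage), x$shrinkage),
            collapse = ", "), "\n")
  rp <- x$regression_posterior
  cat(sprintf("  obs~pred (posterior): slope %.3f, intercept %.3f, r2 %.4f\n",
              rp$slope, rp$intercept, rp$r2))
  invisible(x)
}
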