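# Fully artificial quasi-models: discrete priors whose support points are
# uniform random draws within the stated parameter ranges, all with equal
# probability. None of the points represents a real subject; the ranges are
# the only information carried over from population modeling.

#' Generate one quasi-model
#'
#' Draws `n_points` values uniformly and independently for each parameter of
#' the model type (one uniform stream per parameter, in canonical parameter
#' order); point `j` pairs the `j`-th draw of every parameter and carries
#' probability `1/n_points`. The default of 399 points reflects the support
#' cap of the clinical software the construction was designed around; it is
#' a default here, not a limit.
#'
#' @param ranges generation bounds, 2-row matrix as [default_ranges()];
#'   default the packaged piperacillin ranges for `model_type`.
#' @param model_type model type string.
#' @param n_points number of support points, >= 1.
#' @param seed integer seed; same seed, same mixture.
#' @return a `discrete_mixture` with equal probabilities.
#' @export
generate_quasi_model <- function(ranges = default_ranges(model_type),
                                 model_type = "1c", n_points = 399,
                                 seed = 1) {
  model_type <- match.arg(model_type, MODEL_TYPES)
  ranges <- check_ranges(ranges, model_type)
  n_points <- as.integer(n_points)
  if (n_points < 1L) stop("`n_points` must be >= 1", call. = FALSE)
  set.seed(seed)
  pn <- param_names(model_type)
  pts <- vapply(pn, function(p)
    stats::runif(n_points, ranges[1, p], ranges[2, p]),
    numeric(n_points))
  pts <- matrix(pts, nrow = n_points, dimnames = list(NULL, pn))
  discrete_mixture(pts, rep(1 / n_points, n_points), ranges, model_type)
}

#' Generate a batch of quasi-models
#'
#' Creates `n_models` quasi-models (default 30, the reference batch size per
#' model type) with per-model seeds derived reproducibly from `master_seed`.
#'
#' @inheritParams generate_quasi_model
#' @param n_models number of quasi-models, >= 1.
#' @param master_seed integer seed from which per-model seeds are drawn.
#' @return an object of class `quasi_model_batch`: list with `models`,
#'   `seeds`, `n_points`, `ranges`, `model_type`.
#' @export
generate_batch <- function(ranges = default_ranges(model_type),
                           model_type = "1c", n_models = 30, n_points = 399,
                           master_seed = 1) {
  model_type <- match.arg(model_type, MODEL_TYPES)
  ranges <- check_ranges(ranges, model_type)
  n_models <- as.integer(n_models)
  if (n_models < 1L) stop("`n_models` must be >= 1", call. = FALSE)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max, n_models)
  models <- lapply(seeds, function(s)
    generate_quasi_model(ranges, model_type, n_points, seed = s))
  structure(list(models = models, seeds = seeds, n_points = n_points,
                 ranges = ranges, model_type = model_type),
            class = "quasi_model_batch")
}

#' @export
print.quasi_model_batch <- function(x, ...) {
  cat(sprintf("Quasi-model batch: %d models x %d support points (%s)\n",
              length(x$models), x$n_points, x$model_type))
  invisible(x)
}

#' Select the best quasi-model for a subject by prediction MSE
#'
#' Runs the nonparametric MAP Bayesian [posterior()] for every model in the
#' batch against one subject's data and picks the model with the lowest mean
#' squared prediction error; ties break to the lowest model index, so
#' selection is deterministic and invariant to evaluation order. Models with
#' a degenerate posterior are excluded with a warning.
#'
#' @param batch a [generate_batch()] result.
#' @param subject a `subject_data`.
#' @param error an [error_model()].
#' @return list with `best_index`, `best` (the winning
#'   `individual_posterior`) and `mse_table` (data frame: model, seed, mse).
#' @export
select_best <- function(batch, subject, error = error_model()) {
  stopifnot(inherits(batch, "quasi_model_batch"),
            inherits(subject, "subject_data"))
  mses <- rep(NA_real_, length(batch$models))
  posts <- vector("list", length(batch$models))
  for (m in seq_along(batch$models)) {
    posts[[m]] <- tryCatch(posterior(batch$models[[m]], subject, error),
                           error = function(e) {
                             warning(sprintf(
                               "quasi-model %d excluded for subject %s: %s",
                               m, subject$id, conditionMessage(e)),
                               call. = FALSE)
                             NULL
                           })
    if (!is.null(posts[[m]])) mses[m] <- posts[[m]]$mse
  }
  if (all(is.na(mses)))
    stop(sprintf("all quasi-models degenerate for subject %s", subject$id),
         call. = FALSE)
  best <- which.min(mses)  # NA-safe; ties -> lowest index
  list(best_index = best, best = posts[[best]],
       mse_table = data.frame(model = seq_along(mses), seed = batch$seeds,
                              mse = mses))
}
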