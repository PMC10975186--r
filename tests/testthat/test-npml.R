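# Helpers shared by the estimation tests: a tiny single-infusion world in
# which predictions are easy to control.
one_obs_subject <- function(obs, id = 1) {
  subject_data(id, dose_event(0, 3, 4000), times = 3, observations = obs)
}

test_that("likelihood matrix is a product of normal densities in log space", {
  reg <- dose_event(0, 3, 4000)
  tt <- c(3, 4, 5)
  theta <- c(K = 0.5, V = 20)
  pred <- predict_1c(list(K = 0.5, V = 20), reg, tt)
  err <- error_model(error_polynomial(2))  # constant SD = 2

  # zero residuals: log L = -sum(log(sigma sqrt(2 pi)))
  s <- subject_data(1, reg, tt, pred)
  mix <- discrete_mixture(matrix(theta, 1, dimnames = list(NULL, c("K", "V"))),
                          1, default_ranges("1c"), "1c")
  lm1 <- likelihood_matrix(list(s), mix, err)
  expect_equal(lm1$log_scale[1], -3 * log(2 * sqrt(2 * pi)), tolerance = 1e-12)
  expect_equal(as.vector(lm1$L), 1)

  # one observation, residual 2, SD 2: density exp(-1/2)/(2 sqrt(2 pi))
  s2 <- subject_data(2, reg, 3, pred[1] + 2)
  lm2 <- likelihood_matrix(list(s2), mix, err)
  expect_equal(exp(lm2$log_scale[1]), exp(-0.5) / (2 * sqrt(2 * pi)),
               tolerance = 1e-9)

  # duplicated support points give identical columns
  pts <- rbind(theta, theta)
  mix2 <- discrete_mixture(pts, c(0.5, 0.5), default_ranges("1c"), "1c")
  lm3 <- likelihood_matrix(list(s, s2), mix2, err)
  expect_equal(lm3$L[, 1], lm3$L[, 2])
})

test_that("EM weight optimization finds the simplex maximum and is monotone", {
  # each of two subjects explained by exactly one of two points
  opt <- optimize_weights(diag(2))
  expect_equal(opt$weights, c(0.5, 0.5), tolerance = 1e-8)

  # a single support point takes all the weight
  expect_equal(optimize_weights(matrix(c(0.2, 0.5), 2, 1))$weights, 1)

  # duplicated column: total duplicate weight equals the single-column weight
  L <- matrix(c(1, 0.1, 0.3, 0.9), 2, 2)
  w_ref <- optimize_weights(L)$weights
  L3 <- cbind(L, L[, 2])
  w_dup <- optimize_weights(L3)$weights
  expect_equal(w_dup[2] + w_dup[3], w_ref[2], tolerance = 1e-3)
  expect_equal(optimize_weights(L3)$logLik, optimize_weights(L)$logLik,
               tolerance = 1e-8)

  # monotone log-likelihood trace, and at least as good as uniform weights
  set.seed(21)
  for (i in 1:20) {
    n <- sample(2:4, 1); J <- sample(2:3, 1)
    Lr <- matrix(rexp(n * J), n, J)
    opt <- optimize_weights(Lr)
    expect_true(all(diff(opt$trace) >= -1e-10))
    expect_gte(opt$logLik, sum(log(Lr %*% rep(1 / J, J))) - 1e-12)
  }
})

test_that("EM optima match exhaustive simplex grid search on small problems", {
  set.seed(31)
  for (i in 1:8) {
    n <- sample(2:5, 1); J <- sample(2:3, 1)
    L <- matrix(rexp(n * J, rate = 1), n, J)
    em <- optimize_weights(L, tol = 1e-12, max_iter = 20000)
    gs <- grid_search_weights(L)
    expect_gte(em$logLik, gs$logLik - 1e-6)
  }
})

test_that("observed-versus-predicted regression matches closed-form OLS", {
  expect_equal(obs_pred_regression(c(1, 2, 3), c(1, 2, 3)),
               list(slope = 1, intercept = 0, r2 = 1))
  r <- obs_pred_regression(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$slope, 0.5)
  expect_equal(r$intercept, 0)
  # hand-computed OLS for pairs (predicted, observed) = (1,2),(2,3),(3,5)
  x <- c(1, 2, 3); y <- c(2, 3, 5)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  r2 <- obs_pred_regression(y, x)
  expect_equal(r2$slope, b)
  expect_equal(r2$intercept, a)
  expect_equal(r2$r2, cor(x, y)^2)
  expect_error(obs_pred_regression(c(1, 2, 3), c(2, 2, 2)), "zero variance")
  expect_error(obs_pred_regression(1:2, 1:2), ">= 3")
})

test_that("information criteria use the small-sample AIC correction", {
  ic <- information_criteria(478.8, P = 3, N = 72)
  expect_equal(ic$AIC, 478.8 + 6 + 24 / 68)
  expect_equal(ic$BIC, 478.8 + 3 * log(72))
  expect_error(information_criteria(100, P = 10, N = 11), "N > P \\+ 1")
})

test_that("fit metrics report zero bias and imprecision for perfect predictions", {
  reg <- piperacillin_regimen()
  tt <- sampling_times(reg)
  theta <- c(K = 0.4, V = 30)
  pred <- predict_1c(as.list(theta), reg, tt)
  subjects <- lapply(1:3, function(i) subject_data(i, reg, tt, pred))
  mix <- discrete_mixture(matrix(theta, 1, dimnames = list(NULL, c("K", "V"))),
                          1, default_ranges("1c"), "1c")
  rep <- fit_metrics(subjects, mix, error_model())
  expect_equal(rep$bias, 0)
  expect_equal(rep$imprecision, 0)
  expect_equal(rep$N, 18)
  expect_equal(rep$P, 3)
  expect_equal(rep$n_support, 1)
})

test_that("adaptive grid fit recovers a single generating parameter vector", {
  reg <- piperacillin_regimen()
  tt <- sampling_times(reg)
  theta <- c(K = 0.37, V = 42)
  pred <- predict_1c(as.list(theta), reg, tt)
  subjects <- lapply(1:6, function(i) subject_data(i, reg, tt, pred))
  # noise-free recovery needs a convergence tolerance tighter than the
  # default: within 1% of the truth the log-likelihood surface is nearly flat
  fit <- adaptive_grid_fit(subjects, "1c", n_initial = 60, seed = 5,
                           tol = 1e-4, delta_min = 1e-6, max_cycles = 200,
                           metrics = FALSE)
  mass_near <- sum(fit$mixture$prob[
    abs(fit$mixture$points[, "K"] - theta["K"]) < 0.01 * theta["K"] &
    abs(fit$mixture$points[, "V"] - theta["V"]) < 0.01 * theta["V"]])
  expect_gte(mass_near, 0.999)
  # the cycle log-likelihood trace is non-decreasing up to the tolerance
  expect_true(all(diff(fit$cycle_logLik) > -0.01))
})

test_that("adaptive grid fit separates a well-separated two-point mixture", {
  reg <- piperacillin_regimen()
  tt <- sampling_times(reg)
  thetas <- rbind(c(K = 0.2, V = 70), c(K = 0.6, V = 20))
  err <- error_model(error_polynomial(0.3))  # low constant noise
  set.seed(9)
  subjects <- lapply(1:8, function(i) {
    th <- thetas[(i %% 2) + 1, ]
    pred <- predict_1c(as.list(th), reg, tt)
    subject_data(i, reg, tt, pred + rnorm(length(tt), sd = 0.3))
  })
  fit <- adaptive_grid_fit(subjects, "1c", error = err, n_initial = 60,
                           seed = 2, tol = 1e-3, delta_min = 1e-5,
                           metrics = FALSE)
  near <- function(th) sum(fit$mixture$prob[
    abs(fit$mixture$points[, "K"] - th["K"]) < 0.05 * th["K"] &
    abs(fit$mixture$points[, "V"] - th["V"]) < 0.05 * th["V"]])
  expect_gte(near(thetas[1, ]), 0.3)
  expect_gte(near(thetas[2, ]), 0.3)
})

test_that("adaptive grid fit is deterministic given seed, and tol = Inf stops after one cycle", {
  co <- generate_cohort(n_subjects = 4, seed = 17)
  f1 <- adaptive_grid_fit(co$subjects, "1c", n_initial = 40, seed = 3,
                          max_cycles = 6, metrics = FALSE)
  f2 <- adaptive_grid_fit(co$subjects, "1c", n_initial = 40, seed = 3,
                          max_cycles = 6, metrics = FALSE)
  expect_identical(f1$mixture$points, f2$mixture$points)
  expect_identical(f1$mixture$prob, f2$mixture$prob)

  f3 <- adaptive_grid_fit(co$subjects, "1c", n_initial = 40, seed = 3,
                          tol = Inf, metrics = FALSE)
  expect_equal(f3$cycles, 1L)
  # likelihood equals weight optimization on the bare initial grid
  set.seed(3)
  u <- (npqm:::halton(40, 2) + matrix(runif(2), 40, 2, byrow = TRUE)) %% 1
  rng <- default_ranges("1c")
  grid <- sweep(sweep(u, 2, rng[2, ] - rng[1, ], `*`), 2, rng[1, ], `+`)
  colnames(grid) <- c("K", "V")
  mix0 <- discrete_mixture(grid, rep(1 / 40, 40), rng, "1c")
  opt <- suppressWarnings(
    optimize_weights(likelihood_matrix(co$subjects, mix0, error_model())))
  expect_equal(f3$logLik, opt$logLik, tolerance = 1e-9)
})

test_that("final mixtures satisfy the container invariants", {
  co <- generate_cohort(n_subjects = 5, seed = 23)
  fit <- adaptive_grid_fit(co$subjects, "1c", n_initial = 40, seed = 1,
                           max_cycles = 8, metrics = FALSE)
  m <- fit$mixture
  expect_equal(sum(m$prob), 1, tolerance = 1e-10)
  expect_true(all(m$points[, "K"] >= m$ranges[1, "K"] &
                  m$points[, "K"] <= m$ranges[2, "K"]))
  expect_true(all(m$points[, "V"] >= m$ranges[1, "V"] &
                  m$points[, "V"] <= m$ranges[2, "V"]))
  # serialization round-trip
  path <- tempfile(fileext = ".csv")
  write_mixture(m, path)
  m2 <- read_mixture(path)
  expect_equal(m2$points, m$points, tolerance = 1e-12)
  expect_equal(m2$prob, m$prob, tolerance = 1e-12)
  expect_identical(m2$model_type, "1c")
})

test_that("degenerate likelihoods are reported with the subject id", {
  mix <- discrete_mixture(matrix(c(K = 0.5, V = 20), 1,
                                 dimnames = list(NULL, c("K", "V"))),
                          1, default_ranges("1c"), "1c")
  # an observation absurdly far from anything the point can predict
  s <- one_obs_subject(1e300, id = "X9")
  expect_error(likelihood_matrix(list(s), mix, error_model()), "X9")
})
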