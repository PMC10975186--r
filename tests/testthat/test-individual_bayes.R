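make_1c_mixture <- function(pts, prob = rep(1 / nrow(pts), nrow(pts))) {
  colnames(pts) <- c("K", "V")
  discrete_mixture(pts, prob, default_ranges("1c"), "1c")
}

test_that("posterior reweights the prior by the data likelihood", {
  reg <- dose_event(0, 3, 4000)
  err <- error_model(error_polynomial(2))  # constant SD 2

  # single-point prior: posterior weight 1, MAP point is that point
  mix1 <- make_1c_mixture(matrix(c(0.5, 20), 1))
  s <- subject_data(1, reg, 3, predict_1c(list(K = 0.5, V = 20), reg, 3))
  p1 <- posterior(mix1, s, err)
  expect_equal(p1$posterior_weights, 1)
  expect_equal(p1$map_point, c(K = 0.5, V = 20))
  expect_equal(p1$mse, 0)

  # two equal-prior points engineered to a 3:1 likelihood ratio -> (0.75, 0.25)
  c1 <- predict_1c(list(K = 0.5, V = 20), reg, 3)
  gap <- 2 * sqrt(2 * log(3))          # residual giving density ratio 3 at SD 2
  V2 <- 20 * c1 / (c1 - gap)           # 1c end-of-infusion conc scales as 1/V
  mix2 <- make_1c_mixture(rbind(c(0.5, 20), c(0.5, V2)))
  s2 <- subject_data(2, reg, 3, c1)
  p2 <- posterior(mix2, s2, err)
  expect_equal(unname(p2$posterior_weights), c(0.75, 0.25), tolerance = 1e-9)

  # near-zero assay SD: mass concentrates on the generating point
  tt <- c(3, 4, 5)
  mix3 <- make_1c_mixture(rbind(c(0.45, 25), c(0.3, 40), c(0.6, 15)))
  s3 <- subject_data(3, reg, tt, predict_1c(list(K = 0.45, V = 25), reg, tt))
  p3 <- posterior(mix3, s3, error_model(error_polynomial(1e-4)))
  expect_gt(p3$posterior_weights[1], 1 - 1e-10)
  expect_equal(p3$map_index, 1L)
})

test_that("posterior equals brute-force prior-times-likelihood normalization", {
  reg <- piperacillin_regimen()
  tt <- sampling_times(reg)
  err <- error_model()
  set.seed(13)
  rng <- default_ranges("1c")
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    pts <- cbind(runif(n, rng[1, 1], rng[2, 1]), runif(n, rng[1, 2], rng[2, 2]))
    pr <- rexp(n); pr <- pr / sum(pr)
    mix <- make_1c_mixture(pts, pr)
    truth <- pts[sample(n, 1), ]
    obs <- predict_1c(list(K = truth[1], V = truth[2]), reg, tt) +
      rnorm(length(tt), sd = 1)
    s <- subject_data(rep, reg, tt, abs(obs))
    post <- posterior(mix, s, err)
    ll <- vapply(seq_len(n), function(j)
      brute_loglik(c(K = pts[j, 1], V = pts[j, 2]), s, "1c", err), 0)
    w_brute <- pr * exp(ll - max(ll))
    w_brute <- w_brute / sum(w_brute)
    expect_equal(unname(post$posterior_weights), unname(w_brute),
                 tolerance = 1e-9)
    # predictions are the posterior-weighted average of per-point curves
    preds <- t(vapply(seq_len(n), function(j)
      predict_1c(list(K = pts[j, 1], V = pts[j, 2]), reg, tt),
      numeric(length(tt))))
    expect_equal(post$predictions, colSums(w_brute * preds), tolerance = 1e-9)
  }
})

test_that("more observations sharpen the posterior on data from a support point", {
  reg <- piperacillin_regimen()
  tt <- sampling_times(reg)
  mix <- make_1c_mixture(rbind(c(0.3, 50), c(0.5, 30), c(0.7, 15)))
  entropy <- function(w) { w <- w[w > 0]; -sum(w * log(w)) }
  set.seed(29)
  truth <- c(K = 0.5, V = 30)
  obs <- predict_1c(as.list(truth), reg, tt) + rnorm(length(tt), sd = 0.5)
  s_half <- subject_data(1, reg, tt[1:3], obs[1:3])
  s_full <- subject_data(1, reg, tt, obs)
  e_half <- entropy(posterior(mix, s_half)$posterior_weights)
  e_full <- entropy(posterior(mix, s_full)$posterior_weights)
  expect_lte(e_full, e_half + 1e-12)
})

test_that("posterior-mixture MSE never exceeds the worst single-point MSE", {
  reg <- piperacillin_regimen()
  tt <- sampling_times(reg)
  set.seed(41)
  rng <- default_ranges("1c")
  for (rep in 1:5) {
    pts <- cbind(runif(4, rng[1, 1], rng[2, 1]), runif(4, rng[1, 2], rng[2, 2]))
    mix <- make_1c_mixture(pts)
    obs <- predict_1c(list(K = 0.4, V = 35), reg, tt) + rnorm(6, sd = 2)
    s <- subject_data(rep, reg, tt, abs(obs))
    post <- posterior(mix, s)
    worst <- max(vapply(1:4, function(j)
      mse(s$observations, predict_1c(list(K = pts[j, 1], V = pts[j, 2]),
                                     reg, tt)), 0))
    expect_lte(post$mse, worst + 1e-12)
  }
})

test_that("mean squared error follows the n_dp convention", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(3, 4), c(2, 2)), (1^2 + 2^2) / 2)  # residuals 1, 2 -> 2.5
  expect_error(mse(1:3, 1:2), "equal")
  # the reference rich-sampling design yields 6 data points per subject
  expect_length(sampling_times(piperacillin_regimen()), 6)
})

test_that("estimate comparison reports the documented ratio conventions", {
  reg <- piperacillin_regimen()
  tt <- sampling_times(reg)
  mix <- make_1c_mixture(rbind(c(0.3, 50), c(0.5, 30)))
  s <- subject_data(1, reg, tt,
                    predict_1c(list(K = 0.4, V = 40), reg, tt))
  a <- posterior(mix, s)
  cmp_same <- compare_estimates(a, a)
  expect_equal(cmp_same$mse_ratio, 1)
  expect_equal(unname(cmp_same$param_ratios), c(1, 1))

  # a.mse = 1, b.mse = 2 reads as better performance of a (ratio 0.5)
  b <- a
  a_mod <- a; a_mod$mse <- 1; b$mse <- 2
  expect_equal(compare_estimates(a_mod, b)$mse_ratio, 0.5)
  # parameter ratio arithmetic
  b$posterior_mean <- a$posterior_mean / c(0.8, 1)
  expect_equal(compare_estimates(a, b)$param_ratios[["K"]], 0.8)

  # two-compartment comparisons include the KCP/KPC ratio of ratios
  rng2 <- default_ranges("2c")
  pts2 <- rbind(c(0.5, 1.0, 0.5, 20), c(0.7, 2.0, 1.0, 15))
  colnames(pts2) <- c("K", "KCP", "KPC", "Vc")
  mix2 <- discrete_mixture(pts2, c(0.5, 0.5), rng2, "2c")
  s2 <- subject_data(1, reg, tt,
                     predict_2c(list(K = 0.5, KCP = 1, KPC = 0.5, Vc = 20),
                                reg, tt))
  p2 <- posterior(mix2, s2)
  cmp2 <- compare_estimates(p2, p2)
  expect_equal(cmp2$kcp_kpc_ratio_ratio, 1)

  # mismatched subjects or model types refuse to compare
  s_other <- subject_data(2, reg, tt, s$observations)
  expect_error(compare_estimates(a, posterior(mix, s_other)), "subject")
  expect_error(compare_estimates(a, p2), "model type")
})
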