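# Independent numerical oracle for the infusion compartment models: exact
# piecewise propagation of the linear ODE system with Matrix::expm over
# segments on which the infusion input is constant. Shares no code with the
# package's eigen-decomposition closed forms.

oracle_predict <- function(theta, reg, times, n_cmt) {
  if (n_cmt == 1L) {
    M <- matrix(-theta$K, 1, 1)
    V <- theta$V
  } else {
    M <- matrix(c(-(theta$K + theta$KCP), theta$KCP,
                  theta$KPC, -theta$KPC), 2, 2)
    V <- theta$Vc
  }
  n <- nrow(M)
  bps <- sort(unique(c(0, reg$start, reg$start + reg$duration, times)))
  A <- rep(0, n)
  conc <- setNames(numeric(length(bps)), NULL)
  conc[1] <- A[1] / V
  for (k in seq_len(length(bps) - 1L)) {
    t1 <- bps[k]; t2 <- bps[k + 1L]
    mid <- (t1 + t2) / 2
    rate <- sum(reg$amount[reg$start < mid & (reg$start + reg$duration) > mid] /
                  reg$duration[reg$start < mid & (reg$start + reg$duration) > mid])
    u <- c(rate, rep(0, n - 1L))
    E <- as.matrix(Matrix::expm(M * (t2 - t1)))
    A <- drop(E %*% A + solve(M, (E - diag(n)) %*% u))
    conc[k + 1L] <- A[1] / V
  }
  conc[match(times, bps)]
}

# A random multi-dose regimen for property tests.
random_regimen <- function() {
  n_ev <- sample(1:3, 1)
  starts <- sort(runif(n_ev, 0, 12))
  do.call(regimen, lapply(starts, function(s)
    dose_event(s, runif(1, 0.5, 4), runif(1, 500, 5000))))
}

# Brute-force log-likelihood of one subject under one support point,
# computed directly from normal densities (independent of loglik internals).
brute_loglik <- function(theta, subject, model_type, error) {
  pred <- predict_conc(theta, model_type, subject$regimen, subject$times,
                       crcl = subject$covariates$CRCL)
  v <- observation_variance(error$poly, pred, error$noise, error$gamma)
  sum(dnorm(subject$observations, pred, sqrt(v), log = TRUE))
}

# Exhaustive simplex grid search for mixture weights (2 or 3 columns).
grid_search_weights <- function(L, step = 0.005) {
  stopifnot(ncol(L) %in% 2:3)
  w1 <- seq(0, 1, by = step)
  best <- -Inf; best_w <- NULL
  if (ncol(L) == 2L) {
    for (a in w1) {
      ll <- sum(log(L %*% c(a, 1 - a)))
      if (ll > best) { best <- ll; best_w <- c(a, 1 - a) }
    }
  } else {
    for (a in w1) for (b in seq(0, 1 - a, by = step)) {
      ll <- sum(log(L %*% c(a, b, 1 - a - b)))
      if (ll > best) { best <- ll; best_w <- c(a, b, 1 - a - b) }
    }
  }
  list(weights = best_w, logLik = best)
}
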