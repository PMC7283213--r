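test_that("lagged covariances match explicit loop sums", {
  # hand instance: single forcing, F = 2 O, lag 1
  O <- c(1, 2, 3, 4, 2, 1)
  F <- 2 * O
  Ot <- matrix(O[2:6]); Ol <- matrix(O[1:5])
  cv <- lagged_covariance(F[2:6], Ot, Ol)
  expect_equal(cv$C_FO[1, 1], loop_cov(F[2:6], O[1:5]), tolerance = 1e-12)
  expect_equal(cv$C_OO[1, 1], loop_cov(O[2:6], O[1:5]), tolerance = 1e-12)
  expect_equal(cv$C_FO[1, 1], 2 * cv$C_OO[1, 1], tolerance = 1e-12)

  # tau = 0 with F = O: both covariances collapse to Var(O)
  cv0 <- lagged_covariance(O, matrix(O), matrix(O))
  expect_equal(cv0$C_FO[1, 1], var(O), tolerance = 1e-12)
  expect_equal(cv0$C_OO[1, 1], var(O), tolerance = 1e-12)

  # independent white noise: entries near zero
  set.seed(41)
  n <- 2000
  Fw <- rnorm(n); Ow <- matrix(rnorm(n * 2), n, 2)
  cvw <- lagged_covariance(Fw, Ow, matrix(rnorm(n * 2), n, 2))
  expect_lt(max(abs(cvw$C_FO)), 3 / sqrt(n))

  expect_error(lagged_covariance(rnorm(4), matrix(rnorm(8), 4),
                                 matrix(rnorm(8), 4)), "insufficient")
})

test_that("the response estimator equals the loop-sum oracle everywhere", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(15:50, 1)
    k <- sample(1:5, 1)
    O_t <- matrix(rnorm(n * k), n, k)
    O_lag <- matrix(rnorm(n * k), n, k) + 0.5 * O_t
    F <- rnorm(n)
    expect_equal(unname(estimate_response(F, O_t, O_lag)),
                 loop_response(F, O_t, O_lag), tolerance = 1e-10)
  }
})

test_that("the estimator recovers known responses", {
  # exact linear relation, no noise: recovery is exact
  cfg <- flat_config(n_forcings = 1, ar1_coeffs = 0.8, seed = 43,
                     true_R = 2, fire_noise_sd = 0)
  forc <- gen_forcings(cfg)
  fire <- gen_fire_series(forc, cfg)
  # the series is already a pure anomaly; pool it as-is so the exact
  # linear relation F = 2 O survives
  ps <- pool_season(fire, scale(forc), season = NULL, tau = 1)
  expect_equal(unname(estimate_response(ps$F, ps$O_t, ps$O_lag)), 2,
               tolerance = 1e-8)

  # correlated forcings, noisy fire, long record: within 0.1
  cfg2 <- flat_config(n_forcings = 2, ar1_coeffs = 0.8, forcing_corr = 0.5,
                      seed = 44, n_years = 200, true_R = c(1, -0.5),
                      fire_noise_sd = 1)
  forc2 <- gen_forcings(cfg2)
  fire2 <- gen_fire_series(forc2, cfg2)
  ps2 <- pool_full(fire2, scale(forc2))
  R2 <- estimate_response(ps2$F, ps2$O_t, ps2$O_lag)
  expect_lt(max(abs(R2 - c(1, -0.5))), 0.1)

  # scale equivariance in F
  expect_equal(unname(estimate_response(3 * ps2$F, ps2$O_t, ps2$O_lag)),
               unname(3 * R2), tolerance = 1e-12)
  # column scaling: R_j -> R_j / c, other entries unchanged
  Ot_s <- ps2$O_t; Ol_s <- ps2$O_lag
  Ot_s[, 1] <- 4 * Ot_s[, 1]; Ol_s[, 1] <- 4 * Ol_s[, 1]
  Rs <- estimate_response(ps2$F, Ot_s, Ol_s)
  expect_equal(unname(Rs[1]), unname(R2[1] / 4), tolerance = 1e-10)
  expect_equal(unname(Rs[2]), unname(R2[2]), tolerance = 1e-10)
})

test_that("estimation error shrinks with record length", {
  ns <- c(120, 240, 600, 2400)
  rmse <- sapply(ns, function(n) {
    errs <- sapply(1:20, function(r) {
      cfg <- flat_config(n_forcings = 3, ar1_coeffs = 0.8,
                         forcing_corr = 0.3, seed = 4000 + 17 * r,
                         true_R = c(1, -0.5, 0), fire_noise_sd = 1)
      forc <- gen_forcings(cfg, n_months = n)
      fire <- make_fire(forc, cfg$true_R, seed = 5000 + r)
      ps <- pool_full(fire, scale(forc))
      sqrt(mean((estimate_response(ps$F, ps$O_t, ps$O_lag) -
                   cfg$true_R)^2))
    })
    mean(errs)
  })
  expect_true(all(diff(rmse) < 0))
})

test_that("identification assumption holds: noise is lag-uncorrelated with forcings", {
  cfg <- flat_config(n_forcings = 3, ar1_coeffs = 0.8, forcing_corr = 0.3,
                     seed = 45, n_years = 200, true_R = c(1, 0, 0),
                     fire_noise_sd = 1)
  forc <- gen_forcings(cfg)
  fire <- gen_fire_series(forc, cfg)
  noise <- fire$values - attr(fire, "truth_anomaly")
  n <- length(noise)
  for (j in 1:3)
    expect_lt(abs(cor(noise[2:n], forc[1:(n - 1), j])), 3 / sqrt(n))
})

test_that("AIC scoring follows the penalized likelihood arithmetic", {
  set.seed(46)
  n <- 240
  F <- rnorm(n); F <- F - mean(F)
  O_t <- matrix(rnorm(n * 2), n, 2)
  O_lag <- matrix(rnorm(n * 2), n, 2)
  # null model formula
  expect_equal(aic_score(F, O_t, O_lag, integer(0)),
               n * log(var(F) * (n - 1) / n) + 2, tolerance = 1e-10)
  # nested subsets with identical RSS differ by exactly the 2k penalty
  a1 <- aic_score(F, O_t, O_lag, 1:2)
  R <- estimate_response(F, O_t, O_lag)
  rss <- sum((F - O_t %*% R)^2)
  expect_equal(a1, n * log(rss / n) + 2 * 3, tolerance = 1e-10)
  expect_equal((n * log(rss / n) + 2 * 4) - a1, 2)

  # adding a pure-noise forcing raises AIC in expectation
  diffs <- sapply(1:60, function(r) {
    cfg <- flat_config(n_forcings = 3, ar1_coeffs = 0.8, forcing_corr = 0,
                       seed = 6000 + r, true_R = c(1, -0.8, 0),
                       fire_noise_sd = 1)
    forc <- gen_forcings(cfg)
    fire <- make_fire(forc, cfg$true_R, seed = 7000 + r)
    ps <- pool_full(fire, scale(forc))
    aic_score(ps$F, ps$O_t, ps$O_lag, 1:3) -
      aic_score(ps$F, ps$O_t, ps$O_lag, 1:2)
  })
  expect_gt(mean(diffs), 0)
})

test_that("backward-stepwise selection keeps true forcings and prunes noise", {
  # a single candidate carrying the whole signal is retained
  cfg1 <- flat_config(n_forcings = 1, ar1_coeffs = 0.8, seed = 47,
                      true_R = 1.5, fire_noise_sd = 0.1)
  forc1 <- gen_forcings(cfg1)
  fire1 <- gen_fire_series(forc1, cfg1)
  ps1 <- pool_full(fire1, scale(forc1))
  st1 <- backward_stepwise(ps1$F, ps1$O_t, ps1$O_lag)
  expect_equal(st1$retained, 1L)
  # AIC path is non-increasing
  expect_true(all(diff(st1$aic_path) <= 0))

  # 4 candidates, 2 strong true effects: pair recovered in >= 90% of sims
  hits <- sapply(1:100, function(r) {
    cfg <- flat_config(n_forcings = 4, ar1_coeffs = 0.8, forcing_corr = 0.3,
                       seed = 8000 + r, true_R = c(0.8, -0.6, 0, 0),
                       fire_noise_sd = 1)
    forc <- gen_forcings(cfg)
    fire <- make_fire(forc, cfg$true_R, seed = 9000 + r)
    ps <- pool_full(fire, scale(forc))
    st <- backward_stepwise(ps$F, ps$O_t, ps$O_lag)
    all(c(1, 2) %in% st$retained)
  })
  expect_gte(mean(hits), 0.90)

  # all-noise candidates: selection keeps almost nothing
  kept <- sapply(1:50, function(r) {
    cfg <- flat_config(n_forcings = 4, ar1_coeffs = 0.8, forcing_corr = 0.3,
                       seed = 10000 + r, true_R = rep(0, 4),
                       fire_noise_sd = 1)
    forc <- gen_forcings(cfg)
    fire <- make_fire(forc, cfg$true_R, seed = 11000 + r)
    ps <- pool_full(fire, scale(forc))
    length(backward_stepwise(ps$F, ps$O_t, ps$O_lag)$retained)
  })
  expect_lte(median(kept), 1)
})

test_that("permutation significance is calibrated, strong and deterministic", {
  # strong signal: tiny p-value
  cfg <- flat_config(n_forcings = 1, ar1_coeffs = 0.8, seed = 48,
                     true_R = 2, fire_noise_sd = 0.3)
  forc <- gen_forcings(cfg)
  fire <- gen_fire_series(forc, cfg)
  ps <- pool_full(fire, scale(forc))
  set.seed(1)
  bt <- bootstrap_significance(ps$F, ps$O_t, ps$O_lag, n_iter = 500)
  expect_lt(bt$p_values[1], 0.1)

  # determinism under a fixed seed
  set.seed(99)
  b1 <- bootstrap_significance(ps$F, ps$O_t, ps$O_lag, n_iter = 300)
  set.seed(99)
  b2 <- bootstrap_significance(ps$F, ps$O_t, ps$O_lag, n_iter = 300)
  expect_identical(b1$p_values, b2$p_values)

  # the permutation null preserves the sample multiset exactly
  pm <- sgefafire:::make_permuter(50)
  set.seed(3)
  expect_identical(sort(pm()), 1:50)
  pmb <- sgefafire:::make_permuter(50, block = 7)
  expect_identical(sort(pmb()), 1:50)

  # small n_iter warns
  expect_warning(bootstrap_significance(ps$F, ps$O_t, ps$O_lag,
                                        n_iter = 50), "coarse")
})

test_that("seasonal cycle, max-season and robustness summaries behave", {
  cfg <- flat_config(n_forcings = 2, ar1_coeffs = 0.8, forcing_corr = 0.2,
                     seed = 49, true_R = c(1.2, 0), fire_noise_sd = 1)
  forc <- gen_forcings(cfg)
  fire <- gen_fire_series(forc, cfg)
  fa <- detrend_linear(monthly_anomalies(fire))
  cyc <- seasonal_feedback_cycle(fa, scale(forc), tau = 1, n_iter = 300,
                                 seed = 50)
  ns <- sapply(seq_along(cyc), function(s)
    if (is.null(cyc[[s]])) NA else cyc[[s]]$n_samples)
  expect_true(all(ns <= 60, na.rm = TRUE))

  # stationary truth: seasonal estimates scatter around the true value
  R1 <- sapply(seq_along(cyc), function(s) {
    est <- cyc[[s]]
    if (is.null(est) || !est$retained[1]) return(NA_real_)
    est$R[1]
  })
  expect_gt(sum(!is.na(R1)), 6)
  expect_lt(max(abs(R1 - 1.2), na.rm = TRUE), 0.75)

  # max season: the season with the largest significant |R|
  ms <- max_response_season(cyc, 1)
  sig_R <- sapply(seq_along(cyc), function(s) {
    est <- cyc[[s]]
    if (is.null(est) || !isTRUE(est$significant[1])) return(NA_real_)
    est$R[1]
  })
  expect_equal(ms$season, unname(which.max(abs(sig_R))))
  expect_equal(ms$R, unname(sig_R[which.max(abs(sig_R))]),
               tolerance = 1e-12)
  # a forcing significant nowhere returns the none-marker
  ms0 <- max_response_season(cyc, 2)
  if (all(is.na(sapply(seq_along(cyc), function(s) {
    est <- cyc[[s]]
    if (is.null(est) || !isTRUE(est$significant[2])) NA else 1
  })))) {
    expect_true(is.na(ms0$season))
  }

  # robustness counting across six replicate combinations
  ests <- lapply(1:6, function(r) {
    cfgr <- flat_config(n_forcings = 2, ar1_coeffs = 0.8,
                        forcing_corr = 0.2, seed = 12000 + r,
                        true_R = c(1.2, 0), fire_noise_sd = 1)
    fr <- gen_forcings(cfgr)
    fi <- make_fire(fr, cfgr$true_R, seed = 13000 + r)
    fa_r <- detrend_linear(monthly_anomalies(fi))
    sgefa_fit(fa_r, scale(fr), season = NULL, n_iter = 300,
              seed = 14000 + r)
  })
  rc <- robustness_count(ests)
  expect_equal(unname(rc[1]), 6L)   # strong effect robust everywhere
  expect_lte(unname(rc[2]), 2L)     # null effect rarely significant
  expect_equal(unname(robustness_count(ests[2])[1]), 1L)
})

test_that("seasonally modulated effects concentrate in the active seasons", {
  set.seed(51)
  cfg <- flat_config(n_forcings = 1, ar1_coeffs = 0.8, seed = 52,
                     true_R = 0, fire_noise_sd = 1)
  forc <- gen_forcings(cfg)
  n <- nrow(forc)
  m <- (seq_len(n) - 1) %% 12 + 1
  gain <- ifelse(m %in% 6:8, 1.8, 0)   # forcing active only June-August
  fire <- regional_series(gain * as.numeric(scale(forc)[, 1]) + rnorm(n))
  fa <- detrend_linear(monthly_anomalies(fire))
  cyc <- seasonal_feedback_cycle(fa, scale(forc), n_iter = 300, seed = 53)
  expect_true(cyc[[6]]$significant[1])          # JJA season
  # winter season far from the active months shows no comparable response
  r12 <- cyc[[12]]$R[1]
  expect_true(is.na(r12) || abs(r12) < abs(cyc[[6]]$R[1]))
})

test_that("feedback estimates flag non-retained forcings as absent", {
  cfg <- flat_config(n_forcings = 4, ar1_coeffs = 0.8, forcing_corr = 0.2,
                     seed = 54, true_R = c(1, 0, 0, 0), fire_noise_sd = 1)
  forc <- gen_forcings(cfg)
  fire <- gen_fire_series(forc, cfg)
  fa <- detrend_linear(monthly_anomalies(fire))
  est <- sgefa_fit(fa, scale(forc), season = NULL, n_iter = 300, seed = 55)
  expect_true(est$retained[1])
  expect_true(all(is.na(est$R[!est$retained])))
  expect_true(all(is.na(est$p_values[!est$retained])))
  expect_true(all(est$p_values[est$retained] >= 0 &
                    est$p_values[est$retained] <= 1))
  expect_equal(est$n_samples, 239)
})

test_that("per-cell response maps mask insignificant cells", {
  set.seed(56)
  cfg <- flat_config(n_forcings = 2, ar1_coeffs = 0.8, forcing_corr = 0,
                     seed = 57, true_R = c(0, 0), fire_noise_sd = 1)
  forc <- gen_forcings(cfg)
  O <- scale(forc)
  n <- nrow(O)
  lat <- seq(-10, 10, by = 4); lon <- seq(0, 20, by = 4)
  nl <- length(lat); no <- length(lon)

  # uniform truth: one shared signal, small independent cell noise
  sig <- as.numeric(O[, 1]) * 1.5
  arr <- array(rnorm(n * nl * no, 0, 0.4), c(n, nl, no)) + sig
  g <- gridded_field(arr, lat, lon, anomalized = TRUE, detrended = TRUE)
  mp <- spatial_response_map(g, O, forcing = 1, n_iter = 300, seed = 58)
  vals <- mp$R[!is.na(mp$R)]
  expect_gt(length(vals), 0.8 * nl * no)
  expect_lt(max(vals) - min(vals), 0.6)
  expect_lt(abs(mean(vals) - 1.5), 0.3)

  # opposite-sign regions: the sign boundary is recovered
  arr2 <- array(rnorm(n * nl * no, 0, 0.4), c(n, nl, no))
  for (i in seq_len(nl)) {
    s <- if (lat[i] < 0) -1.5 else 1.5
    arr2[, i, ] <- arr2[, i, ] + s * as.numeric(O[, 1])
  }
  g2 <- gridded_field(arr2, lat, lon, anomalized = TRUE, detrended = TRUE)
  mp2 <- spatial_response_map(g2, O, forcing = 1, n_iter = 300, seed = 59)
  south <- mp2$R[lat < 0, ]; north <- mp2$R[lat >= 0, ]
  expect_true(all(south[!is.na(south)] < 0))
  expect_true(all(north[!is.na(north)] > 0))

  # all-noise field: about the nominal fraction of cells stays unmasked
  arr3 <- array(rnorm(n * nl * no), c(n, nl, no))
  g3 <- gridded_field(arr3, lat, lon, anomalized = TRUE, detrended = TRUE)
  mp3 <- spatial_response_map(g3, O, forcing = 1, n_iter = 300, seed = 60)
  frac <- mean(!is.na(mp3$R))
  expect_lt(frac, 0.3)
})
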