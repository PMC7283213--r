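# shared fixture builders; everything is generated in code at test time

# flat generator: no seasonal cycle, no trend (anomaly-scale studies)
flat_config <- function(..., n_forcings = 3, seed = 1) {
  zero12 <- rep(0, 12)
  synth_config(
    n_forcings = n_forcings, seed = seed,
    seasonal_cycle = list(fire = zero12, sst = zero12,
                          lai = zero12, sm = zero12),
    trend_slope = list(fire = 0, sst = 0, lai = 0, sm = 0),
    ...)
}

# predictor table built directly from a matrix (bypasses lagging; used when
# the experiment prescribes the predictors themselves)
direct_table <- function(X, y, start_year = 1997, set = "ocean_land") {
  n <- nrow(X)
  stopifnot(n %% 12 == 0)
  structure(list(X = as.matrix(X), y = y,
                 year = rep(start_year - 1 + seq_len(n / 12), each = 12),
                 month = rep(1:12, n / 12),
                 lead = 1L, season = NULL, set = set),
            class = "predictor_table")
}

# fire series generated from prescribed forcings with everything else flat
make_fire <- function(forcings, true_R, noise_sd = 1, seed = 2) {
  cfg <- flat_config(n_forcings = ncol(forcings), true_R = true_R,
                     fire_noise_sd = noise_sd, seed = seed)
  gen_fire_series(forcings, cfg, seed = seed)
}

# pooled full-record triples at lag tau from a series and forcing matrix
pool_full <- function(fire, O, tau = 1) {
  fa <- detrend_linear(monthly_anomalies(fire))
  pool_season(fa, O, season = NULL, tau = tau)
}
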