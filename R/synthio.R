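#' Configuration for the synthetic ocean/land/fire generator
#'
#' Defines the generative conditions for a synthetic study: red-noise
#' (AR(1)) environmental forcings that may be mutually correlated, basin SST
#' fields built from two prescribed spatial modes, and a fire series that
#' responds instantaneously to the standardized forcings through a known
#' response vector plus short-memory noise. All downstream ground-truth
#' checks (response recovery, predictability ceilings) read their truth from
#' this object.
#'
#' Default conditions: a 20-year (240-month) monthly record, 18 forcings
#' (two SST principal components for each of eight ocean basins, plus
#' regional LAI and surface soil moisture), lag-1 autocorrelation 0.8 for
#' every forcing, exchangeable cross-forcing correlation 0.2, three nonzero
#' true responses (tropical-Pacific PC1 = 0.8, LAI = 0.5, soil moisture =
#' -0.6, in fire-anomaly units per forcing standard deviation) and unit
#' fire-noise standard deviation.
#'
#' @param n_years simulated record length in years (>= 2).
#' @param ar1_coeffs lag-1 autocorrelation per forcing, each in [0, 1);
#'   recycled to `n_forcings`.
#' @param forcing_corr target stationary cross-forcing correlation matrix
#'   (symmetric positive semidefinite), or a single scalar giving an
#'   exchangeable off-diagonal correlation.
#' @param true_R true response per unit standard deviation of each forcing.
#' @param fire_noise_sd standard deviation of the i.i.d. Gaussian fire noise.
#' @param n_forcings number of forcings (default 18: 16 oceanic + 2
#'   terrestrial).
#' @param seasonal_cycle named list of 12-value monthly climatologies for
#'   `fire`, `sst`, `lai`, `sm` (defaults provided).
#' @param trend_slope named list of per-month linear trend slopes for the
#'   same variables.
#' @param grid_res grid resolution in degrees for synthetic basin SST fields.
#' @param atmos_corr target correlation of each monthly atmospheric
#'   predictor with the fire anomaly (named vector).
#' @param seed integer seed making the whole bundle reproducible.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_years = 20L,
                         ar1_coeffs = 0.8,
                         forcing_corr = 0.2,
                         true_R = NULL,
                         fire_noise_sd = 1,
                         n_forcings = 18L,
                         seasonal_cycle = NULL,
                         trend_slope = NULL,
                         grid_res = 5,
                         atmos_corr = c(lightning = 0.1, temp = 0.4,
                                        moisture = -0.4, wind = 0.25),
                         seed = 1L) {
  if (n_years < 2) stop("n_years must be >= 2", call. = FALSE)
  n_forcings <- as.integer(n_forcings)
  ar1 <- rep_len(as.numeric(ar1_coeffs), n_forcings)
  if (any(ar1 < 0) || any(ar1 >= 1))
    stop("ar1_coeffs must lie in [0, 1)", call. = FALSE)
  if (is.matrix(forcing_corr)) {
    C <- forcing_corr
    if (nrow(C) != n_forcings || ncol(C) != n_forcings)
      stop("forcing_corr dimension must match n_forcings", call. = FALSE)
  } else {
    C <- matrix(as.numeric(forcing_corr), n_forcings, n_forcings)
    diag(C) <- 1
  }
  if (max(abs(C - t(C))) > 1e-10)
    stop("forcing_corr must be symmetric", call. = FALSE)
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("forcing_corr must be positive semidefinite", call. = FALSE)

  labels <- forcing_labels(n_forcings)
  if (is.null(true_R)) {
    true_R <- numeric(n_forcings)
    if (n_forcings >= 18) {
      true_R[match(c("TP-PC1", "LAI", "SM"), labels)] <- c(0.8, 0.5, -0.6)
    } else {
      true_R[1] <- 0.8
    }
  }
  if (length(true_R) != n_forcings)
    stop("true_R length must equal n_forcings", call. = FALSE)

  cyc0 <- function(amp, peak) amp * cos(2 * pi * (1:12 - peak) / 12)
  cyc <- list(fire = cyc0(2, 1), sst = cyc0(3, 3),
              lai = cyc0(0.5, 8), sm = cyc0(0.1, 8))
  if (!is.null(seasonal_cycle)) cyc[names(seasonal_cycle)] <- seasonal_cycle
  lapply(cyc, function(v) stopifnot(length(v) == 12))
  tr <- list(fire = 0.001, sst = 0.002, lai = 0.0005, sm = 0)
  if (!is.null(trend_slope)) tr[names(trend_slope)] <- trend_slope

  structure(list(
    n_years = as.integer(n_years), n_forcings = n_forcings,
    ar1_coeffs = ar1, forcing_corr = C, forcing_labels = labels,
    true_R = as.numeric(true_R), fire_noise_sd = fire_noise_sd,
    seasonal_cycle = cyc, trend_slope = tr, grid_res = grid_res,
    atmos_corr = atmos_corr, seed = as.integer(seed)
  ), class = "synth_config")
}

forcing_labels <- function(k) {
  base <- as.vector(t(outer(c("TP", "TA", "TI", "NP", "NA.", "SP", "SA", "SI"),
                            c("PC1", "PC2"), paste, sep = "-")))
  base <- c(base, "LAI", "SM")
  if (k <= length(base)) base[seq_len(k)] else
    c(base, paste0("X", seq_len(k - length(base))))
}

#' Generate correlated AR(1) forcing truth series
#'
#' Simulates `n_forcings` zero-mean, unit-variance AR(1) series whose
#' stationary cross-correlation matrix equals `config$forcing_corr`. The
#' innovations are drawn jointly through a Cholesky factor of an innovation
#' covariance adjusted for the per-series memory, so both the marginal lag-1
#' autocorrelations and the target instantaneous cross-correlations hold
#' exactly in the stationary distribution. A 240-month burn-in is discarded.
#'
#' @param config a [synth_config()].
#' @param n_months optional override of the record length.
#' @return numeric matrix `[months x n_forcings]`, columns labelled.
#' @export
gen_forcings <- function(config, n_months = NULL) {
  stopifnot(inherits(config, "synth_config"))
  n <- if (is.null(n_months)) config$n_years * 12L else as.integer(n_months)
  k <- config$n_forcings
  phi <- config$ar1_coeffs
  # innovation covariance giving stationary correlation == forcing_corr
  s <- sqrt(1 - phi^2)
  Cinn <- config$forcing_corr * (1 - outer(phi, phi)) /
    outer(sqrt(1 - phi^2), sqrt(1 - phi^2))
  diag(Cinn) <- 1
  ev <- eigen(Cinn, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("forcing_corr is not attainable with these ar1_coeffs ",
         "(memory-adjusted innovation covariance not positive semidefinite)",
         call. = FALSE)
  L <- chol(Cinn + diag(1e-10, k))
  burn <- 240L
  set.seed(config$seed)
  z <- matrix(stats::rnorm((n + burn) * k), n + burn, k) %*% L
  z <- sweep(z, 2, s, `*`)  # innovation sd sqrt(1-phi^2) -> unit variance
  x <- vapply(seq_len(k), function(j) {
    as.numeric(stats::filter(z[, j], phi[j], method = "recursive"))
  }, numeric(n + burn))
  x <- x[(burn + 1):(burn + n), , drop = FALSE]
  colnames(x) <- config$forcing_labels
  x
}

#' Generate a synthetic basin SST field from two principal-component series
#'
#' Builds `field = sd1 * pattern1 x pc1(t) + sd2 * pattern2 x pc2(t) +
#' white noise + seasonal cycle + linear trend` on the basin's lat/lon grid.
#' The two spatial patterns are orthonormal under sqrt(cos(latitude)) area
#' weights (a broad monopole and a meridional dipole by default), so with
#' unit-variance pc series the prescribed mode standard deviations set the
#' explained-variance shares; `sd1 > sd2` is required so mode order is
#' well defined.
#'
#' @param basin a [basin_spec()].
#' @param pc1,pc2 unit-variance principal-component time series (equal
#'   length).
#' @param config a [synth_config()] (grid resolution, SST cycle/trend).
#' @param mode_sd standard deviations of the two modes in field units.
#' @param noise_sd spatially white noise standard deviation.
#' @param patterns optional list of two user patterns `[lat x lon]`; must be
#'   orthogonal under the area weights.
#' @param seed seed for the white-noise draw.
#' @return a [gridded_field()].
#' @export
gen_sst_field <- function(basin, pc1, pc2, config,
                          mode_sd = c(1.5, 1.0), noise_sd = 0.3,
                          patterns = NULL, seed = config$seed + 1L) {
  stopifnot(inherits(basin, "basin_spec"), length(pc1) == length(pc2))
  if (mode_sd[1] <= mode_sd[2])
    stop("mode_sd[1] must exceed mode_sd[2] so mode 1 dominates",
         call. = FALSE)
  res <- config$grid_res
  lat <- seq(basin$lat_min + res / 2, basin$lat_max - res / 2, by = res)
  lon_w <- basin_lon_width(basin)
  lon <- lon360(basin$lon_min + seq(res / 2, lon_w - res / 2, by = res))
  nlat <- length(lat); nlon <- length(lon)
  w <- matrix(cos(lat * pi / 180), nlat, nlon)  # area weights

  if (is.null(patterns)) {
    u <- (lat - mean(lat)) / max(1e-9, diff(range(lat)))
    p1 <- matrix(cos(pi * u), nlat, nlon)
    p2 <- matrix(sin(pi * u), nlat, nlon)
  } else {
    p1 <- patterns[[1]]; p2 <- patterns[[2]]
  }
  ip <- function(a, b) sum(w * a * b)
  # Gram-Schmidt under area weights, then unit weighted norm
  p2 <- p2 - ip(p1, p2) / ip(p1, p1) * p1
  if (!is.null(patterns) && abs(ip(patterns[[1]], patterns[[2]])) >
      1e-6 * sqrt(ip(patterns[[1]], patterns[[1]]) * ip(patterns[[2]], patterns[[2]])))
    stop("prescribed patterns are not orthogonal under area weights",
         call. = FALSE)
  p1 <- p1 / sqrt(ip(p1, p1))
  p2 <- p2 / sqrt(ip(p2, p2))

  n <- length(pc1)
  set.seed(seed)
  fld <- array(0, c(n, nlat, nlon))
  noise <- array(stats::rnorm(n * nlat * nlon, 0, noise_sd), c(n, nlat, nlon))
  cyc <- config$seasonal_cycle$sst
  tr <- config$trend_slope$sst
  m <- (seq_len(n) - 1L) %% 12L + 1L
  for (t in seq_len(n)) {
    fld[t, , ] <- mode_sd[1] * p1 * pc1[t] + mode_sd[2] * p2 * pc2[t] +
      noise[t, , ] + cyc[m[t]] + tr * t
  }
  out <- gridded_field(fld, lat, lon, units = "K")
  attr(out, "truth") <- list(patterns = list(p1, p2), mode_sd = mode_sd,
                             noise_sd = noise_sd)
  out
}

#' Generate the fire carbon-emission series from the forcing truth
#'
#' Applies the linear instantaneous-response model: the fire anomaly at
#' month t is the inner product of the true response vector with the
#' standardized forcings at t, plus i.i.d. Gaussian noise; the published
#' series adds the fire seasonal cycle and linear trend back on top.
#' Standardization (centre, unit sample variance) happens before the
#' response is applied, so `true_R` is in fire units per forcing standard
#' deviation.
#'
#' @param forcings matrix `[months x k]` from [gen_forcings()].
#' @param config a [synth_config()]; `config$true_R` must have k entries.
#' @param seed seed for the noise draw.
#' @return a [regional_series()] with attribute `"truth_anomaly"` holding
#'   the noise-free response component.
#' @export
gen_fire_series <- function(forcings, config, seed = config$seed + 2L) {
  k <- ncol(forcings)
  if (length(config$true_R) != k)
    stop("true_R length (", length(config$true_R),
         ") does not match forcing count (", k, ")", call. = FALSE)
  O <- scale(forcings)  # unit sample variance per column
  signal <- as.numeric(O %*% config$true_R)
  n <- nrow(forcings)
  set.seed(seed)
  noise <- stats::rnorm(n, 0, config$fire_noise_sd)
  m <- (seq_len(n) - 1L) %% 12L + 1L
  values <- signal + noise + config$seasonal_cycle$fire[m] +
    config$trend_slope$fire * seq_len(n)
  out <- regional_series(values, units = "kg C m-2 month-1",
                         region_id = "synthetic-region")
  attr(out, "truth_anomaly") <- signal
  out
}

#' Generate atmospheric and socioeconomic predictor series
#'
#' Monthly atmospheric predictors (lightning occurrence, low-level
#' temperature, moisture, wind speed) are built with a configurable
#' correlation to the fire anomaly: `x = rho * f_std + sqrt(1 - rho^2) *
#' e`, with `e` a unit-variance AR(1) (memory 0.3) disturbance. Annual
#' socioeconomic predictors (population density, land-use change) follow a
#' yearly random walk and are expanded to monthly cadence by the
#' antecedent-year rule: every month of calendar year y carries the value
#' reported at the end of year y - 1.
#'
#' @param config a [synth_config()].
#' @param fire the fire [regional_series()] the atmospheric predictors
#'   should correlate with.
#' @param seed seed for the disturbance draws.
#' @return list with elements `atmos` (list of monthly
#'   [regional_series()]) and `socio` (list of monthly step series, plus an
#'   `annual` table of the underlying yearly values).
#' @export
gen_predictor_suite <- function(config, fire, seed = config$seed + 3L) {
  n <- length(fire$values)
  # correlate against the deseasonalized fire anomaly, not the raw series
  f_std <- as.numeric(scale(fire$values - stats::ave(fire$values,
                                                     fire$month)))
  set.seed(seed)
  atmos <- lapply(seq_along(config$atmos_corr), function(j) {
    rho <- config$atmos_corr[[j]]
    e <- as.numeric(stats::filter(stats::rnorm(n + 60, 0, sqrt(1 - 0.3^2)),
                                  0.3, method = "recursive"))[61:(60 + n)]
    regional_series(rho * f_std + sqrt(1 - rho^2) * e,
                    units = "", region_id = names(config$atmos_corr)[j])
  })
  names(atmos) <- names(config$atmos_corr)

  years <- sort(unique(fire$year))
  ny <- length(years)
  annual <- list(
    population = 10 + cumsum(stats::rnorm(ny + 1, 0.2, 0.5)),
    landuse = cumsum(stats::rnorm(ny + 1, 0, 0.3))
  )
  socio <- lapply(annual, function(a) {
    # month in year y takes the value reported at the end of year y - 1
    idx <- match(fire$year, years)        # 1..ny
    regional_series(a[idx], units = "", region_id = "socio")
  })
  names(socio) <- names(annual)
  list(atmos = atmos, socio = socio,
       annual = data.frame(year = c(years[1] - 1L, years),
                           population = annual$population,
                           landuse = annual$landuse))
}

#' Simulate a complete synthetic study bundle
#'
#' Orchestrates the generator: correlated AR(1) forcing truth series, one
#' rank-2-plus-noise SST field per ocean basin (driven by that basin's two
#' PC truth series), LAI and soil-moisture regional series (terrestrial
#' forcings with their own seasonal cycle and trend added back), the fire
#' carbon-emission series from the known response vector, a burned-area
#' fraction series (a logistic squash of the fire anomaly into [0, 1]),
#' and the atmospheric/socioeconomic predictor suite.
#'
#' @param config a [synth_config()] with `n_forcings = 18`.
#' @return an object of class `synth_bundle` with elements `forcings`
#'   (truth matrix), `sst` (named list of [gridded_field()]), `lai`, `sm`,
#'   `fire`, `burned_area`, `predictors`, and `truth` (the config echo).
#' @export
simulate_bundle <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_forcings != 18)
    stop("simulate_bundle expects the full 18-forcing layout ",
         "(16 ocean PCs + LAI + SM)", call. = FALSE)
  forc <- gen_forcings(config)
  basins <- default_basins()
  sst <- vector("list", 8L)
  names(sst) <- names(basins)
  for (b in seq_len(8L)) {
    sst[[b]] <- gen_sst_field(basins[[b]], forc[, 2 * b - 1], forc[, 2 * b],
                              config, seed = config$seed + 10L + b)
  }
  n <- nrow(forc)
  m <- (seq_len(n) - 1L) %% 12L + 1L
  lai <- regional_series(0.6 * forc[, 17] + config$seasonal_cycle$lai[m] +
                           config$trend_slope$lai * seq_len(n) + 3,
                         units = "m2 m-2", region_id = "synthetic-region")
  sm <- regional_series(0.05 * forc[, 18] + config$seasonal_cycle$sm[m] +
                          config$trend_slope$sm * seq_len(n) + 0.25,
                        units = "m3 m-3", region_id = "synthetic-region")
  fire <- gen_fire_series(forc, config)
  ba <- regional_series(stats::plogis(-3 + 0.8 * attr(fire, "truth_anomaly")),
                        units = "fraction month-1",
                        region_id = "synthetic-region")
  pred <- gen_predictor_suite(config, fire)
  structure(list(forcings = forc, sst = sst, lai = lai, sm = sm,
                 fire = fire, burned_area = ba, predictors = pred,
                 truth = config),
            class = "synth_bundle")
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat(sprintf(
    "<synth_bundle: %d months, %d forcings, %d SST basins, seed %d>\n",
    nrow(x$forcings), ncol(x$forcings), length(x$sst), x$truth$seed))
  invisible(x)
}
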