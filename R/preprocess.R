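#' Ocean basin bounding box
#'
#' Rectangular lat/lon basin definition; boxes may wrap the dateline
#' (lon_min east of lon_max), in which case the box is treated as one
#' contiguous region in a [0, 360) longitude frame.
#'
#' @param name basin label.
#' @param lat_min,lat_max latitude bounds in degrees.
#' @param lon_min,lon_max longitude bounds in degrees (any convention).
#' @return an object of class `basin_spec`.
#' @export
basin_spec <- function(name, lat_min, lat_max, lon_min, lon_max) {
  stopifnot(lat_min >= -90, lat_max <= 90, lat_min < lat_max)
  structure(list(name = name, lat_min = lat_min, lat_max = lat_max,
                 lon_min = lon_min, lon_max = lon_max),
            class = "basin_spec")
}

basin_lon_width <- function(basin) {
  w <- lon360(basin$lon_max) - lon360(basin$lon_min)
  if (w <= 0) w <- w + 360
  w
}

#' The eight canonical ocean basins
#'
#' Default basin boxes used to build the oceanic forcing matrix: tropical
#' Pacific (20S-20N, 120E-60W), tropical Atlantic (20S-20N, 70W-20E),
#' tropical Indian (20S-20N, 35E-105E), North Pacific (20N-60N, 120E-100W),
#' North Atlantic (20N-60N, 90W-10W), South Pacific (60S-20S, 150E-70W),
#' South Atlantic (60S-20S, 70W-20E) and South Indian (60S-20S, 20E-120E).
#'
#' @return named list of [basin_spec()] objects.
#' @export
default_basins <- function() {
  list(
    TP  = basin_spec("tropical Pacific",  -20, 20, 120, -60),
    TA  = basin_spec("tropical Atlantic", -20, 20, -70, 20),
    TI  = basin_spec("tropical Indian",   -20, 20, 35, 105),
    NP  = basin_spec("North Pacific",      20, 60, 120, -100),
    NA. = basin_spec("North Atlantic",     20, 60, -90, -10),
    SP  = basin_spec("South Pacific",     -60, -20, 150, -70),
    SA  = basin_spec("South Atlantic",    -60, -20, -70, 20),
    SI  = basin_spec("South Indian",      -60, -20, 20, 120)
  )
}

#' Three-month season window
#'
#' Overlapping 3-month seasons indexed 1-12: index 1 is January-March,
#' index 2 February-April, ..., index 12 December-February (wrapping into
#' the next calendar year).
#'
#' @param index season index in 1..12.
#' @return integer vector of the three calendar months.
#' @export
season_months <- function(index) {
  stopifnot(index >= 1, index <= 12)
  (as.integer(index) - 1L + 0:2) %% 12L + 1L
}

#' Season label such as "JFM"
#' @param index season index in 1..12.
#' @return three-letter label.
#' @export
season_label <- function(index) {
  paste(substr(month.abb, 1, 1)[season_months(index)], collapse = "")
}

check_two_years <- function(month) {
  cnt <- table(factor(month, levels = 1:12))
  if (any(cnt < 2))
    stop("at least 2 full years (every calendar month twice) are required",
         call. = FALSE)
}

#' Remove the mean seasonal cycle
#'
#' Subtracts the per-calendar-month sample mean (the monthly climatology)
#' from a series or, cell by cell, from a gridded field. Missing values
#' propagate and are excluded from the climatology.
#'
#' @param x a [regional_series()] or [gridded_field()].
#' @return the same type, flagged `anomalized`.
#' @export
monthly_anomalies <- function(x) UseMethod("monthly_anomalies")

#' @export
monthly_anomalies.regional_series <- function(x) {
  check_two_years(x$month)
  clim <- tapply(x$values, factor(x$month, levels = 1:12),
                 mean, na.rm = TRUE)
  x$values <- x$values - as.numeric(clim[x$month])
  x$anomalized <- TRUE
  x
}

#' @export
monthly_anomalies.gridded_field <- function(x) {
  check_two_years(x$month)
  for (m in 1:12) {
    sel <- which(x$month == m)
    clim <- colMeans(x$values[sel, , , drop = FALSE], na.rm = TRUE)
    x$values[sel, , ] <- sweep(x$values[sel, , , drop = FALSE],
                               c(2, 3), clim, `-`)
  }
  x$anomalized <- TRUE
  x
}

ols_detrend <- function(v) {
  ok <- !is.na(v)
  if (!any(ok)) stop("cannot detrend an all-missing series", call. = FALSE)
  t <- seq_along(v)
  fit <- stats::lm.fit(cbind(1, t[ok]), v[ok])
  v[ok] <- fit$residuals
  v
}

#' Remove a long-term linear trend
#'
#' Ordinary least squares on the month index, per series or per grid cell;
#' the residual (intercept and slope removed) is returned.
#'
#' @param x a [regional_series()] or [gridded_field()].
#' @return the same type, flagged `detrended`.
#' @export
detrend_linear <- function(x) UseMethod("detrend_linear")

#' @export
detrend_linear.regional_series <- function(x) {
  x$values <- ols_detrend(x$values)
  x$detrended <- TRUE
  x
}

#' @export
detrend_linear.gridded_field <- function(x) {
  d <- dim(x$values)
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    v <- x$values[, i, j]
    if (all(is.na(v))) next
    x$values[, i, j] <- ols_detrend(v)
  }
  x$detrended <- TRUE
  x
}

#' Extract the cells of a field inside a basin box
#'
#' Keeps only grid cells whose centres fall inside the basin bounds.
#' Longitudes are compared in a [0, 360) frame so dateline-wrapping boxes
#' (e.g. 120E-60W) select one contiguous region; the output keeps the
#' field's original longitude labels.
#'
#' @param field a [gridded_field()].
#' @param basin a [basin_spec()].
#' @return a [gridded_field()] restricted to the basin.
#' @export
extract_basin <- function(field, basin) {
  stopifnot(inherits(field, "gridded_field"), inherits(basin, "basin_spec"))
  keep_lat <- field$lat >= basin$lat_min & field$lat <= basin$lat_max
  l0 <- lon360(basin$lon_min); l1 <- lon360(basin$lon_max)
  lf <- lon360(field$lon)
  keep_lon <- if (l0 < l1) lf >= l0 & lf <= l1 else lf >= l0 | lf <= l1
  if (!any(keep_lat) || !any(keep_lon))
    stop("basin '", basin$name, "' selects no grid cells", call. = FALSE)
  out <- field
  out$values <- field$values[, keep_lat, keep_lon, drop = FALSE]
  out$lat <- field$lat[keep_lat]
  out$lon <- field$lon[keep_lon]
  out
}

#' Area-weighted regional mean series
#'
#' Cosine-of-latitude weighted spatial mean per month; missing cells are
#' excluded from both the numerator and the weight sum. A month with no
#' valid cell yields NA and is counted in attribute `"n_empty_months"`.
#'
#' @param field a [gridded_field()].
#' @param basin optional [basin_spec()] to restrict to first.
#' @param region_id label for the output series.
#' @return a [regional_series()].
#' @export
regional_mean <- function(field, basin = NULL, region_id = "region") {
  if (!is.null(basin)) field <- extract_basin(field, basin)
  d <- dim(field$values)
  w <- matrix(cos(field$lat * pi / 180), d[2], d[3])
  vals <- vapply(seq_len(d[1]), function(t) {
    v <- field$values[t, , ]
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    sum(w[ok] * v[ok]) / sum(w[ok])
  }, numeric(1))
  out <- regional_series(vals, start_year = field$year[1],
                         start_month = field$month[1], units = field$units,
                         region_id = region_id,
                         anomalized = field$anomalized,
                         detrended = field$detrended)
  attr(out, "n_empty_months") <- sum(is.na(vals))
  out
}

#' Pool fire/forcing observations into a 3-month season
#'
#' For each year of the record and each of the three calendar months m of
#' the season, emits the triple (F(t), O(t), O(t - tau)) where t is the
#' month m of that year. The lagged forcing may fall in the month
#' preceding the season (e.g. December for a January-March season with
#' tau = 1); triples whose lagged month precedes the record, or that
#' contain any missing value, are dropped and counted. A full y-year
#' record yields 3y triples minus these enumerated losses.
#'
#' @param F a [regional_series()] of anomalized, detrended fire values.
#' @param O forcing matrix `[months x k]` aligned with `F`'s time axis.
#' @param season season index 1-12 (see [season_months()]), or NULL to
#'   pool the whole record.
#' @param tau lag in whole months (>= 0).
#' @return list with `F` (vector), `O_t` and `O_lag` (matrices), `n_pairs`,
#'   `n_dropped`, `season`, `tau`.
#' @export
pool_season <- function(F, O, season = NULL, tau = 1L) {
  O <- as.matrix(O)
  n <- length(F$values)
  stopifnot(nrow(O) == n)
  if (tau >= n) stop("tau must be smaller than the record length",
                     call. = FALSE)
  idx <- if (is.null(season)) seq_len(n) else
    which(F$month %in% season_months(season))
  lag_idx <- idx - as.integer(tau)
  keep <- lag_idx >= 1L
  dropped <- sum(!keep)
  idx <- idx[keep]; lag_idx <- lag_idx[keep]
  ok <- !is.na(F$values[idx]) &
    stats::complete.cases(O[idx, , drop = FALSE]) &
    stats::complete.cases(O[lag_idx, , drop = FALSE])
  dropped <- dropped + sum(!ok)
  idx <- idx[ok]; lag_idx <- lag_idx[ok]
  list(F = F$values[idx],
       O_t = O[idx, , drop = FALSE],
       O_lag = O[lag_idx, , drop = FALSE],
       n_pairs = length(idx), n_dropped = dropped,
       season = season, tau = as.integer(tau))
}
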