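#' Monthly regional time series
#'
#' Lightweight container for a single area-averaged monthly series (fire
#' carbon emission, burned-area fraction, LAI, soil moisture, an atmospheric
#' predictor, ...). The time axis is a pair of parallel integer vectors
#' (`year`, `month`) covering consecutive calendar months.
#'
#' @param values numeric vector, one value per month (NA = missing).
#' @param start_year calendar year of the first value.
#' @param start_month calendar month (1-12) of the first value.
#' @param units unit string, e.g. `"kg C m-2 month-1"`.
#' @param region_id short region label.
#' @param anomalized,detrended processing flags carried through the pipeline.
#' @return an object of class `regional_series`.
#' @export
regional_series <- function(values, start_year = 1997L, start_month = 1L,
                            units = "", region_id = "region",
                            anomalized = FALSE, detrended = FALSE) {
  stopifnot(is.numeric(values), length(values) >= 1,
            start_month >= 1, start_month <= 12)
  n <- length(values)
  mseq <- (start_month - 1L) + seq_len(n) - 1L
  structure(list(
    values = as.numeric(values),
    year = as.integer(start_year + mseq %/% 12L),
    month = as.integer(mseq %% 12L + 1L),
    units = units,
    region_id = region_id,
    anomalized = isTRUE(anomalized),
    detrended = isTRUE(detrended)
  ), class = "regional_series")
}

#' @export
length.regional_series <- function(x) length(x$values)

#' @export
print.regional_series <- function(x, ...) {
  cat(sprintf("<regional_series '%s': %d months, %d-%02d to %d-%02d%s>\n",
              x$region_id, length(x$values),
              x$year[1], x$month[1],
              x$year[length(x$year)], x$month[length(x$month)],
              if (nzchar(x$units)) paste0(", ", x$units) else ""))
  invisible(x)
}

#' Monthly gridded field
#'
#' Container for a lat/lon gridded monthly field (e.g. basin SST).
#' `values` is a numeric array with dimensions time x lat x lon; NA encodes
#' missing cells (e.g. land in an SST field).
#'
#' @param values numeric array `[time, lat, lon]`.
#' @param lat,lon cell-centre coordinates in degrees; `lat` in (-90, 90),
#'   `lon` in any convention (normalized internally where needed).
#' @param start_year,start_month calendar stamp of the first time slice.
#' @param units unit string.
#' @param anomalized,detrended processing flags.
#' @return an object of class `gridded_field`.
#' @export
gridded_field <- function(values, lat, lon, start_year = 1997L,
                          start_month = 1L, units = "",
                          anomalized = FALSE, detrended = FALSE) {
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3,
            dim(values)[2] == length(lat), dim(values)[3] == length(lon),
            all(lat >= -90), all(lat <= 90))
  n <- dim(values)[1]
  mseq <- (start_month - 1L) + seq_len(n) - 1L
  structure(list(
    values = values,
    lat = as.numeric(lat), lon = as.numeric(lon),
    year = as.integer(start_year + mseq %/% 12L),
    month = as.integer(mseq %% 12L + 1L),
    units = units,
    anomalized = isTRUE(anomalized),
    detrended = isTRUE(detrended)
  ), class = "gridded_field")
}

#' @export
print.gridded_field <- function(x, ...) {
  cat(sprintf("<gridded_field: %d months x %d lat x %d lon%s>\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              if (nzchar(x$units)) paste0(", ", x$units) else ""))
  invisible(x)
}

# 0-based month offset from the series origin; used for lag arithmetic.
time_index <- function(x) (x$year - x$year[1]) * 12L + (x$month - x$month[1])

# normalize longitudes to [0, 360)
lon360 <- function(lon) ((lon %% 360) + 360) %% 360
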