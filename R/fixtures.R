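#' Write a synthetic bundle to plain-text fixture files
#'
#' Serializes a [simulate_bundle()] result into a directory of portable
#' text files: each regional series as a CSV with columns `month`
#' (ISO "YYYY-MM") and `value`, each gridded SST field as a long-format CSV
#' with columns `time`, `lat`, `lon`, `value` (time again ISO months) and a
#' `# units:` comment header, the forcing truth matrix as CSV, and the
#' generator configuration (the ground truth) as YAML. Values are written
#' with 17 significant digits so a round trip reproduces them bit for bit.
#'
#' @param bundle a `synth_bundle`.
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(bundle, path) {
  stopifnot(inherits(bundle, "synth_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ws <- function(s, file) {
    con <- file(file.path(path, file), "w")
    on.exit(close(con))
    writeLines(sprintf("# units: %s", s$units), con)
    writeLines("month,value", con)
    writeLines(sprintf("%04d-%02d,%s", s$year, s$month,
                       fmt_num(s$values)), con)
  }
  ws(bundle$fire, "fire.csv")
  ws(bundle$burned_area, "burned_area.csv")
  ws(bundle$lai, "lai.csv")
  ws(bundle$sm, "sm.csv")
  for (nm in names(bundle$predictors$atmos))
    ws(bundle$predictors$atmos[[nm]], paste0("atmos_", nm, ".csv"))
  ann <- bundle$predictors$annual
  ann[-1] <- lapply(ann[-1], fmt_num)
  utils::write.csv(ann, file.path(path, "socio_annual.csv"),
                   row.names = FALSE, quote = FALSE)

  fm <- data.frame(month = sprintf("%04d-%02d", bundle$fire$year,
                                   bundle$fire$month))
  for (j in seq_len(ncol(bundle$forcings)))
    fm[[colnames(bundle$forcings)[j]]] <- fmt_num(bundle$forcings[, j])
  utils::write.csv(fm, file.path(path, "forcings_truth.csv"),
                   row.names = FALSE, quote = FALSE)

  for (nm in names(bundle$sst)) {
    g <- bundle$sst[[nm]]
    con <- file(file.path(path, paste0("sst_", nm, ".csv")), "w")
    writeLines(sprintf("# units: %s", g$units), con)
    writeLines("time,lat,lon,value", con)
    tstamp <- sprintf("%04d-%02d", g$year, g$month)
    d <- dim(g$values)
    for (i in seq_along(g$lat)) for (j in seq_along(g$lon)) {
      writeLines(sprintf("%s,%s,%s,%s", tstamp, fmt_num(g$lat[i]),
                         fmt_num(g$lon[j]), fmt_num(g$values[, i, j])), con)
    }
    close(con)
  }

  tr <- bundle$truth
  yaml::write_yaml(list(
    n_years = tr$n_years, n_forcings = tr$n_forcings,
    ar1_coeffs = tr$ar1_coeffs, forcing_corr = as.vector(tr$forcing_corr),
    true_R = tr$true_R, fire_noise_sd = tr$fire_noise_sd,
    grid_res = tr$grid_res, atmos_corr = as.list(tr$atmos_corr),
    seasonal_cycle = tr$seasonal_cycle, trend_slope = tr$trend_slope,
    seed = tr$seed
  ), file.path(path, "truth.yaml"))
  invisible(path)
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

read_series_csv <- function(file) {
  d <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  if (!"month" %in% names(d))
    stop("fixture parse error in '", basename(file),
         "': missing 'month' column", call. = FALSE)
  if (!"value" %in% names(d))
    stop("fixture parse error in '", basename(file),
         "': missing 'value' column", call. = FALSE)
  hdr <- readLines(file, n = 1L)
  units <- if (grepl("^# units:", hdr)) sub("^# units: ?", "", hdr) else ""
  yr <- as.integer(substr(d$month, 1, 4))
  mo <- as.integer(substr(d$month, 6, 7))
  regional_series(d$value, start_year = yr[1], start_month = mo[1],
                  units = units)
}

read_grid_csv <- function(file) {
  d <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time", "lat", "lon", "value")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("fixture parse error in '", basename(file), "': missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  hdr <- readLines(file, n = 1L)
  units <- if (grepl("^# units:", hdr)) sub("^# units: ?", "", hdr) else ""
  lat <- sort(unique(d$lat)); lon <- unique(d$lon)  # lon order as written
  tms <- sort(unique(d$time))
  arr <- array(NA_real_, c(length(tms), length(lat), length(lon)))
  ti <- match(d$time, tms); li <- match(d$lat, lat); oi <- match(d$lon, lon)
  arr[cbind(ti, li, oi)] <- d$value
  yr <- as.integer(substr(tms[1], 1, 4)); mo <- as.integer(substr(tms[1], 6, 7))
  gridded_field(arr, lat, lon, start_year = yr, start_month = mo,
                units = units)
}

#' Read a synthetic bundle back from fixture files
#'
#' Inverse of [write_fixture()]; malformed files raise a parse error naming
#' the offending file and column.
#'
#' @param path fixture directory.
#' @return a `synth_bundle` (the truth echo is rebuilt from `truth.yaml`).
#' @export
read_fixture <- function(path) {
  tr <- yaml::read_yaml(file.path(path, "truth.yaml"))
  k <- tr$n_forcings
  config <- synth_config(
    n_years = tr$n_years, n_forcings = k,
    ar1_coeffs = unlist(tr$ar1_coeffs),
    forcing_corr = matrix(unlist(tr$forcing_corr), k, k),
    true_R = unlist(tr$true_R), fire_noise_sd = tr$fire_noise_sd,
    grid_res = tr$grid_res, atmos_corr = unlist(tr$atmos_corr),
    seasonal_cycle = lapply(tr$seasonal_cycle, unlist),
    trend_slope = tr$trend_slope, seed = tr$seed)

  fm <- utils::read.csv(file.path(path, "forcings_truth.csv"),
                        stringsAsFactors = FALSE)
  if (!"month" %in% names(fm))
    stop("fixture parse error in 'forcings_truth.csv': missing 'month' column",
         call. = FALSE)
  forc <- as.matrix(fm[, -1, drop = FALSE])

  sst_files <- list.files(path, pattern = "^sst_.*\\.csv$")
  sst <- lapply(file.path(path, sst_files), read_grid_csv)
  names(sst) <- sub("^sst_(.*)\\.csv$", "\\1", sst_files)
  sst <- sst[intersect(names(default_basins()), names(sst))]

  atm_files <- list.files(path, pattern = "^atmos_.*\\.csv$")
  atmos <- lapply(file.path(path, atm_files), read_series_csv)
  names(atmos) <- sub("^atmos_(.*)\\.csv$", "\\1", atm_files)
  atmos <- atmos[intersect(names(config$atmos_corr), names(atmos))]

  annual <- utils::read.csv(file.path(path, "socio_annual.csv"))
  fire <- read_series_csv(file.path(path, "fire.csv"))
  socio <- lapply(annual[-1], function(a) {
    idx <- match(fire$year, annual$year[-1])
    regional_series(a[idx], start_year = fire$year[1], units = "",
                    region_id = "socio")
  })

  structure(list(
    forcings = forc,
    sst = sst,
    lai = read_series_csv(file.path(path, "lai.csv")),
    sm = read_series_csv(file.path(path, "sm.csv")),
    fire = fire,
    burned_area = read_series_csv(file.path(path, "burned_area.csv")),
    predictors = list(atmos = atmos, socio = socio, annual = annual),
    truth = config
  ), class = "synth_bundle")
}
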