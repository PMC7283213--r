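#' Default pipeline run configuration
#'
#' The RunConfig consumed by the `cmd_*` drivers: generator conditions,
#' estimator settings (lag, significance level, permutation count,
#' seasons), prediction settings (leads, predictor sets, model modes,
#' ensemble size) and the master seed.
#'
#' @return named list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    synth = list(n_years = 20L, ar1_coeffs = 0.8, forcing_corr = 0.2,
                 fire_noise_sd = 1),
    sgefa = list(tau = 1L, alpha = 0.1, n_iter = 1000L, seasons = 1:12),
    forecast = list(leads = 1:3, sets = c("atmos_socio", "ocean_land", "all"),
                    modes = "all_season", n_members = 100L,
                    learners = learner_families(),
                    split_mode = "year_block",
                    use_truth_forcings = FALSE)
  )
}

#' Read and validate a pipeline run configuration
#'
#' Loads a YAML RunConfig (or takes a list), overlays it on
#' [default_run_config()], and validates types and ranges before any
#' stage runs. Unknown top-level keys are an error, so typos fail fast.
#'
#' @param config path to a YAML file, or a list.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  def <- default_run_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in names(config)) {
    if (is.list(def[[k]]) && is.list(config[[k]])) {
      bad <- setdiff(names(config[[k]]), names(def[[k]]))
      if (length(bad))
        stop("unknown config key(s) under '", k, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      def[[k]][names(config[[k]])] <- config[[k]]
    } else {
      def[[k]] <- config[[k]]
    }
  }
  if (is.null(def$seed) || !is.numeric(def$seed))
    stop("config error: 'seed' must be an integer", call. = FALSE)
  with(def$sgefa, {
    if (tau < 0) stop("config error: sgefa.tau must be >= 0", call. = FALSE)
    if (alpha <= 0 || alpha >= 1)
      stop("config error: sgefa.alpha must be in (0, 1)", call. = FALSE)
  })
  if (any(!def$forecast$sets %in% c("atmos_socio", "ocean_land", "all")))
    stop("config error: unknown predictor set", call. = FALSE)
  if (any(!def$forecast$learners %in% learner_families()))
    stop("config error: unknown learner family", call. = FALSE)
  structure(def, class = "run_config")
}

write_run_metadata <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(config)
  cfg$forecast$leads <- as.integer(cfg$forecast$leads)
  cfg$sgefa$seasons <- as.integer(cfg$sgefa$seasons)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  pk <- c("sgefafire", "glmnet", "ranger", "e1071", "nnet", "xgboost")
  vers <- data.frame(package = c("R", pk),
                     version = c(paste(R.version$major, R.version$minor,
                                       sep = "."),
                                 vapply(pk, function(p)
                                   as.character(utils::packageVersion(p)),
                                   "")))
  utils::write.csv(vers, file.path(out_dir, "versions.csv"),
                   row.names = FALSE)
  invisible(file.path(out_dir, "config.yaml"))
}

config_hash <- function(out_dir) {
  unname(tools::md5sum(file.path(out_dir, "config.yaml")))
}

#' Generate and write a synthetic fixture bundle
#'
#' Wraps the generator: builds the [synth_config()] from the run
#' configuration, simulates the bundle, and writes the fixture files plus
#' the truth echo and run metadata to `out_dir`.
#'
#' @param config a [run_config()] (list or YAML path accepted).
#' @param out_dir output directory.
#' @return the bundle, invisibly.
#' @export
cmd_simulate <- function(config = list(), out_dir) {
  config <- run_config(config)
  sc <- do.call(synth_config, c(config$synth, list(seed = config$seed)))
  bundle <- simulate_bundle(sc)
  write_fixture(bundle, out_dir)
  write_run_metadata(config, out_dir)
  invisible(bundle)
}

#' Run the seasonal feedback assessment stage
#'
#' Reads a fixture bundle, preprocesses the fire series (monthly
#' anomalies, linear detrend), assembles the 18-column forcing matrix
#' (basin EOF PCs + terrestrial series), runs the stepwise estimator with
#' permutation significance for every configured season, and writes
#' long-format result tables: `seasonal_response.csv` (season, forcing,
#' R, p, retained, significant, n) and `max_season.csv` (per forcing, the
#' season of maximum absolute significant response). Reruns with the same
#' config and fixture are byte-identical.
#'
#' @param config a [run_config()].
#' @param fixture_dir directory written by [cmd_simulate()].
#' @param out_dir output directory.
#' @return the `feedback_cycle`, invisibly.
#' @export
cmd_sgefa <- function(config = list(), fixture_dir, out_dir) {
  config <- run_config(config)
  bundle <- read_fixture(fixture_dir)
  fire <- detrend_linear(monthly_anomalies(bundle$fire))
  O <- build_forcing_matrix(bundle)
  cyc <- seasonal_feedback_cycle(fire, O,
                                 seasons = config$sgefa$seasons,
                                 tau = config$sgefa$tau,
                                 n_iter = config$sgefa$n_iter,
                                 alpha = config$sgefa$alpha,
                                 seed = config$seed)
  rows <- list()
  for (s in seq_along(cyc)) {
    est <- cyc[[s]]
    if (is.null(est)) next
    rows[[length(rows) + 1L]] <- data.frame(
      season = s, season_label = season_label(s), forcing = est$labels,
      R = round(est$R, 10), p = round(est$p_values, 6),
      retained = est$retained, significant = est$significant,
      n = est$n_samples, row.names = NULL)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(season = integer(0), season_label = character(0),
               forcing = character(0), R = numeric(0), p = numeric(0),
               retained = logical(0), significant = logical(0),
               n = integer(0))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tab, file.path(out_dir, "seasonal_response.csv"),
                   row.names = FALSE)
  labels <- colnames(O)
  mx <- do.call(rbind, lapply(labels, function(lb) {
    ms <- max_response_season(cyc, lb)
    data.frame(forcing = lb, max_season = ms$season,
               R = round(ms$R, 10))
  }))
  utils::write.csv(mx, file.path(out_dir, "max_season.csv"),
                   row.names = FALSE)
  write_run_metadata(config, out_dir)
  invisible(cyc)
}

#' Run the seasonal prediction stage
#'
#' Reads a fixture bundle, assembles the predictor pool, evaluates the
#' learner-ensemble predictability over the configured grid of predictor
#' sets, leads and model modes, and writes `predictability.csv` (one row
#' per grid cell with the best learner, ensemble-mean R^2 and 10th/90th
#' percentiles). Reruns with the same config and fixture are
#' byte-identical.
#'
#' @param config a [run_config()].
#' @param fixture_dir directory written by [cmd_simulate()].
#' @param out_dir output directory.
#' @return the predictability data.frame, invisibly.
#' @export
cmd_forecast <- function(config = list(), fixture_dir, out_dir) {
  config <- run_config(config)
  bundle <- read_fixture(fixture_dir)
  pool <- predictor_pool(
    bundle, use_truth_forcings = isTRUE(config$forecast$use_truth_forcings))
  fc <- config$forecast
  tab <- compare_predictor_sets(pool, leads = fc$leads, sets = fc$sets,
                                modes = fc$modes,
                                n_members = fc$n_members,
                                seed = config$seed,
                                learners = fc$learners,
                                split_mode = fc$split_mode)
  tab$mean_r2 <- round(tab$mean_r2, 10)
  tab$q10 <- round(tab$q10, 10)
  tab$q90 <- round(tab$q90, 10)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tab, file.path(out_dir, "predictability.csv"),
                   row.names = FALSE)
  write_run_metadata(config, out_dir)
  invisible(tab)
}

md_table <- function(d) {
  d[] <- lapply(d, function(x) if (is.numeric(x)) format(x, digits = 4)
                else as.character(x))
  hdr <- paste0("| ", paste(names(d), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(d)), collapse = "|"), "|")
  body <- apply(d, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                         " |"))
  c(hdr, sep, body)
}

#' Render a human-readable run report
#'
#' Collects whatever result tables are present in a results directory
#' (seasonal responses, max-response seasons, predictability grid) into a
#' markdown report with stable row ordering and the config hash of the
#' run. Missing stages are reported explicitly.
#'
#' @param results_dir directory holding `cmd_sgefa()` / `cmd_forecast()`
#'   outputs.
#' @param file output file name (default `report.md` inside
#'   `results_dir`).
#' @return the report lines, invisibly.
#' @export
cmd_report <- function(results_dir, file = file.path(results_dir,
                                                     "report.md")) {
  if (!dir.exists(results_dir))
    stop("results directory '", results_dir, "' does not exist",
         call. = FALSE)
  lines <- c("# Seasonal fire feedback and predictability report", "")
  cfg <- file.path(results_dir, "config.yaml")
  if (file.exists(cfg))
    lines <- c(lines, sprintf("Config hash: `%s`", config_hash(results_dir)),
               "")
  sr <- file.path(results_dir, "seasonal_response.csv")
  if (file.exists(sr)) {
    d <- utils::read.csv(sr)
    sig <- d[d$significant %in% TRUE, , drop = FALSE]
    lines <- c(lines, "## Significant seasonal responses", "")
    if (nrow(sig) == 0) {
      lines <- c(lines, "No significant responses.", "")
    } else {
      sig <- sig[order(sig$season, sig$forcing), ]
      lines <- c(lines,
                 md_table(sig[, c("season_label", "forcing", "R", "p",
                                  "n")]),
                 "")
    }
    mx <- file.path(results_dir, "max_season.csv")
    if (file.exists(mx)) {
      m <- utils::read.csv(mx)
      m <- m[!is.na(m$max_season), , drop = FALSE]
      lines <- c(lines, "## Season of maximum significant response", "")
      if (nrow(m)) lines <- c(lines, md_table(m), "") else
        lines <- c(lines, "No forcing is significant in any season.", "")
    }
  } else {
    lines <- c(lines, "## Significant seasonal responses", "",
               "Feedback stage results not found.", "")
  }
  pr <- file.path(results_dir, "predictability.csv")
  if (file.exists(pr)) {
    d <- utils::read.csv(pr)
    d <- d[order(d$set, d$mode, d$lead), ]
    lines <- c(lines, "## Predictability by predictor set and lead", "",
               md_table(d), "")
  } else {
    lines <- c(lines, "## Predictability by predictor set and lead", "",
               "Prediction stage results not found.", "")
  }
  writeLines(lines, file)
  invisible(lines)
}
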