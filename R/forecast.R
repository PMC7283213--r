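#' Assemble the standardized predictor pool for the prediction system
#'
#' Collects everything the predictor tables draw from, already
#' anomalized/detrended and standardized: the 18 oceanic + terrestrial
#' forcings (either recomputed from the bundle's SST fields via basin EOFs
#' or taken from the generator truth matrix), the monthly atmospheric
#' predictors, the annual socioeconomic step series (antecedent-year
#' cadence), and the fire anomaly target.
#'
#' @param bundle a `synth_bundle`.
#' @param use_truth_forcings use `bundle$forcings` directly instead of
#'   recomputing basin EOFs (default FALSE).
#' @return object of class `predictor_pool` with matrices `ocean_land`,
#'   `atmos`, `socio`, the target series `fire`, and the time axis.
#' @export
predictor_pool <- function(bundle, use_truth_forcings = FALSE) {
  fire <- detrend_linear(monthly_anomalies(bundle$fire))
  OL <- if (use_truth_forcings) {
    scale(bundle$forcings)
  } else {
    build_forcing_matrix(bundle, standardized = TRUE)
  }
  atm <- vapply(bundle$predictors$atmos, function(s) {
    as.numeric(scale(detrend_linear(monthly_anomalies(s))$values))
  }, numeric(length(fire$values)))
  soc <- vapply(bundle$predictors$socio, function(s) s$values,
                numeric(length(fire$values)))
  soc <- scale(soc)
  structure(list(ocean_land = unclass(OL), atmos = atm, socio = unclass(soc),
                 fire = fire, year = fire$year, month = fire$month),
            class = "predictor_pool")
}

#' Build a lagged predictor table for one lead time and predictor set
#'
#' For environmental (oceanic, terrestrial, atmospheric) predictors the
#' table holds the three lags `t - lead`, `t - lead - 1`, `t - lead - 2`,
#' extending the one-to-three-months-in-advance convention to longer
#' leads; no environmental column uses information later than `t - lead`.
#' Socioeconomic predictors enter as a single column carrying the value
#' reported at the end of the target month's antecedent calendar year.
#' The target is the regional fire anomaly at t. Rows with any missing
#' entry (including the record head, where lags are unavailable) are
#' dropped and counted in attribute `"n_dropped"`.
#'
#' @param pool a [predictor_pool()].
#' @param lead lead time in months (>= 1).
#' @param season optional season index 1-12 restricting target months.
#' @param set `"ocean_land"`, `"atmos_socio"`, or `"all"`.
#' @return object of class `predictor_table` with `X`, `y`, `year`,
#'   `month`, `lead`, `season`, `set`.
#' @export
build_predictor_table <- function(pool, lead = 1L,
                                  season = NULL,
                                  set = c("all", "ocean_land",
                                          "atmos_socio")) {
  set <- match.arg(set)
  lead <- as.integer(lead)
  stopifnot(lead >= 1)
  n <- length(pool$fire$values)
  env <- switch(set,
    ocean_land = pool$ocean_land,
    atmos_socio = pool$atmos,
    all = cbind(pool$ocean_land, pool$atmos))
  lags <- lead + 0:2
  blocks <- lapply(lags, function(L) {
    B <- rbind(matrix(NA_real_, L, ncol(env)),
               env[seq_len(n - L), , drop = FALSE])
    colnames(B) <- sprintf("%s(t-%d)", colnames(env), L)
    B
  })
  X <- do.call(cbind, blocks)
  if (set %in% c("atmos_socio", "all")) {
    S <- pool$socio
    colnames(S) <- sprintf("%s(y-1)", colnames(S))
    X <- cbind(X, S)
  }
  y <- pool$fire$values
  keep <- seq_len(n) > (lead + 2L)
  if (!is.null(season)) keep <- keep & pool$month %in% season_months(season)
  keep <- keep & stats::complete.cases(X) & !is.na(y)
  n_dropped <- if (is.null(season)) sum(!keep) else
    sum(pool$month %in% season_months(season)) - sum(keep)
  out <- structure(list(X = X[keep, , drop = FALSE], y = y[keep],
                        year = pool$year[keep], month = pool$month[keep],
                        lead = lead, season = season, set = set),
                   class = "predictor_table")
  if (nrow(out$X) == 0)
    stop("predictor table is empty after dropping incomplete rows",
         call. = FALSE)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Split a predictor table into training and testing parts
#'
#' Two protocols: `"year_block"` holds out whole randomly chosen years
#' (one quarter of the years, i.e. 5 of a 20-year record, so an
#' all-season table tests on ~60 monthly rows and a season-specific table
#' on ~15), guaranteeing that no calendar year contributes to both sides;
#' `"month_random"` holds out one quarter of the rows (60 of 240 months)
#' irrespective of year and season.
#'
#' @param table a [build_predictor_table()] result.
#' @param mode `"year_block"` or `"month_random"`.
#' @param seed integer seed for the random draw.
#' @return list with integer row indices `train` and `test` and the
#'   held-out `test_years` (year-block mode).
#' @export
split_train_test <- function(table, mode = c("year_block", "month_random"),
                             seed = 1L) {
  mode <- match.arg(mode)
  n <- length(table$y)
  set.seed(seed)
  if (mode == "year_block") {
    years <- sort(unique(table$year))
    if (length(years) < 4)
      stop("year-block splitting needs at least 4 distinct years",
           call. = FALSE)
    n_test <- max(1L, round(length(years) / 4))
    test_years <- sort(sample(years, n_test))
    test <- which(table$year %in% test_years)
    list(train = setdiff(seq_len(n), test), test = test,
         test_years = test_years)
  } else {
    n_test <- max(1L, round(n / 4))
    test <- sort(sample.int(n, n_test))
    list(train = setdiff(seq_len(n), test), test = test,
         test_years = NULL)
  }
}

learner_families <- function() c("rf", "svm", "nnet", "lasso", "gbm")

learner_grid <- function(learner, p) {
  switch(learner,
    rf = {
      mtry <- unique(pmax(1L, c(floor(p / 3), floor(sqrt(p)))))
      lapply(mtry, function(m) list(mtry = m))
    },
    svm = {
      g <- expand.grid(cost = c(1, 10), gamma = c(0.5, 2) / p)
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    nnet = list(list(size = 3L, decay = 0.1),
                list(size = 6L, decay = 0.01)),
    gbm = list(list(max_depth = 2L), list(max_depth = 3L)),
    lasso = list(list()),
    stop("unknown learner '", learner, "'", call. = FALSE))
}

fit_learner_raw <- function(learner, X, y, params, seed) {
  set.seed(seed)
  switch(learner,
    rf = ranger::ranger(x = as.data.frame(X), y = y, num.trees = 300L,
                        mtry = min(params$mtry, ncol(X)),
                        min.node.size = 5L, seed = seed,
                        num.threads = 1L),
    svm = e1071::svm(x = X, y = y, type = "eps-regression",
                     kernel = "radial", cost = params$cost,
                     gamma = params$gamma, scale = FALSE),
    nnet = nnet::nnet(x = X, y = y, size = params$size,
                      decay = params$decay, linout = TRUE, trace = FALSE,
                      maxit = 200L, MaxNWts = 10000L),
    gbm = xgboost::xgb.train(
      params = list(max_depth = params$max_depth, eta = 0.1,
                    objective = "reg:squarederror", nthread = 1L),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
      nrounds = 120L, verbose = 0),
    lasso = NULL)
}

predict_learner_raw <- function(learner, model, X) {
  switch(learner,
    rf = stats::predict(model, data = as.data.frame(X),
                        num.threads = 1L)$predictions,
    svm = as.numeric(stats::predict(model, X)),
    nnet = as.numeric(stats::predict(model, X)),
    gbm = as.numeric(stats::predict(model,
                                    xgboost::xgb.DMatrix(X, nthread = 1L))),
    lasso = as.numeric(stats::predict(model, newx = X,
                                      s = "lambda.min")))
}

#' Fit one learner family with cross-validated hyperparameters
#'
#' Standardizes the predictors on training statistics only, then selects
#' hyperparameters from a small fixed grid by 10-fold cross-validation
#' minimizing RMSE, and refits on the full training set. The L1-penalized
#' linear model tunes its penalty along the glmnet path with the same
#' fixed folds. Everything is deterministic given `seed`. A constant
#' training target yields a constant predictor with a warning.
#'
#' @param learner one of `"rf"`, `"svm"`, `"nnet"`, `"lasso"`, `"gbm"`
#'   (random forest, support-vector regressor, feed-forward neural
#'   network, L1-penalized linear model, gradient-boosted trees).
#' @param X training predictor matrix.
#' @param y training target vector.
#' @param seed integer seed controlling folds and stochastic fits.
#' @param cv_folds number of cross-validation folds (default 10).
#' @return object of class `fitted_learner`.
#' @export
fit_learner <- function(learner, X, y, seed = 1L, cv_folds = 10L) {
  learner <- match.arg(learner, learner_families())
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 3, length(y) == n)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  if (stats::sd(y) < 1e-12) {
    warning("constant training target; fitting a constant predictor",
            call. = FALSE)
    return(structure(list(learner = learner, constant = mean(y),
                          center = ctr, scale = scl, chosen = NULL),
                     class = "fitted_learner"))
  }
  k <- min(cv_folds, n)
  set.seed(seed)
  foldid <- sample(rep(seq_len(k), length.out = n))
  if (learner == "lasso") {
    model <- glmnet::cv.glmnet(Xs, y, alpha = 1, foldid = foldid,
                               standardize = FALSE, nfolds = k)
    return(structure(list(learner = learner, model = model, center = ctr,
                          scale = scl,
                          chosen = list(lambda = model$lambda.min)),
                     class = "fitted_learner"))
  }
  grid <- learner_grid(learner, ncol(Xs))
  cv_rmse <- vapply(seq_along(grid), function(g) {
    err <- 0
    for (f in seq_len(k)) {
      tr <- foldid != f
      m <- fit_learner_raw(learner, Xs[tr, , drop = FALSE], y[tr],
                           grid[[g]], seed = seed + 13L * g + f)
      pr <- predict_learner_raw(learner, m, Xs[!tr, , drop = FALSE])
      err <- err + sum((y[!tr] - pr)^2)
    }
    sqrt(err / n)
  }, numeric(1))
  best <- which.min(cv_rmse)
  model <- fit_learner_raw(learner, Xs, y, grid[[best]], seed = seed)
  structure(list(learner = learner, model = model, center = ctr,
                 scale = scl, chosen = grid[[best]],
                 cv_rmse = cv_rmse),
            class = "fitted_learner")
}

#' @export
predict.fitted_learner <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$constant)) return(rep(object$constant, nrow(X)))
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  predict_learner_raw(object$learner, object$model, Xs)
}

#' Squared Pearson correlation between observations and predictions
#'
#' The prediction-skill metric: R^2 = cor(obs, pred)^2. By this
#' definition perfectly anti-correlated predictions also score 1; that is
#' a documented property of the correlation-squared semantics. If either
#' side has (near-)zero variance the score is undefined and NA is
#' returned; ensemble aggregation treats such members as 0 and counts
#' them.
#'
#' @param obs observed values.
#' @param pred predicted values.
#' @return scalar in [0, 1], or NA if undefined.
#' @export
r2_score <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 3)
  if (stats::sd(obs) < 1e-12 || stats::sd(pred) < 1e-12) return(NA_real_)
  stats::cor(obs, pred)^2
}

#' Ensemble predictability of a predictor table
#'
#' The repeated-random-split protocol: for each of `n_members` seeded
#' splits, every learner family is tuned by 10-fold CV on the training
#' part and scored by R^2 on the held-out part. The best learner is the
#' family with the highest ensemble-mean R^2 (never chosen per member),
#' and the reported predictability is that family's ensemble mean with
#' its 10th/90th percentile member range. Undefined member R^2 values
#' (constant predictions) count as 0 and are tallied.
#'
#' @param table a [build_predictor_table()] result.
#' @param n_members ensemble size (default 100).
#' @param seed master seed; fully determines every member.
#' @param learners learner families to include (default all five).
#' @param split_mode passed to [split_train_test()].
#' @param keep_models keep fitted models and test indices per member
#'   (needed by [importance_scores()]).
#' @return object of class `forecast_result`.
#' @export
ensemble_predictability <- function(table, n_members = 100L, seed = 1L,
                                    learners = learner_families(),
                                    split_mode = "year_block",
                                    keep_models = FALSE) {
  set.seed(seed)
  member_seeds <- sample.int(.Machine$integer.max %/% 2L, n_members)
  r2 <- matrix(NA_real_, n_members, length(learners),
               dimnames = list(NULL, learners))
  n_undefined <- 0L
  models <- if (keep_models) vector("list", n_members) else NULL
  tests <- if (keep_models) vector("list", n_members) else NULL
  for (m in seq_len(n_members)) {
    sp <- split_train_test(table, mode = split_mode,
                           seed = member_seeds[m])
    Xtr <- table$X[sp$train, , drop = FALSE]; ytr <- table$y[sp$train]
    Xte <- table$X[sp$test, , drop = FALSE]; yte <- table$y[sp$test]
    fits <- list()
    for (j in seq_along(learners)) {
      fit <- fit_learner(learners[j], Xtr, ytr,
                         seed = member_seeds[m] + 1000L * j)
      pr <- predict(fit, Xte)
      v <- r2_score(yte, pr)
      if (is.na(v)) { n_undefined <- n_undefined + 1L; v <- 0 }
      r2[m, j] <- v
      if (keep_models) fits[[learners[j]]] <- fit
    }
    if (keep_models) { models[[m]] <- fits; tests[[m]] <- sp$test }
    # booster/forest handles accumulate quickly across members; collecting
    # them promptly keeps long ensembles stable
    if (m %% 10L == 0L) gc(verbose = FALSE)
  }
  mean_by_learner <- colMeans(r2)
  best <- learners[which.max(mean_by_learner)]
  bm <- r2[, best]
  structure(list(r2_members = r2, mean_by_learner = mean_by_learner,
                 best_learner = best, mean_r2 = mean(bm),
                 q10 = unname(stats::quantile(bm, 0.10)),
                 q90 = unname(stats::quantile(bm, 0.90)),
                 n_undefined = n_undefined,
                 lead = table$lead, season = table$season,
                 set = table$set, n_members = as.integer(n_members),
                 split_mode = split_mode, seed = as.integer(seed),
                 models = models, test_rows = tests),
            class = "forecast_result")
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf(
    "<forecast_result: set=%s lead=%d%s, best=%s, mean R2=%.3f [%.3f, %.3f], %d members>\n",
    x$set, x$lead,
    if (is.null(x$season)) "" else paste0(" season=", x$season),
    x$best_learner, x$mean_r2, x$q10, x$q90, x$n_members))
  invisible(x)
}

#' Permutation importance of each predictor
#'
#' For the best learner of a kept-models ensemble, shuffles one predictor
#' column at a time within each member's test rows and records the drop
#' in test R^2; scores are the mean drop across members. A predictor the
#' model never uses scores ~0; note that collinear duplicates share
#' (split) their importance.
#'
#' @param result an [ensemble_predictability()] result built with
#'   `keep_models = TRUE`.
#' @param table the same predictor table.
#' @param seed seed for the shuffles.
#' @return named numeric vector of mean R^2 drops, one per predictor.
#' @export
importance_scores <- function(result, table, seed = 1L) {
  if (is.null(result$models))
    stop("ensemble was not run with keep_models = TRUE", call. = FALSE)
  set.seed(seed)
  best <- result$best_learner
  p <- ncol(table$X)
  drops <- matrix(0, result$n_members, p,
                  dimnames = list(NULL, colnames(table$X)))
  for (m in seq_len(result$n_members)) {
    fit <- result$models[[m]][[best]]
    te <- result$test_rows[[m]]
    Xte <- table$X[te, , drop = FALSE]; yte <- table$y[te]
    base <- result$r2_members[m, best]
    for (j in seq_len(p)) {
      Xp <- Xte
      Xp[, j] <- Xp[sample.int(nrow(Xp)), j]
      v <- r2_score(yte, predict(fit, Xp))
      if (is.na(v)) v <- 0
      drops[m, j] <- base - v
    }
  }
  colMeans(drops)
}

#' Predictability across predictor sets, leads and model modes
#'
#' Runs the ensemble protocol over the full grid of predictor sets
#' (oceanic+terrestrial, atmospheric+socioeconomic, all), lead times, and
#' model modes. `"all_season"` fits one model on all months;
#' `"season_specific"` fits and evaluates one model per 3-month season
#' and reports the across-season mean of the per-season predictability.
#'
#' @param pool a [predictor_pool()].
#' @param leads lead times in months (default 1:6).
#' @param sets predictor sets to compare.
#' @param modes model modes.
#' @param seasons seasons used by the season-specific mode.
#' @param n_members ensemble size per cell of the grid.
#' @param seed master seed.
#' @param learners learner families.
#' @param split_mode passed through to the splits.
#' @return data.frame with one row per (set, lead, mode): best learner,
#'   mean R^2, 10th/90th percentiles.
#' @export
compare_predictor_sets <- function(pool, leads = 1:6,
                                   sets = c("atmos_socio", "ocean_land",
                                            "all"),
                                   modes = "all_season",
                                   seasons = 1:12,
                                   n_members = 100L, seed = 1L,
                                   learners = learner_families(),
                                   split_mode = "year_block") {
  rows <- list()
  for (set in sets) for (lead in leads) for (mode in modes) {
    if (mode == "all_season") {
      tab <- build_predictor_table(pool, lead = lead, set = set)
      res <- ensemble_predictability(tab, n_members = n_members,
                                     seed = seed + 97L * lead,
                                     learners = learners,
                                     split_mode = split_mode)
      row <- data.frame(set = set, lead = lead, mode = mode,
                        best_learner = res$best_learner,
                        mean_r2 = res$mean_r2, q10 = res$q10,
                        q90 = res$q90)
    } else {
      per <- lapply(seasons, function(s) {
        tab <- build_predictor_table(pool, lead = lead, season = s,
                                     set = set)
        ensemble_predictability(tab, n_members = n_members,
                                seed = seed + 97L * lead + s,
                                learners = learners,
                                split_mode = split_mode)
      })
      row <- data.frame(set = set, lead = lead, mode = mode,
                        best_learner = names(which.max(table(
                          vapply(per, `[[`, "", "best_learner")))),
                        mean_r2 = mean(vapply(per, `[[`, 0, "mean_r2")),
                        q10 = mean(vapply(per, `[[`, 0, "q10")),
                        q90 = mean(vapply(per, `[[`, 0, "q90")))
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}
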