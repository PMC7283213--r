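make_pool <- function(seed = 61, n_years = 20, true_R = NULL,
                      atmos_corr = c(lightning = 0.1, temp = 0.4,
                                     moisture = -0.4, wind = 0.25)) {
  cfg <- synth_config(seed = seed, n_years = n_years, true_R = true_R,
                      atmos_corr = atmos_corr)
  bundle <- simulate_bundle(cfg)
  predictor_pool(bundle, use_truth_forcings = TRUE)
}

test_that("predictor tables respect lag structure and the leakage guard", {
  pool <- make_pool()
  # lead 1: each environmental predictor appears at lags t-1, t-2, t-3
  tab <- build_predictor_table(pool, lead = 1, set = "ocean_land")
  expect_equal(ncol(tab$X), 18 * 3)
  expect_setequal(grep("^TP-PC1", colnames(tab$X), value = TRUE),
                  c("TP-PC1(t-1)", "TP-PC1(t-2)", "TP-PC1(t-3)"))

  # lag columns really are the shifted series
  t0 <- which(pool$year == 1998 & pool$month == 5)
  row <- which(tab$year == 1998 & tab$month == 5)
  expect_equal(unname(tab$X[row, "SM(t-2)"]),
               unname(pool$ocean_land[t0 - 2, "SM"]))

  # lead 6: no environmental column later than t - 6
  tab6 <- build_predictor_table(pool, lead = 6, set = "ocean_land")
  lags <- as.integer(sub(".*\\(t-(\\d+)\\)$", "\\1", colnames(tab6$X)))
  expect_true(all(lags >= 6))

  # socioeconomic predictors: single antecedent-year column
  taba <- build_predictor_table(pool, lead = 1, set = "atmos_socio")
  expect_true(all(c("population(y-1)", "landuse(y-1)") %in%
                    colnames(taba$X)))
  expect_equal(ncol(taba$X), 4 * 3 + 2)
  # constant within each target year
  pop <- taba$X[, "population(y-1)"]
  expect_true(all(tapply(pop, taba$year, function(v) diff(range(v))) == 0))

  # "all" combines both plus socio
  tball <- build_predictor_table(pool, lead = 1, set = "all")
  expect_equal(ncol(tball$X), (18 + 4) * 3 + 2)

  # head-of-record rows without full lags are dropped
  expect_equal(nrow(tab$X), 240 - 3)
  expect_equal(attr(tab, "n_dropped"), 3)
})

test_that("train/test splits are disjoint and sized per protocol", {
  pool <- make_pool()
  tab <- build_predictor_table(pool, lead = 1, set = "ocean_land")

  sp <- split_train_test(tab, "year_block", seed = 3)
  expect_length(sp$test_years, 5)
  expect_length(intersect(sp$train, sp$test), 0)
  # no calendar year on both sides
  expect_length(intersect(unique(tab$year[sp$train]),
                          unique(tab$year[sp$test])), 0)
  # an all-season split away from the record head tests on 5 x 12 rows
  for (s in 1:50) {
    spx <- split_train_test(tab, "year_block", seed = s)
    if (!(1997 %in% spx$test_years)) {
      expect_length(spx$test, 60)
      break
    }
  }

  # season-specific table (mid-year season, no boundary loss): 15 test rows
  tj <- build_predictor_table(pool, lead = 1, season = 6,
                              set = "ocean_land")
  expect_equal(nrow(tj$X), 60)
  spj <- split_train_test(tj, "year_block", seed = 4)
  expect_length(spj$test, 15)

  # month-random mode: 60 of 240 rows regardless of season
  spm <- split_train_test(tab, "month_random", seed = 5)
  expect_length(spm$test, round(nrow(tab$X) / 4))
  expect_length(intersect(spm$train, spm$test), 0)

  expect_error(split_train_test(tab, "fortnight"), "arg")
})

test_that("R2 scoring matches its definition and a loop oracle", {
  y <- c(0.3, -1.2, 0.5, 2.0, -0.7)
  expect_equal(r2_score(y, y), 1)
  expect_equal(r2_score(y, -y), 1)   # correlation-squared semantics
  p <- c(0.1, -0.9, 0.8, 1.5, -0.2)
  # explicit loop Pearson oracle
  n <- 5; sy <- sum(y); sp <- sum(p)
  num <- n * sum(y * p) - sy * sp
  den <- sqrt(n * sum(y^2) - sy^2) * sqrt(n * sum(p^2) - sp^2)
  expect_equal(r2_score(y, p), (num / den)^2, tolerance = 1e-12)
  # degenerate prediction is flagged undefined
  expect_true(is.na(r2_score(y, rep(1, 5))))
})

test_that("learners fit deterministically and nail an exact linear target", {
  set.seed(62)
  X <- matrix(rnorm(200 * 6), 200, 6,
              dimnames = list(NULL, paste0("x", 1:6)))
  y <- X %*% c(1, -0.5, 0.25, 0, 0, 0)
  f <- fit_learner("lasso", X, y, seed = 7)
  pr <- predict(f, X)
  expect_lt(sqrt(mean((y - pr)^2)), 0.05)

  # same seed, same predictions, for every family
  Xs <- X[1:80, ]; ys <- y[1:80] + rnorm(80, 0, 0.2)
  for (fam in c("rf", "svm", "nnet", "lasso", "gbm")) {
    f1 <- fit_learner(fam, Xs, ys, seed = 11)
    f2 <- fit_learner(fam, Xs, ys, seed = 11)
    expect_identical(predict(f1, X[81:120, ]), predict(f2, X[81:120, ]),
                     info = fam)
  }

  # constant target: constant predictor with a warning
  expect_warning(fc <- fit_learner("rf", Xs, rep(2, 80), seed = 3),
                 "constant")
  expect_equal(unique(predict(fc, Xs)), 2)
})

test_that("ensemble predictability is reproducible and honest about noise", {
  pool <- make_pool(seed = 63)
  tab <- build_predictor_table(pool, lead = 1, set = "ocean_land")

  # pure-noise target: no skill
  tabn <- tab
  set.seed(64)
  tabn$y <- rnorm(length(tab$y))
  resn <- ensemble_predictability(tabn, n_members = 6, seed = 8,
                                  learners = c("lasso", "rf"))
  expect_lt(resn$mean_r2, 0.1)

  # reproducibility: identical members for identical seeds
  res1 <- ensemble_predictability(tab, n_members = 4, seed = 9,
                                  learners = c("lasso", "rf"))
  res2 <- ensemble_predictability(tab, n_members = 4, seed = 9,
                                  learners = c("lasso", "rf"))
  expect_identical(res1$r2_members, res2$r2_members)
  expect_identical(res1$best_learner, res2$best_learner)
  # percentile order respected
  expect_lte(res1$q10, res1$mean_r2 + 1e-12)
  expect_lte(res1$q10, res1$q90)

  # noiseless linear target: near-perfect skill
  tabl <- tab
  tabl$y <- as.numeric(tab$X %*% c(rep(0, 10), 1, rep(0, ncol(tab$X) - 11)))
  resl <- ensemble_predictability(tabl, n_members = 4, seed = 10,
                                  learners = "lasso")
  expect_gte(resl$mean_r2, 0.99)
})

test_that("importance scores rank generative predictors correctly", {
  set.seed(65)
  n <- 240
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, c("strong", "weak", "null1", "null2")))
  y <- 1.5 * X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, 0.8)
  tab <- direct_table(X, y)
  res <- ensemble_predictability(tab, n_members = 5, seed = 12,
                                 learners = c("lasso", "rf"),
                                 keep_models = TRUE)
  imp <- importance_scores(res, tab, seed = 13)
  expect_equal(names(which.max(imp)), "strong")
  # predictors absent from the generative model score near zero
  expect_lt(max(imp[c("null1", "null2")]), 0.1)
  expect_gt(imp["strong"], imp["weak"])

  # without kept models the scores are unavailable
  res2 <- ensemble_predictability(tab, n_members = 2, seed = 12,
                                  learners = "lasso")
  expect_error(importance_scores(res2, tab), "keep_models")
})

test_that("no-leakage: fresh-noise targets keep members near zero skill", {
  pool <- make_pool(seed = 66)
  tab <- build_predictor_table(pool, lead = 1, set = "all")
  set.seed(67)
  tab$y <- rnorm(length(tab$y))
  res <- ensemble_predictability(tab, n_members = 8, seed = 14,
                                 learners = "lasso")
  expect_lt(res$mean_r2, 0.1)
})
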