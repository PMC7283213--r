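#' Lagged covariance statistics for the feedback estimator
#'
#' Computes the two ingredients of the lagged-covariance response
#' estimator from pooled samples: `C_FO`, the sample covariance (row
#' vector) of the fire value F(t) with each forcing at the earlier time
#' O(t - tau), and `C_OO`, the square lagged autocovariance matrix of the
#' forcings, cov(O(t), O(t - tau)). Sample covariances use the n - 1
#' denominator. Because the slowly evolving forcings cannot be driven by
#' subsequent fire noise, the noise term drops out of the lagged moment
#' equation and R = C_FO %*% solve(C_OO) identifies the instantaneous
#' response.
#'
#' @param F numeric vector of pooled fire values F(t).
#' @param O_t matrix of contemporaneous forcings O(t), rows matching `F`.
#' @param O_lag matrix of lagged forcings O(t - tau), rows matching `F`.
#' @return list with `C_FO` (1 x k) and `C_OO` (k x k).
#' @export
lagged_covariance <- function(F, O_t, O_lag) {
  O_t <- as.matrix(O_t); O_lag <- as.matrix(O_lag)
  n <- length(F)
  stopifnot(nrow(O_t) == n, nrow(O_lag) == n)
  if (n <= ncol(O_t) + 2)
    stop("insufficient pooled samples (n = ", n, ") for ", ncol(O_t),
         " forcings", call. = FALSE)
  Fc <- F - mean(F)
  Tc <- sweep(O_t, 2, colMeans(O_t))
  Lc <- sweep(O_lag, 2, colMeans(O_lag))
  list(C_FO = matrix(crossprod(Fc, Lc) / (n - 1), 1),
       C_OO = crossprod(Tc, Lc) / (n - 1))
}

# returns a closure drawing one permutation of 1..n; with a block length,
# contiguous blocks are shuffled so short-range memory survives under the
# null. Either way the result is a permutation: the sample multiset is
# preserved exactly.
make_permuter <- function(n, block = NULL) {
  if (is.null(block)) return(function() sample.int(n))
  nb <- ceiling(n / block)
  function() {
    starts <- (sample.int(nb) - 1L) * block + 1L
    idx <- unlist(lapply(starts, function(s) s:min(s + block - 1L, n)))
    idx[seq_len(n)]
  }
}

pinv <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Estimate the feedback response vector
#'
#' The lagged-covariance estimator R = C_FO(tau) %*% C_OO(tau)^-1,
#' giving the fire response per unit (standardized) forcing. When C_OO is
#' ill-conditioned (condition number > 1e8) a pseudo-inverse is used with
#' a warning recommending stepwise forcing reduction, which is the
#' intended guard against sampling error from too many simultaneous
#' forcings.
#'
#' @inheritParams lagged_covariance
#' @param cond_tol condition-number threshold for the pseudo-inverse
#'   fallback.
#' @return named numeric response vector (length k).
#' @export
estimate_response <- function(F, O_t, O_lag, cond_tol = 1e8) {
  cv <- lagged_covariance(F, O_t, O_lag)
  kap <- tryCatch(kappa(cv$C_OO, exact = TRUE), error = function(e) Inf)
  R <- if (!is.finite(kap) || kap > cond_tol) {
    warning("C_OO(tau) is near-singular (condition number ",
            format(kap, digits = 3),
            "); using pseudo-inverse - consider stepwise forcing reduction",
            call. = FALSE)
    cv$C_FO %*% pinv(cv$C_OO)
  } else {
    cv$C_FO %*% solve(cv$C_OO)
  }
  stats::setNames(as.numeric(R), colnames(O_t))
}

#' AIC of a forcing-subset response model
#'
#' Gaussian concentrated-likelihood form: AIC = n * log(RSS / n) + 2k,
#' with RSS the sum of squared residuals of the instantaneous response
#' model, F(t) minus the subset's lagged-covariance response estimate
#' applied to the contemporaneous forcings O(t), and k = (number of
#' forcings) + 1 counting the noise variance. Lower is better. The
#' residual is taken against O(t), not O(t - tau), because the response
#' model being scored is F(t) = R O(t) + N(t); the lag enters only
#' through the estimation of R. A zero RSS returns -Inf with a warning.
#'
#' @inheritParams lagged_covariance
#' @param subset integer/logical index of forcing columns; empty for the
#'   null (noise-only) model.
#' @return scalar AIC.
#' @export
aic_score <- function(F, O_t, O_lag, subset = seq_len(ncol(as.matrix(O_t)))) {
  n <- length(F)
  if (length(subset) == 0 || (is.logical(subset) && !any(subset))) {
    rss <- sum(F^2)  # null model: fitted value 0
    k <- 1
  } else {
    R <- estimate_response(F, as.matrix(O_t)[, subset, drop = FALSE],
                           as.matrix(O_lag)[, subset, drop = FALSE])
    res <- F - as.matrix(O_t)[, subset, drop = FALSE] %*% R
    rss <- sum(res^2)
    k <- length(R) + 1
  }
  if (rss <= 0) {
    warning("zero residual sum of squares; AIC is -Inf", call. = FALSE)
    return(-Inf)
  }
  n * log(rss / n) + 2 * k
}

# analytic (bootstrap-free) standard errors used only for deterministic
# tie-breaking in the stepwise search
response_se <- function(F, O_t, O_lag, subset) {
  Tc <- sweep(as.matrix(O_t)[, subset, drop = FALSE], 2,
              colMeans(as.matrix(O_t)[, subset, drop = FALSE]))
  R <- estimate_response(F, as.matrix(O_t)[, subset, drop = FALSE],
                         as.matrix(O_lag)[, subset, drop = FALSE])
  res <- F - mean(F) - Tc %*% R
  n <- length(F); k <- length(subset)
  s2 <- sum(res^2) / max(1, n - k - 1)
  XtX <- crossprod(Tc)
  dv <- diag(pinv(XtX))
  sqrt(pmax(s2 * dv, 1e-300))
}

#' Backward-stepwise AIC selection of the forcing subset
#'
#' Starting from the full forcing matrix, repeatedly removes the single
#' forcing whose removal most decreases the AIC of the lagged-covariance
#' response model; stops when no removal decreases the AIC. Ties (equal
#' AIC gain within 1e-9) are broken deterministically by removing the
#' forcing with the smallest |R|/SE using an analytic standard error. The
#' final response vector is re-estimated on the retained subset.
#'
#' @inheritParams lagged_covariance
#' @return list with `retained` (integer column indices), `R` (response on
#'   the retained subset), `aic_path` (AIC after each removal, starting
#'   with the full model), `labels`.
#' @export
backward_stepwise <- function(F, O_t, O_lag) {
  O_t <- as.matrix(O_t); O_lag <- as.matrix(O_lag)
  k <- ncol(O_t)
  labels <- colnames(O_t)
  if (is.null(labels)) labels <- paste0("O", seq_len(k))
  current <- seq_len(k)
  aic_cur <- aic_score(F, O_t, O_lag, current)
  path <- aic_cur
  while (length(current) > 0) {
    cand <- vapply(seq_along(current), function(i) {
      aic_score(F, O_t, O_lag, current[-i])
    }, numeric(1))
    best <- min(cand)
    if (best >= aic_cur - 1e-12) break
    ties <- which(cand <= best + 1e-9)
    drop_i <- if (length(ties) > 1) {
      R <- estimate_response(F, O_t[, current, drop = FALSE],
                             O_lag[, current, drop = FALSE])
      se <- response_se(F, O_t, O_lag, current)
      ties[which.min((abs(R) / se)[ties])]
    } else ties
    current <- current[-drop_i]
    aic_cur <- aic_score(F, O_t, O_lag, current)
    path <- c(path, aic_cur)
  }
  R <- if (length(current)) {
    estimate_response(F, O_t[, current, drop = FALSE],
                      O_lag[, current, drop = FALSE])
  } else numeric(0)
  list(retained = current, R = R, aic_path = path,
       labels = labels[current])
}

#' Monte-Carlo permutation significance of the response estimates
#'
#' Builds the null distribution of each response coefficient by
#' re-estimating the response on random permutations of the pooled fire
#' sample vector (the forcing samples stay fixed), which preserves the
#' fire marginal distribution exactly while destroying any lagged
#' relationship. Two-sided p-value per forcing: the fraction of permuted
#' |R*| at least as large as the observed |R|, with the (count + 1) /
#' (n_iter + 1) continuity correction. Significance is declared at
#' p < alpha (default 0.1, i.e. 90% confidence).
#'
#' @inheritParams lagged_covariance
#' @param n_iter number of permutations (default 1000; fewer than 100
#'   triggers a warning).
#' @param alpha two-sided significance level.
#' @param block optional block length: permute contiguous blocks of the
#'   fire sample vector instead of single values, preserving short-range
#'   memory under the null (for autocorrelated fire samples).
#' @return list with `p_values`, `significant` (logical), `R_obs`,
#'   `n_iter`, `alpha`.
#' @export
bootstrap_significance <- function(F, O_t, O_lag, n_iter = 1000L,
                                   alpha = 0.1, block = NULL) {
  if (n_iter < 100)
    warning("n_iter < 100 gives coarse p-values", call. = FALSE)
  O_t <- as.matrix(O_t); O_lag <- as.matrix(O_lag)
  n <- length(F)
  cv <- lagged_covariance(F, O_t, O_lag)
  kap <- tryCatch(kappa(cv$C_OO, exact = TRUE), error = function(e) Inf)
  Cinv <- if (!is.finite(kap) || kap > 1e8) pinv(cv$C_OO) else solve(cv$C_OO)
  R_obs <- as.numeric(cv$C_FO %*% Cinv)
  Fc <- F - mean(F)
  Lc <- sweep(O_lag, 2, colMeans(O_lag))
  # all permutations at once: columns of P are permuted centred fire vectors
  perm1 <- make_permuter(n, block)
  P <- vapply(seq_len(n_iter), function(i) Fc[perm1()],
              numeric(n))                       # n x n_iter
  C_FO_null <- crossprod(P, Lc) / (n - 1)        # n_iter x k
  R_null <- C_FO_null %*% Cinv                   # n_iter x k
  exceed <- sweep(abs(R_null), 2, abs(R_obs), `>=`)
  p <- (colSums(exceed) + 1) / (n_iter + 1)
  names(p) <- colnames(O_t)
  list(p_values = p, significant = p < alpha,
       R_obs = stats::setNames(R_obs, colnames(O_t)),
       n_iter = as.integer(n_iter), alpha = alpha)
}

#' Full feedback assessment for one season (or the whole record)
#'
#' The stepwise estimator end to end: pool the fire and forcing samples
#' for the season at lag tau, run the backward-stepwise AIC selection,
#' then assess the retained responses with the Monte-Carlo permutation
#' test. Forcings eliminated by the stepwise search carry NA (absent)
#' responses, not zeros.
#'
#' @param F anomalized, detrended fire [regional_series()].
#' @param O forcing matrix `[months x k]` aligned with `F`.
#' @param season season index 1-12, or NULL for the full record.
#' @param tau lag in months (default 1).
#' @param n_iter permutation count (default 1000).
#' @param alpha significance level (default 0.1).
#' @param stepwise run the backward-stepwise selection first (default
#'   TRUE); otherwise all forcings are kept.
#' @param seed optional seed for the permutation draw.
#' @return object of class `feedback_estimate`: `R` (length-k vector, NA
#'   where not retained), `retained`, `p_values` (NA where not retained),
#'   `significant`, `C_FO`, `C_OO`, `tau`, `season`, `n_samples`,
#'   `n_dropped`, `labels`, `aic_path`.
#' @export
sgefa_fit <- function(F, O, season = NULL, tau = 1L, n_iter = 1000L,
                      alpha = 0.1, stepwise = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  O <- as.matrix(O)
  labels <- colnames(O)
  if (is.null(labels)) labels <- paste0("O", seq_len(ncol(O)))
  ps <- pool_season(F, O, season = season, tau = tau)
  k <- ncol(O)
  if (stepwise) {
    st <- backward_stepwise(ps$F, ps$O_t, ps$O_lag)
  } else {
    st <- list(retained = seq_len(k),
               R = estimate_response(ps$F, ps$O_t, ps$O_lag),
               aic_path = aic_score(ps$F, ps$O_t, ps$O_lag))
  }
  R <- rep(NA_real_, k); p <- rep(NA_real_, k); sig <- rep(FALSE, k)
  cv <- lagged_covariance(ps$F, ps$O_t, ps$O_lag)
  if (length(st$retained)) {
    bt <- bootstrap_significance(ps$F,
                                 ps$O_t[, st$retained, drop = FALSE],
                                 ps$O_lag[, st$retained, drop = FALSE],
                                 n_iter = n_iter, alpha = alpha)
    R[st$retained] <- bt$R_obs
    p[st$retained] <- bt$p_values
    sig[st$retained] <- bt$significant
  }
  structure(list(R = stats::setNames(R, labels),
                 retained = seq_len(k) %in% st$retained,
                 p_values = stats::setNames(p, labels),
                 significant = stats::setNames(sig, labels),
                 C_FO = cv$C_FO, C_OO = cv$C_OO,
                 tau = as.integer(tau), season = season,
                 n_samples = ps$n_pairs, n_dropped = ps$n_dropped,
                 labels = labels, aic_path = st$aic_path,
                 alpha = alpha),
            class = "feedback_estimate")
}

#' @export
print.feedback_estimate <- function(x, ...) {
  sl <- if (is.null(x$season)) "full record" else
    paste0("season ", x$season, " (", season_label(x$season), ")")
  cat(sprintf("<feedback_estimate: %s, tau=%d, n=%d, %d/%d retained, %d significant (p<%.2g)>\n",
              sl, x$tau, x$n_samples, sum(x$retained), length(x$R),
              sum(x$significant), x$alpha))
  if (any(x$retained)) {
    d <- data.frame(forcing = x$labels[x$retained],
                    R = round(x$R[x$retained], 4),
                    p = round(x$p_values[x$retained], 4))
    print(d, row.names = FALSE)
  }
  invisible(x)
}

#' Seasonal cycle of feedback estimates
#'
#' Runs the stepwise estimator plus permutation significance independently
#' for each of the twelve overlapping 3-month seasons. Seasons with fewer
#' pooled samples than `min_samples` are skipped with a message.
#'
#' @inheritParams sgefa_fit
#' @param seasons season indices to assess (default 1:12).
#' @param min_samples minimum pooled samples required per season.
#' @return object of class `feedback_cycle`: a list of
#'   [sgefa_fit()] results indexed by season (NULL where skipped).
#' @export
seasonal_feedback_cycle <- function(F, O, seasons = 1:12, tau = 1L,
                                    n_iter = 1000L, alpha = 0.1,
                                    min_samples = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(min_samples)) min_samples <- ncol(as.matrix(O)) + 3L
  out <- vector("list", 12L)
  for (s in seasons) {
    ps <- pool_season(F, O, season = s, tau = tau)
    if (ps$n_pairs < min_samples) {
      message("season ", s, " skipped: only ", ps$n_pairs,
              " pooled samples (< ", min_samples, ")")
      next
    }
    out[[s]] <- sgefa_fit(F, O, season = s, tau = tau, n_iter = n_iter,
                          alpha = alpha)
  }
  structure(out, class = "feedback_cycle")
}

#' Season of maximum absolute significant response
#'
#' For one forcing, scans a [seasonal_feedback_cycle()] and returns the
#' season (1-12) in which the forcing's significant response has the
#' largest magnitude, together with the signed response. Seasons where the
#' forcing is not retained or not significant are ignored; if no season is
#' significant the season is NA ("none").
#'
#' @param cycle a `feedback_cycle`.
#' @param forcing forcing label or column index.
#' @param alpha significance level (defaults to the cycle's own).
#' @return list with `season` (integer or NA) and `R` (signed value or NA).
#' @export
max_response_season <- function(cycle, forcing, alpha = NULL) {
  best_s <- NA_integer_; best_R <- NA_real_
  for (s in seq_along(cycle)) {
    est <- cycle[[s]]
    if (is.null(est)) next
    j <- if (is.character(forcing)) match(forcing, est$labels) else forcing
    a <- if (is.null(alpha)) est$alpha else alpha
    if (is.na(j) || !est$retained[j]) next
    if (is.na(est$p_values[j]) || est$p_values[j] >= a) next
    if (is.na(best_R) || abs(est$R[j]) > abs(best_R)) {
      best_R <- unname(est$R[j]); best_s <- s
    }
  }
  list(season = best_s, R = best_R)
}

#' Robustness count across dataset combinations
#'
#' Counts, per forcing, how many of several dataset combinations (e.g.
#' alternative LAI / soil-moisture sources, or synthetic replicates) give
#' a significant response. Input is a list of [sgefa_fit()] results with a
#' common forcing layout; the count per forcing lies in
#' [0, number of combinations].
#'
#' @param estimates list of `feedback_estimate` objects.
#' @return named integer vector of counts.
#' @export
robustness_count <- function(estimates) {
  stopifnot(length(estimates) >= 1)
  labels <- estimates[[1]]$labels
  counts <- integer(length(labels))
  for (est in estimates) {
    stopifnot(identical(est$labels, labels))
    counts <- counts + as.integer(est$significant)
  }
  stats::setNames(counts, labels)
}

#' Per-cell response map with significance masking
#'
#' Applies the response estimator and permutation test independently to
#' the fire anomaly series of every grid cell (no stepwise selection: the
#' caller passes an already-reduced forcing set). Cells whose test fails
#' or errors are masked and counted. The returned maps hold the response
#' for one chosen forcing with insignificant cells set to NA.
#'
#' @param fire_field anomalized, detrended fire [gridded_field()].
#' @param O reduced forcing matrix `[months x k]`.
#' @param forcing which forcing's response to map (label or index).
#' @param season season index or NULL.
#' @param tau lag in months.
#' @param n_iter,alpha permutation-test settings.
#' @param seed optional seed.
#' @return list of matrices `R` (masked response), `p`, plus
#'   `n_failed` cells.
#' @export
spatial_response_map <- function(fire_field, O, forcing = 1L, season = NULL,
                                 tau = 1L, n_iter = 500L, alpha = 0.1,
                                 seed = NULL) {
  stopifnot(inherits(fire_field, "gridded_field"))
  if (!is.null(seed)) set.seed(seed)
  O <- as.matrix(O)
  j <- if (is.character(forcing)) match(forcing, colnames(O)) else forcing
  d <- dim(fire_field$values)
  Rmap <- matrix(NA_real_, d[2], d[3])
  pmap <- matrix(NA_real_, d[2], d[3])
  n_failed <- 0L
  for (ii in seq_len(d[2])) for (jj in seq_len(d[3])) {
    v <- fire_field$values[, ii, jj]
    if (all(is.na(v))) next
    s <- regional_series(v, start_year = fire_field$year[1],
                         start_month = fire_field$month[1],
                         anomalized = TRUE, detrended = TRUE)
    res <- tryCatch({
      ps <- pool_season(s, O, season = season, tau = tau)
      bootstrap_significance(ps$F, ps$O_t, ps$O_lag, n_iter = n_iter,
                             alpha = alpha)
    }, error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    pmap[ii, jj] <- res$p_values[j]
    if (res$p_values[j] < alpha) Rmap[ii, jj] <- res$R_obs[j]
  }
  list(R = Rmap, p = pmap, n_failed = n_failed,
       lat = fire_field$lat, lon = fire_field$lon)
}
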