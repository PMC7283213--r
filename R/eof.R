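#' Empirical orthogonal function decomposition of a gridded anomaly field
#'
#' Area-true EOF analysis: the time x space data matrix is weighted by
#' sqrt(cos(latitude)) per cell and decomposed by SVD. Spatial patterns are
#' orthonormal under the area weights, principal-component time series are
#' mutually uncorrelated, and explained-variance fractions are the
#' normalized squared singular values (non-increasing). Cells that are
#' missing at any time are excluded consistently across the whole record.
#'
#' @param field an anomalized, detrended [gridded_field()].
#' @param k number of modes to retain.
#' @param basin_name label carried into the result.
#' @return object of class `eof_result` with `patterns` (array
#'   `[k, lat, lon]`, NA outside valid cells), `pcs` (matrix
#'   `[time x k]`), `explained` (fractions), `weights`, `valid_mask`,
#'   `lat`, `lon`, `basin`.
#' @export
compute_eof <- function(field, k = 2L, basin_name = "basin") {
  stopifnot(inherits(field, "gridded_field"))
  d <- dim(field$values)
  n <- d[1]
  X <- matrix(field$values, nrow = n)   # time x (lat*lon), lat fastest
  valid <- !apply(is.na(X), 2, any)
  if (!any(valid)) stop("no valid cells for EOF analysis", call. = FALSE)
  w <- rep(cos(field$lat * pi / 180), times = d[3])
  Xv <- X[, valid, drop = FALSE]
  Xv <- sweep(Xv, 2, colMeans(Xv))      # centre in time
  Xw <- sweep(Xv, 2, sqrt(w[valid]), `*`)
  sv <- svd(Xw)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (k > rank)
    stop("requested ", k, " modes but field rank is only ", rank,
         call. = FALSE)
  expl <- sv$d^2 / sum(sv$d^2)
  pats <- array(NA_real_, c(k, d[2], d[3]))
  for (m in seq_len(k)) {
    pm <- rep(NA_real_, d[2] * d[3])
    # v is orthonormal in weighted coordinates; dividing by sqrt(w) gives
    # native-units patterns orthonormal under the area weights
    pm[valid] <- sv$v[, m] / sqrt(w[valid])
    pats[m, , ] <- pm
  }
  pcs <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  colnames(pcs) <- paste0("PC", seq_len(k))
  structure(list(patterns = pats, pcs = pcs,
                 explained = expl[seq_len(k)], all_explained = expl,
                 weights = w, valid_mask = valid,
                 lat = field$lat, lon = field$lon,
                 year = field$year, month = field$month,
                 basin = basin_name),
            class = "eof_result")
}

#' @export
print.eof_result <- function(x, ...) {
  cat(sprintf("<eof_result '%s': %d modes, explained %s>\n", x$basin,
              ncol(x$pcs),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' Reconstruct the centred field from an EOF truncation
#'
#' @param eof an [compute_eof()] result.
#' @param modes which modes to use (default: all retained).
#' @return matrix `[time x valid cells]` in the field's native units
#'   (time-centred); with all non-degenerate modes this reproduces the
#'   centred input field.
#' @export
eof_reconstruct <- function(eof, modes = seq_len(ncol(eof$pcs))) {
  V <- vapply(modes, function(m) {
    as.vector(eof$patterns[m, , ])[eof$valid_mask]
  }, numeric(sum(eof$valid_mask)))
  eof$pcs[, modes, drop = FALSE] %*% t(V)
}

#' Standardize a principal component into a unit-variance forcing
#'
#' Divides the PC by its sample standard deviation and records that
#' standard deviation (`sigma_forcing`, in the field's native units) so
#' responses expressed per forcing standard deviation can be converted
#' back. Sign convention: the area-weighted spatial mean of the pattern is
#' made non-negative, flipping pattern and PC together (which leaves every
#' reconstruction invariant).
#'
#' @param eof an `eof_result`.
#' @param mode mode number.
#' @param label forcing label (default `"<basin>-PC<mode>"`).
#' @return object of class `standardized_forcing` with `values`
#'   (unit-sample-variance series), `sigma_forcing`, `label`, `pattern`.
#' @export
standardize_forcing <- function(eof, mode = 1L,
                                label = paste0(eof$basin, "-PC", mode)) {
  pc <- eof$pcs[, mode]
  sdev <- stats::sd(pc)
  if (!is.finite(sdev) || sdev <= 0)
    stop("mode ", mode, " has zero variance; cannot standardize",
         call. = FALSE)
  pat <- eof$patterns[mode, , ]
  wmean <- sum(eof$weights[eof$valid_mask] *
                 as.vector(pat)[eof$valid_mask])
  if (wmean < 0) {
    pat <- -pat
    pc <- -pc
  }
  structure(list(values = pc / sdev,
                 sigma_forcing = sdev, label = label, pattern = pat,
                 mode = mode, basin = eof$basin),
            class = "standardized_forcing")
}

#' Assemble the 18-column forcing matrix from a synthetic bundle
#'
#' The oceanic columns are the standardized leading-two PC series from the
#' EOF decomposition of each basin's anomalized, detrended SST field; the
#' terrestrial columns are the standardized anomalized, detrended regional
#' LAI and surface soil-moisture series. Column order matches
#' [synth_config()]'s forcing labels.
#'
#' @param bundle a `synth_bundle` (or any list with `sst`, `lai`, `sm`).
#' @param standardized divide each column by its sample standard deviation
#'   (default TRUE); the divisors are kept in attribute `"sigma_forcing"`.
#' @return matrix `[months x 18]` with labelled columns.
#' @export
build_forcing_matrix <- function(bundle, standardized = TRUE) {
  cols <- list(); sig <- numeric(0)
  for (nm in names(bundle$sst)) {
    fld <- detrend_linear(monthly_anomalies(bundle$sst[[nm]]))
    eof <- compute_eof(fld, k = 2L, basin_name = nm)
    for (m in 1:2) {
      sf <- standardize_forcing(eof, m)
      cols[[sf$label]] <- if (standardized) sf$values else
        sf$values * sf$sigma_forcing
      sig[sf$label] <- sf$sigma_forcing
    }
  }
  for (nm in c("lai", "sm")) {
    s <- detrend_linear(monthly_anomalies(bundle[[nm]]))
    sdev <- stats::sd(s$values, na.rm = TRUE)
    lbl <- toupper(nm)
    cols[[lbl]] <- if (standardized) s$values / sdev else s$values
    sig[lbl] <- sdev
  }
  O <- do.call(cbind, cols)
  attr(O, "sigma_forcing") <- sig
  O
}
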