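#' Demean and linearly detrend a series
#'
#' Removes, per voxel, the least-squares linear trend (including the mean)
#' over all volumes.
#'
#' @param series A `volume_series`.
#' @return The detrended `volume_series`.
#' @export
detrend_series <- function(series) {
  X <- .ts_matrix(series)
  nt <- nrow(X)
  tc <- seq_len(nt) - (nt + 1) / 2          # centred time, orthogonal to 1
  slope <- crossprod(tc, X)[1, ] / sum(tc^2)
  X <- sweep(X, 2, colMeans(X)) - outer(tc, slope)
  .from_ts_matrix(X, series)
}

#' Nuisance regression with 16 confound regressors
#'
#' Builds the standard confound matrix — white-matter mean, CSF mean, the
#' six motion parameters, and the backward temporal derivative of each of
#' those eight — z-scores every regressor using the mean and SD of the
#' clean (non-flagged) volumes only, estimates the regression on the clean
#' volumes, and subtracts the fitted confounds from all volumes. The
#' series should already be demeaned/detrended ([detrend_series()]).
#'
#' @param series A detrended `volume_series`.
#' @param motion Motion matrix (one row per volume, 6 columns).
#' @param tissue Tissue label array (1 GM, 2 WM, 3 CSF).
#' @param qc A `qc_mask`; clean volumes are `!qc$flag`.
#' @return The residual `volume_series`, with the design matrix attached
#'   as attribute `nuisance_design`.
#' @export
nuisance_regression <- function(series, motion, tissue, qc) {
  X <- .ts_matrix(series)
  nt <- nrow(X)
  if (nrow(motion) != nt) stop("motion trace length mismatch")
  tiss <- as.integer(tissue)
  wm <- rowMeans(X[, tiss == 2L, drop = FALSE])
  csf <- rowMeans(X[, tiss == 3L, drop = FALSE])
  base <- cbind(wm, csf, motion)
  D <- cbind(base, rbind(0, diff(base)))
  colnames(D) <- c("wm", "csf", paste0("mot", 1:6),
                   paste0("d_", c("wm", "csf", paste0("mot", 1:6))))
  clean <- !qc$flag
  if (sum(clean) <= ncol(D))
    stop("too few clean volumes for nuisance regression")
  mu <- colMeans(D[clean, , drop = FALSE])
  sdv <- apply(D[clean, , drop = FALSE], 2, stats::sd)
  if (any(sdv == 0)) stop("constant nuisance regressor: ",
                          paste(colnames(D)[sdv == 0], collapse = ", "))
  Dz <- sweep(sweep(D, 2, mu), 2, sdv, "/")
  qrD <- qr(Dz[clean, , drop = FALSE])
  if (qrD$rank < ncol(Dz)) {
    bad <- colnames(Dz)[qrD$pivot[(qrD$rank + 1):ncol(Dz)]]
    stop("rank-deficient nuisance design; collinear regressors: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrD, X[clean, , drop = FALSE])
  res <- .from_ts_matrix(X - Dz %*% beta, series)
  attr(res, "nuisance_design") <- Dz
  res
}

# Butterworth band-pass coefficients for a series sampled every `tr` s
.bp_coef <- function(tr, low, high, order = 2) {
  nyq <- 1 / (2 * tr)
  if (low <= 0 || high >= nyq || low >= high)
    stop("band edges must satisfy 0 < low < high < Nyquist (", round(nyq, 4), " Hz)")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  list(b = bf$b, a = bf$a)
}

# Zero-phase (forward-backward) filtering with odd-reflection padding,
# applied to every column time series of a time x voxel matrix
.filtfilt_mat <- function(b, a, X, padlen = NULL) {
  n <- nrow(X)
  # padding long enough for the slow low-cut pole to settle, so DC and
  # start-up transients stay below ~1e-3 of the input scale
  if (is.null(padlen)) padlen <- min(n - 1, 150)
  .filtfilt_cols(X, as.numeric(b), as.numeric(a), as.integer(padlen))
}

#' Band-pass filter a series
#'
#' Applies a second-order Butterworth band-pass (default 0.009-0.08 Hz)
#' to every voxel time course. The filter is run forward and backward
#' (zero phase), which squares the magnitude response; edge transients are
#' suppressed by odd-reflection padding.
#'
#' @param series A `volume_series`.
#' @param low,high Band edges in Hz.
#' @param order Butterworth order of a single pass.
#' @return The filtered `volume_series`.
#' @export
bandpass <- function(series, low = 0.009, high = 0.08, order = 2) {
  co <- .bp_coef(series$tr, low, high, order)
  .from_ts_matrix(.filtfilt_mat(co$b, co$a, .ts_matrix(series)), series)
}

#' Squared magnitude response of the zero-phase band-pass
#'
#' Amplitude gain applied to a sinusoid of frequency `f` by the
#' forward-backward Butterworth filter of [bandpass()] (i.e. `|H(f)|^2`
#' of the single-pass filter).
#'
#' @param f Frequencies in Hz.
#' @param tr Sampling interval in seconds.
#' @inheritParams bandpass
#' @return Amplitude gain(s) in `[0, 1]`.
#' @export
bandpass_gain <- function(f, tr, low = 0.009, high = 0.08, order = 2) {
  co <- .bp_coef(tr, low, high, order)
  w <- 2 * pi * f * tr
  H <- vapply(w, function(wi) {
    z <- exp(-1i * wi * (seq_along(co$b) - 1))
    Mod(sum(co$b * z) / sum(co$a * z))
  }, numeric(1))
  H^2
}

# 1D Gaussian kernel, truncated at 4 sigma
.gauss_kernel <- function(sigma_vox) {
  half <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-(-half:half)^2 / (2 * sigma_vox^2))
  list(w = w / sum(w), half = half)
}

#' Gaussian spatial smoothing
#'
#' Smooths every volume with an isotropic Gaussian kernel of the given
#' full width at half maximum, applied separably along the three axes
#' (sigma = FWHM / (2 sqrt(2 ln 2)) converted to voxel units). Kernel
#' rows are renormalised at the volume borders, so a constant image is
#' unchanged.
#'
#' @param series A `volume_series`.
#' @param fwhm_mm Kernel FWHM in mm (default 8).
#' @return The smoothed `volume_series`.
#' @export
smooth_series <- function(series, fwhm_mm = 8) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / series$voxel_mm
  if (sigma <= 0) return(series)
  k <- .gauss_kernel(sigma)
  d <- dim(series$data)
  A <- series$data
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:4, ax))
    Ap <- aperm(A, perm)
    dp <- dim(Ap)
    Ap <- array(.conv_axis(matrix(Ap, dp[1]), k$w, k$half), dp)
    A <- aperm(Ap, order(perm))
  }
  series$data <- A
  series
}

#' Run the full per-session preprocessing chain
#'
#' Fixed order: demean/detrend, nuisance regression (16 regressors),
#' Butterworth band-pass, Gaussian smoothing. Noisy volumes are never
#' removed from the series here; the flags are applied later, when the
#' metrics are estimated.
#'
#' @param series A `volume_series` (initial volumes already dropped).
#' @param motion Matching motion matrix.
#' @param tissue Tissue label array.
#' @param qc A `qc_mask` computed on the pre-regression data.
#' @param low,high Band edges in Hz.
#' @param fwhm_mm Smoothing kernel FWHM in mm.
#' @return The preprocessed `volume_series`.
#' @export
preprocess_session <- function(series, motion, tissue, qc,
                               low = 0.009, high = 0.08, fwhm_mm = 8) {
  series <- detrend_series(series)
  series <- nuisance_regression(series, motion, tissue, qc)
  series <- bandpass(series, low = low, high = high)
  smooth_series(series, fwhm_mm = fwhm_mm)
}
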