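# internal: flatten a volume_series to a time x voxel matrix
.ts_matrix <- function(series) {
  d <- dim(series$data)
  t(array(series$data, c(prod(d[1:3]), d[4])))
}

.from_ts_matrix <- function(X, series) {
  d <- dim(series$data)
  series$data <- array(t(X), d)
  series
}

#' Framewise displacement
#'
#' Power-convention framewise displacement: the sum of absolute
#' backward differences of the three translations (mm) plus the three
#' rotations (rad) converted to arc length on a 50 mm sphere. The first
#' volume has FD 0.
#'
#' @param motion Matrix with one row per volume: 3 translations (mm) then
#'   3 rotations (rad).
#' @param rotation_radius_mm Radius for the rotation-to-displacement
#'   conversion (default 50 mm).
#' @return Numeric vector of FD values (mm), one per volume.
#' @export
framewise_displacement <- function(motion, rotation_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("'motion' must have 6 columns")
  if (nrow(motion) < 2) stop("need at least 2 volumes")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' DVARS and spatial SD over a grey-matter mask
#'
#' DVARS(t) is the root mean square, over grey-matter voxels, of the
#' backward temporal difference of the series (0 at the first volume);
#' SD(t) is the spatial standard deviation over the same mask at volume t.
#'
#' @param series A `volume_series`.
#' @param gm_mask Logical or 0/1 3D array selecting grey-matter voxels.
#' @return A data.frame with columns `dvars` and `sd`, one row per volume.
#' @export
dvars_and_sd <- function(series, gm_mask) {
  mask <- as.logical(gm_mask)
  if (!any(mask)) stop("empty grey-matter mask")
  X <- .ts_matrix(series)[, mask, drop = FALSE]
  dv <- c(0, sqrt(rowMeans(diff(X)^2)))
  mu <- rowMeans(X)
  sdv <- sqrt(pmax(rowSums(X^2) - ncol(X) * mu^2, 0) / (ncol(X) - 1))
  data.frame(dvars = dv, sd = sdv)
}

#' Flag noisy volumes
#'
#' A volume is tagged noisy when framewise displacement exceeds `fd_max`
#' (default 0.3 mm, a conservative cutoff), or DVARS or spatial SD exceeds
#' its own adaptive cutoff of 75th percentile + 1.5 x inter-quartile range
#' (quantiles by linear interpolation; strict inequality at every cutoff).
#'
#' @param fd,dvars,sd Equal-length per-volume metric vectors.
#' @param fd_max FD cutoff in mm.
#' @return An object of class `qc_mask`: list with logical `flag`, the
#'   three metric vectors, the two adaptive cutoffs, and `flagged_fraction`.
#' @export
flag_noisy_volumes <- function(fd, dvars, sd, fd_max = 0.3) {
  n <- length(fd)
  if (length(dvars) != n || length(sd) != n)
    stop("metric vectors must have equal length")
  tukey_cut <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    q[2] + 1.5 * (q[2] - q[1])
  }
  cut_dv <- tukey_cut(dvars); cut_sd <- tukey_cut(sd)
  flag <- (fd > fd_max) | (dvars > cut_dv) | (sd > cut_sd)
  structure(
    list(flag = flag, fd = fd, dvars = dvars, sd = sd,
         fd_max = fd_max, dvars_cut = cut_dv, sd_cut = cut_sd,
         flagged_fraction = mean(flag)),
    class = "qc_mask"
  )
}

#' @export
print.qc_mask <- function(x, ...) {
  cat(sprintf("qc_mask: %d/%d volumes flagged (%.1f%%)\n",
              sum(x$flag), length(x$flag), 100 * x$flagged_fraction))
  invisible(x)
}

#' Subject-level motion exclusion
#'
#' A session is excluded when strictly more than `max_fraction` of its
#' volumes are tagged noisy.
#'
#' @param qc A `qc_mask`.
#' @param max_fraction Exclusion threshold (default 0.35).
#' @return `TRUE` to keep, `FALSE` to exclude.
#' @export
exclusion_check <- function(qc, max_fraction = 0.35) {
  qc$flagged_fraction <= max_fraction
}

#' Run the volume-level quality control of one session
#'
#' Convenience wrapper computing FD from the motion trace, DVARS and
#' spatial SD over grey matter, and the combined noisy-volume flags.
#'
#' @param series A `volume_series` (after initial-volume dropping).
#' @param motion Matching motion matrix.
#' @param gm_mask Logical 3D grey-matter mask.
#' @param fd_max FD cutoff in mm.
#' @return A `qc_mask`.
#' @export
compute_qc <- function(series, motion, gm_mask, fd_max = 0.3) {
  if (nrow(motion) != dim(series$data)[4])
    stop("motion trace and series have different volume counts")
  fd <- framewise_displacement(motion)
  ds <- dvars_and_sd(series, gm_mask)
  flag_noisy_volumes(fd, ds$dvars, ds$sd, fd_max = fd_max)
}
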