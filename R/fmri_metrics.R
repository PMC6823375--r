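#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Per-voxel sample variance of the band-passed series over the clean
#' (non-flagged) volumes. The log transform commonly used for group
#' statistics is left to the caller.
#'
#' @param series A band-passed `volume_series`.
#' @param qc A `qc_mask`, or `NULL` to use every volume.
#' @return A 3D array of variances.
#' @export
alff <- function(series, qc = NULL) {
  X <- .ts_matrix(series)
  if (!is.null(qc)) X <- X[!qc$flag, , drop = FALSE]
  if (nrow(X) < 10) stop("fewer than 10 clean volumes")
  mu <- colMeans(X)
  v <- (colSums(X^2) - nrow(X) * mu^2) / (nrow(X) - 1)
  array(pmax(v, 0), dim(series$data)[1:3])
}

#' Regional homogeneity (Kendall's W)
#'
#' For each voxel, Kendall's coefficient of concordance between the
#' rank-ordered clean-volume time courses of the voxel and its 3x3x3
#' neighbourhood (neighbourhoods shrink at the volume borders). With m
#' voxels ranked over n time points,
#' \deqn{W = 12 \sum_t (R_t - m(n+1)/2)^2 / (m^2 (n^3 - n) - m \sum_j T_j)}
#' where R_t is the summed rank at time t and T_j the usual tie
#' correction of voxel j's ranking. W is 1 for m identical time courses
#' and has expectation 1/m for independent ones. Voxels whose own time
#' course is constant are returned as `NA`.
#'
#' @param series A preprocessed `volume_series`.
#' @param qc A `qc_mask`, or `NULL`.
#' @param mask Optional logical 3D array restricting the output (ranks are
#'   still computed everywhere so border neighbourhoods stay honest).
#' @return A 3D array of W values in `[0, 1]` (`NA` where degenerate).
#' @export
reho <- function(series, qc = NULL, mask = NULL) {
  X <- .ts_matrix(series)
  if (!is.null(qc)) X <- X[!qc$flag, , drop = FALSE]
  n <- nrow(X)
  if (n < 10) stop("fewer than 10 clean volumes")
  d <- dim(series$data)[1:3]
  const <- apply(X, 2, function(v) max(v) == min(v))
  R <- apply(X, 2, rank)  # ties: average rank
  # per-voxel tie correction sum(t^3 - t) over tied groups
  Tj <- apply(R, 2, function(r) {
    tt <- tabulate(match(r, unique(r)))
    sum(tt^3 - tt)
  })

  # neighbourhood rank sums via 27 shifted additions
  Rarr <- array(t(R), c(d, n))
  S <- array(0, c(d, n))   # sum over neighbourhood of ranks, per time
  M <- array(0, d)         # neighbourhood size per voxel
  Tsum <- array(0, d)      # neighbourhood tie-correction sum
  Tarr <- array(Tj, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    S[xs, ys, zs, ] <- S[xs, ys, zs, , drop = FALSE] +
      Rarr[xs - dx, ys - dy, zs - dz, , drop = FALSE]
    M[xs, ys, zs] <- M[xs, ys, zs] + 1
    Tsum[xs, ys, zs] <- Tsum[xs, ys, zs] + Tarr[xs - dx, ys - dy, zs - dz]
  }
  Smat <- array(S, c(prod(d), n))
  m <- as.numeric(M)
  dev2 <- rowSums((Smat - m * (n + 1) / 2)^2)
  W <- 12 * dev2 / (m^2 * (n^3 - n) - m * as.numeric(Tsum))
  W[const] <- NA_real_
  array(pmin(W, 1), d)
}

#' Seed-based functional connectivity map
#'
#' Correlates the mean clean-volume time course of a seed region with
#' every voxel's clean-volume time course (Pearson), and Fisher
#' z-transforms the result, clipping |r| at 1 - 1e-7 so the map stays
#' finite. Zero-variance voxels get z = 0 and are counted in the
#' `n_degenerate` attribute.
#'
#' @param series A preprocessed `volume_series`.
#' @param roi Region label array.
#' @param seed_id Label value of the seed region.
#' @param qc A `qc_mask`, or `NULL`.
#' @return A 3D array of Fisher z values with attribute `n_degenerate`.
#' @export
seed_fc <- function(series, roi, seed_id, qc = NULL) {
  sel <- as.integer(roi) == seed_id
  if (!any(sel)) stop("seed region ", seed_id, " is empty")
  X <- .ts_matrix(series)
  if (!is.null(qc)) X <- X[!qc$flag, , drop = FALSE]
  s <- rowMeans(X[, sel, drop = FALSE])
  sc <- s - mean(s)
  Xc <- sweep(X, 2, colMeans(X))
  num <- as.numeric(crossprod(sc, Xc))
  den <- sqrt(sum(sc^2)) * sqrt(colSums(Xc^2))
  bad <- den == 0
  r <- numeric(ncol(X))
  r[!bad] <- num[!bad] / den[!bad]
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  z[bad] <- 0
  out <- array(z, dim(series$data)[1:3])
  attr(out, "n_degenerate") <- sum(bad)
  out
}
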