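#' Time-by-Stimulation paired contrast
#'
#' The crossover interaction of a pre/post x real/sham design, reduced to
#' its paired form: for each subject compute the post-minus-pre change
#' under each stimulation, then compare the two changes with a paired t
#' test on `d = delta_real - delta_sham`. Inputs may be per-subject
#' scalars (ROI summaries) or per-subject maps (matrix with one row per
#' subject), in which case the test is run voxelwise.
#'
#' @param delta_real,delta_sham Numeric vectors (one value per subject) or
#'   matrices (subjects x voxels) of post-minus-pre changes.
#' @return A list with `t`, `p` (two-sided), `df`, `mean_d`, and the
#'   difference matrix `d`.
#' @export
condition_contrast <- function(delta_real, delta_sham) {
  d <- as.matrix(delta_real) - as.matrix(delta_sham)
  if (any(!is.finite(d))) stop("missing cells in the paired design")
  n <- nrow(d)
  if (n < 2) stop("need at least 2 subjects")
  mu <- colMeans(d)
  se <- sqrt(pmax(colSums(d^2) - n * mu^2, 0) / (n - 1) / n)
  tt <- ifelse(se > 0, mu / se, 0)  # identical deltas: no evidence, t = 0
  out <- list(t = tt, p = 2 * stats::pt(-abs(tt), df = n - 1),
              df = n - 1, mean_d = mu, d = d)
  if (length(tt) == 1) {
    out$t <- as.numeric(tt); out$p <- as.numeric(out$p)
    out$mean_d <- as.numeric(mu)
  }
  out
}

#' Connected components of a logical 3D mask (26-connectivity)
#'
#' @param mask Logical 3D array.
#' @return Integer 3D array of cluster labels (0 = background), with
#'   attribute `sizes` (voxel count per label).
#' @export
label_clusters <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (!length(idx)) { attr(lab, "sizes") <- integer(0); return(lab) }
  coord <- arrayInd(idx, d)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  pos <- integer(prod(d)); pos[idx] <- seq_along(idx)  # voxel -> node id
  lab_v <- integer(length(idx))
  cur <- 0L
  for (i in seq_along(idx)) {
    if (lab_v[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    lab_v[i] <- cur
    while (length(queue)) {
      j <- queue[length(queue)]; queue <- queue[-length(queue)]
      nb <- sweep(off, 2, coord[j, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nid <- pos[(nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]]
      nid <- nid[nid > 0L]
      new <- nid[lab_v[nid] == 0L]
      lab_v[new] <- cur
      queue <- c(queue, new)
    }
  }
  lab[idx] <- lab_v
  attr(lab, "sizes") <- tabulate(lab_v, cur)
  lab
}

# max cluster extent of |t| (or signed t) maps above threshold, in mask
.max_extent <- function(tvec, t_crit, dim3, mask_vec) {
  supra <- array(abs(tvec) > t_crit & mask_vec, dim3)
  sz <- attr(label_clusters(supra), "sizes")
  if (length(sz)) max(sz) else 0L
}

#' Cluster-extent inference by sign-flip permutation
#'
#' Family-wise-error-corrected cluster inference for the paired contrast:
#' voxels with `|t|` above the two-sided cluster-forming threshold (df
#' from the number of subjects) are grouped by 26-connectivity within the
#' inclusion mask; the null distribution of the maximum cluster extent is
#' built by randomly sign-flipping each subject's difference map (exact
#' under exchangeability of real/sham labels within subject); and each
#' observed cluster's corrected p is its extent's position in that null.
#'
#' @param d Subjects x voxels matrix of paired differences
#'   (`delta_real - delta_sham`), e.g. `condition_contrast(...)$d`.
#' @param dim3 Spatial dimensions of the maps.
#' @param mask Logical 3D inclusion mask (e.g. positive baseline
#'   connectivity); `NULL` for all voxels.
#' @param cluster_forming_p Two-sided voxel-level threshold (default 0.01).
#' @param n_perm Number of sign-flip permutations (>= 100).
#' @param seed Integer seed.
#' @return An object of class `cluster_result`: data.frame `clusters`
#'   (label, extent, peak t, corrected p), the `t` map, the label array,
#'   threshold, and null distribution.
#' @export
cluster_inference <- function(d, dim3, mask = NULL,
                              cluster_forming_p = 0.01,
                              n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("'n_perm' must be at least 100")
  d <- as.matrix(d)
  n <- nrow(d)
  df <- n - 1
  t_crit <- stats::qt(1 - cluster_forming_p / 2, df)
  mask_vec <- if (is.null(mask)) rep(TRUE, ncol(d)) else as.logical(mask)

  ss <- colSums(d^2)
  t_of <- function(mu) {
    se <- sqrt(pmax(ss - n * mu^2, 0) / df / n)
    ifelse(se > 0, mu / se, 0)
  }
  t_obs <- t_of(colMeans(d))

  supra <- array(abs(t_obs) > t_crit & mask_vec, dim3)
  lab <- label_clusters(supra)
  sizes <- attr(lab, "sizes")

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  Sg <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  Mu <- (Sg %*% d) / n
  null_max <- vapply(seq_len(n_perm), function(i)
    .max_extent(t_of(Mu[i, ]), t_crit, dim3, mask_vec), integer(1))

  clusters <- if (length(sizes)) {
    data.frame(
      label = seq_along(sizes),
      extent = sizes,
      peak_t = vapply(seq_along(sizes), function(k)
        t_obs[which(lab == k)][which.max(abs(t_obs[which(lab == k)]))],
        numeric(1)),
      p_corrected = vapply(sizes, function(sz)
        (1 + sum(null_max >= sz)) / (n_perm + 1), numeric(1))
    )
  } else {
    data.frame(label = integer(0), extent = integer(0),
               peak_t = numeric(0), p_corrected = numeric(0))
  }
  structure(
    list(clusters = clusters[order(-clusters$extent), , drop = FALSE],
         t_map = array(t_obs, dim3), labels = lab, t_crit = t_crit,
         df = df, null_max_extent = null_max),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: |t| > %.2f (df=%d), %d cluster(s)\n",
              x$t_crit, x$df, nrow(x$clusters)))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Baseline positive-connectivity inclusion mask
#'
#' One-sample t test of the subjects' baseline (pre-session average) FC
#' maps against zero; the mask keeps voxels with significantly positive
#' group-mean connectivity.
#'
#' @param baseline_maps Subjects x voxels matrix of baseline Fisher z maps.
#' @param dim3 Spatial dimensions.
#' @param p Voxel-level one-sided significance threshold (default 0.05).
#' @return A logical 3D array.
#' @export
baseline_fc_mask <- function(baseline_maps, dim3, p = 0.05) {
  B <- as.matrix(baseline_maps)
  n <- nrow(B)
  mu <- colMeans(B)
  se <- sqrt((colSums(B^2) - n * mu^2) / (n - 1) / n)
  tt <- ifelse(se > 0, mu / se, 0)
  array(tt > stats::qt(1 - p, n - 1), dim3)
}
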