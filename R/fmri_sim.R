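#' Specify a synthetic resting-state scanning session
#'
#' Describes the generative model for a small-grid 4D resting-state scan:
#' per-voxel AR(1) noise, a band-limited low-frequency component, shared
#' latent signals linking a seed region to a distant cluster, tissue
#' confounds (white matter / CSF), and motion with scheduled spikes that
#' also perturb global intensity (so displacement and intensity-based
#' quality metrics flag the same volumes). Two effects can be planted,
#' both applied only to the post-stimulation scan of the real condition:
#' a multiplicative increase of the right-seed signal variance (a local
#' activity effect) and an increment of the cluster's loading on the
#' latent shared with the right seed (a connectivity effect).
#'
#' The grid is deliberately small and in native space: the pipeline under
#' test starts after registration, so regions are delivered directly as
#' label volumes.
#'
#' @param dim Grid dimensions in voxels, default `c(16, 16, 12)`.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param tr Repetition time in seconds.
#' @param n_volumes Volumes acquired; the first `n_drop` are discarded
#'   downstream for signal stabilisation.
#' @param n_drop Initial volumes to discard.
#' @param ar1 AR(1) coefficient of the voxel noise, in `[0, 0.9]`.
#' @param noise_sd Innovation SD of the voxel noise.
#' @param lowfreq_amp Amplitude of each voxel's random-phase low-frequency
#'   sinusoid (frequency drawn in 0.01-0.06 Hz).
#' @param latent_seed_weight Loading of seed voxels on the shared latent.
#' @param latent_cluster_weight Baseline loading of cluster voxels on the
#'   latent shared with the right seed (gives positive baseline
#'   connectivity, as the inclusion-mask step assumes).
#' @param confound_weight Weight of the CSF confound leaked into grey
#'   matter (what nuisance regression must remove).
#' @param walk_sd Per-volume SD of the motion random walk (mm for
#'   translations; rotations use `walk_sd / 50` rad).
#' @param n_spikes Number of scheduled motion spikes per session.
#' @param spike_mm Spike magnitude range (mm), each spike drawn uniformly.
#' @param spike_gain Global intensity deviation per mm of spike.
#' @param alff_multiplier Planted variance multiplier in the right seed
#'   (real-post only); 1 = no effect.
#' @param fc_increment Planted addition to the cluster latent loading
#'   (real-post only); 0 = no effect.
#' @param seed Master integer seed.
#' @return An object of class `scan_spec`.
#' @export
scan_spec <- function(dim = c(16, 16, 12), voxel_mm = 3, tr = 2.4,
                      n_volumes = 250, n_drop = 5,
                      ar1 = 0.3, noise_sd = 1, lowfreq_amp = 1,
                      latent_seed_weight = 0.8,
                      latent_cluster_weight = 0.4,
                      confound_weight = 0.3,
                      walk_sd = 0.015, n_spikes = 4,
                      spike_mm = c(0.4, 1.0), spike_gain = 3,
                      alff_multiplier = 1.5, fc_increment = 0.4,
                      seed = 1L) {
  stopifnot(length(dim) == 3, all(dim >= 8), tr > 0, n_volumes > n_drop + 10)
  if (ar1 < 0 || ar1 > 0.9) stop("'ar1' must lie in [0, 0.9]")
  if (alff_multiplier <= 0) stop("'alff_multiplier' must be positive")
  if (min(spike_mm) <= 0.3)
    stop("spike magnitudes must exceed 0.3 mm so spikes are flaggable")
  structure(
    list(dim = as.integer(dim), voxel_mm = voxel_mm, tr = tr,
         n_volumes = as.integer(n_volumes), n_drop = as.integer(n_drop),
         ar1 = ar1, noise_sd = noise_sd, lowfreq_amp = lowfreq_amp,
         latent_seed_weight = latent_seed_weight,
         latent_cluster_weight = latent_cluster_weight,
         confound_weight = confound_weight,
         walk_sd = walk_sd, n_spikes = as.integer(n_spikes),
         spike_mm = spike_mm, spike_gain = spike_gain,
         alff_multiplier = alff_multiplier, fc_increment = fc_increment,
         seed = as.integer(seed)),
    class = "scan_spec"
  )
}

#' Tissue and region label volumes for the synthetic grid
#'
#' Builds disjoint label volumes: a tissue volume (0 background, 1 grey
#' matter, 2 white matter, 3 CSF) as nested ellipsoids, and a region
#' volume (0 none, 1 left seed, 2 right seed, 3 distant cluster) with two
#' mirrored 3x3x3 seed blocks and a 60-voxel distant cluster block, all
#' inside grey matter.
#'
#' @param dim Grid dimensions (same convention as [scan_spec()]).
#' @return List with 3D integer arrays `tissue` and `roi`.
#' @export
generate_labels <- function(dim = c(16, 16, 12)) {
  cx <- (dim + 1) / 2
  g <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]), z = seq_len(dim[3]))
  ell <- function(rx, ry, rz)
    ((g$x - cx[1]) / rx)^2 + ((g$y - cx[2]) / ry)^2 + ((g$z - cx[3]) / rz)^2 <= 1
  brain <- ell(0.42 * dim[1], 0.42 * dim[2], 0.41 * dim[3])
  wm <- ell(0.17 * dim[1], 0.17 * dim[2], 0.17 * dim[3])
  csf <- ell(0.09 * dim[1], 0.09 * dim[2], 0.11 * dim[3])
  tissue <- integer(nrow(g))
  tissue[brain] <- 1L
  tissue[wm] <- 2L
  tissue[csf] <- 3L
  tissue <- array(tissue, dim)

  # regions = the nearest-n grey-matter voxels around a target point, so
  # each region keeps its full size on any grid
  gm_idx <- which(tissue == 1L)
  nearest_gm <- function(target, n) {
    dd <- (g$x[gm_idx] - target[1])^2 + (g$y[gm_idx] - target[2])^2 +
      (g$z[gm_idx] - target[3])^2
    gm_idx[order(dd)[seq_len(n)]]
  }
  roi <- array(0L, dim)
  roi[nearest_gm(c(0.28, 0.56, 0.70) * dim, 27)] <- 1L
  roi[nearest_gm(c(0.72, 0.56, 0.70) * dim, 27)] <- 2L
  roi[nearest_gm(c(0.46, 0.26, 0.45) * dim, 60)] <- 3L
  list(tissue = tissue, roi = roi)
}

# band-limited unit-variance latent: sum of sinusoids at random in-band
# frequencies and phases
.lowfreq_latent <- function(tt, tr, n_comp = 6, f_range = c(0.015, 0.06)) {
  f <- stats::runif(n_comp, f_range[1], f_range[2])
  ph <- stats::runif(n_comp, 0, 2 * pi)
  u <- rowSums(sin(outer(tt * tr, 2 * pi * f) +
                     matrix(ph, length(tt), n_comp, byrow = TRUE)))
  as.numeric(scale(u))
}

.session_seed <- function(master, subject, condition, phase) {
  code <- (subject - 1) * 4 + 2 * (condition == "real") + (phase == "post")
  as.integer((as.double(master) + 15485863 * code) %% 2147483647)
}

#' Generate the motion trace of one session
#'
#' Six-parameter motion (3 translations in mm, then 3 rotations in rad) as
#' a smooth random walk plus single-volume displacement spikes at scheduled
#' volumes: the affected volume is displaced and returns to the walk at the
#' next volume.
#'
#' @param spec A [scan_spec()].
#' @param spike_volumes Integer volume indices for spikes; by default drawn
#'   from the retained volume range.
#' @param seed Integer seed.
#' @return A matrix with `n_volumes` rows and 6 columns, with attribute
#'   `spike_volumes`.
#' @export
generate_motion <- function(spec, spike_volumes = NULL, seed = spec$seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  nt <- spec$n_volumes
  m <- sapply(1:6, function(j) {
    sd_j <- if (j <= 3) spec$walk_sd else spec$walk_sd / 50
    cumsum(stats::rnorm(nt, 0, sd_j))
  })
  if (is.null(spike_volumes)) {
    lo <- spec$n_drop + 10
    spike_volumes <- if (spec$n_spikes > 0)
      sort(sample(seq(lo, nt - 5), spec$n_spikes)) else integer(0)
  }
  if (length(spike_volumes)) {
    mag <- stats::runif(length(spike_volumes), spec$spike_mm[1], spec$spike_mm[2])
    m[spike_volumes, 1] <- m[spike_volumes, 1] + mag
    attr_mag <- mag
  } else attr_mag <- numeric(0)
  attr(m, "spike_volumes") <- spike_volumes
  attr(m, "spike_mm") <- attr_mag
  m
}

#' Generate one synthetic resting-state session
#'
#' Simulates the 4D series and matching motion trace for one subject,
#' stimulation condition (`"real"` / `"sham"`) and phase (`"pre"` /
#' `"post"`). The planted local-activity and connectivity effects are
#' applied only when `condition == "real"` and `phase == "post"`. The draw
#' is fully determined by the spec's seed together with (subject,
#' condition, phase), so sessions can be generated in any order.
#'
#' @param spec A [scan_spec()].
#' @param condition `"real"` or `"sham"`.
#' @param phase `"pre"` or `"post"`.
#' @param subject Subject index (>= 1).
#' @param labels Label volumes from [generate_labels()]; regenerated from
#'   `spec$dim` when omitted.
#' @return A list with `series` (a `volume_series`: 4D array `data`, `tr`,
#'   `voxel_mm`), `motion` (matrix), and `labels`.
#' @export
generate_session <- function(spec, condition, phase, subject = 1,
                             labels = NULL) {
  condition <- match.arg(condition, c("real", "sham"))
  phase <- match.arg(phase, c("pre", "post"))
  if (is.null(labels)) labels <- generate_labels(spec$dim)
  if (!all(dim(labels$tissue) == spec$dim)) stop("label volume dims mismatch")
  planted <- condition == "real" && phase == "post"

  sseed <- .session_seed(spec$seed, subject, condition, phase)
  motion <- generate_motion(spec, seed = sseed + 7L)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(sseed)

  nt <- spec$n_volumes
  nvox <- prod(spec$dim)
  tiss <- as.integer(labels$tissue)
  roi <- as.integer(labels$roi)
  in_brain <- tiss > 0L

  # AR(1) noise, time x voxel
  X <- matrix(0, nt, nvox)
  eps <- matrix(stats::rnorm(nt * nvox, 0, spec$noise_sd), nt, nvox)
  X[1, ] <- eps[1, ] / sqrt(1 - spec$ar1^2)
  for (t in 2:nt) X[t, ] <- spec$ar1 * X[t - 1, ] + eps[t, ]

  tt <- seq_len(nt)
  # per-voxel low-frequency sinusoid (random frequency and phase),
  # brain voxels only
  nb <- sum(in_brain)
  f <- stats::runif(nb, 0.01, 0.06)
  ph <- stats::runif(nb, 0, 2 * pi)
  X[, in_brain] <- X[, in_brain] + spec$lowfreq_amp *
    sin(outer(tt * spec$tr, 2 * pi * f) + rep(ph, each = nt))

  # shared latents: right seed <-> cluster carries the planted FC effect;
  # left seed gets its own latent for symmetric baseline structure
  u_r <- .lowfreq_latent(tt, spec$tr)
  u_l <- .lowfreq_latent(tt, spec$tr)
  lam_cl <- spec$latent_cluster_weight + if (planted) spec$fc_increment else 0
  X[, roi == 2L] <- X[, roi == 2L] + spec$latent_seed_weight * u_r
  X[, roi == 1L] <- X[, roi == 1L] + spec$latent_seed_weight * u_l
  X[, roi == 3L] <- X[, roi == 3L] + lam_cl * u_r

  # planted local-activity effect: scale the centred right-seed series
  if (planted && spec$alff_multiplier != 1)
    X[, roi == 2L] <- X[, roi == 2L] * sqrt(spec$alff_multiplier)

  # tissue confounds
  csf_sig <- .lowfreq_latent(tt, spec$tr, f_range = c(0.01, 0.08))
  wm_sig <- .lowfreq_latent(tt, spec$tr, f_range = c(0.01, 0.08))
  X[, tiss == 3L] <- X[, tiss == 3L] + 1.5 * csf_sig
  X[, tiss == 2L] <- X[, tiss == 2L] + 1.5 * wm_sig
  X[, tiss == 1L] <- X[, tiss == 1L] + spec$confound_weight * csf_sig

  # motion-locked global intensity deviations at spike volumes
  sv <- attr(motion, "spike_volumes")
  if (length(sv)) {
    dev <- spec$spike_gain * attr(motion, "spike_mm")
    X[sv, in_brain] <- X[sv, in_brain] + dev
  }

  X[, in_brain] <- X[, in_brain] + 100  # baseline intensity
  series <- structure(
    list(data = array(t(X), c(nvox, nt)) |> array(c(spec$dim, nt)),
         tr = spec$tr, voxel_mm = spec$voxel_mm),
    class = "volume_series"
  )
  list(series = series, motion = motion, labels = labels)
}

#' Drop initial volumes for signal stabilisation
#'
#' Removes the first `n` volumes from a series and its motion trace.
#'
#' @param series A `volume_series`.
#' @param motion Matching motion matrix.
#' @param n Number of initial volumes to drop.
#' @return List with trimmed `series` and `motion`.
#' @export
drop_initial_volumes <- function(series, motion, n = 5) {
  nt <- dim(series$data)[4]
  if (nt - n < 10) stop("fewer than 10 volumes would remain")
  keep <- (n + 1):nt
  series$data <- series$data[, , , keep, drop = FALSE]
  list(series = series, motion = motion[keep, , drop = FALSE])
}

#' Write a synthetic session to disk
#'
#' Writes the 4D series and the label volumes as NIfTI-1 files and the
#' motion trace as 6-column whitespace-delimited text (translations in mm
#' then rotations in rad, one row per volume).
#'
#' @param session Output of [generate_session()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The directory, invisibly.
#' @export
write_session <- function(session, dir, prefix = "session") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vdim <- rep(session$series$voxel_mm, 3)
  img <- RNifti::asNifti(session$series$data)
  RNifti::pixdim(img) <- c(vdim, session$series$tr)
  RNifti::writeNifti(img, file.path(dir, paste0(prefix, "_bold.nii")))
  tis <- RNifti::asNifti(session$labels$tissue)
  RNifti::pixdim(tis) <- vdim
  RNifti::writeNifti(tis, file.path(dir, paste0(prefix, "_tissue.nii")))
  roi <- RNifti::asNifti(session$labels$roi)
  RNifti::pixdim(roi) <- vdim
  RNifti::writeNifti(roi, file.path(dir, paste0(prefix, "_roi.nii")))
  utils::write.table(session$motion,
                     file.path(dir, paste0(prefix, "_motion.txt")),
                     row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Directory containing the files.
#' @param prefix File-name prefix used when writing.
#' @return A session list (`series`, `motion`, `labels`).
#' @export
read_session <- function(dir, prefix = "session") {
  bold <- RNifti::readNifti(file.path(dir, paste0(prefix, "_bold.nii")))
  pd <- RNifti::pixdim(bold)
  series <- structure(
    list(data = array(as.numeric(bold), dim(bold)),
         tr = if (length(pd) >= 4) pd[4] else NA_real_, voxel_mm = pd[1]),
    class = "volume_series"
  )
  labels <- list(
    tissue = array(as.integer(RNifti::readNifti(
      file.path(dir, paste0(prefix, "_tissue.nii")))), dim(bold)[1:3]),
    roi = array(as.integer(RNifti::readNifti(
      file.path(dir, paste0(prefix, "_roi.nii")))), dim(bold)[1:3])
  )
  motion <- as.matrix(utils::read.table(
    file.path(dir, paste0(prefix, "_motion.txt"))))
  dimnames(motion) <- NULL
  list(series = series, motion = motion, labels = labels)
}
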