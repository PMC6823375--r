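# shared fixtures, all built in code

# a single-voxel (or nx-voxel) series wrapping a plain time course
series_from_ts <- function(x, tr = 2.4, voxel_mm = 3, dim3 = c(1, 1, 1)) {
  nt <- if (is.matrix(x)) nrow(x) else length(x)
  structure(list(data = array(t(x), c(dim3, nt)), tr = tr, voxel_mm = voxel_mm),
            class = "volume_series")
}

# pool of (it, correct) simulated from a diffusion spec
simulate_pool <- function(spec, n, seed) {
  fp <- sample_first_passage(spec, n, seed = seed)
  data.frame(it = fp$decision_time + spec$ter, correct = fp$hit_upper)
}

# a qc mask with no flags
no_flags <- function(n) {
  structure(list(flag = rep(FALSE, n), fd = numeric(n), dvars = numeric(n),
                 sd = numeric(n), flagged_fraction = 0),
            class = "qc_mask")
}

# central window of a filtered series, clear of filter edge transients
central_window <- function(n, margin = 50) (margin + 1):(n - margin)

# time x voxel matrix view of a series
ts_mat <- function(series) {
  d <- dim(series$data)
  t(array(series$data, c(prod(d[1:3]), d[4])))
}
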