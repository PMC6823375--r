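test_that("ALFF is the clean-volume variance and scales quadratically", {
  nt <- 245; tr <- 2.4
  flat <- series_from_ts(rep(3, nt), tr = tr)
  expect_equal(as.numeric(alff(flat)), 0)

  x <- 2 * sin(2 * pi * 0.03 * (1:nt) * tr) + rnorm(nt, 0, 0.01)
  ser <- series_from_ts(x, tr = tr)
  qc <- no_flags(nt)
  qc$flag[c(10, 50, 90)] <- TRUE
  expect_equal(as.numeric(alff(ser, qc)), var(x[-c(10, 50, 90)]))
  expect_equal(as.numeric(alff(series_from_ts(5 * x, tr = tr))),
               25 * as.numeric(alff(ser)), tolerance = 1e-10)
})

test_that("band-passed in-band sinusoid has ALFF near its analytic power", {
  nt <- 345; tr <- 2.4
  x <- 2 * sin(2 * pi * 0.03 * (1:nt) * tr)
  filtered <- bandpass(series_from_ts(x, tr = tr))
  qc <- no_flags(nt)
  qc$flag[c(1:50, (nt - 49):nt)] <- TRUE   # exclude filter edge transients
  a <- as.numeric(alff(filtered, qc))
  expected <- 2 * bandpass_gain(0.03, tr)^2   # A^2/2 x squared gain
  expect_lt(abs(a - expected) / expected, 0.05)
})

test_that("Kendall W is exactly 1 for identical neighbours and 1/27 for noise", {
  d3 <- c(7, 7, 7); nt <- 80
  x <- sin(2 * pi * (1:nt) / 16)   # tied values exercise the tie correction
  same <- series_from_ts(matrix(x, nt, prod(d3)), dim3 = d3)
  W <- reho(same)
  expect_equal(as.numeric(W), rep(1, prod(d3)), tolerance = 1e-12)

  set.seed(33)
  d3b <- c(12, 12, 10); ntb <- 245
  noise <- series_from_ts(matrix(rnorm(ntb * prod(d3b)), ntb), dim3 = d3b)
  Wn <- reho(noise)
  interior <- Wn[2:11, 2:11, 2:9]
  # overlapping neighbourhoods correlate nearby W values, so the
  # effective number of independent voxels is about length/27
  se <- sqrt(2 / (ntb - 1)) / 27 / sqrt(length(interior) / 27)
  expect_lt(abs(mean(interior) - 1 / 27), 3 * se)
})

test_that("ReHo is invariant under monotone rescaling and flags constants", {
  d3 <- c(5, 5, 4); nt <- 60
  set.seed(4)
  X <- matrix(rnorm(nt * prod(d3)), nt)
  w1 <- reho(series_from_ts(X, dim3 = d3))
  w2 <- reho(series_from_ts(exp(3 * X), dim3 = d3))
  expect_equal(w1, w2, tolerance = 1e-12)

  Xc <- X; Xc[, 13] <- 1
  wc <- reho(series_from_ts(Xc, dim3 = d3))
  expect_true(is.na(as.numeric(wc)[13]))
})

test_that("seed connectivity clips perfect correlation and recovers planted loadings", {
  d3 <- c(4, 4, 2); nv <- prod(d3); nt <- 400
  roi <- array(0L, d3); roi[1, 1, 1] <- 2L
  set.seed(12)
  u <- rnorm(nt)
  X <- matrix(rnorm(nt * nv), nt)
  X[, 1] <- u
  lam <- 0.7
  X[, 2] <- lam * u + rnorm(nt)          # target with known loading
  X[, 3] <- sin(2 * pi * (1:nt) / 20)    # deterministic, orthogonal-ish
  z <- seed_fc(series_from_ts(X, dim3 = d3), roi, 2L)
  expect_equal(z[1, 1, 1], atanh(1 - 1e-7))
  r_theory <- lam / sqrt(1 + lam^2)
  expect_lt(abs(tanh(z[2, 1, 1]) - r_theory), 0.05)
  expect_lt(abs(z[3, 1, 1]), 0.15)
  expect_error(seed_fc(series_from_ts(X, dim3 = d3), roi, 5L), "empty")
})

test_that("a zero-variance voxel maps to z = 0 and is counted", {
  d3 <- c(3, 1, 1); nt <- 50
  roi <- array(c(2L, 0L, 0L), d3)
  X <- cbind(rnorm(nt), rnorm(nt), rep(1, nt))
  z <- seed_fc(series_from_ts(X, dim3 = d3), roi, 2L)
  expect_equal(z[3, 1, 1], 0)
  expect_equal(attr(z, "n_degenerate"), 1L)
})

test_that("ALFF and ReHo covary across voxels on structured synthetic data", {
  sp <- scan_spec(seed = 51, n_spikes = 0)
  lab <- generate_labels(sp$dim)
  ses <- generate_session(sp, "sham", "pre", 1, lab)
  tr <- drop_initial_volumes(ses$series, ses$motion, sp$n_drop)
  qc <- compute_qc(tr$series, tr$motion, lab$tissue == 1L)
  pp <- preprocess_session(tr$series, tr$motion, lab$tissue, qc)
  a <- alff(pp, qc); w <- reho(pp, qc)
  gm <- lab$tissue == 1L
  ok <- gm & !is.na(w)
  expect_gt(cor(log(a[ok]), w[ok]), 0)
})
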