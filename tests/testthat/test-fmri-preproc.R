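test_that("detrending removes mean and linear drift exactly", {
  nt <- 60
  x <- 3 + 0.2 * (1:nt) + sin(2 * pi * (1:nt) / 10)
  out <- as.numeric(detrend_series(series_from_ts(x))$data)
  expect_lt(abs(mean(out)), 1e-10)
  expect_lt(abs(coef(lm(out ~ seq_len(nt)))[2]), 1e-10)
})

test_that("nuisance regression removes confounds and spares orthogonal signal", {
  set.seed(8)
  nt <- 400
  d3 <- c(3, 3, 2); nv <- prod(d3)
  tissue <- array(1L, d3); tissue[1, 1, ] <- 2L; tissue[3, 3, ] <- 3L
  motion <- matrix(rnorm(nt * 6, 0, 0.01), nt, 6)
  csf_sig <- as.numeric(scale(cumsum(rnorm(nt))))
  wm_sig <- as.numeric(scale(cumsum(rnorm(nt))))
  signal <- sin(2 * pi * 0.05 * (1:nt) * 2.4)

  X <- matrix(rnorm(nt * nv, 0, 0.001), nt, nv)
  X[, as.integer(tissue) == 2L] <- wm_sig
  X[, as.integer(tissue) == 3L] <- csf_sig
  gm_cols <- which(as.integer(tissue) == 1L)
  X[, gm_cols[1]] <- csf_sig                 # a pure confound voxel
  X[, gm_cols[2]] <- signal + 0.8 * csf_sig  # signal + confound leak
  ser <- detrend_series(series_from_ts(X, dim3 = d3))
  qc <- no_flags(nt)
  res <- nuisance_regression(ser, motion, tissue, qc)
  R <- ts_mat(res)

  expect_lt(var(R[, gm_cols[1]]), 0.01 * var(csf_sig))
  # 16 fitted regressors remove a chance fraction of any series of order
  # chi^2_16 / n; bound at its extreme quantile, ~10% for n = 400
  v_sig <- var(signal - mean(signal))
  expect_lt(abs(var(R[, gm_cols[2]]) - v_sig) / v_sig, 0.10)

  bad_motion <- motion; bad_motion[, 2] <- motion[, 1]
  expect_error(nuisance_regression(ser, bad_motion, tissue, qc),
               "rank-deficient|collinear")
})

test_that("band-pass preserves in-band amplitude and removes DC and out-of-band power", {
  nt <- 245; tr <- 2.4
  tt <- (1:nt) * tr
  ctr <- central_window(nt)

  keep <- bandpass(series_from_ts(2 * sin(2 * pi * 0.03 * tt), tr = tr))
  g <- bandpass_gain(0.03, tr)
  expect_lt(abs(sd(as.numeric(keep$data)[ctr]) / sd(2 * sin(2 * pi * 0.03 * tt)) - g),
            0.05 * g)

  kill <- bandpass(series_from_ts(2 * sin(2 * pi * 0.2 * tt), tr = tr))
  expect_lt(sd(as.numeric(kill$data)[ctr]) / sd(2 * sin(2 * pi * 0.2 * tt)), 0.1)

  dc <- bandpass(series_from_ts(rep(7, nt), tr = tr))
  expect_lt(max(abs(as.numeric(dc$data))), 0.01 * 7)

  expect_error(bandpass(series_from_ts(rnorm(nt), tr = tr), high = 0.3),
               "Nyquist")
})

test_that("zero-phase filtering matches the analytic squared magnitude response", {
  tr <- 2.4
  for (f in c(0.02, 0.05, 0.1)) {
    nt <- 400
    x <- sin(2 * pi * f * (1:nt) * tr)
    y <- as.numeric(bandpass(series_from_ts(x, tr = tr))$data)
    ctr <- central_window(nt, 80)
    expect_equal(sd(y[ctr]) / sd(x[ctr]), bandpass_gain(f, tr),
                 tolerance = 0.06)
  }
})

test_that("Gaussian smoothing is linear, mass-preserving and has the right width", {
  d3 <- c(15, 15, 15)
  mk <- function(vals) series_from_ts(matrix(vals, 1), dim3 = d3, tr = 2)

  flat <- smooth_series(mk(rep(4, prod(d3))), fwhm_mm = 8)
  expect_equal(as.numeric(flat$data), rep(4, prod(d3)), tolerance = 1e-10)

  delta_vals <- rep(0, prod(d3)); delta_vals[cumprod(d3)[3] / 2 + 0.5] <- 1
  # place the impulse at the centre voxel (8,8,8)
  delta_vals <- rep(0, prod(d3))
  delta_vals[8 + (8 - 1) * 15 + (8 - 1) * 225] <- 1
  sm <- smooth_series(mk(delta_vals), fwhm_mm = 8)
  A <- sm$data[, , , 1]
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 3
  prof <- A[, 8, 8] / A[8, 8, 8]
  expect_equal(prof[9], exp(-1 / (2 * sigma^2)), tolerance = 1e-6)
  # border rows renormalise, so mass is preserved only to kernel truncation
  expect_equal(sum(A), 1, tolerance = 1e-4)

  two <- rep(0, prod(d3))
  two[8 + 7 * 15 + 7 * 225] <- 1; two[4 + 7 * 15 + 7 * 225] <- 2
  sm2 <- smooth_series(mk(two), fwhm_mm = 8)
  one_a <- smooth_series(mk(replace(rep(0, prod(d3)), 8 + 7 * 15 + 7 * 225, 1)), 8)
  one_b <- smooth_series(mk(replace(rep(0, prod(d3)), 4 + 7 * 15 + 7 * 225, 2)), 8)
  expect_equal(sm2$data, one_a$data + one_b$data, tolerance = 1e-10)
})
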