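# Vectorised moment computation over B index resamples. `idx` is an
# n x B integer matrix of row indices into (it, correct).
.boot_moments <- function(it, correct, idx) {
  n <- nrow(idx)
  C <- matrix(correct[idx], n)
  X <- matrix(it[idx], n)
  nc <- colSums(C)
  sum_it <- colSums(X * C)
  mrt <- sum_it / nc
  ssq <- colSums(X * X * C)
  vrt <- (ssq - nc * mrt^2) / (nc - 1)
  pc <- nc / n
  pc[pc == 1] <- 1 - 1 / (2 * n)
  list(pc = pc, mrt = mrt, vrt = vrt, nc = nc)
}

# Vectorised EZ fit; invalid summaries yield NA which callers re-draw.
.ez_fit_vec <- function(pc, mrt, vrt, s = 1) {
  ok <- is.finite(pc) & pc > 0.5 & pc < 1 & is.finite(vrt) & vrt > 0
  L <- v <- a <- mdt <- rep(NA_real_, length(pc))
  L[ok] <- log(pc[ok] / (1 - pc[ok]))
  x <- L[ok] * (pc[ok]^2 * L[ok] - pc[ok] * L[ok] + pc[ok] - 0.5) / vrt[ok]
  v[ok] <- s * x^(1 / 4)
  a[ok] <- s^2 * L[ok] / v[ok]
  y <- exp(-v[ok] * a[ok] / s^2)
  mdt[ok] <- (a[ok] / (2 * v[ok])) * (1 - y) / (1 + y)
  list(a = a, v = v, ter = mrt - mdt, ok = ok)
}

.draw_params <- function(it, correct, sizes, B, s, max_fail_frac = 0.1) {
  # Draw B resamples for each pool size in `sizes` (a list of index bases);
  # returns per-pool parameter matrices, re-drawing failed resamples.
  n_src <- length(it)
  out <- vector("list", length(sizes))
  n_failed <- 0L
  for (k in seq_along(sizes)) {
    n <- sizes[[k]]
    idx <- matrix(sample.int(n_src, n * B, replace = TRUE), n)
    mo <- .boot_moments(it, correct, idx)
    fit <- .ez_fit_vec(mo$pc, mo$mrt, mo$vrt, s)
    bad <- which(!fit$ok)
    tries <- 0L
    while (length(bad) > 0L && tries < 50L) {
      tries <- tries + 1L
      n_failed <- n_failed + length(bad)
      if (n_failed > max_fail_frac * B * length(sizes) + 50)
        stop("more than 10% of bootstrap resamples failed EZ estimation; ",
             "input pool is pathological")
      idx2 <- matrix(sample.int(n_src, n * length(bad), replace = TRUE), n)
      mo2 <- .boot_moments(it, correct, idx2)
      fit2 <- .ez_fit_vec(mo2$pc, mo2$mrt, mo2$vrt, s)
      for (p in c("a", "v", "ter")) fit[[p]][bad] <- fit2[[p]]
      bad <- bad[!fit2$ok]
    }
    out[[k]] <- fit[c("a", "v", "ter")]
  }
  attr(out, "n_failed") <- n_failed
  out
}

#' Percentile-bootstrap confidence intervals for EZ parameters
#'
#' Resamples the pooled (initiation time, correctness) pairs with
#' replacement, `B` times at the original pool size, refits the EZ
#' estimator to each resample, and reports the 2.5th and 97.5th percentiles
#' of each parameter's bootstrap distribution. The resampling unit is the
#' trial, matching the pooled-population framing of the estimator.
#' Resamples on which the estimator is undefined (for example a resample at
#' or below chance) are re-drawn so exactly `B` valid replicates enter the
#' percentiles; the number of re-draws is recorded.
#'
#' @param pool Data.frame with `it` (seconds) and `correct`.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed; the draw is fully reproducible.
#' @param s Noise scale passed to the estimator.
#' @param conf Confidence level (default 0.95).
#' @return A data.frame with one row per parameter (`a`, `v`, `ter`):
#'   `point` (fit to the original pool), `ci_low`, `ci_high`, `B`, `seed`;
#'   attribute `n_failed` counts re-drawn resamples.
#' @export
bootstrap_ci <- function(pool, B = 2000, seed = 1L, s = 1, conf = 0.95) {
  if (B < 100) stop("'B' must be at least 100")
  point <- ez_fit(summarize_trials(pool), s = s)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  draws <- .draw_params(pool$it, pool$correct, list(nrow(pool)), B, s)[[1]]
  alpha <- (1 - conf) / 2
  res <- do.call(rbind, lapply(c("a", "v", "ter"), function(p) {
    q <- stats::quantile(draws[[p]], c(alpha, 1 - alpha), names = FALSE)
    data.frame(parameter = p, point = point[[p]],
               ci_low = q[1], ci_high = q[2],
               B = as.integer(B), seed = as.integer(seed))
  }))
  attr(res, "n_failed") <- attr(draws, "n_failed")
  res
}

#' Between-condition bootstrap hypothesis test for EZ parameters
#'
#' Tests, for each parameter, whether the pools of two stimulation
#' conditions could have been drawn from one common distribution of
#' initiation times. The two pools are merged; `B` pairs of datasets are
#' drawn from the merged pool with replacement, preserving the two original
#' sample sizes; the EZ estimator is fit to each member; and the two-sided
#' p-value is the proportion of pairs whose absolute parameter difference
#' exceeds the observed absolute difference, floored at `1/B`.
#'
#' @param pool_a,pool_b Data.frames with `it` (seconds) and `correct`.
#' @param B Number of bootstrap pairs (>= 100).
#' @param seed Integer seed.
#' @param s Noise scale.
#' @return A data.frame with one row per parameter: observed estimates in
#'   both pools, `delta_obs`, and `p_value` (floored at 1/B).
#' @export
bootstrap_test <- function(pool_a, pool_b, B = 2000, seed = 1L, s = 1) {
  if (B < 100) stop("'B' must be at least 100")
  fit_a <- ez_fit(summarize_trials(pool_a), s = s)
  fit_b <- ez_fit(summarize_trials(pool_b), s = s)
  it <- c(pool_a$it, pool_b$it)
  correct <- c(pool_a$correct, pool_b$correct)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  draws <- .draw_params(it, correct, list(nrow(pool_a), nrow(pool_b)), B, s)
  res <- do.call(rbind, lapply(c("a", "v", "ter"), function(p) {
    d_obs <- fit_a[[p]] - fit_b[[p]]
    d_star <- draws[[1]][[p]] - draws[[2]][[p]]
    p_val <- max(mean(abs(d_star) > abs(d_obs)), 1 / B)
    data.frame(parameter = p, estimate_a = fit_a[[p]], estimate_b = fit_b[[p]],
               delta_obs = d_obs, p_value = p_val,
               B = as.integer(B), seed = as.integer(seed))
  }))
  attr(res, "n_failed") <- attr(draws, "n_failed")
  res
}

#' Bonferroni correction
#'
#' Multiplies a p-value by the number of comparisons `k` and caps at 1;
#' with the three tasks of the standard design, `k = 3`.
#'
#' @param p P-value(s) in (0, 1].
#' @param k Number of comparisons (>= 1).
#' @return Corrected p-value(s).
#' @export
bonferroni <- function(p, k = 3) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("'p' must lie in (0, 1]")
  if (k < 1) stop("'k' must be >= 1")
  pmin(1, k * p)
}
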