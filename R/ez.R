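#' Filter initiation times before pooling
#'
#' Applies the trial-screening rules used ahead of population pooling:
#' initiation times above 1000 ms are eliminated from the table entirely
#' (they enter neither the accuracy denominator nor the moments), while
#' initiation times below 150 ms are kept but counted as errors
#' (anticipations). All other rows pass through unchanged.
#'
#' @param trials Trial data.frame with `initiation_time` (ms) and `correct`.
#' @param upper_ms,lower_ms Elimination and anticipation cutoffs in ms.
#' @return The filtered data.frame, with attribute `filter_counts`
#'   (`n_removed`, `n_marked_error`).
#' @export
filter_initiation_times <- function(trials, upper_ms = 1000, lower_ms = 150) {
  if (!is.data.frame(trials) || nrow(trials) == 0)
    stop("empty trial table")
  if (!all(c("initiation_time", "correct") %in% names(trials)))
    stop("'trials' must have 'initiation_time' and 'correct' columns")
  it <- trials$initiation_time
  drop <- it > upper_ms
  out <- trials[!drop, , drop = FALSE]
  if (nrow(out) == 0) stop("no trials survive filtering")
  ant <- out$initiation_time < lower_ms
  n_marked <- sum(ant & out$correct)
  out$correct[ant] <- FALSE
  if ("error_type" %in% names(out)) out$error_type[ant] <- "anticipation"
  rownames(out) <- NULL
  attr(out, "filter_counts") <- c(n_removed = sum(drop),
                                  n_marked_error = n_marked)
  out
}

#' Pool initiation times across subjects
#'
#' Concatenates the filtered trials of every subject in one stimulation
#' group x task cell into a single population distribution, the unit on
#' which the diffusion parameters are estimated. Order is stable: subjects
#' in id order, trials in table order within subject.
#'
#' @param trials Filtered trial data.frame.
#' @param group,task Cell selectors.
#' @return A data.frame with `it` (initiation time, seconds) and `correct`.
#' @export
pool_across_subjects <- function(trials, group, task) {
  sel <- trials$group == group & trials$task == task
  if (!any(sel)) stop("no trials for group '", group, "', task '", task, "'")
  sub <- trials[sel, , drop = FALSE]
  sub <- sub[order(sub$subject_id), , drop = FALSE]
  data.frame(it = sub$initiation_time / 1000, correct = sub$correct)
}

#' Moment summary of a pooled trial distribution
#'
#' Computes the three sufficient statistics of the EZ estimator: the
#' probability of a correct response `pc` over all pooled trials, and the
#' mean (`mrt`, seconds) and unbiased variance (`vrt`, seconds^2) of the
#' initiation times of correct trials only. A perfect-accuracy pool is
#' edge-corrected to `pc = 1 - 1/(2 n)` so the log-odds stays finite;
#' at-or-below-chance accuracy is left as computed and rejected downstream.
#'
#' @param pool Data.frame with `it` (seconds) and `correct`, as returned by
#'   [pool_across_subjects()].
#' @return An object of class `ez_summary`: list with `pc`, `mrt`, `vrt`,
#'   `n_total`, `n_correct`.
#' @export
summarize_trials <- function(pool) {
  stopifnot(is.data.frame(pool), all(c("it", "correct") %in% names(pool)))
  n <- nrow(pool)
  nc <- sum(pool$correct)
  if (nc < 2) stop("need at least 2 correct trials to estimate a variance")
  pc <- nc / n
  if (pc == 1) pc <- 1 - 1 / (2 * n)
  its <- pool$it[pool$correct]
  structure(
    list(pc = pc, mrt = mean(its), vrt = stats::var(its),
         n_total = n, n_correct = nc),
    class = "ez_summary"
  )
}

#' @export
print.ez_summary <- function(x, ...) {
  cat(sprintf("ez_summary: Pc=%.4f  MRT=%.4f s  VRT=%.6f s^2  (n=%d, %d correct)\n",
              x$pc, x$mrt, x$vrt, x$n_total, x$n_correct))
  invisible(x)
}

#' Closed-form EZ-diffusion estimation
#'
#' Maps the moment summary (Pc, MRT, VRT) to the three diffusion
#' parameters. With the log-odds `L = log(Pc / (1 - Pc))`:
#' \deqn{v = sign(Pc - 1/2) \, s \, \{ L (Pc^2 L - Pc L + Pc - 1/2) / VRT \}^{1/4}}
#' \deqn{a = s^2 L / v}
#' \deqn{MDT = (a / 2v) \, (1 - e^{-va/s^2}) / (1 + e^{-va/s^2})}
#' \deqn{T_{er} = MRT - MDT}
#' The estimator assumes an unbiased starting point and no across-trial
#' parameter variability; it is undefined at or below chance accuracy and
#' for zero reaction-time variance.
#'
#' @param summary An `ez_summary` (or list with `pc`, `mrt`, `vrt`).
#' @param s Noise scale, fixed by convention (default 1).
#' @return An object of class `ez_parameters`: list with `v`, `a`, `mdt`,
#'   `ter` (all in seconds-based units) and `s`.
#' @examples
#' p <- ez_fit(ez_forward(list(a = 1, v = 2, ter = 0.3, s = 1)))
#' unlist(p[c("a", "v", "ter")])
#' @export
ez_fit <- function(summary, s = 1) {
  pc <- summary$pc; mrt <- summary$mrt; vrt <- summary$vrt
  if (!is.finite(pc) || pc <= 0.5)
    stop("EZ undefined at or below chance accuracy (Pc <= 0.5)")
  if (pc >= 1) stop("Pc = 1 must be edge-corrected before fitting")
  if (!is.finite(vrt) || vrt <= 0)
    stop("EZ undefined for zero reaction-time variance (VRT <= 0)")
  L <- log(pc / (1 - pc))
  x <- L * (pc^2 * L - pc * L + pc - 0.5) / vrt
  v <- sign(pc - 0.5) * s * x^(1 / 4)
  a <- s^2 * L / v
  y <- exp(-v * a / s^2)
  mdt <- (a / (2 * v)) * (1 - y) / (1 + y)
  structure(list(v = v, a = a, mdt = mdt, ter = mrt - mdt, s = s),
            class = "ez_parameters")
}

#' @export
print.ez_parameters <- function(x, ...) {
  cat(sprintf("ez_parameters: a=%.4f  v=%.4f  Ter=%.1f ms  (MDT=%.1f ms, s=%g)\n",
              x$a, x$v, 1000 * x$ter, 1000 * x$mdt, x$s))
  invisible(x)
}

#' Exact forward model: parameters to moments
#'
#' Inverts the EZ equations analytically. With `L = a v / s^2`:
#' `Pc = 1/(1 + e^{-L})`, `MDT = (a/2v) tanh(L/2)`, `MRT = Ter + MDT`, and
#' `VRT = s^4 L (Pc^2 L - Pc L + Pc - 1/2) / v^4`. Used for round-trip
#' testing and for constructing pools with known ground truth.
#'
#' @param params List with `a`, `v`, `ter` and optionally `s` (default 1).
#' @return An `ez_summary` (with `n_total`/`n_correct` set to `NA`).
#' @export
ez_forward <- function(params) {
  a <- params$a; v <- params$v; ter <- params$ter
  s <- if (is.null(params$s)) 1 else params$s
  if (a <= 0) stop("'a' must be positive")
  if (v == 0) stop("forward model undefined at v = 0 (Pc would be 1/2)")
  L <- a * v / s^2
  pc <- 1 / (1 + exp(-L))
  mdt <- (a / (2 * v)) * tanh(L / 2)
  vrt <- s^4 * L * (pc^2 * L - pc * L + pc - 0.5) / v^4
  structure(
    list(pc = pc, mrt = ter + mdt, vrt = vrt,
         n_total = NA_integer_, n_correct = NA_integer_),
    class = "ez_summary"
  )
}
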