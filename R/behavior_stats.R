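#' Per-cell descriptive behavioral measures
#'
#' One row per subject x task x target location: mean initiation, movement
#' and reaction time over correct trials (ms), the error rate as a
#' percentage of all trials in the cell, and the trial counts. Cells with
#' no correct trials keep `NA` means and are flagged rather than dropped.
#'
#' @param trials Trial data.frame with `subject_id`, `group`, `task`,
#'   `location`, `initiation_time`, `movement_time`, `reaction_time`,
#'   `correct`.
#' @return A data.frame of per-cell statistics.
#' @export
aggregate_measures <- function(trials) {
  need <- c("subject_id", "group", "task", "location",
            "initiation_time", "movement_time", "reaction_time", "correct")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  key <- interaction(trials$subject_id, trials$task, trials$location,
                     drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(seq_len(nrow(trials)), key), function(ix) {
    d <- trials[ix, , drop = FALSE]
    ok <- d$correct
    data.frame(
      subject_id = d$subject_id[1], group = d$group[1],
      task = d$task[1], location = d$location[1],
      mean_it = if (any(ok)) mean(d$initiation_time[ok]) else NA_real_,
      mean_mt = if (any(ok)) mean(d$movement_time[ok]) else NA_real_,
      mean_rt = if (any(ok)) mean(d$reaction_time[ok]) else NA_real_,
      error_rate = 100 * sum(!ok) / nrow(d),
      n_trials = nrow(d), n_correct = sum(ok),
      undefined = !any(ok),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson chi-square test for a 2x2 contingency table
#'
#' The uncorrected statistic \eqn{\chi^2 = n (ad - bc)^2 /
#' [(a+b)(c+d)(a+c)(b+d)]} with 1 degree of freedom and no continuity
#' correction. Used, for example, to test whether subjects' guesses about
#' which stimulation they received depend on the stimulation actually
#' delivered (rows = actual condition, columns = guessed condition).
#'
#' @param tab A 2x2 numeric matrix of counts.
#' @return A list with `chi2`, `p`, `df = 1`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("'tab' must be 2x2")
  if (any(tab < 0)) stop("counts must be non-negative")
  n <- sum(tab)
  if (n <= 0) stop("empty table")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in contingency table")
  chi2 <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    (rs[1] * rs[2] * cs[1] * cs[2])
  chi2 <- unname(chi2)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE), df = 1)
}

#' Two-proportion z test
#'
#' Pooled-proportion z statistic for comparing `k1/n1` against `k2/n2`,
#' with a two-sided normal p-value.
#'
#' @param k1,n1,k2,n2 Successes and totals in the two groups.
#' @return A list with `z` and `p`.
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p_pool <- (k1 + k2) / (n1 + n2)
  if (p_pool <= 0 || p_pool >= 1)
    stop("pooled proportion is 0 or 1: zero-variance test")
  z <- (k1 / n1 - k2 / n2) /
    sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
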