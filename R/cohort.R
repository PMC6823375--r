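#' Specify a synthetic choice-reaction-time cohort
#'
#' Describes a two-group (real / sham stimulation) factorial design in which
#' every subject performs each task as one block of `trials_per_task` trials,
#' balanced over the inter-stimulus intervals in `isi_levels`. Initiation
#' times are generated by a drift-diffusion decision process (one
#' [ddm_spec()] per group x task), movement times by a log-normal
#' distribution, and a small fraction of trials is replaced by contaminants:
#' anticipations (premature releases, initiation time uniform in 50-149 ms,
#' always an error) and lapses (attentional lapses, initiation time uniform
#' in 1000-2000 ms).
#'
#' @param n_real,n_sham Subjects per stimulation group.
#' @param tasks Character vector of task labels; defaults to the fully-cued
#'   ("FC"), uncued-compatible ("UC") and uncued-incompatible ("UI") tasks.
#' @param trials_per_task Trials per subject per task; must be divisible by
#'   `length(isi_levels)`.
#' @param isi_levels Inter-stimulus intervals in ms. Default
#'   `c(200, 400, 800, 1600, 3200)`, five levels so 15 x 5 = 75.
#' @param ddm Named list mapping `"<group>.<task>"` to a [ddm_spec()];
#'   missing entries fall back to built-in defaults that reproduce the
#'   reported condition effects of this study design: a raised decision
#'   boundary under real stimulation in the fully-cued task, a slowed
#'   drift in the uncued-compatible task, and a faster drift with longer
#'   non-decision time in the uncued-incompatible task, on top of the
#'   usual task-difficulty gradient.
#' @param mt_meanlog,mt_sdlog Log-normal movement-time parameters
#'   (log-milliseconds); defaults give a median of about 180 ms.
#' @param anticipation_rate,lapse_rate Contamination proportions in `[0,1)`;
#'   their sum must be < 1.
#' @param seed Integer master seed. Per-subject substreams are derived as
#'   `(seed + 104729 * subject_index) mod (2^31 - 1)`, so any subject's data
#'   are independent of how many other subjects are generated.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_real = 20, n_sham = 22,
                        tasks = c("FC", "UC", "UI"),
                        trials_per_task = 75,
                        isi_levels = c(200, 400, 800, 1600, 3200),
                        ddm = NULL,
                        mt_meanlog = log(180), mt_sdlog = 0.18,
                        anticipation_rate = 0.02, lapse_rate = 0.04,
                        seed = 1L) {
  stopifnot(n_real >= 1, n_sham >= 1, trials_per_task >= 1)
  if (trials_per_task %% length(isi_levels) != 0)
    stop("'trials_per_task' must be divisible by the number of ISI levels")
  if (anticipation_rate < 0 || lapse_rate < 0 ||
      anticipation_rate + lapse_rate >= 1)
    stop("contamination rates must be non-negative and sum to < 1")

  defaults <- list(
    real.FC = ddm_spec(a = 1.05, v = 4.3, ter = 0.33),
    sham.FC = ddm_spec(a = 0.92, v = 4.3, ter = 0.33),
    real.UC = ddm_spec(a = 1.00, v = 3.74, ter = 0.35),
    sham.UC = ddm_spec(a = 1.00, v = 4.25, ter = 0.35),
    real.UI = ddm_spec(a = 1.05, v = 3.43, ter = 0.360),
    sham.UI = ddm_spec(a = 1.05, v = 3.14, ter = 0.339)
  )
  full <- list()
  for (g in c("real", "sham")) for (tk in tasks) {
    key <- paste(g, tk, sep = ".")
    if (!is.null(ddm[[key]])) {
      if (!inherits(ddm[[key]], "ddm_spec")) stop("ddm[['", key, "']] is not a ddm_spec")
      full[[key]] <- ddm[[key]]
    } else if (!is.null(defaults[[key]])) {
      full[[key]] <- defaults[[key]]
    } else {
      stop("no ddm_spec supplied for ", key, " and no built-in default")
    }
  }

  structure(
    list(n_real = as.integer(n_real), n_sham = as.integer(n_sham),
         tasks = tasks, trials_per_task = as.integer(trials_per_task),
         isi_levels = isi_levels, ddm = full,
         mt_meanlog = mt_meanlog, mt_sdlog = mt_sdlog,
         anticipation_rate = anticipation_rate, lapse_rate = lapse_rate,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

.subject_seed <- function(master, subject_index) {
  as.integer((as.double(master) + 104729 * as.double(subject_index)) %%
               2147483647)
}

.locations <- c("upper-left", "lower-left", "upper-right", "lower-right")

#' Generate a trial table for a synthetic cohort
#'
#' Produces one row per trial with the layout of a trial-level
#' choice-reaction-time export: subject, group, task, target location, ISI,
#' initiation time, movement time, reaction time (their sum), correctness,
#' and an error-type annotation (`none`, `anticipation`, `wrong-choice`,
#' `lapse`). Initiation time is `1000 * (decision_time + ter)` ms from the
#' diffusion process; correctness is the boundary hit. Contaminant trials
#' overwrite the simulated initiation time: anticipations are uniform in
#' [50, 149] ms and always incorrect; lapses are uniform in (1000, 2000] ms
#' and keep the simulated correctness. The draw is fully determined by the
#' spec's seed.
#'
#' @param cohort A [cohort_spec()].
#' @return A data.frame of trials.
#' @export
generate_trials <- function(cohort) {
  if (!inherits(cohort, "cohort_spec")) stop("'cohort' must be a cohort_spec")
  groups <- c(rep("real", cohort$n_real), rep("sham", cohort$n_sham))
  n_sub <- length(groups)
  n_isi <- length(cohort$isi_levels)
  per_isi <- cohort$trials_per_task %/% n_isi

  pieces <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    sub_rows <- vector("list", length(cohort$tasks))
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(.subject_seed(cohort$seed, i))
    for (j in seq_along(cohort$tasks)) {
      tk <- cohort$tasks[j]
      spec <- cohort$ddm[[paste(groups[i], tk, sep = ".")]]
      nt <- cohort$trials_per_task
      fp <- sample_first_passage(spec, nt)
      it <- 1000 * (fp$decision_time + spec$ter)
      correct <- fp$hit_upper
      err <- ifelse(correct, "none", "wrong-choice")

      u <- stats::runif(nt)
      is_ant <- u < cohort$anticipation_rate
      is_lap <- !is_ant &
        u < cohort$anticipation_rate + cohort$lapse_rate
      it[is_ant] <- stats::runif(sum(is_ant), 50, 149)
      correct[is_ant] <- FALSE
      err[is_ant] <- "anticipation"
      it[is_lap] <- stats::runif(sum(is_lap), 1000 + .Machine$double.eps, 2000)
      err[is_lap] <- "lapse"

      mt <- stats::rlnorm(nt, cohort$mt_meanlog, cohort$mt_sdlog)
      isi <- sample(rep(cohort$isi_levels, per_isi))
      loc <- sample(rep_len(.locations, nt))

      sub_rows[[j]] <- data.frame(
        subject_id = sprintf("S%02d", i),
        group = groups[i], session = 1L, task = tk, location = loc,
        isi = isi,
        initiation_time = round(it, 3), movement_time = round(mt, 3),
        correct = correct, error_type = err,
        stringsAsFactors = FALSE
      )
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    pieces[[i]] <- do.call(rbind, sub_rows)
  }
  out <- do.call(rbind, pieces)
  out$reaction_time <- round(out$initiation_time + out$movement_time, 3)
  rownames(out) <- NULL
  out[, c("subject_id", "group", "session", "task", "location", "isi",
          "initiation_time", "movement_time", "reaction_time",
          "correct", "error_type")]
}

#' Write / read a trial table as CSV
#'
#' Plain CSV with a header row and times in milliseconds (3 decimal
#' places, as generated).
#'
#' @param trials A trial data.frame from [generate_trials()].
#' @param path Output file path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns
#'   the trial data.frame.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "task", "initiation_time", "correct")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("trial file is missing columns: ", paste(miss, collapse = ", "))
  out$correct <- as.logical(out$correct)
  out
}
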