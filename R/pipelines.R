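#' Run the full behavioral analysis pipeline
#'
#' Filter, pool, summarise, fit the EZ-diffusion estimator, and run the
#' bootstrap confidence intervals and between-condition tests (Bonferroni
#' corrected over tasks), for every task in a trial table. Trials may come
#' from [generate_trials()] or from a CSV in the same dialect
#' ([read_trials()]), which is also how a deposited real dataset is
#' replayed for full-number replication.
#'
#' @param trials Trial data.frame.
#' @param B Bootstrap replicates (>= 100); 1e5 for replication-grade CIs,
#'   smaller for desk-scale runs.
#' @param seed Integer seed driving all resampling.
#' @param s Diffusion noise scale.
#' @param tasks Tasks to analyse; defaults to those present.
#' @param out_dir Optional directory: writes `ez_parameters.json` and
#'   `ez_tests.json`.
#' @return A list with per-task summaries, parameter tables with CIs, and
#'   the corrected test table.
#' @export
run_behavior_pipeline <- function(trials, B = 2000, seed = 1L, s = 1,
                                  tasks = NULL, out_dir = NULL) {
  filtered <- filter_initiation_times(trials)
  if (is.null(tasks)) tasks <- unique(filtered$task)
  params <- list(); tests <- list()
  for (tk in tasks) {
    pool_r <- pool_across_subjects(filtered, "real", tk)
    pool_s <- pool_across_subjects(filtered, "sham", tk)
    ci_r <- bootstrap_ci(pool_r, B = B, seed = seed, s = s)
    ci_s <- bootstrap_ci(pool_s, B = B, seed = seed + 1L, s = s)
    ci_r$group <- "real"; ci_s$group <- "sham"
    ci <- rbind(ci_r, ci_s)
    ci$task <- tk
    ci$n_pooled <- ifelse(ci$group == "real", nrow(pool_r), nrow(pool_s))
    params[[tk]] <- ci
    tst <- bootstrap_test(pool_r, pool_s, B = B, seed = seed + 2L, s = s)
    tst$task <- tk
    tests[[tk]] <- tst
  }
  test_table <- do.call(rbind, tests)
  test_table$p_bonferroni <- bonferroni(test_table$p_value, k = length(tasks))
  param_table <- do.call(rbind, params)
  rownames(param_table) <- rownames(test_table) <- NULL
  out <- list(parameters = param_table, tests = test_table,
              filter_counts = attr(filtered, "filter_counts"),
              B = B, seed = seed,
              manifest = list(
                package_version = as.character(utils::packageVersion("ezstim")),
                B = B, seed = seed, s = s, tasks = tasks,
                n_trials_in = nrow(trials)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(param_table, file.path(out_dir, "ez_parameters.json"),
                         dataframe = "rows", digits = NA)
    jsonlite::write_json(test_table, file.path(out_dir, "ez_tests.json"),
                         dataframe = "rows", digits = NA)
  }
  out
}

# per-session metric extraction used by the fMRI pipeline
.session_metrics <- function(spec, condition, phase, subject, labels,
                             fwhm_mm = 8, compute_reho = FALSE) {
  ses <- generate_session(spec, condition, phase, subject, labels)
  tr <- drop_initial_volumes(ses$series, ses$motion, spec$n_drop)
  gm <- labels$tissue == 1L
  qc <- compute_qc(tr$series, tr$motion, gm)
  keep <- exclusion_check(qc)
  pp <- preprocess_session(tr$series, tr$motion, labels$tissue, qc,
                           fwhm_mm = fwhm_mm)
  amap <- alff(pp, qc)
  roi <- labels$roi
  res <- list(
    qc_fraction = qc$flagged_fraction, keep = keep,
    alff_left = mean(amap[roi == 1L]),
    alff_right = mean(amap[roi == 2L]),
    fc_right = as.numeric(seed_fc(pp, roi, 2L, qc))
  )
  if (compute_reho) {
    w <- reho(pp, qc)
    res$reho_left <- mean(w[roi == 1L], na.rm = TRUE)
    res$reho_right <- mean(w[roi == 2L], na.rm = TRUE)
  }
  res
}

#' Run the full resting-state fMRI pipeline on a synthetic cohort
#'
#' For each subject, generates the four sessions of the crossover design
#' (real/sham x pre/post), runs volume QC and the preprocessing chain,
#' and extracts ROI ALFF (left/right seed), optionally ROI ReHo, and the
#' right-seed FC map. Subjects failing the motion-exclusion rule in any
#' session are dropped (and reported). It then tests the
#' Time-by-Stimulation interaction on right-seed log-ALFF and runs
#' sign-flip cluster inference on the FC difference maps inside the
#' baseline positive-connectivity mask.
#'
#' @param spec A [scan_spec()]; its `seed` separates cohorts.
#' @param n_subjects Number of crossover subjects.
#' @param n_perm Permutations for cluster inference.
#' @param cluster_forming_p Voxel-level threshold for cluster forming.
#' @param compute_reho Also extract ROI ReHo (slower).
#' @return A list: per-session QC table, excluded subjects, ROI tables,
#'   the interaction tests, and the `cluster_result` for right-seed FC.
#' @export
run_fmri_pipeline <- function(spec, n_subjects = 19, n_perm = 500,
                              cluster_forming_p = 0.01,
                              compute_reho = FALSE) {
  labels <- generate_labels(spec$dim)
  conds <- expand.grid(phase = c("pre", "post"),
                       condition = c("real", "sham"),
                       stringsAsFactors = FALSE)
  nvox <- prod(spec$dim)
  alff_tab <- NULL
  fc <- list()
  qc_tab <- NULL
  for (i in seq_len(n_subjects)) {
    for (k in seq_len(nrow(conds))) {
      cc <- conds$condition[k]; pp <- conds$phase[k]
      m <- .session_metrics(spec, cc, pp, i, labels,
                            compute_reho = compute_reho)
      row <- data.frame(subject = i, condition = cc, phase = pp,
                        qc_fraction = m$qc_fraction, keep = m$keep,
                        alff_left = m$alff_left, alff_right = m$alff_right)
      if (compute_reho) {
        row$reho_left <- m$reho_left; row$reho_right <- m$reho_right
      }
      alff_tab <- rbind(alff_tab, row)
      fc[[paste(i, cc, pp, sep = ".")]] <- m$fc_right
      qc_tab <- rbind(qc_tab, row[c("subject", "condition", "phase",
                                    "qc_fraction", "keep")])
    }
  }
  excluded <- unique(alff_tab$subject[!alff_tab$keep])
  keep_sub <- setdiff(seq_len(n_subjects), excluded)
  if (!length(keep_sub)) stop("all subjects excluded for motion")

  get <- function(sub, cond, ph, col)
    alff_tab[[col]][alff_tab$subject == sub &
                      alff_tab$condition == cond & alff_tab$phase == ph]
  d_alff <- function(col) {
    dr <- vapply(keep_sub, function(s)
      log(get(s, "real", "post", col)) - log(get(s, "real", "pre", col)),
      numeric(1))
    ds <- vapply(keep_sub, function(s)
      log(get(s, "sham", "post", col)) - log(get(s, "sham", "pre", col)),
      numeric(1))
    condition_contrast(dr, ds)
  }
  alff_right_test <- d_alff("alff_right")
  alff_left_test <- d_alff("alff_left")

  fc_mat <- function(cond, ph)
    do.call(rbind, lapply(keep_sub, function(s)
      fc[[paste(s, cond, ph, sep = ".")]]))
  d_fc <- (fc_mat("real", "post") - fc_mat("real", "pre")) -
    (fc_mat("sham", "post") - fc_mat("sham", "pre"))
  base <- (fc_mat("real", "pre") + fc_mat("sham", "pre")) / 2
  mask <- baseline_fc_mask(base, spec$dim)
  mask[labels$roi == 2L] <- FALSE  # the seed itself is not a finding
  clus <- cluster_inference(d_fc, spec$dim, mask = mask,
                            cluster_forming_p = cluster_forming_p,
                            n_perm = n_perm, seed = spec$seed)
  list(qc = qc_tab, excluded = excluded, roi = alff_tab,
       alff_right_test = alff_right_test, alff_left_test = alff_left_test,
       fc_delta = d_fc, baseline_mask = mask, clusters = clus,
       labels = labels,
       manifest = list(
         package_version = as.character(utils::packageVersion("ezstim")),
         seed = spec$seed, n_subjects = n_subjects, n_perm = n_perm,
         cluster_forming_p = cluster_forming_p, dim = spec$dim,
         n_volumes = spec$n_volumes, tr = spec$tr))
}
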