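test_that("cohort generation has the factorial layout and is seed-deterministic", {
  co <- cohort_spec(n_real = 3, n_sham = 2, trials_per_task = 25,
                    isi_levels = c(200, 400, 800, 1600, 3200), seed = 4)
  tr <- generate_trials(co)
  expect_equal(nrow(tr), 5 * 3 * 25)
  expect_equal(tr$reaction_time, tr$initiation_time + tr$movement_time,
               tolerance = 1e-3)
  expect_setequal(unique(tr$location),
                  c("upper-left", "lower-left", "upper-right", "lower-right"))
  # ISI balanced within every subject x task block
  tab <- table(tr$subject_id, tr$task, tr$isi)
  expect_true(all(tab == 5))
  expect_identical(tr, generate_trials(cohort_spec(
    n_real = 3, n_sham = 2, trials_per_task = 25,
    isi_levels = c(200, 400, 800, 1600, 3200), seed = 4)))
})

test_that("a subject's trials do not depend on cohort size (seed substreams)", {
  t_small <- generate_trials(cohort_spec(n_real = 2, n_sham = 1, seed = 8))
  t_large <- generate_trials(cohort_spec(n_real = 5, n_sham = 3, seed = 8))
  s1 <- t_small[t_small$subject_id == "S02", ]
  s2 <- t_large[t_large$subject_id == "S02", ]
  rownames(s1) <- rownames(s2) <- NULL
  expect_identical(s1, s2)
})

test_that("without contamination all initiation times are decision-driven", {
  co <- cohort_spec(n_real = 2, n_sham = 2, anticipation_rate = 0,
                    lapse_rate = 0, seed = 3)
  tr <- generate_trials(co)
  expect_true(all(tr$initiation_time > 150))
  expect_true(all(tr$error_type %in% c("none", "wrong-choice")))
  expect_identical(tr$correct, tr$error_type == "none")
})

test_that("contaminant trials land in their time windows and invalid rates are rejected", {
  co <- cohort_spec(n_real = 4, n_sham = 4, anticipation_rate = 0.1,
                    lapse_rate = 0.1, seed = 12)
  tr <- generate_trials(co)
  ant <- tr[tr$error_type == "anticipation", ]
  lap <- tr[tr$error_type == "lapse", ]
  expect_gt(nrow(ant), 0)
  expect_true(all(ant$initiation_time >= 50 & ant$initiation_time <= 149))
  expect_true(all(!ant$correct))
  expect_true(all(lap$initiation_time > 1000 & lap$initiation_time <= 2000))
  expect_error(cohort_spec(anticipation_rate = 0.6, lapse_rate = 0.5), "rates")
  expect_error(cohort_spec(trials_per_task = 76), "divisible")
})

test_that("a study-mimicking configuration pools 1400-1530 trials per cell", {
  # 20 real vs 21 sham subjects (one sham subject missing per task in the
  # emulated design), default contamination
  co <- cohort_spec(n_real = 20, n_sham = 21, seed = 9)
  filt <- filter_initiation_times(generate_trials(co))
  for (tk in c("FC", "UC", "UI")) for (g in c("real", "sham")) {
    n <- nrow(pool_across_subjects(filt, g, tk))
    expect_gte(n, 1400)
    expect_lte(n, 1530)
  }
})

test_that("trial CSV round-trips through write/read", {
  tr <- generate_trials(cohort_spec(n_real = 1, n_sham = 1, seed = 2))
  path <- tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(back$initiation_time, tr$initiation_time)
  expect_identical(back$correct, tr$correct)
  expect_identical(back$subject_id, tr$subject_id)
  expect_error(read_trials(write_trials(
    data.frame(x = 1), tempfile(fileext = ".csv"))), "missing columns")
})
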