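test_that("initiation-time filtering eliminates slow trials and marks anticipations", {
  tr <- data.frame(initiation_time = c(120, 500, 1200),
                   correct = c(TRUE, TRUE, TRUE),
                   error_type = "none")
  out <- filter_initiation_times(tr)
  expect_equal(nrow(out), 2)
  expect_identical(out$correct, c(FALSE, TRUE))
  expect_identical(out$error_type[1], "anticipation")
  expect_equal(unname(attr(out, "filter_counts")), c(1, 1))

  mid <- data.frame(initiation_time = c(200, 600, 999), correct = TRUE)
  expect_equal(filter_initiation_times(mid)$initiation_time, mid$initiation_time)

  slow <- data.frame(initiation_time = c(1200, 1500), correct = TRUE)
  expect_error(filter_initiation_times(slow), "no trials survive")
  expect_error(filter_initiation_times(tr[0, ]), "empty")
})

test_that("pooling concatenates matching subjects in stable order and converts to seconds", {
  tr <- data.frame(
    subject_id = rep(c("S02", "S01"), each = 3),
    group = "real", task = "FC",
    initiation_time = c(400, 500, 600, 300, 310, 320),
    correct = TRUE)
  pool <- pool_across_subjects(tr, "real", "FC")
  expect_equal(pool$it, c(0.300, 0.310, 0.320, 0.400, 0.500, 0.600))
  expect_error(pool_across_subjects(tr, "sham", "FC"), "no trials")
  one <- pool_across_subjects(tr[tr$subject_id == "S01", ], "real", "FC")
  expect_equal(nrow(one), 3)
})

test_that("the moment summary implements Pc, correct-trial moments, and the edge rule", {
  its <- c(rnorm(95, 0.48, sqrt(0.012)), rnorm(5, 0.4, 0.05))
  pool <- data.frame(it = its, correct = rep(c(TRUE, FALSE), c(95, 5)))
  s <- summarize_trials(pool)
  expect_equal(s$pc, 0.95)
  expect_equal(s$mrt, mean(its[1:95]))
  expect_equal(s$vrt, var(its[1:95]))

  all_right <- data.frame(it = rnorm(100, 0.5, 0.05), correct = TRUE)
  expect_equal(summarize_trials(all_right)$pc, 1 - 1 / 200)
  expect_error(summarize_trials(data.frame(it = 0.5, correct = TRUE)),
               "at least 2")
})

test_that("the estimator rejects its undefined domain", {
  expect_error(ez_fit(list(pc = 0.4, mrt = 0.5, vrt = 0.01)), "chance")
  expect_error(ez_fit(list(pc = 0.5, mrt = 0.5, vrt = 0.01)), "chance")
  expect_error(ez_fit(list(pc = 0.9, mrt = 0.5, vrt = 0)), "variance")
  expect_error(ez_forward(list(a = 1, v = 0, ter = 0.3)), "v = 0")
})

test_that("forward model reproduces the closed-form accuracy and decision time", {
  s <- ez_forward(list(a = 1, v = 2, ter = 0.3))
  expect_equal(s$pc, 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(s$mrt - 0.3, 0.25 * tanh(1), tolerance = 1e-12)
})

test_that("fit-forward round trip is exact over the admissible domain", {
  set.seed(42)
  n_draws <- 1000
  a <- runif(n_draws, 0.5, 2.5)
  v <- runif(n_draws, 0.5, 5)
  ter <- runif(n_draws, 0, 0.6)
  worst <- 0
  for (i in seq_len(n_draws)) {
    p <- ez_fit(ez_forward(list(a = a[i], v = v[i], ter = ter[i])))
    rel <- max(abs(p$a - a[i]) / a[i], abs(p$v - v[i]) / v[i],
               abs(p$ter - ter[i]) / max(ter[i], 1e-6))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-10)
})

test_that("forward-model variance matches an independent first-passage simulation", {
  spec <- ddm_spec(a = 1, v = 3.7, ter = 0.36, step_dt = 2.5e-4)
  fp <- sample_first_passage(spec, 60000, seed = 17)
  emp <- var(fp$decision_time[fp$hit_upper])
  th <- ez_forward(list(a = 1, v = 3.7, ter = 0.36))$vrt
  se <- sd((fp$decision_time[fp$hit_upper] - mean(fp$decision_time[fp$hit_upper]))^2) /
    sqrt(sum(fp$hit_upper))
  # 3 Monte-Carlo SE plus a margin for the Euler crossing bias
  expect_lt(abs(emp - th), 3 * se + 0.1 * th)
})

test_that("moments of a large simulated pool recover the generating parameters", {
  spec <- ddm_spec(a = 1, v = 3.7, ter = 0.36, step_dt = 2.5e-4)
  pool <- simulate_pool(spec, 100000, seed = 3)
  p <- ez_fit(summarize_trials(pool))
  expect_lt(abs(p$a - 1) / 1, 0.02)
  expect_lt(abs(p$v - 3.7) / 3.7, 0.02)
  expect_lt(abs(p$ter - 0.36), 0.005)
})

test_that("estimated drift and boundary grow with accuracy at fixed moments", {
  pcs <- c(0.8, 0.85, 0.9, 0.95)
  fits <- lapply(pcs, function(pc) ez_fit(list(pc = pc, mrt = 0.45, vrt = 0.012)))
  vs <- vapply(fits, `[[`, numeric(1), "v")
  as_ <- vapply(fits, `[[`, numeric(1), "a")
  expect_true(all(diff(vs) > 0))
  expect_true(all(diff(as_) > 0))
})

test_that("study-like pooled inputs give estimates in plausible ranges", {
  filt <- filter_initiation_times(generate_trials(cohort_spec(seed = 14)))
  for (tk in c("FC", "UC", "UI")) {
    p <- ez_fit(summarize_trials(pool_across_subjects(filt, "sham", tk)))
    expect_gt(p$a, 0.8); expect_lt(p$a, 1.3)
    expect_gt(p$v, 2.8); expect_lt(p$v, 4.8)
    expect_gt(p$ter, 0.30); expect_lt(p$ter, 0.40)
  }
})
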