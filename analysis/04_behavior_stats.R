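#!/usr/bin/env Rscript
# Descriptive behavioral statistics and the categorical blinding checks:
# per subject x task x location means and error rates; Pearson chi-square
# on the study's sham-blinding guess table (real: 14/20 correct guesses,
# sham: 13/22); two-proportion z test for the gender match.
#
# Reads results/trials.csv; writes results/subject_task_stats.csv and
# results/categorical_tests.json.

library(ezstim)

trials <- read_trials("results/trials.csv")
stats_tab <- aggregate_measures(trials)
write.csv(stats_tab, "results/subject_task_stats.csv", row.names = FALSE)

cat("mean reaction time by task (ms):\n")
print(round(tapply(stats_tab$mean_rt, stats_tab$task, mean, na.rm = TRUE), 1))
cat("mean error rate by task (%):\n")
print(round(tapply(stats_tab$error_rate, stats_tab$task, mean), 2))

# actual condition (rows) x guessed condition (columns)
guesses <- matrix(c(14, 9, 6, 13), 2,
                  dimnames = list(c("real", "sham"), c("guess real", "guess sham")))
chi <- chi_square_2x2(guesses)
zt <- two_proportion_z(14, 20, 14, 22)
cat(sprintf("\nblinding: chi2 = %.2f, p = %.4f (df = 1)\n", chi$chi2, chi$p))
cat(sprintf("gender match: z = %.2f, p = %.2f\n", zt$z, zt$p))

jsonlite::write_json(
  list(guessing = list(chi2 = chi$chi2, p = chi$p, df = chi$df),
       gender = list(z = zt$z, p = zt$p)),
  "results/categorical_tests.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/subject_task_stats.csv, results/categorical_tests.json\n")
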