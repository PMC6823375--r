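#!/usr/bin/env Rscript
# Simulate the behavioral experiment: two stimulation groups (20 real, 22
# sham), three choice-reaction-time tasks of 75 trials each (15 per ISI),
# initiation times from a first-passage diffusion process plus log-normal
# movement times, with anticipation/lapse contamination.
#
# Writes results/trials.csv (one row per trial).

library(ezstim)

seed <- 1L
cohort <- cohort_spec(seed = seed)
trials <- generate_trials(cohort)

dir.create("results", showWarnings = FALSE)
write_trials(trials, "results/trials.csv")

cat(sprintf("simulated %d trials (%d subjects x %d tasks x %d trials)\n",
            nrow(trials), cohort$n_real + cohort$n_sham,
            length(cohort$tasks), cohort$trials_per_task))
cat(sprintf("anticipations: %.1f%%  lapses: %.1f%%\n",
            100 * mean(trials$error_type == "anticipation"),
            100 * mean(trials$error_type == "lapse")))
cat("wrote results/trials.csv\n")
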