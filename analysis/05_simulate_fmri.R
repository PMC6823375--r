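#!/usr/bin/env Rscript
# Generate one example synthetic resting-state session per cell of the
# crossover design (real/sham x pre/post) and write it out as NIfTI-1
# volumes plus 6-column motion text, demonstrating the on-disk interface.
# The full-cohort analysis (06) generates its sessions in memory.
#
# Writes results/fmri_example/.

library(ezstim)

spec <- scan_spec(seed = 42)
labels <- generate_labels(spec$dim)
out <- "results/fmri_example"

for (cond in c("real", "sham")) for (ph in c("pre", "post")) {
  ses <- generate_session(spec, cond, ph, subject = 1, labels = labels)
  write_session(ses, out, prefix = paste0("sub01_", cond, "_", ph))
  cat(sprintf("%s/%s: %d spikes planted at volumes %s\n", cond, ph,
              length(attr(ses$motion, "spike_volumes")),
              paste(attr(ses$motion, "spike_volumes"), collapse = ", ")))
}
cat(sprintf("grid %s, %d volumes, TR %.1f s; planted effects on real/post:\n",
            paste(spec$dim, collapse = "x"), spec$n_volumes, spec$tr))
cat(sprintf("  right-seed variance x%.1f, cluster FC loading +%.1f\n",
            spec$alff_multiplier, spec$fc_increment))
cat("wrote", out, "\n")
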