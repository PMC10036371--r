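#!/usr/bin/env Rscript

# Step 2 — group-level detection across repeated blocks.
#
# Simulates a control group (17 subjects, 5 blocks, stationary component
# presence), runs the paired serial permutation t-tests (Tmax-corrected,
# one negative-tail pass for the MMN, one positive-tail pass for the P3a)
# and Bayes-factor timecourses per block and deviant, and tabulates
# presence decisions, significant intervals and effect sizes.
#
# Finding: with stationary presence, both the MMN and the P3a of every
# deviant are detected at the group level in every block by both methods,
# mirroring the reliability of group-level responses across a 12-hour
# session; Bayes evidence is mostly "very strong to extreme".

library(mmntrack)

dir.create("results", showWarnings = FALSE)
cfg <- paradigm_config(n_tones = 600, sampling_rate_hz = 125, seed = 42)
plan <- study_plan(n_subjects = 17, n_blocks = 5, seed = 42)
st <- run_study(cfg, plan)

write_tsv_table(st$group_ledger, "results/02_group_ledger.tsv")
write_tsv_table(st$amplitudes, "results/02_amplitudes.tsv")

grid <- report_detection_grid(st$group_ledger)
write_tsv_table(grid, "results/02_group_grid.tsv")
cat("Group-level presence grid (+/- permutation; Bayes strength symbols):\n")
print(as.data.frame(grid), row.names = FALSE)

es <- do.call(rbind, lapply(names(st$group), function(k) {
  g <- st$group[[k]]
  do.call(rbind, lapply(names(g$effect_sizes), function(comp) {
    e <- g$effect_sizes[[comp]]
    data.frame(cell = k, component = comp,
               peak_ms = e$peak_latency_ms,
               peak_uV = round(e$peak_amplitude_uV, 2),
               d_50 = round(e$d_50, 2), d_100 = round(e$d_100, 2))
  }))
}))
write_tsv_table(es, "results/02_effect_sizes.tsv")
cat("\nPeak-anchored effect sizes (first rows):\n")
print(utils::head(es, 8), row.names = FALSE)
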