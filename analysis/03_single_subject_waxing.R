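#!/usr/bin/env Rscript

# Step 3 — single-subject detection and the waxing/waning phenomenon.
#
# Runs trial-level independent permutation t-tests and Bayes factors for a
# single simulated subject under two scenarios: stationary component
# presence, and presence alternating across blocks (gain 1,0,1,0,1 — the
# "waxing and waning" control).  Tabulates per-block detection calls the
# way the per-patient tables are laid out (one row per block x deviant x
# component, one column per method).
#
# Finding: with full presence every block is called present; with
# alternating presence the per-block permutation and Bayes calls follow
# the programmed gains, i.e. the pipeline recovers block-to-block
# fluctuation when it is really there rather than smearing it out.

library(mmntrack)
library(dplyr)

dir.create("results", showWarnings = FALSE)
cfg <- paradigm_config(n_tones = 600, sampling_rate_hz = 125, seed = 7)
settings <- detection_settings()

run_scenario <- function(gains, tag) {
  led <- list()
  for (b in seq_along(gains)) {
    ep <- simulate_block(cfg, seed = derive_seed(7, b),
                         deviance_gain = gains[b],
                         subject_id = "P01", block_id = b)
    ep <- reject_artifacts(baseline_correct(ep))
    blk <- analyze_block(ep, settings, seed = derive_seed(7, b, 99))
    led[[b]] <- blk$ledger
  }
  led <- bind_rows(led)
  write_tsv_table(led, sprintf("results/03_ledger_%s.tsv", tag))
  grid <- report_detection_grid(led)
  write_tsv_table(grid, sprintf("results/03_grid_%s.tsv", tag))
  grid
}

cat("Scenario A: stationary presence (gain 1 in all 5 blocks)\n")
ga <- run_scenario(rep(1, 5), "stationary")
print(as.data.frame(ga[ga$deviant == "duration", ]), row.names = FALSE)

cat("\nScenario B: waxing/waning (gains 1,0,1,0,1)\n")
gb <- run_scenario(c(1, 0, 1, 0, 1), "waxing")
print(as.data.frame(gb[gb$deviant == "duration" & gb$component == "MMN", ]),
      row.names = FALSE)

cat("\nDuration-MMN permutation calls across blocks (scenario B):\n")
led_b <- read.delim("results/03_ledger_waxing.tsv")
calls <- led_b[led_b$deviant == "duration" & led_b$component == "MMN" &
                 led_b$method == "permutation", c("block_id", "present")]
print(calls, row.names = FALSE)
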