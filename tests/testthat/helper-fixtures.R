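# Shared fixture builders: small paradigms that keep the suite fast while
# preserving the statistical structure of the full 2,400-tone blocks.

quick_config <- function(n_tones = 300, fs = 200, seed = 1L, ...) {
  paradigm_config(n_tones = n_tones, sampling_rate_hz = fs, seed = seed, ...)
}

noiseless <- function(seed = 1L) noise_model(0, 0, 0, 1, seed = seed)

# One preprocessed block (baseline-corrected, artifact-flagged)
quick_block <- function(config = quick_config(), seed = 1L,
                        noise = noise_model(seed = seed), gain = 1) {
  ep <- simulate_block(config, noise = noise, seed = seed,
                       deviance_gain = gain)
  reject_artifacts(baseline_correct(ep))
}

# Simulate a group of subjects' evoked ROI difference material for one
# block; returns subjects x samples matrices for one deviant and standard.
quick_group_evoked <- function(n_subjects, config, deviant = "duration",
                               seed = 1L, subject_sd = 0.6,
                               gain = 1) {
  plan <- study_plan(n_subjects, 1, gain_schedule = gain,
                     subject_amplitude_sd = subject_sd, seed = seed)
  dev_m <- NULL; std_m <- NULL
  for (i in seq_len(nrow(plan))) {
    ep <- simulate_block(config, seed = plan$seed[i],
                         deviance_gain = plan$deviance_gain[i],
                         subject_id = plan$subject_id[i])
    ep <- reject_artifacts(baseline_correct(ep))
    ev <- average_by_condition(ep, c(deviant, "standard"))
    dev_m <- rbind(dev_m, roi_mean(ev[[deviant]]))
    std_m <- rbind(std_m, roi_mean(ev[["standard"]]))
  }
  list(dev = dev_m, std = std_m, time_ms = epoch_times(config))
}
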