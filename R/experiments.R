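# Monte-Carlo experiment drivers over the simulation + detection pipeline.
# These power the numbered analysis scripts and the acceptance checks; all
# randomness flows from one root seed via derived sub-streams.

#' Paradigm-composition summary of one generated block
#'
#' @param config a [paradigm_config()].
#' @param seed sequence seed.
#' @return list with per-condition `counts`, the realised `soa_ms`, and the
#'   total tone count.
#' @export
composition_check <- function(config = paradigm_config(), seed = 1L) {
  sq <- generate_sequence(config, seed = seed)
  soa <- unique(diff(sq$onset_ms))
  list(counts = sequence_counts(sq), soa_ms = soa, n_tones = nrow(sq))
}

# Internal: simulate one block and return band-limited baseline-corrected
# ROI trial matrices for one deviant and the standards.
block_roi_trials <- function(config, seed, gain, deviant = "duration",
                             band = c(0.1, 30), threshold_uV = 200) {
  ep <- simulate_block(config, seed = seed, deviance_gain = gain)
  ep <- reject_artifacts(baseline_correct(ep), threshold_uV)
  r <- roi_mean(ep)
  if (!is.null(band)) {
    r <- bandpass(r, band[1], band[2],
                  sampling_rate_hz = config$sampling_rate_hz)
  }
  list(dev = r[ep$condition == deviant & !ep$rejected, , drop = FALSE],
       std = r[ep$condition == "standard" & !ep$rejected, , drop = FALSE],
       time_ms = ep$time_ms)
}

#' Family-wise false-positive rate of the Tmax test under the null
#'
#' Repeatedly simulates blocks with presence gain 0 (deviant trials are
#' statistically identical to standards) and runs the single-subject
#' one-tailed Tmax-corrected test, recording how often any sample of the
#' epoch reaches corrected significance, and how often the per-block
#' presence decision (minimum-duration rule, component window) fires.
#'
#' @param n_sims number of null simulations.
#' @param config paradigm; defaults to a reduced 240-tone block at 200 Hz.
#' @param settings a [detection_settings()].
#' @param seed root seed.
#' @return list with `fwer` (any significant sample), `decision_rate`
#'   (presence decisions), `n_sims`, and the per-sim logical vectors.
#' @export
fwer_experiment <- function(n_sims = 200,
                            config = paradigm_config(n_tones = 240,
                                                     sampling_rate_hz = 200),
                            settings = detection_settings(), seed = 1L) {
  w <- settings$windows[[1]]
  any_sig <- logical(n_sims); decided <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    tr <- block_roi_trials(config, seed = derive_seed(seed, i), gain = 0,
                           band = settings$band)
    pr <- perm_ttest_serial(tr$dev, tr$std, design = "independent",
                            tail = w$polarity,
                            n_permutations = settings$n_permutations,
                            alpha = settings$alpha,
                            seed = derive_seed(seed, i, 2L),
                            time_ms = tr$time_ms,
                            var_equal = settings$var_equal)
    any_sig[i] <- any(pr$p_corr < settings$alpha)
    iv <- pr$significant_intervals
    decided[i] <- any(iv$end_ms >= w$search_window_ms[1] &
                        iv$start_ms <= w$search_window_ms[2] &
                        iv$duration_ms >= settings$min_duration_ms)
  }
  list(fwer = mean(any_sig), decision_rate = mean(decided),
       n_sims = n_sims, any_sig = any_sig, decided = decided)
}

#' Group-level power and effect-size recovery
#'
#' For each seed, simulates a control group, runs the paired Tmax test on
#' the subjects' evoked ROI series (deviant vs standard), applies the
#' presence decision for the MMN window, and extracts peak-anchored effect
#' sizes.  The programmed standardized window effect is
#' `1 / subject_amplitude_sd`.
#'
#' @param n_seeds number of simulated studies.
#' @param n_subjects subjects per study.
#' @param config paradigm; defaults to a reduced 400-tone block at 200 Hz.
#' @param subject_amplitude_sd between-subject amplitude SD.
#' @param settings a [detection_settings()].
#' @param seed root seed.
#' @return tibble with one row per seed: `detected`, `d_50`, `g_50`,
#'   `peak_latency_ms`; the programmed effect is in the
#'   `programmed_effect` attribute.
#' @export
power_experiment <- function(n_seeds = 100, n_subjects = 17,
                             config = paradigm_config(n_tones = 400,
                                                      sampling_rate_hz = 200),
                             subject_amplitude_sd = 0.6,
                             settings = detection_settings(), seed = 1L) {
  w <- settings$windows[[1]]
  rows <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    plan <- study_plan(n_subjects, 1, subject_amplitude_sd = subject_amplitude_sd,
                       seed = derive_seed(seed, s))
    dev_m <- matrix(NA_real_, n_subjects, length(epoch_times(config)))
    std_m <- dev_m
    for (i in seq_len(nrow(plan))) {
      ep <- simulate_block(config, seed = plan$seed[i],
                           deviance_gain = plan$deviance_gain[i],
                           subject_id = plan$subject_id[i])
      ep <- reject_artifacts(baseline_correct(ep))
      ev <- average_by_condition(ep, c("duration", "standard"))
      dv <- roi_mean(ev$duration); st <- roi_mean(ev$standard)
      if (!is.null(settings$band)) {
        f <- bandpass(rbind(dv, st), settings$band[1], settings$band[2],
                      sampling_rate_hz = config$sampling_rate_hz)
        dv <- f[1, ]; st <- f[2, ]
      }
      dev_m[i, ] <- dv; std_m[i, ] <- st
    }
    t_ms <- epoch_times(config)
    pr <- perm_ttest_serial(dev_m, std_m, design = "paired",
                            tail = w$polarity,
                            n_permutations = settings$n_permutations,
                            alpha = settings$alpha,
                            seed = derive_seed(seed, s, 2L), time_ms = t_ms)
    iv <- pr$significant_intervals
    detected <- any(iv$end_ms >= w$search_window_ms[1] &
                      iv$start_ms <= w$search_window_ms[2] &
                      iv$duration_ms >= settings$min_duration_ms)
    es <- effect_size(dev_m, std_m, "paired", w, t_ms)
    rows[[s]] <- tibble::tibble(seed = s, detected = detected,
                                d_50 = es$d_50, g_50 = es$g_50,
                                peak_latency_ms = es$peak_latency_ms)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "programmed_effect") <- 1 / subject_amplitude_sd
  out
}

#' Waxing/waning recovery across alternating-presence blocks
#'
#' Simulates a single subject recorded over several blocks whose
#' deviance-component presence alternates (`gains`), runs the
#' single-subject Tmax detection per block, and reports how often the full
#' per-block present/absent pattern is recovered.  The per-block Bayes
#' maximum is returned alongside for permutation/Bayes concordance
#' summaries.
#'
#' @param n_seeds number of simulated subjects.
#' @param gains per-block presence gains (default `c(1, 0, 1, 0, 1)`).
#' @param config paradigm; defaults to a reduced 500-tone block at 200 Hz.
#' @param settings a [detection_settings()].
#' @param seed root seed.
#' @return tibble with one row per seed x block: `block`, `gain`,
#'   `perm_present`, `max_bf10`, `pattern_correct` (per-seed constant).
#' @export
waxing_experiment <- function(n_seeds = 100, gains = c(1, 0, 1, 0, 1),
                              config = paradigm_config(n_tones = 500,
                                                       sampling_rate_hz = 200),
                              settings = detection_settings(), seed = 1L) {
  w <- settings$windows[[1]]
  rows <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    calls <- logical(length(gains)); bfs <- numeric(length(gains))
    for (b in seq_along(gains)) {
      tr <- block_roi_trials(config, seed = derive_seed(seed, s, b),
                             gain = gains[b], band = settings$band)
      pr <- perm_ttest_serial(tr$dev, tr$std, design = "independent",
                              tail = w$polarity,
                              n_permutations = settings$n_permutations,
                              alpha = settings$alpha,
                              seed = derive_seed(seed, s, b, 2L),
                              time_ms = tr$time_ms,
                              var_equal = settings$var_equal)
      iv <- pr$significant_intervals
      calls[b] <- any(iv$end_ms >= w$search_window_ms[1] &
                        iv$start_ms <= w$search_window_ms[2] &
                        iv$duration_ms >= settings$min_duration_ms)
      bs <- bayes_series(tr$dev, tr$std, "independent", window = w,
                         time_ms = tr$time_ms)
      bfs[b] <- bs$max_bf10
    }
    rows[[s]] <- tibble::tibble(seed = s, block = seq_along(gains),
                                gain = gains, perm_present = calls,
                                max_bf10 = bfs,
                                pattern_correct = all(calls == (gains > 0)))
  }
  dplyr::bind_rows(rows)
}
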