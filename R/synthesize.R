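#' Pink (1/f) noise series
#'
#' Spectrally shaped white noise: the DFT of a white series is multiplied by
#' an amplitude profile proportional to `1/sqrt(f)` (power spectral density
#' proportional to `1/f`, canonical pink noise), the DC term is zeroed, and
#' the result is rescaled so each series has the requested per-sample SD in
#' expectation.
#'
#' @param n_samples samples per series.
#' @param n_series number of independent series.
#' @param sd_uV target per-sample standard deviation.
#' @return numeric matrix, n_samples x n_series.
#' @export
pink_noise <- function(n_samples, n_series = 1, sd_uV = 1) {
  if (sd_uV == 0) return(matrix(0, n_samples, n_series))
  w <- matrix(stats::rnorm(n_samples * n_series), n_samples, n_series)
  k <- 0:(n_samples - 1)
  f_idx <- pmin(k, n_samples - k)          # symmetric frequency index
  amp <- ifelse(f_idx == 0, 0, 1 / sqrt(f_idx))
  amp <- amp / sqrt(mean(amp^2))           # unit per-sample variance (Parseval)
  # the filter is real and spectrally symmetric, so two real series can be
  # shaped per complex FFT: one in the real part, one in the imaginary part
  n_pair <- ceiling(n_series / 2)
  z <- matrix(0 + 0i, n_samples, n_pair)
  z[] <- complex(real = w[, seq_len(n_pair) * 2 - 1],
                 imaginary = if (n_series %% 2 == 0) {
                   w[, seq_len(n_pair) * 2]
                 } else {
                   cbind(w[, seq_len(n_pair - 1) * 2, drop = FALSE], 0)
                 })
  sh <- stats::mvfft(stats::mvfft(z) * amp, inverse = TRUE) / n_samples
  shaped <- matrix(0, n_samples, n_series)
  shaped[, seq(1, n_series, by = 2)] <- Re(sh)
  if (n_series > 1) {
    shaped[, seq(2, n_series, by = 2)] <- Im(sh[, seq_len(n_series %/% 2),
                                                drop = FALSE])
  }
  shaped * sd_uV
}

#' Synthesize an epochs set from a stimulus sequence
#'
#' One epoch per sequence event:
#' `epoch = (1 + jitter_t) * (obligatory + gain * deviance) + pink + white`,
#' where `gain = noise$block_presence_gain * deviance_gain` scales the
#' deviance-related components only.  Epochs are time-locked but baseline
#' *uncorrected* (baseline correction is a preprocessing step).  The draw
#' order (trial jitter, then white noise, then pink noise) is fixed, so a
#' given seed yields bit-identical output.
#'
#' @param sequence a `stimulus_sequence` from [generate_sequence()].
#' @param templates per-condition template pairs from
#'   [condition_templates()].
#' @param noise a [noise_model()].
#' @param config the [paradigm_config()] the templates were rendered on.
#' @param deviance_gain extra multiplier on deviance components (e.g. a
#'   subject-level amplitude factor); default 1.
#' @param subject_id,block_id identifiers stored in the result.
#' @return an `epochs_set`.
#' @export
synthesize_epochs <- function(sequence, templates, noise, config,
                              deviance_gain = 1,
                              subject_id = "S01", block_id = 1L) {
  stopifnot(inherits(noise, "noise_model"))
  conds <- unique(as.character(sequence$condition))
  missing <- setdiff(conds, names(templates))
  if (length(missing) > 0) {
    stopf("no template for condition(s): %s", paste(missing, collapse = ", "))
  }
  t_ms <- epoch_times(config)
  channels <- rownames(templates[[1]]$obligatory)
  n <- nrow(sequence); C <- length(channels); S <- length(t_ms)
  gain <- noise$block_presence_gain * deviance_gain

  arr <- array(0, c(n, C, S))
  with_seed(noise$seed, {
    jit <- 1 + stats::rnorm(n, 0, noise$trial_amplitude_jitter)
    for (cond in conds) {
      tm <- templates[[cond]]$obligatory + gain * templates[[cond]]$deviance
      idx <- which(sequence$condition == cond)
      arr[idx, , ] <- outer(jit[idx], as.vector(tm))
    }
    if (noise$white_sd_uV > 0) {
      arr <- arr + stats::rnorm(n * C * S, 0, noise$white_sd_uV)
    }
    if (noise$pink_sd_uV > 0) {
      pk <- pink_noise(S, n * C, noise$pink_sd_uV)
      arr <- arr + aperm(array(pk, c(S, n, C)), c(2, 3, 1))
    }
  })
  epochs_set(arr, channels, config$sampling_rate_hz, t_ms,
             as.character(sequence$condition), block_id, subject_id,
             post_deviant = sequence$post_deviant)
}

#' Simulate one recording block end to end
#'
#' Generates a stimulus sequence and synthesizes its epochs with
#' deterministic sub-stream seeds derived from `seed`.
#'
#' @param config a [paradigm_config()].
#' @param components per-condition component sets.
#' @param noise a [noise_model()]; its `seed` is overridden by a derived
#'   sub-stream seed.
#' @param seed root seed for this block.
#' @param deviance_gain multiplier on deviance components (subject-level
#'   amplitude times any block presence schedule).
#' @param subject_id,block_id identifiers.
#' @param channels montage.
#' @return an `epochs_set`.
#' @export
simulate_block <- function(config, components = default_components(),
                           noise = noise_model(), seed = config$seed,
                           deviance_gain = 1, subject_id = "S01",
                           block_id = 1L, channels = default_channels()) {
  sequence <- generate_sequence(config, seed = derive_seed(seed, 1L))
  templates <- condition_templates(config, components, channels)
  noise$seed <- derive_seed(seed, 2L)
  synthesize_epochs(sequence, templates, noise, config,
                    deviance_gain = deviance_gain,
                    subject_id = subject_id, block_id = block_id)
}

#' Plan a multi-subject, multi-block simulated study
#'
#' Lays out per-subject/per-block simulation parameters: independent derived
#' seeds, a block presence-gain schedule (the waxing/waning control), and
#' subject-level deviance-amplitude factors drawn as
#' `N(1, subject_amplitude_sd)`.  The implied programmed standardized group
#' effect for any deviance-component window mean is
#' `1 / subject_amplitude_sd`.
#'
#' @param n_subjects number of subjects.
#' @param n_blocks number of recording blocks per subject.
#' @param gain_schedule block presence gains: scalar, per-block vector, or
#'   subjects x blocks matrix.
#' @param subject_amplitude_sd SD of the subject-level amplitude factor
#'   (default 0.6).
#' @param seed root study seed.
#' @return tibble with one row per subject x block: `subject_id`, `block_id`,
#'   `subject_gain`, `presence_gain`, `deviance_gain`, `seed`.
#' @export
study_plan <- function(n_subjects = 17, n_blocks = 5, gain_schedule = 1,
                       subject_amplitude_sd = 0.6, seed = 1L) {
  gm <- if (is.matrix(gain_schedule)) {
    stopifnot(nrow(gain_schedule) == n_subjects,
              ncol(gain_schedule) == n_blocks)
    gain_schedule
  } else if (length(gain_schedule) == 1) {
    matrix(gain_schedule, n_subjects, n_blocks)
  } else {
    stopifnot(length(gain_schedule) == n_blocks)
    matrix(gain_schedule, n_subjects, n_blocks, byrow = TRUE)
  }
  sg <- with_seed(derive_seed(seed, 9001L),
                  stats::rnorm(n_subjects, 1, subject_amplitude_sd))
  grid <- expand.grid(block_id = seq_len(n_blocks),
                      subject = seq_len(n_subjects))
  tibble::tibble(
    subject_id = sprintf("S%02d", grid$subject),
    block_id = grid$block_id,
    subject_gain = sg[grid$subject],
    presence_gain = gm[cbind(grid$subject, grid$block_id)],
    deviance_gain = sg[grid$subject] * gm[cbind(grid$subject, grid$block_id)],
    seed = vapply(seq_len(nrow(grid)), function(i) {
      derive_seed(seed, grid$subject[i], grid$block_id[i])
    }, integer(1))
  )
}
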