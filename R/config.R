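#' Multi-deviant oddball paradigm configuration
#'
#' Describes one recording block of the auditory oddball paradigm: a regular
#' stream of tones in which rare duration, frequency and intensity deviants
#' are embedded among frequent standards.  Defaults follow the recorded
#' paradigm: 2,400 tones at a regular 450 ms stimulus onset asynchrony, 82%
#' standards and 6% of each deviant type, digitised at 512 Hz.
#'
#' @param n_tones total number of tone events in the block.
#' @param soa_ms stimulus onset asynchrony in milliseconds.
#' @param p_standard probability of a standard tone.
#' @param p_deviant named numeric vector of per-deviant probabilities; names
#'   are the deviant conditions.
#' @param tone_specs named list of physical tone descriptions (duration ms,
#'   frequency Hz, level dB SPL); metadata only, never used numerically.
#' @param sampling_rate_hz EEG sampling rate in Hz.
#' @param epoch_window_ms epoch span relative to tone onset, milliseconds.
#'   Sample times are `t_k = epoch_window_ms[1] + k * 1000 / sampling_rate_hz`.
#' @param seed integer seed controlling sequence randomisation.
#' @param min_standard_gap logical; if `TRUE` (default) at least one standard
#'   separates any two deviants.
#'
#' @return an object of class `paradigm_config`.
#' @export
paradigm_config <- function(n_tones = 2400,
                            soa_ms = 450,
                            p_standard = 0.82,
                            p_deviant = c(duration = 0.06,
                                          frequency = 0.06,
                                          intensity = 0.06),
                            tone_specs = default_tone_specs(),
                            sampling_rate_hz = 512,
                            epoch_window_ms = c(-100, 600),
                            seed = 1L,
                            min_standard_gap = TRUE) {
  if (!is_count(n_tones)) stopf("`n_tones` must be a positive integer")
  if (!is.numeric(soa_ms) || soa_ms <= 0) stopf("`soa_ms` must be > 0")
  if (is.null(names(p_deviant)) || any(names(p_deviant) == "")) {
    stopf("`p_deviant` must be a named vector of deviant probabilities")
  }
  tot <- p_standard + sum(p_deviant)
  if (abs(tot - 1) > 1e-12) {
    stopf("condition probabilities must sum to 1 (got %.15f)", tot)
  }
  if (sampling_rate_hz <= 0) stopf("`sampling_rate_hz` must be > 0")
  if (length(epoch_window_ms) != 2 || diff(epoch_window_ms) <= 0) {
    stopf("`epoch_window_ms` must be an increasing pair")
  }
  structure(
    list(n_tones = as.integer(n_tones), soa_ms = soa_ms,
         p_standard = p_standard, p_deviant = p_deviant,
         tone_specs = tone_specs, sampling_rate_hz = sampling_rate_hz,
         epoch_window_ms = epoch_window_ms, seed = as.integer(seed),
         min_standard_gap = isTRUE(min_standard_gap)),
    class = "paradigm_config"
  )
}

#' @export
print.paradigm_config <- function(x, ...) {
  cat("<paradigm_config>\n")
  cat(sprintf("  %d tones @ %g ms SOA, fs = %g Hz\n",
              x$n_tones, x$soa_ms, x$sampling_rate_hz))
  cat(sprintf("  P(standard) = %.2f; deviants: %s\n", x$p_standard,
              paste(sprintf("%s %.2f", names(x$p_deviant), x$p_deviant),
                    collapse = ", ")))
  invisible(x)
}

default_tone_specs <- function() {
  list(standard  = list(duration_ms = 50,  frequency_hz = 1000, level_db = 80),
       duration  = list(duration_ms = 125, frequency_hz = 1000, level_db = 80),
       frequency = list(duration_ms = 50,  frequency_hz = 1200, level_db = 80),
       intensity = list(duration_ms = 50,  frequency_hz = 1000, level_db = 90))
}

#' Sample times of the epoch grid
#'
#' @param config a [paradigm_config()].
#' @return numeric vector of per-sample times in ms relative to tone onset.
#' @export
epoch_times <- function(config) {
  span_s <- diff(config$epoch_window_ms) / 1000
  k <- 0:floor(span_s * config$sampling_rate_hz)
  config$epoch_window_ms[1] + k * (1000 / config$sampling_rate_hz)
}

#' ERP component specification
#'
#' A single evoked component modelled as a Gaussian pulse in time with a
#' per-channel gain.  Negative components (N1, MMN, DRN) must carry
#' non-positive peak amplitudes; positive components (P3a) non-negative.
#'
#' @param name component label, one of `"N1"`, `"MMN"`, `"DRN"`, `"P3a"`.
#' @param polarity `"negative"` or `"positive"`.
#' @param peak_latency_ms latency of the pulse maximum, ms post-stimulus.
#' @param width_ms Gaussian standard deviation of the pulse, ms.
#' @param amplitude_uV signed peak amplitude in microvolts.
#' @param channel_weights per-channel scalar gain; defaults to 1 for every
#'   channel (frontocentral-maximal montage).
#' @return an object of class `component_spec`.
#' @export
component_spec <- function(name, polarity, peak_latency_ms, width_ms,
                           amplitude_uV, channel_weights = NULL) {
  polarity <- match.arg(polarity, c("negative", "positive"))
  if (width_ms <= 0) stopf("`width_ms` must be > 0")
  if (polarity == "negative" && amplitude_uV > 0) {
    stopf("negative component '%s' must have amplitude_uV <= 0", name)
  }
  if (polarity == "positive" && amplitude_uV < 0) {
    stopf("positive component '%s' must have amplitude_uV >= 0", name)
  }
  structure(list(name = name, polarity = polarity,
                 peak_latency_ms = peak_latency_ms, width_ms = width_ms,
                 amplitude_uV = amplitude_uV,
                 channel_weights = channel_weights),
            class = "component_spec")
}

#' Default component sets per condition
#'
#' Standards carry the obligatory N1 only; deviant conditions add their
#' deviance-related components on top of the standard response, so the
#' noiseless deviant-minus-standard difference wave equals the deviance
#' components exactly.  The duration deviant carries a dissociated MMN
#' (peak 205 ms) and P3a (peak 300 ms); frequency and intensity deviants
#' carry an early deviant-related negativity (DRN, peak 105 ms, a fused
#' N1/MMN response) followed by a P3a.  Pulse widths (Gaussian SD 22 ms for
#' the negativities, 35 ms for the P3a) keep component overlap small enough
#' that each rendered peak stays within one sample of its configured
#' latency; amplitudes reproduce the reported ordering of deviant window
#' means (duration and intensity responses about 1.3 microvolts larger
#' than frequency).
#'
#' @return named list: per condition, a list with elements `obligatory` and
#'   `deviance`, each a list of [component_spec()]s.
#' @export
default_components <- function() {
  n1 <- component_spec("N1", "negative", 100, 22, -2)
  list(
    standard = list(obligatory = list(n1), deviance = list()),
    duration = list(
      obligatory = list(n1),
      deviance = list(
        component_spec("MMN", "negative", 205, 22, -3),
        component_spec("P3a", "positive", 300, 35, 3))),
    frequency = list(
      obligatory = list(n1),
      deviance = list(
        component_spec("DRN", "negative", 105, 22, -1.45),
        component_spec("P3a", "positive", 290, 35, 2))),
    intensity = list(
      obligatory = list(n1),
      deviance = list(
        component_spec("DRN", "negative", 105, 22, -3.07),
        component_spec("P3a", "positive", 290, 35, 2.2)))
  )
}

#' Background-noise and presence model for synthetic epochs
#'
#' @param white_sd_uV per-sample white-noise standard deviation, microvolts.
#' @param pink_sd_uV per-sample SD of the 1/f-shaped (pink) noise component.
#' @param trial_amplitude_jitter multiplicative trial-to-trial SD of the
#'   evoked template (0.2 = 20% amplitude variability).
#' @param block_presence_gain scalar in `[0, 1]` scaling deviance-related
#'   components only; 1 = component fully present, 0 = absent.  This is the
#'   control used to emulate block-to-block waxing and waning.
#' @param seed integer seed for the noise streams.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(white_sd_uV = 4, pink_sd_uV = 6,
                        trial_amplitude_jitter = 0.2,
                        block_presence_gain = 1, seed = 1L) {
  if (white_sd_uV < 0 || pink_sd_uV < 0 || trial_amplitude_jitter < 0) {
    stopf("noise SDs must be >= 0")
  }
  if (block_presence_gain < 0 || block_presence_gain > 1) {
    stopf("`block_presence_gain` must lie in [0, 1]")
  }
  structure(list(white_sd_uV = white_sd_uV, pink_sd_uV = pink_sd_uV,
                 trial_amplitude_jitter = trial_amplitude_jitter,
                 block_presence_gain = block_presence_gain,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Default recording montage
#'
#' Six frontocentral channels; these are also the default analysis region of
#' interest.
#' @return character vector of 10/20 channel names.
#' @export
default_channels <- function() c("F3", "Fz", "F4", "C3", "Cz", "C4")

#' Default frontocentral region of interest
#' @return character vector of ROI channel names.
#' @export
default_roi <- function() c("F3", "Fz", "F4", "C3", "Cz", "C4")

#' Component search windows used for detection
#'
#' The MMN is searched as the most negative peak within 80-230 ms (covering
#' both the early fused DRN of frequency/intensity deviants and the later
#' duration MMN); the P3a as the most positive peak within 250-350 ms.
#'
#' @param name `"MMN"` or `"P3a"`.
#' @param search_window_ms interval searched for the component peak.
#' @param polarity expected polarity of the component.
#' @return an object of class `component_window`.
#' @export
component_window <- function(name = c("MMN", "P3a"),
                             search_window_ms = NULL,
                             polarity = NULL) {
  name <- match.arg(name)
  if (is.null(search_window_ms)) {
    search_window_ms <- if (name == "MMN") c(80, 230) else c(250, 350)
  }
  if (is.null(polarity)) {
    polarity <- if (name == "MMN") "negative" else "positive"
  }
  polarity <- match.arg(polarity, c("negative", "positive"))
  if (length(search_window_ms) != 2 || diff(search_window_ms) <= 0) {
    stopf("`search_window_ms` must be an increasing pair")
  }
  structure(list(name = name, search_window_ms = search_window_ms,
                 polarity = polarity, effect_windows_ms = c(50, 100)),
            class = "component_window")
}
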