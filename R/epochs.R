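#' Construct an epochs set
#'
#' The central data container: a trials x channels x samples tensor of
#' baseline-referenced EEG segments with per-trial condition labels and
#' recording metadata.
#'
#' @param data 3-D numeric array, trials x channels x samples, microvolts.
#' @param channel_names ordered channel labels (10/20 system).
#' @param sampling_rate_hz sampling rate.
#' @param time_ms per-sample times relative to stimulus onset (ms).
#' @param condition per-trial condition label (character or factor).
#' @param block_id block identifier (scalar or per-trial).
#' @param subject_id subject identifier.
#' @param rejected per-trial logical artifact flags.
#' @param post_deviant optional per-trial logical: standard immediately
#'   following a deviant.
#' @return an object of class `epochs_set`.
#' @export
epochs_set <- function(data, channel_names, sampling_rate_hz, time_ms,
                       condition, block_id = 1L, subject_id = "S01",
                       rejected = NULL, post_deviant = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  n_trials <- dim(data)[1]
  if (dim(data)[2] != length(channel_names)) {
    stopf("channel dimension (%d) != length(channel_names) (%d)",
          dim(data)[2], length(channel_names))
  }
  if (dim(data)[3] != length(time_ms)) {
    stopf("sample dimension (%d) != length(time_ms) (%d)",
          dim(data)[3], length(time_ms))
  }
  dt <- diff(time_ms)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
    stopf("`time_ms` must be strictly increasing with uniform spacing")
  }
  if (abs(mean(dt) - 1000 / sampling_rate_hz) > 1e-6) {
    stopf("`time_ms` spacing inconsistent with sampling rate")
  }
  if (length(condition) != n_trials) {
    stopf("`condition` must have one label per trial")
  }
  rejected <- rejected %||% rep(FALSE, n_trials)
  stopifnot(length(rejected) == n_trials)
  structure(
    list(data = data, channel_names = channel_names,
         sampling_rate_hz = sampling_rate_hz, time_ms = time_ms,
         condition = as.character(condition),
         block_id = if (length(block_id) == 1) rep(block_id, n_trials) else block_id,
         subject_id = subject_id, rejected = as.logical(rejected),
         post_deviant = post_deviant %||% rep(FALSE, n_trials)),
    class = "epochs_set"
  )
}

#' @export
print.epochs_set <- function(x, ...) {
  cat("<epochs_set>\n")
  cat(sprintf("  subject %s, %d trial(s), %d channel(s), %d sample(s) @ %g Hz\n",
              x$subject_id, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$sampling_rate_hz))
  cat(sprintf("  epoch [%g, %g] ms; %d rejected\n", x$time_ms[1],
              x$time_ms[length(x$time_ms)], sum(x$rejected)))
  print(table(x$condition))
  invisible(x)
}

#' Number of trials in an epochs set
#' @param epochs an `epochs_set`.
#' @param unrejected count only artifact-free trials.
#' @return integer count.
#' @export
n_trials <- function(epochs, unrejected = FALSE) {
  if (unrejected) sum(!epochs$rejected) else dim(epochs$data)[1]
}

#' Subset an epochs set by trial index
#' @param epochs an `epochs_set`.
#' @param idx logical or integer trial index.
#' @return an `epochs_set` with the selected trials.
#' @export
subset_trials <- function(epochs, idx) {
  epochs_set(epochs$data[idx, , , drop = FALSE], epochs$channel_names,
             epochs$sampling_rate_hz, epochs$time_ms,
             epochs$condition[idx], epochs$block_id[idx],
             epochs$subject_id, epochs$rejected[idx],
             epochs$post_deviant[idx])
}

#' Segment continuous multichannel data into epochs around event markers
#'
#' @param x channels x samples numeric matrix of continuous data (microvolts).
#' @param sampling_rate_hz sampling rate of `x`.
#' @param onsets_ms event onset times, ms from recording start.
#' @param conditions per-event condition labels.
#' @param config a [paradigm_config()] supplying the epoch window.
#' @param channel_names channel labels for the rows of `x`.
#' @param ... passed to [epochs_set()] (`block_id`, `subject_id`, ...).
#' @return an `epochs_set`.
#' @export
epoch_continuous <- function(x, sampling_rate_hz, onsets_ms, conditions,
                             config, channel_names = rownames(x), ...) {
  stopifnot(is.matrix(x), length(onsets_ms) == length(conditions))
  t_rel <- epoch_times(config)
  n_s <- length(t_rel)
  dat <- array(NA_real_, c(length(onsets_ms), nrow(x), n_s))
  for (i in seq_along(onsets_ms)) {
    k0 <- round((onsets_ms[i] + t_rel[1]) * sampling_rate_hz / 1000) + 1
    ks <- k0 + seq_len(n_s) - 1
    if (ks[1] < 1 || ks[n_s] > ncol(x)) {
      stopf("event %d at %g ms: epoch window extends beyond the recording",
            i, onsets_ms[i])
    }
    dat[i, , ] <- x[, ks]
  }
  epochs_set(dat, channel_names, sampling_rate_hz, t_rel, conditions, ...)
}
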