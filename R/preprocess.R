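#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward-backward
#' ([signal::filtfilt()]), giving zero phase distortion and doubled
#' attenuation.  Defaults reproduce the offline analysis band of
#' 0.1-30 Hz.
#'
#' @param x an `epochs_set`, a channels x samples matrix, or a numeric
#'   vector.
#' @param low_hz,high_hz band edges in Hz.
#' @param sampling_rate_hz required when `x` is not an `epochs_set`.
#' @param order filter order (per band edge) before the forward-backward
#'   pass.
#' @return object of the same shape as `x`, filtered along time.
#' @export
bandpass <- function(x, low_hz = 0.1, high_hz = 30,
                     sampling_rate_hz = NULL, order = 4) {
  if (inherits(x, "epochs_set")) {
    flt <- design_bandpass(low_hz, high_hz, x$sampling_rate_hz, order)
    d <- x$data
    n <- dim(d)[1]; C <- dim(d)[2]; S <- dim(d)[3]
    # all trial x channel series as columns of one samples x series matrix
    m <- matrix(aperm(d, c(3, 1, 2)), S, n * C)
    m <- filtfilt_mat(flt, m)
    x$data <- aperm(array(m, c(S, n, C)), c(2, 3, 1))
    return(x)
  }
  fs <- sampling_rate_hz
  if (is.null(fs)) stopf("`sampling_rate_hz` is required for matrix/vector input")
  flt <- design_bandpass(low_hz, high_hz, fs, order)
  if (is.matrix(x)) {
    t(filtfilt_mat(flt, t(x)))
  } else {
    drop(filtfilt_mat(flt, matrix(x, length(x), 1)))
  }
}

design_bandpass <- function(low_hz, high_hz, fs, order) {
  nyq <- fs / 2
  if (high_hz >= nyq) {
    stopf("high cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
          high_hz, nyq)
  }
  if (low_hz <= 0 || low_hz >= high_hz) stopf("need 0 < low_hz < high_hz")
  signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
}

# Zero-phase IIR filtering of every column of a samples x series matrix:
# one forward and one time-reversed pass with zero initial conditions,
# vectorised across columns via stats::filter.
filtfilt_mat <- function(flt, m) {
  b <- flt$b; a <- flt$a
  one_pass <- function(M) {
    pad <- matrix(0, length(b) - 1, ncol(M))
    tmp <- stats::filter(rbind(pad, M), b, method = "convolution", sides = 1)
    tmp <- tmp[-seq_len(nrow(pad)), , drop = FALSE]
    out <- stats::filter(tmp, -a[-1], method = "recursive")
    matrix(out, nrow(M), ncol(M))
  }
  rev_rows <- function(M) M[rev(seq_len(nrow(M))), , drop = FALSE]
  rev_rows(one_pass(rev_rows(one_pass(m))))
}

#' Baseline-correct every trial and channel
#'
#' Subtracts, per trial and channel, the mean over the pre-stimulus baseline
#' window from the whole epoch.
#'
#' @param epochs an `epochs_set`.
#' @param window_ms baseline window, default `c(-100, 0)`.
#' @return the corrected `epochs_set`.
#' @export
baseline_correct <- function(epochs, window_ms = c(-100, 0)) {
  stopifnot(inherits(epochs, "epochs_set"))
  idx <- which(epochs$time_ms >= window_ms[1] & epochs$time_ms <= window_ms[2])
  if (length(idx) == 0) {
    stopf("baseline window [%g, %g] ms contains no samples",
          window_ms[1], window_ms[2])
  }
  d <- dim(epochs$data)
  m <- matrix(epochs$data, d[1] * d[2], d[3])  # rows = trial x channel
  bl <- rowMeans(m[, idx, drop = FALSE])
  epochs$data <- array(m - bl, d)
  epochs
}

#' Flag trials containing non-ocular artifacts
#'
#' A trial is flagged when any channel's peak-to-peak amplitude within the
#' epoch exceeds the threshold.  Flagged trials are excluded from all
#' downstream statistics; counts are recorded in the `rejection_log`
#' attribute.
#'
#' @param epochs an `epochs_set`.
#' @param threshold_uV peak-to-peak rejection threshold, microvolts
#'   (default 200).
#' @return the `epochs_set` with updated `rejected` flags.
#' @export
reject_artifacts <- function(epochs, threshold_uV = 200) {
  stopifnot(inherits(epochs, "epochs_set"))
  if (threshold_uV <= 0) stopf("`threshold_uV` must be > 0")
  d <- dim(epochs$data)
  m <- matrix(epochs$data, d[1] * d[2], d[3])
  mx <- m[, 1]; mn <- m[, 1]
  for (j in seq_len(d[3])[-1]) {       # running per-row extrema
    mx <- pmax(mx, m[, j]); mn <- pmin(mn, m[, j])
  }
  ptp <- matrix(mx - mn, d[1], d[2])
  flag <- apply(ptp, 1, max) > threshold_uV
  epochs$rejected <- flag
  lev <- sort(unique(epochs$condition))
  attr(epochs, "rejection_log") <- tibble::tibble(
    condition = lev,
    n_total = as.integer(table(factor(epochs$condition, levels = lev))),
    n_rejected = as.integer(table(factor(epochs$condition[flag],
                                         levels = lev)))
  )
  epochs
}

#' Average unrejected trials per condition
#'
#' @param epochs an `epochs_set`.
#' @param conditions conditions to average; default all present.
#' @return named list of `evoked_response` objects (channels x samples
#'   matrices with metadata), one per condition.
#' @export
average_by_condition <- function(epochs, conditions = NULL) {
  stopifnot(inherits(epochs, "epochs_set"))
  conditions <- conditions %||% unique(epochs$condition)
  out <- lapply(conditions, function(cond) {
    idx <- which(epochs$condition == cond & !epochs$rejected)
    if (length(idx) == 0) {
      stopf("condition '%s' (subject %s, block %s) has no unrejected trials",
            cond, epochs$subject_id, epochs$block_id[1])
    }
    m <- colMeans(epochs$data[idx, , , drop = FALSE])  # channels x samples
    rownames(m) <- epochs$channel_names
    structure(
      list(data = m, n_trials_averaged = length(idx), condition = cond,
           block_id = epochs$block_id[1], subject_id = epochs$subject_id,
           time_ms = epochs$time_ms,
           sampling_rate_hz = epochs$sampling_rate_hz),
      class = "evoked_response"
    )
  })
  stats::setNames(out, conditions)
}

#' @export
print.evoked_response <- function(x, ...) {
  cat(sprintf("<evoked_response> %s (subject %s, block %s): %d trials, %d ch x %d samples\n",
              x$condition, x$subject_id, x$block_id, x$n_trials_averaged,
              nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Standard preprocessing chain for one block
#'
#' Filter (optional for synthetic data already inside the band), baseline
#' correction, artifact rejection, and per-condition averaging, in that
#' order.
#'
#' @param epochs an `epochs_set`.
#' @param band band edges in Hz, or `NULL` to skip filtering.
#' @param baseline_ms baseline window.
#' @param threshold_uV rejection threshold.
#' @return list with `epochs` (processed set) and `evoked` (per-condition
#'   list).
#' @export
preprocess_block <- function(epochs, band = NULL, baseline_ms = c(-100, 0),
                             threshold_uV = 200) {
  if (!is.null(band)) epochs <- bandpass(epochs, band[1], band[2])
  epochs <- baseline_correct(epochs, baseline_ms)
  epochs <- reject_artifacts(epochs, threshold_uV)
  list(epochs = epochs, evoked = average_by_condition(epochs))
}
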