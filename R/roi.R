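#' Region-of-interest mean series
#'
#' Unweighted mean across the ROI channels at every sample.  The default ROI
#' is the six frontocentral electrodes (F3, Fz, F4, C3, Cz, C4).
#'
#' @param x an `epochs_set` (returns trials x samples), an
#'   `evoked_response` or a channels x samples matrix (returns a numeric
#'   series).
#' @param roi character vector of ROI channel names.
#' @return trials x samples matrix, or numeric vector, with a `time_ms`
#'   attribute when available.
#' @export
roi_mean <- function(x, roi = default_roi()) {
  if (inherits(x, "epochs_set")) {
    ci <- match(roi, x$channel_names)
    if (anyNA(ci)) {
      stopf("ROI channel(s) %s not present; available: %s",
            paste(roi[is.na(ci)], collapse = ", "),
            paste(x$channel_names, collapse = ", "))
    }
    out <- colMeans(aperm(x$data[, ci, , drop = FALSE], c(2, 1, 3)))
    attr(out, "time_ms") <- x$time_ms
    return(out)
  }
  m <- if (inherits(x, "evoked_response")) x$data else x
  stopifnot(is.matrix(m))
  ci <- match(roi, rownames(m))
  if (anyNA(ci)) {
    stopf("ROI channel(s) %s not present; available: %s",
          paste(roi[is.na(ci)], collapse = ", "),
          paste(rownames(m), collapse = ", "))
  }
  out <- colMeans(m[ci, , drop = FALSE])
  attr(out, "time_ms") <- if (inherits(x, "evoked_response")) x$time_ms else
    attr(x, "time_ms")
  out
}
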