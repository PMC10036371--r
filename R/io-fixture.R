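#' Write an epochs set as a portable fixture dataset
#'
#' A directory containing the epochs tensor in Feather (Arrow) columnar
#' binary — one row per trial x channel, one column per sample — and a JSON
#' sidecar with channels, sampling rate, time grid, per-trial labels and
#' any configuration echo.  Round-trips losslessly (doubles are preserved
#' bit-for-bit by the Arrow format).
#'
#' @param epochs an `epochs_set`.
#' @param path directory to create.
#' @param config optional configuration echoed into the sidecar.
#' @return `path`, invisibly.
#' @export
write_fixture_dataset <- function(epochs, path, config = NULL) {
  stopifnot(inherits(epochs, "epochs_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- epochs$data
  n <- dim(d)[1]; C <- dim(d)[2]; S <- dim(d)[3]
  flat <- matrix(aperm(d, c(2, 1, 3)), n * C, S)  # row = (channel within trial)
  df <- data.frame(trial = rep(seq_len(n), each = C),
                   channel = rep(epochs$channel_names, n))
  mat <- as.data.frame(flat)
  names(mat) <- sprintf("s%04d", seq_len(S))
  arrow::write_feather(cbind(df, mat), file.path(path, "epochs.feather"))
  meta <- list(
    channels = epochs$channel_names,
    sampling_rate_hz = epochs$sampling_rate_hz,
    time_ms = epochs$time_ms,
    condition = epochs$condition,
    block_id = epochs$block_id,
    subject_id = epochs$subject_id,
    rejected = epochs$rejected,
    post_deviant = epochs$post_deviant,
    config = config
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a fixture dataset back into an epochs set
#'
#' @param path fixture directory written by [write_fixture_dataset()].
#' @return an `epochs_set`; any config echo is attached as the `config`
#'   attribute.
#' @export
read_fixture_dataset <- function(path) {
  tab <- as.data.frame(arrow::read_feather(file.path(path, "epochs.feather")))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  C <- length(meta$channels)
  S <- length(meta$time_ms)
  n <- nrow(tab) / C
  flat <- as.matrix(tab[, -(1:2)])
  d <- aperm(array(flat, c(C, n, S)), c(2, 1, 3))
  out <- epochs_set(d, meta$channels, meta$sampling_rate_hz, meta$time_ms,
                    meta$condition, meta$block_id, meta$subject_id,
                    meta$rejected, meta$post_deviant)
  attr(out, "config") <- meta$config
  out
}
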