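# Minimal EDF(+) reader/writer.  No R EDF package is available, so the
# format is handled directly: fixed 256-byte ASCII header, 256 bytes per
# signal header, 16-bit little-endian samples record by record.  Event
# markers use the EDF+ "EDF Annotations" signal (time-stamped annotation
# lists).  Supports continuous recordings with one sampling rate across
# ordinary signals, which is all the pipeline needs.

pad_ascii <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  sprintf("%-*s", width, x)
}

#' Write continuous multichannel data as an EDF+ file
#'
#' @param x channels x samples numeric matrix (microvolts).
#' @param path output file.
#' @param sampling_rate_hz sampling rate; the number of samples must be a
#'   multiple of it (whole 1-second records).
#' @param channel_names labels for the rows of `x`.
#' @param events optional data frame with `onset_ms` and `label` written as
#'   EDF+ annotations.
#' @param patient,recording free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(x, path, sampling_rate_hz,
                      channel_names = rownames(x), events = NULL,
                      patient = "X", recording = "synthetic") {
  stopifnot(is.matrix(x))
  fs <- sampling_rate_hz
  if (ncol(x) %% fs != 0) {
    stopf("sample count (%d) must be a whole number of 1-second records",
          ncol(x))
  }
  n_rec <- ncol(x) / fs
  nc <- nrow(x)
  has_ann <- !is.null(events)
  ns <- nc + has_ann

  # digital/physical scaling per channel
  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  same <- pmax_ - pmin_ < 1e-9
  pmin_[same] <- pmin_[same] - 1; pmax_[same] <- pmax_[same] + 1
  dmin <- -32768; dmax <- 32767

  ann_spr <- 0L
  ann_recs <- NULL
  if (has_ann) {
    ann_recs <- lapply(seq_len(n_rec) - 1, function(r) {
      # TALs are nul-terminated; R strings cannot hold nul bytes, so the
      # stream is assembled as integer byte values
      bytes <- c(utf8ToInt(sprintf("+%g\x14\x14", r)), 0L)  # record timestamp
      ev <- events[events$onset_ms >= r * 1000 &
                     events$onset_ms < (r + 1) * 1000, , drop = FALSE]
      for (k in seq_len(nrow(ev))) {
        bytes <- c(bytes,
                   utf8ToInt(sprintf("+%g\x14%s\x14", ev$onset_ms[k] / 1000,
                                     ev$label[k])), 0L)
      }
      bytes
    })
    ann_spr <- as.integer(ceiling(max(vapply(ann_recs, length, integer(1))) / 2))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    pad_ascii("0", 8), pad_ascii(patient, 80), pad_ascii(recording, 80),
    "01.01.26", "00.00.00", pad_ascii(hdr_bytes, 8),
    pad_ascii(if (has_ann) "EDF+C" else "", 44),
    pad_ascii(n_rec, 8), pad_ascii("1", 8), pad_ascii(ns, 4)
  ), con, eos = NULL)
  labels <- c(channel_names, if (has_ann) "EDF Annotations")
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, pad_ascii, "", width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(labels, 16)
  field(rep("", ns), 80)                                   # transducer
  field(c(rep("uV", nc), if (has_ann) ""), 8)              # physical dim
  field(c(sprintf("%.6g", pmin_), if (has_ann) "-1"), 8)
  field(c(sprintf("%.6g", pmax_), if (has_ann) "1"), 8)
  field(c(rep(dmin, nc), if (has_ann) dmin), 8)
  field(c(rep(dmax, nc), if (has_ann) dmax), 8)
  field(rep("", ns), 80)                                   # prefiltering
  field(c(rep(fs, nc), if (has_ann) ann_spr), 8)
  field(rep("", ns), 32)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (c in seq_len(nc)) {
      dig <- round((x[c, cols] - pmin_[c]) * scale[c]) + dmin
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
    if (has_ann) {
      bytes <- ann_recs[[r]]
      bytes <- c(bytes, rep(0L, 2 * ann_spr - length(bytes)))
      writeBin(as.raw(bytes), con)
    }
  }
  invisible(path)
}

#' Read an EDF(+) file
#'
#' @param path EDF file.
#' @return list with `data` (channels x samples matrix, physical units),
#'   `sampling_rate_hz`, `channel_names`, `events` (tibble `onset_ms`,
#'   `label`; empty when the file has no annotation signal).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                         # version
  rd(80); rd(80); rd(8); rd(8)  # patient, recording, date, time
  rd(8)                         # header bytes
  rd(44)                        # reserved / EDF+ flag
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80)
  rdv(8)                        # physical dimension
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)

  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  data <- lapply(sig_idx, function(i) numeric(0))
  ann_raw <- raw(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        ann_raw <- c(ann_raw, readBin(con, "raw", 2 * spr[i]))
      } else {
        dig <- readBin(con, "integer", spr[i], size = 2, endian = "little")
        j <- match(i, sig_idx)
        data[[j]] <- c(data[[j]], dig)
      }
    }
  }
  mat <- do.call(rbind, lapply(seq_along(sig_idx), function(j) {
    i <- sig_idx[j]
    (data[[j]] - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i]) + pmin_[i]
  }))
  rownames(mat) <- labels[sig_idx]
  fs <- spr[sig_idx[1]] / rec_dur

  events <- tibble::tibble(onset_ms = numeric(0), label = character(0))
  if (any(is_ann)) {
    txt <- rawToChar(ann_raw[ann_raw != as.raw(0)])
    tals <- strsplit(txt, "\x14", fixed = TRUE)[[1]]
    # TAL stream alternates "+onset" and "label"; record timestamps carry
    # empty labels and are dropped
    ons <- NULL; labs <- NULL; pending <- NA_real_
    for (tok in tals) {
      if (grepl("^[+-][0-9.]+$", tok)) {
        pending <- as.numeric(tok)
      } else if (nzchar(tok) && !is.na(pending)) {
        ons <- c(ons, pending * 1000); labs <- c(labs, tok)
        pending <- NA_real_
      }
    }
    if (length(ons) > 0) events <- tibble::tibble(onset_ms = ons, label = labs)
  }
  list(data = mat, sampling_rate_hz = fs,
       channel_names = labels[sig_idx], events = events)
}

#' Read an EDF+ recording straight into epochs
#'
#' Segments the continuous EDF data around its annotation markers.
#'
#' @param path EDF file.
#' @param config a [paradigm_config()] (epoch window; its sampling rate
#'   must match the file).
#' @param label_map named vector mapping annotation labels to condition
#'   names; by default labels are used as conditions directly.
#' @param ... passed to [epochs_set()].
#' @return an `epochs_set`.
#' @export
read_edf_epochs <- function(path, config, label_map = NULL, ...) {
  e <- read_edf(path)
  if (abs(e$sampling_rate_hz - config$sampling_rate_hz) > 1e-6) {
    stopf("EDF sampling rate (%g) differs from configuration (%g)",
          e$sampling_rate_hz, config$sampling_rate_hz)
  }
  if (nrow(e$events) == 0) stopf("EDF file carries no event annotations")
  conds <- if (is.null(label_map)) e$events$label else label_map[e$events$label]
  epoch_continuous(e$data, e$sampling_rate_hz, e$events$onset_ms, conds,
                   config, channel_names = e$channel_names, ...)
}
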