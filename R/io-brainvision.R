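# Minimal BrainVision (.vhdr/.vmrk/.eeg) reader/writer.  The header and
# marker files are INI-style text; the data file holds multiplexed binary
# samples (IEEE_FLOAT_32 or INT_16 with per-channel resolution).  No R
# reader for the format is available, so it is parsed directly.

parse_ini <- function(lines) {
  sec <- NULL; out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      out[[sec]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && !is.null(sec)) {
      kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
      out[[sec]][[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  out
}

#' Write continuous data in BrainVision format
#'
#' Emits the `.vhdr` header, `.vmrk` marker file and multiplexed binary
#' `.eeg` data file.
#'
#' @param x channels x samples matrix (microvolts).
#' @param basename output path without extension.
#' @param sampling_rate_hz sampling rate.
#' @param channel_names row labels of `x`.
#' @param markers optional data frame with `onset_ms` and `label`
#'   (`Stimulus` markers).
#' @param binary_format `"IEEE_FLOAT_32"` or `"INT_16"`.
#' @return the `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(x, basename, sampling_rate_hz,
                              channel_names = rownames(x), markers = NULL,
                              binary_format = c("IEEE_FLOAT_32", "INT_16")) {
  binary_format <- match.arg(binary_format)
  stopifnot(is.matrix(x))
  stem <- basename(basename)
  vhdr <- paste0(basename, ".vhdr")
  res <- rep(1, nrow(x))
  if (binary_format == "INT_16") {
    res <- pmax(apply(abs(x), 1, max), 1e-12) / 32000  # uV per digital unit
  }
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", stem),
    sprintf("MarkerFile=%s.vmrk", stem),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nrow(x)),
    sprintf("SamplingInterval=%.9g", 1e6 / sampling_rate_hz),
    "[Binary Infos]",
    sprintf("BinaryFormat=%s", binary_format),
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%.9g,uV", seq_len(nrow(x)), channel_names, res)
  )
  writeLines(hdr, vhdr)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Common Infos]", sprintf("DataFile=%s.eeg", stem),
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  if (!is.null(markers) && nrow(markers) > 0) {
    pos <- round(markers$onset_ms * sampling_rate_hz / 1000) + 1
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(markers)) + 1, markers$label, pos))
  }
  writeLines(mk, paste0(basename, ".vmrk"))
  con <- file(paste0(basename, ".eeg"), "wb")
  on.exit(close(con))
  if (binary_format == "IEEE_FLOAT_32") {
    writeBin(as.numeric(x), con, size = 4, endian = "little")  # multiplexed
  } else {
    dig <- round(sweep(x, 1, res, "/"))
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(vhdr)
}

#' Read a BrainVision recording
#'
#' @param vhdr path to the `.vhdr` header file.
#' @return list with `data` (channels x samples, microvolts),
#'   `sampling_rate_hz`, `channel_names`, `markers` (tibble `onset_ms`,
#'   `label`, `type`).
#' @export
read_brainvision <- function(vhdr) {
  ini <- parse_ini(readLines(vhdr, warn = FALSE))
  ci <- ini[["Common Infos"]]
  if (!identical(ci$DataFormat, "BINARY") ||
      !identical(ci$DataOrientation, "MULTIPLEXED")) {
    stopf("only BINARY MULTIPLEXED BrainVision data are supported")
  }
  nc <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)
  fmt <- ini[["Binary Infos"]]$BinaryFormat
  chan <- ini[["Channel Infos"]]
  chn <- character(nc); res <- rep(1, nc)
  for (i in seq_len(nc)) {
    parts <- strsplit(chan[[sprintf("Ch%d", i)]], ",")[[1]]
    chn[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) res[i] <- as.numeric(parts[3])
  }
  dir <- dirname(vhdr)
  eeg <- file.path(dir, ci$DataFile)
  sz <- file.info(eeg)$size
  con <- file(eeg, "rb")
  on.exit(close(con))
  if (identical(fmt, "IEEE_FLOAT_32")) {
    raw_v <- readBin(con, "numeric", sz / 4, size = 4, endian = "little")
  } else if (identical(fmt, "INT_16")) {
    raw_v <- readBin(con, "integer", sz / 2, size = 2, endian = "little")
  } else {
    stopf("unsupported BinaryFormat '%s'", fmt)
  }
  ns <- length(raw_v) / nc
  mat <- matrix(raw_v, nc, ns) * res
  rownames(mat) <- chn

  markers <- tibble::tibble(onset_ms = numeric(0), label = character(0),
                            type = character(0))
  vmrk <- file.path(dir, ci$MarkerFile %||% "")
  if (nzchar(ci$MarkerFile %||% "") && file.exists(vmrk)) {
    mi <- parse_ini(readLines(vmrk, warn = FALSE))[["Marker Infos"]]
    rows <- lapply(mi, function(v) strsplit(v, ",")[[1]])
    keep <- vapply(rows, function(p) length(p) >= 3 && p[1] != "New Segment",
                   logical(1))
    rows <- rows[keep]
    if (length(rows) > 0) {
      markers <- tibble::tibble(
        onset_ms = unname(vapply(rows, function(p) as.numeric(p[3]), 0) - 1) *
          1000 / fs,
        label = unname(vapply(rows, function(p) p[2], "")),
        type = unname(vapply(rows, function(p) p[1], ""))
      )
    }
  }
  list(data = mat, sampling_rate_hz = fs, channel_names = chn,
       markers = markers)
}

#' Read a BrainVision recording straight into epochs
#'
#' @param vhdr path to the `.vhdr` file.
#' @param config a [paradigm_config()] (epoch window; sampling rates must
#'   match).
#' @param label_map optional named vector mapping marker labels to
#'   condition names.
#' @param ... passed to [epochs_set()].
#' @return an `epochs_set`.
#' @export
read_brainvision_epochs <- function(vhdr, config, label_map = NULL, ...) {
  b <- read_brainvision(vhdr)
  if (abs(b$sampling_rate_hz - config$sampling_rate_hz) > 1e-6) {
    stopf("BrainVision sampling rate (%g) differs from configuration (%g)",
          b$sampling_rate_hz, config$sampling_rate_hz)
  }
  if (nrow(b$markers) == 0) stopf("no stimulus markers found")
  conds <- if (is.null(label_map)) b$markers$label else label_map[b$markers$label]
  epoch_continuous(b$data, b$sampling_rate_hz, b$markers$onset_ms, conds,
                   config, channel_names = b$channel_names, ...)
}
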