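#' Evidence-strength symbol for a Bayes factor
#'
#' `+` anecdotal, `++` moderate, `+++` strong, `++++` very strong to
#' extreme, `-` evidence favouring the null.
#'
#' @param bf10 Bayes factor (vectorised).
#' @return character symbols.
#' @export
bf_symbol <- function(bf10) {
  vapply(bf10, function(b) {
    if (is.na(b)) return("n/a")
    switch(classify_evidence(b),
           "favors-null" = "-", "anecdotal" = "+", "moderate" = "++",
           "strong" = "+++", "very strong" = "++++", "extreme" = "++++")
  }, character(1))
}

#' Render a per-block presence grid
#'
#' One row per subject x block x deviant x component; one column per
#' method.  Permutation and manual-visual cells show `+`/`-`; Bayes cells
#' show the evidence-strength symbols.  Methods absent from the ledger are
#' rendered `n/a`.
#'
#' @param ledger detection ledger tibble.
#' @return tibble grid (also printed nicely by `print()`).
#' @export
report_detection_grid <- function(ledger) {
  led <- ledger
  led$symbol <- ifelse(led$method == "bayes",
                       ifelse(led$present, bf_symbol(led$strength), "-"),
                       ifelse(led$present, "+", "-"))
  wide <- tidyr::pivot_wider(
    led[, c("subject_id", "block_id", "deviant", "component", "method",
            "symbol")],
    names_from = "method", values_from = "symbol")
  for (m in c("manual-visual", "permutation", "bayes")) {
    if (!m %in% names(wide)) wide[[m]] <- "n/a"
    wide[[m]][is.na(wide[[m]])] <- "n/a"
  }
  cols <- c("subject_id", "block_id", "deviant", "component",
            "manual-visual", "permutation", "bayes")
  wide[, cols]
}

#' Write a tibble as a tab-separated file
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export significant intervals as BED-like half-open rows
#'
#' @param perm a `perm_result`.
#' @param path output path.
#' @param name interval label.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(perm, path, name = "significant") {
  iv <- perm$significant_intervals
  dt <- if (length(perm$time_ms) > 1) perm$time_ms[2] - perm$time_ms[1] else 0
  bed <- data.frame(chrom = "epoch", start_ms = iv$start_ms,
                    end_ms = iv$end_ms + dt, name = name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export an evoked response as a channel x time TSV table
#'
#' @param evoked an `evoked_response`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_evoked_tsv <- function(evoked, path) {
  m <- evoked$data
  df <- data.frame(channel = rownames(m), m, check.names = FALSE)
  names(df)[-1] <- sprintf("%.6g", evoked$time_ms)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
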