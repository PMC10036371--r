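#' Per-block presence decision for one component
#'
#' Operationalises the per-method present/absent calls.  Permutation
#' presence: at least `min_duration_ms` of contiguous Tmax-significant
#' samples (the test's tail already encodes the component polarity)
#' intersecting the component search window.  Bayes presence: maximum BF10
#' within the window at or above `bf_threshold`.  Manual-visual decisions,
#' if supplied, are merged as a third method.
#'
#' @param perm a `perm_result` for this block/deviant, run with the tail
#'   matching the component polarity.
#' @param bayes a `bayes_series` for the same block/deviant (its window
#'   maximum must have been taken in the component window).
#' @param window the [component_window()] being decided.
#' @param subject_id,block_id,deviant identifiers for the ledger row.
#' @param min_duration_ms minimum contiguous significant duration (default
#'   10 ms; set 0 to accept single-sample intervals).
#' @param bf_threshold Bayes presence threshold (default 3, the lower edge
#'   of "moderate" evidence).
#' @param manual optional one-row data frame with columns `present` and
#'   `annotator` (and optionally `strength`) carrying a visual-inspection
#'   call for this cell.
#' @return tibble, one row per method, columns `subject_id`, `block_id`,
#'   `deviant`, `component`, `method`, `present`, `strength`, `annotator`.
#' @export
decide_presence <- function(perm, bayes, window, subject_id, block_id,
                            deviant, min_duration_ms = 10,
                            bf_threshold = 3, manual = NULL) {
  stopifnot(inherits(perm, "perm_result"), inherits(bayes, "bayes_series"),
            inherits(window, "component_window"))
  if (!is.null(perm$cell) && !is.null(bayes$cell) &&
      !identical(perm$cell, bayes$cell)) {
    stopf("permutation and Bayes results refer to different block/deviant cells (%s vs %s)",
          paste(perm$cell, collapse = "/"), paste(bayes$cell, collapse = "/"))
  }
  iv <- perm$significant_intervals
  hit <- iv[iv$end_ms >= window$search_window_ms[1] &
              iv$start_ms <= window$search_window_ms[2] &
              iv$duration_ms >= min_duration_ms, , drop = FALSE]
  perm_present <- nrow(hit) > 0
  # window maximum recomputed from the BF10 series so one bayes_series can
  # serve several component windows
  widx <- which(bayes$time_ms >= window$search_window_ms[1] &
                  bayes$time_ms <= window$search_window_ms[2])
  max_bf <- if (length(widx) > 0) max(bayes$bf10[widx]) else bayes$max_bf10
  bayes_present <- max_bf >= bf_threshold
  out <- tibble::tibble(
    subject_id = subject_id, block_id = block_id, deviant = deviant,
    component = window$name,
    method = c("permutation", "bayes"),
    present = c(perm_present, bayes_present),
    strength = c(min(perm$p_corr), max_bf),
    annotator = NA_character_
  )
  if (!is.null(manual)) {
    if (is.null(manual$annotator) || is.na(manual$annotator[1]) ||
        !nzchar(manual$annotator[1])) {
      stopf("manual-visual decisions must carry an annotator tag")
    }
    out <- dplyr::bind_rows(out, tibble::tibble(
      subject_id = subject_id, block_id = block_id, deviant = deviant,
      component = window$name, method = "manual-visual",
      present = as.logical(manual$present[1]),
      strength = as.numeric(manual$strength[1] %||% NA_real_),
      annotator = as.character(manual$annotator[1])
    ))
  }
  out
}

#' Read manual-visual annotations from CSV
#'
#' Expected columns: `subject_id`, `block_id` (or `block`), `deviant`,
#' `component`, `present`, `annotator`, optional `strength`.
#'
#' @param path CSV file path.
#' @return tibble of annotations.
#' @export
read_annotations <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("block" %in% names(x) && !"block_id" %in% names(x)) {
    names(x)[names(x) == "block"] <- "block_id"
  }
  need <- c("subject_id", "block_id", "deviant", "component", "present",
            "annotator")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stopf("annotation file lacks column(s): %s", paste(miss, collapse = ", "))
  }
  x$present <- as.logical(x$present)
  tibble::as_tibble(x)
}

#' Merge manual-visual annotations into a detection ledger
#'
#' @param ledger a detection ledger tibble (from [decide_presence()] rows).
#' @param annotations tibble from [read_annotations()].
#' @return the ledger with `manual-visual` rows appended.
#' @export
merge_annotations <- function(ledger, annotations) {
  ann <- annotations
  ann$method <- "manual-visual"
  if (!"strength" %in% names(ann)) ann$strength <- NA_real_
  dplyr::bind_rows(ledger,
                   ann[, c("subject_id", "block_id", "deviant", "component",
                           "method", "present", "strength", "annotator")])
}
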