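#' Detection settings
#'
#' Bundles the tunables of the detection stage.
#'
#' @param roi ROI channel names.
#' @param windows list of [component_window()]s to decide.
#' @param n_permutations permutations for the Tmax test.
#' @param alpha significance level.
#' @param bf_threshold Bayes presence threshold.
#' @param min_duration_ms minimum contiguous significant duration.
#' @param band analysis band in Hz applied (zero-phase) to the ROI series
#'   entering the statistics; `NULL` to skip.
#' @param exclude_post_deviant_standards drop standards that immediately
#'   follow a deviant from the standard set.
#' @param var_equal pooled-variance Student t instead of Welch for
#'   independent designs.
#' @return list of settings.
#' @export
detection_settings <- function(roi = default_roi(),
                               windows = list(component_window("MMN"),
                                              component_window("P3a")),
                               n_permutations = 1000, alpha = 0.05,
                               bf_threshold = 3, min_duration_ms = 10,
                               exclude_post_deviant_standards = FALSE,
                               var_equal = FALSE, band = c(0.1, 30)) {
  list(roi = roi, windows = windows, n_permutations = n_permutations,
       alpha = alpha, bf_threshold = bf_threshold,
       min_duration_ms = min_duration_ms,
       exclude_post_deviant_standards = exclude_post_deviant_standards,
       var_equal = var_equal, band = band)
}

#' Single-subject detection for one block
#'
#' Runs, for every deviant condition present, independent-samples serial
#' permutation t-tests across trials (deviant vs standard; one negative-tail
#' pass for the MMN, one positive-tail pass for the P3a), the Bayes-factor
#' timecourse, and the presence decisions for each component window.
#'
#' @param epochs a baseline-corrected `epochs_set` (artifact flags
#'   respected).
#' @param settings a [detection_settings()].
#' @param seed RNG seed for the permutation resampling.
#' @return list with `ledger` (decision tibble), `results` (per deviant:
#'   `perm` per component, `bayes`), `evoked_diff` (per deviant ROI
#'   difference series).
#' @export
analyze_block <- function(epochs, settings = detection_settings(),
                          seed = 1L) {
  stopifnot(inherits(epochs, "epochs_set"))
  conds <- setdiff(unique(epochs$condition), "standard")
  if (!"standard" %in% epochs$condition) {
    stopf("block contains no standard trials")
  }
  keep_std <- epochs$condition == "standard" & !epochs$rejected
  if (settings$exclude_post_deviant_standards) {
    keep_std <- keep_std & !epochs$post_deviant
  }
  roi_tr <- roi_mean(epochs, settings$roi)
  if (!is.null(settings$band)) {
    roi_tr <- bandpass(roi_tr, settings$band[1], settings$band[2],
                       sampling_rate_hz = epochs$sampling_rate_hz)
  }
  std <- roi_tr[keep_std, , drop = FALSE]
  if (nrow(std) == 0) stopf("all standard trials rejected")
  t_ms <- epochs$time_ms

  ledger <- list(); results <- list(); evoked_diff <- list()
  for (dv in conds) {
    idx <- epochs$condition == dv & !epochs$rejected
    if (!any(idx)) stopf("all '%s' trials rejected", dv)
    dev <- roi_tr[idx, , drop = FALSE]
    cell <- list(subject = epochs$subject_id, block = epochs$block_id[1],
                 deviant = dv)
    bs <- bayes_series(dev, std, design = "independent", time_ms = t_ms)
    bs$cell <- cell
    res <- list(bayes = bs, perm = list())
    dfw <- colMeans(dev) - colMeans(std)
    attr(dfw, "time_ms") <- t_ms
    evoked_diff[[dv]] <- dfw
    for (w in settings$windows) {
      pr <- perm_ttest_serial(
        dev, std, design = "independent", tail = w$polarity,
        n_permutations = settings$n_permutations, alpha = settings$alpha,
        seed = derive_seed(seed, match(dv, conds), match(w$name, c("MMN", "P3a"))),
        time_ms = t_ms, var_equal = settings$var_equal)
      pr$cell <- cell
      res$perm[[w$name]] <- pr
      ledger[[paste(dv, w$name)]] <- decide_presence(
        pr, bs, w, subject_id = epochs$subject_id,
        block_id = epochs$block_id[1], deviant = dv,
        min_duration_ms = settings$min_duration_ms,
        bf_threshold = settings$bf_threshold)
    }
    results[[dv]] <- res
  }
  list(ledger = dplyr::bind_rows(ledger), results = results,
       evoked_diff = evoked_diff)
}

#' Group-level detection across subjects
#'
#' Paired serial permutation t-tests across subjects' evoked ROI series
#' (deviant vs standard), Bayes timecourses, effect sizes, and presence
#' decisions, for one block and deviant.
#'
#' @param dev_mat,std_mat subjects x samples matrices of evoked ROI series.
#' @param time_ms per-sample times.
#' @param settings a [detection_settings()].
#' @param block_id,deviant identifiers.
#' @param seed RNG seed.
#' @return list with `ledger`, `perm` (per component), `bayes`,
#'   `effect_sizes` (per component).
#' @export
analyze_group <- function(dev_mat, std_mat, time_ms,
                          settings = detection_settings(),
                          block_id = 1L, deviant = "duration", seed = 1L) {
  cell <- list(subject = "group", block = block_id, deviant = deviant)
  bs <- bayes_series(dev_mat, std_mat, design = "paired", time_ms = time_ms)
  bs$cell <- cell
  ledger <- list(); perm <- list(); esz <- list()
  for (w in settings$windows) {
    pr <- perm_ttest_serial(
      dev_mat, std_mat, design = "paired", tail = w$polarity,
      n_permutations = settings$n_permutations, alpha = settings$alpha,
      seed = derive_seed(seed, match(w$name, c("MMN", "P3a"))),
      time_ms = time_ms)
    pr$cell <- cell
    perm[[w$name]] <- pr
    esz[[w$name]] <- effect_size(dev_mat, std_mat, design = "paired",
                                 window = w, time_ms = time_ms)
    ledger[[w$name]] <- decide_presence(
      pr, bs, w, subject_id = "group", block_id = block_id, deviant = deviant,
      min_duration_ms = settings$min_duration_ms,
      bf_threshold = settings$bf_threshold)
  }
  list(ledger = dplyr::bind_rows(ledger), perm = perm, bayes = bs,
       effect_sizes = esz)
}

#' Simulate and analyse a full multi-subject, multi-block study
#'
#' Streams over the [study_plan()]: each subject x block is simulated,
#' preprocessed (baseline correction, artifact rejection, per-condition
#' averaging) and reduced to evoked ROI difference series; optionally each
#' block also gets the single-subject trial-level detection.  Group-level
#' paired detection is then run per block x deviant.
#'
#' @param config a [paradigm_config()].
#' @param plan a [study_plan()].
#' @param components per-condition component sets.
#' @param noise a [noise_model()] (its seed/presence gain are overridden
#'   per block from the plan).
#' @param settings a [detection_settings()].
#' @param single_subject also run trial-level detection per block (slower).
#' @param threshold_uV artifact-rejection threshold.
#' @return list with `group_ledger`, `single_ledger` (may be empty),
#'   `amplitudes` (mean-amplitude tibble), `group` (per block x deviant
#'   analyze_group results), `plan`.
#' @export
run_study <- function(config, plan = study_plan(),
                      components = default_components(),
                      noise = noise_model(),
                      settings = detection_settings(),
                      single_subject = FALSE, threshold_uV = 200) {
  t_ms <- epoch_times(config)
  deviants <- names(config$p_deviant)
  blocks <- sort(unique(plan$block_id))
  subjects <- unique(plan$subject_id)

  # evoked ROI series store: [[block]][[condition]] -> subject x sample
  evoked <- lapply(blocks, function(b) list())
  names(evoked) <- as.character(blocks)
  single_ledger <- list()
  amp_rows <- list()
  aw <- amplitude_export_windows()

  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    epochs <- simulate_block(config, components, noise, seed = row$seed,
                             deviance_gain = row$deviance_gain,
                             subject_id = row$subject_id,
                             block_id = row$block_id)
    epochs <- baseline_correct(epochs)
    epochs <- reject_artifacts(epochs, threshold_uV)
    ev <- average_by_condition(epochs)
    for (cond in names(ev)) {
      r <- roi_mean(ev[[cond]], settings$roi)
      if (!is.null(settings$band)) {
        r <- drop(bandpass(matrix(r, 1), settings$band[1], settings$band[2],
                           sampling_rate_hz = config$sampling_rate_hz))
      }
      bkey <- as.character(row$block_id)
      evoked[[bkey]][[cond]] <-
        rbind(evoked[[bkey]][[cond]], matrix(r, 1, length(r)))
    }
    bkey <- as.character(row$block_id)
    last_row <- function(cond) {
      m <- evoked[[bkey]][[cond]]
      m[nrow(m), ]
    }
    for (dv in intersect(deviants, names(ev))) {
      dfw <- last_row(dv) - last_row("standard")
      w <- aw[[dv]] %||% c(80, 230)
      amp_rows[[length(amp_rows) + 1]] <- tibble::tibble(
        subject_id = row$subject_id, deviant = dv, block = row$block_id,
        mean_amplitude_uV = window_mean_amplitude(dfw, w, t_ms))
    }
    if (single_subject) {
      blk <- analyze_block(epochs, settings, seed = derive_seed(row$seed, 77L))
      single_ledger[[i]] <- blk$ledger
    }
  }

  group <- list(); group_ledger <- list()
  for (b in as.character(blocks)) {
    for (dv in deviants) {
      if (is.null(evoked[[b]][[dv]])) next
      g <- analyze_group(evoked[[b]][[dv]], evoked[[b]][["standard"]], t_ms,
                         settings, block_id = as.integer(b), deviant = dv,
                         seed = derive_seed(config$seed, as.integer(b),
                                            match(dv, deviants)))
      group[[paste(b, dv)]] <- g
      group_ledger[[paste(b, dv)]] <- g$ledger
    }
  }
  list(group_ledger = dplyr::bind_rows(group_ledger),
       single_ledger = dplyr::bind_rows(single_ledger),
       amplitudes = dplyr::bind_rows(amp_rows),
       group = group, plan = plan)
}
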