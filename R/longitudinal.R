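#' Amplitude export windows per deviant
#'
#' +/-50 ms around the group-average component peak: 180-230 ms for the
#' duration MMN, 80-130 ms for the fused deviant-related negativity of
#' frequency and intensity deviants.
#'
#' @return named list of `c(start, end)` windows in ms.
#' @export
amplitude_export_windows <- function() {
  list(duration = c(180, 230), frequency = c(80, 130), intensity = c(80, 130))
}

#' Build the subject x deviant x block mean-amplitude table
#'
#' @param diffs named nested list `diffs[[subject]][[block]][[deviant]]` of
#'   ROI difference series (deviant - standard) with `time_ms` attributes,
#'   or a tibble already holding `subject_id`, `deviant`, `block`,
#'   `mean_amplitude_uV`.
#' @param windows per-deviant export windows; default
#'   [amplitude_export_windows()].
#' @return tibble with one row per cell: `subject_id`, `deviant`, `block`,
#'   `mean_amplitude_uV`.
#' @export
amplitude_table <- function(diffs, windows = amplitude_export_windows()) {
  if (is.data.frame(diffs)) return(tibble::as_tibble(diffs))
  rows <- list()
  for (subj in names(diffs)) {
    for (blk in names(diffs[[subj]])) {
      for (dev in names(diffs[[subj]][[blk]])) {
        w <- windows[[dev]]
        if (is.null(w)) stopf("no export window for deviant '%s'", dev)
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject_id = subj, deviant = dev, block = as.integer(blk),
          mean_amplitude_uV = window_mean_amplitude(diffs[[subj]][[blk]][[dev]], w)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Deviant x block repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Two-way within-subject ANOVA (subject as random factor) on the
#' mean-amplitude table, fitted as a multivariate linear model with
#' [car::Anova()].  Reports, per effect, the F statistic, nominal and
#' Greenhouse-Geisser-adjusted degrees of freedom, the sphericity estimate
#' epsilon, uncorrected and GG-corrected p-values, and partial eta squared
#' (`SS_effect / (SS_effect + SS_error)`).  Only complete cases (subjects
#' with every deviant x block cell) enter; dropped subjects are listed in
#' the `dropped_subjects` attribute.  Bonferroni pairwise post-hoc
#' comparisons on the deviant marginal means (averaged over blocks) are
#' attached when the deviant main effect is significant.
#'
#' @param table amplitude tibble with columns `subject_id`, `deviant`,
#'   `block`, `mean_amplitude_uV`.
#' @param alpha significance level gating the post-hoc tests.
#' @param force_posthoc run the post-hocs regardless of significance.
#' @return an object of class `anova_table`: tibble of effects plus
#'   `posthoc` attribute (tibble of `pair`, `mean_difference_uV`, `p_raw`,
#'   `p_bonferroni`; sign convention: first-named minus second-named level).
#' @export
rm_anova <- function(table, alpha = 0.05, force_posthoc = FALSE) {
  tb <- tibble::as_tibble(table)
  need <- c("subject_id", "deviant", "block", "mean_amplitude_uV")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stopf("amplitude table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  tb$deviant <- factor(tb$deviant)
  tb$block <- factor(tb$block)
  kd <- nlevels(tb$deviant); kb <- nlevels(tb$block)
  if (kd < 2 || kb < 2) stopf("both factors need at least 2 levels")
  if (anyDuplicated(tb[, c("subject_id", "deviant", "block")])) {
    stopf("amplitude table has duplicate subject x deviant x block cells")
  }

  # complete cases: listwise deletion of subjects missing any cell
  cnt <- table(tb$subject_id)
  complete <- names(cnt)[cnt == kd * kb]
  dropped <- setdiff(unique(tb$subject_id), complete)
  tb <- tb[tb$subject_id %in% complete, ]
  n <- length(complete)
  if (n < 3) stopf("need at least 3 complete-case subjects (have %d)", n)

  # wide matrix: columns ordered deviant (slow) x block (fast)
  tb <- tb[order(tb$subject_id, tb$deviant, tb$block), ]
  Y <- matrix(tb$mean_amplitude_uV, nrow = n, byrow = TRUE,
              dimnames = list(sort(complete), NULL))
  idata <- data.frame(deviant = factor(rep(levels(tb$deviant), each = kb)),
                      block = factor(rep(levels(tb$block), kd)))

  fit <- stats::lm(Y ~ 1)
  av <- car::Anova(fit, idata = idata, idesign = ~ deviant * block,
                   type = "III")
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests

  # Greenhouse-Geisser epsilon per effect, from the error SSCP of the
  # orthonormal (polynomial) contrast space; computed here rather than
  # taken from the summary so that effects with few error df still get
  # the standard estimate
  Cd <- stats::contr.poly(kd); Cb <- stats::contr.poly(kb)
  dj <- rep(seq_len(kd), each = kb); bj <- rep(seq_len(kb), kd)
  contr <- list(
    "deviant" = Cd[dj, , drop = FALSE],
    "block" = Cb[bj, , drop = FALSE],
    "deviant:block" = Cd[dj, rep(seq_len(kd - 1), kb - 1), drop = FALSE] *
      Cb[bj, rep(seq_len(kb - 1), each = kd - 1), drop = FALSE])
  gg_eps <- function(M) {
    Z <- Y %*% M
    E <- crossprod(sweep(Z, 2, colMeans(Z)))
    tr <- sum(diag(E))
    if (tr < 1e-12) return(1)
    tr^2 / (ncol(M) * sum(E * E))
  }

  effects <- c("deviant", "block", "deviant:block")
  res <- lapply(effects, function(ef) {
    ss <- ut[ef, "Sum Sq"]; sse <- ut[ef, "Error SS"]
    df1 <- ut[ef, "num Df"]; df2 <- ut[ef, "den Df"]
    degenerate <- ss < 1e-12 && sse < 1e-12
    Fv <- if (degenerate) 0 else ut[ef, "F value"]
    p <- if (degenerate) 1 else ut[ef, "Pr(>F)"]
    eps <- gg_eps(contr[[ef]])
    p_gg <- if (degenerate) 1 else
      stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
    tibble::tibble(
      effect = ef, F = Fv, df_num = df1, df_den = df2,
      epsilon_gg = eps, df_num_gg = df1 * eps, df_den_gg = df2 * eps,
      p_uncorrected = p, p_gg = p_gg,
      eta_p_sq = if (ss + sse > 0) ss / (ss + sse) else 0,
      ss_effect = ss, ss_error = sse
    )
  })
  out <- dplyr::bind_rows(res)

  dev_sig <- out$p_gg[out$effect == "deviant"] < alpha
  posthoc <- NULL
  if (isTRUE(dev_sig) || force_posthoc) {
    # marginal means per subject, averaged over the levels of block
    marg <- vapply(levels(tb$deviant), function(dv) {
      rowMeans(Y[, idata$deviant == dv, drop = FALSE])
    }, numeric(n))
    prs <- utils::combn(levels(tb$deviant), 2)
    n_cmp <- ncol(prs)
    posthoc <- dplyr::bind_rows(lapply(seq_len(n_cmp), function(j) {
      d <- marg[, prs[1, j]] - marg[, prs[2, j]]
      tt <- stats::t.test(d)
      tibble::tibble(
        pair = paste(prs[1, j], prs[2, j], sep = " - "),
        mean_difference_uV = mean(d),
        p_raw = tt$p.value,
        p_bonferroni = min(1, tt$p.value * n_cmp)
      )
    }))
  }
  structure(out, class = c("anova_table", class(out)),
            posthoc = posthoc, n_subjects = n, dropped_subjects = dropped)
}

#' Detection-rate table across blocks
#'
#' Per block x deviant x component x method: the proportion of subjects
#' called present.  Subjects lacking a block are excluded from that block's
#' denominator.
#'
#' @param ledger detection ledger tibble ([decide_presence()] rows).
#' @return tibble with `block_id`, `deviant`, `component`, `method`,
#'   `n_subjects`, `n_present`, `proportion_present`.
#' @export
detection_rates <- function(ledger) {
  stopifnot(nrow(ledger) > 0)
  dplyr::summarise(
    dplyr::group_by(ledger, .data$block_id, .data$deviant, .data$component,
                    .data$method),
    n_subjects = dplyr::n_distinct(.data$subject_id),
    n_present = sum(.data$present),
    proportion_present = mean(.data$present),
    .groups = "drop"
  )
}
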