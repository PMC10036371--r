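#' Generate a pseudo-random oddball stimulus sequence
#'
#' Places exactly `round(n_tones * p)` tones of each deviant condition (any
#' rounding remainder goes to standards) at a regular SOA.  Deviant
#' positions are drawn uniformly at random subject, by default, to the
#' constraint that at least one standard separates any two deviants; the
#' constrained sequence is built by shuffling deviant labels into the gaps
#' of a standard backbone, which makes every admissible arrangement equally
#' likely.
#'
#' @param config a [paradigm_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return a tibble of class `stimulus_sequence` with columns `onset_ms` and
#'   `condition` (factor, standard first).
#' @export
generate_sequence <- function(config, seed = NULL) {
  stopifnot(inherits(config, "paradigm_config"))
  seed <- seed %||% config$seed
  n <- config$n_tones
  n_dev <- round(n * config$p_deviant)
  n_std <- n - sum(n_dev)
  if (n_std < 0) stopf("deviant probabilities leave no room for standards")
  conds <- c("standard", names(config$p_deviant))

  dev_labels <- rep(names(n_dev), n_dev)
  total_dev <- length(dev_labels)

  labels <- with_seed(seed, {
    dev_labels <- if (total_dev > 0) sample(dev_labels) else dev_labels
    if (config$min_standard_gap && total_dev > 0) {
      # place each deviant in one of the n_std + 1 gaps around a standard
      # backbone, at most one deviant per gap, so no two deviants are ever
      # adjacent; each admissible arrangement is equally likely
      if (total_dev > n_std + 1) {
        stopf(paste("cannot place %d deviants among %d standards with at",
                    "least one standard between deviants"),
              total_dev, n_std)
      }
      gaps <- sample.int(n_std + 1, total_dev)
      items <- c(rep("standard", n_std), dev_labels)
      # gap g sorts a deviant just before standard g (or to the end when
      # g = n_std + 1); standards themselves sit at keys g + 0.5
      key <- c(seq_len(n_std) + 0.5, as.numeric(gaps))
      items[order(key)]
    } else {
      sample(c(rep("standard", n_std), dev_labels))
    }
  })
  stopifnot(length(labels) == n)

  post_dev <- c(FALSE, labels[-n] != "standard") & labels == "standard"
  tibble::new_tibble(
    list(onset_ms = (seq_len(n) - 1) * config$soa_ms,
         condition = factor(labels, levels = conds),
         post_deviant = post_dev),
    class = "stimulus_sequence"
  )
}

#' Per-condition event counts of a sequence
#' @param sequence a `stimulus_sequence`.
#' @return named integer vector of counts.
#' @export
sequence_counts <- function(sequence) {
  table(sequence$condition)
}
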