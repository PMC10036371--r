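mk_perm <- function(p, t_ms, alpha = 0.05, tail = "negative") {
  structure(list(t_obs = rep(0, length(p)), null_max = numeric(0),
                 p_corr = p, p_uncorr = p, alpha = alpha, design = "paired",
                 tail = tail, n_permutations = 1000, time_ms = t_ms,
                 significant_intervals =
                   significant_intervals(p, t_ms, alpha)),
            class = "perm_result")
}
mk_bayes <- function(bf, t_ms) {
  k <- which.max(bf)
  structure(list(bf10 = bf, t = rep(0, length(bf)), time_ms = t_ms,
                 max_bf10 = bf[k], max_latency_ms = t_ms[k],
                 category = classify_evidence(bf[k]), design = "paired",
                 method = "bic"),
            class = "bayes_series")
}

test_that("presence thresholds for bayes and minimum duration are honoured", {
  t_ms <- seq(0, 395, by = 5)
  w <- component_window("MMN")
  p <- rep(0.5, length(t_ms))
  bf <- rep(0.2, length(t_ms)); bf[t_ms == 150] <- 2.9
  d <- decide_presence(mk_perm(p, t_ms), mk_bayes(bf, t_ms), w,
                       "S01", 1, "duration")
  expect_false(d$present[d$method == "bayes"])     # 2.9 < threshold 3
  bf[t_ms == 150] <- 3
  d2 <- decide_presence(mk_perm(p, t_ms), mk_bayes(bf, t_ms), w,
                        "S01", 1, "duration")
  expect_true(d2$present[d2$method == "bayes"])
  # single significant sample (5 ms) fails the 10 ms duration rule...
  p1 <- p; p1[t_ms == 150] <- 0.01
  d3 <- decide_presence(mk_perm(p1, t_ms), mk_bayes(bf, t_ms), w,
                        "S01", 1, "duration")
  expect_false(d3$present[d3$method == "permutation"])
  # ...but passes with min_duration_ms = 0
  d4 <- decide_presence(mk_perm(p1, t_ms), mk_bayes(bf, t_ms), w,
                        "S01", 1, "duration", min_duration_ms = 0)
  expect_true(d4$present[d4$method == "permutation"])
  # a long run outside the search window does not count
  p2 <- p; p2[t_ms >= 300 & t_ms <= 350] <- 0.01
  d5 <- decide_presence(mk_perm(p2, t_ms), mk_bayes(bf, t_ms), w,
                        "S01", 1, "duration")
  expect_false(d5$present[d5$method == "permutation"])
})

test_that("mismatched block/deviant cells are refused", {
  t_ms <- seq(0, 100, by = 5)
  pr <- mk_perm(rep(0.5, length(t_ms)), t_ms)
  bs <- mk_bayes(rep(0.4, length(t_ms)), t_ms)
  pr$cell <- list(subject = "S01", block = 1, deviant = "duration")
  bs$cell <- list(subject = "S01", block = 2, deviant = "duration")
  expect_error(decide_presence(pr, bs, component_window("MMN"),
                               "S01", 1, "duration"), "different")
})

test_that("manual-visual entries require an annotator tag", {
  t_ms <- seq(0, 100, by = 5)
  pr <- mk_perm(rep(0.5, length(t_ms)), t_ms)
  bs <- mk_bayes(rep(0.4, length(t_ms)), t_ms)
  w <- component_window("MMN", c(10, 90))
  expect_error(decide_presence(pr, bs, w, "S01", 1, "duration",
                               manual = list(present = TRUE, annotator = "")),
               "annotator")
  d <- decide_presence(pr, bs, w, "S01", 1, "duration",
                       manual = list(present = TRUE, annotator = "expert1"))
  expect_equal(nrow(d), 3)
  expect_true(d$present[d$method == "manual-visual"])
})

test_that("strong synthetic MMN is present by both methods end to end", {
  cfg <- quick_config(n_tones = 500, seed = 31)
  ep <- quick_block(cfg, seed = 31)
  blk <- analyze_block(ep, seed = 5)
  led <- blk$ledger
  mmn <- led[led$deviant == "duration" & led$component == "MMN", ]
  expect_true(all(mmn$present))
})

test_that("annotation CSV round-trips into the ledger", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,block,deviant,component,present,annotator",
               "S01,1,duration,MMN,TRUE,expert1",
               "S01,2,duration,MMN,FALSE,expert1"), path)
  ann <- read_annotations(path)
  expect_equal(nrow(ann), 2)
  expect_true("block_id" %in% names(ann))
  led <- merge_annotations(tibble::tibble(
    subject_id = "S01", block_id = 1L, deviant = "duration",
    component = "MMN", method = "permutation", present = TRUE,
    strength = 0.01, annotator = NA_character_), ann)
  expect_equal(sum(led$method == "manual-visual"), 2)
})

test_that("detection grid renders +/- and Bayes strength symbols", {
  led <- tibble::tibble(
    subject_id = "S01", block_id = 1L, deviant = "duration",
    component = "MMN",
    method = c("permutation", "bayes"),
    present = c(TRUE, TRUE),
    strength = c(0.001, 200),
    annotator = NA_character_)
  g <- report_detection_grid(led)
  expect_equal(g$permutation, "+")
  expect_equal(g$bayes, "++++")     # BF10 = 200: very strong to extreme
  expect_equal(g[["manual-visual"]], "n/a")
  expect_equal(bf_symbol(c(0.4, 2, 5, 20, 50, 500)),
               c("-", "+", "++", "+++", "++++", "++++"))
})
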