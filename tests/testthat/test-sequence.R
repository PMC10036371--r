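test_that("default paradigm reproduces the printed composition", {
  cfg <- paradigm_config()
  sq <- generate_sequence(cfg, seed = 3)
  cnt <- sequence_counts(sq)
  expect_equal(as.integer(cnt["standard"]), 1968)
  expect_equal(as.integer(cnt[c("duration", "frequency", "intensity")]),
               rep(144L, 3))
  expect_equal(nrow(sq), 2400)
  expect_equal(unique(diff(sq$onset_ms)), 450)
  expect_equal(sq$onset_ms[1], 0)
})

test_that("degenerate probabilities yield an all-standard block", {
  cfg <- paradigm_config(p_standard = 1, p_deviant = c(duration = 0),
                         n_tones = 2400)
  sq <- generate_sequence(cfg)
  expect_true(all(sq$condition == "standard"))
})

test_that("no two deviants are adjacent under the default constraint", {
  for (s in 1:10) {
    sq <- generate_sequence(quick_config(n_tones = 200), seed = s)
    lab <- as.character(sq$condition)
    dev <- lab != "standard"
    expect_false(any(dev[-1] & dev[-length(dev)]))
  }
})

test_that("post-deviant standards are tagged", {
  sq <- generate_sequence(quick_config(n_tones = 200), seed = 4)
  lab <- as.character(sq$condition)
  expect_equal(sq$post_deviant,
               c(FALSE, lab[-length(lab)] != "standard") & lab == "standard")
})

test_that("identical seeds give identical sequences, different seeds differ", {
  cfg <- quick_config(n_tones = 400, seed = 9)
  expect_identical(generate_sequence(cfg), generate_sequence(cfg))
  expect_false(identical(generate_sequence(cfg, seed = 10),
                         generate_sequence(cfg, seed = 11)))
})

test_that("deviant placement is uniform over admissible arrangements", {
  # tiny paradigm whose admissible-position marginal can be enumerated:
  # 8 standards, 2 deviants, no adjacency => gap pairs from choose(9, 2)
  cfg <- paradigm_config(n_tones = 10, p_standard = 0.8,
                         p_deviant = c(duration = 0.2), soa_ms = 450)
  # enumerate the exact marginal over sequence positions
  gaps <- utils::combn(9, 2)
  marginal <- numeric(10)
  for (j in seq_len(ncol(gaps))) {
    g <- sort(gaps[, j])
    pos1 <- g[1]                 # deviant before standard g sits at slot g
    pos2 <- g[2] + 1             # second deviant shifted by the first
    marginal[pos1] <- marginal[pos1] + 1
    marginal[pos2] <- marginal[pos2] + 1
  }
  marginal <- marginal / sum(marginal)
  obs <- numeric(10)
  for (s in 1:400) {
    sq <- generate_sequence(cfg, seed = s)
    w <- which(sq$condition == "duration")
    obs[w] <- obs[w] + 1
  }
  keep <- marginal > 0
  gof <- suppressWarnings(
    stats::chisq.test(obs[keep], p = marginal[keep] / sum(marginal[keep])))
  expect_gt(gof$p.value, 0.01)
})

test_that("invalid configurations are refused", {
  expect_error(paradigm_config(p_standard = 0.9), "sum to 1")
  expect_error(paradigm_config(n_tones = 0), "positive integer")
  expect_error(paradigm_config(soa_ms = -1), "> 0")
  # more deviants than gaps
  cfg <- paradigm_config(n_tones = 10, p_standard = 0.2,
                         p_deviant = c(duration = 0.8))
  expect_error(generate_sequence(cfg), "cannot place")
})
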