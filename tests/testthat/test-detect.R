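test_that("roi_mean averages exactly the requested channels", {
  cfg <- quick_config(n_tones = 20, seed = 1)
  ep <- simulate_block(cfg, noise = noiseless(), seed = 1)
  # identical channels: ROI mean reproduces any single channel
  expect_equal(roi_mean(ep)[1, ], ep$data[1, 1, ], ignore_attr = TRUE)
  # +3/-3/0... average to zero
  m <- matrix(0, 6, 4, dimnames = list(default_channels(), NULL))
  m[1, ] <- 3; m[2, ] <- -3
  expect_equal(unname(roi_mean(m)), rep(0, 4))
  expect_error(roi_mean(m[1:3, , drop = FALSE]), "available")
})

test_that("ROI is montage-invariant: 11-channel patient montage matches", {
  cfg <- quick_config(n_tones = 30, seed = 2)
  ep6 <- simulate_block(cfg, seed = 2)
  extra <- c("P3", "Pz", "P4", "T7", "T8")
  d11 <- array(0, c(dim(ep6$data)[1], 11, dim(ep6$data)[3]))
  d11[, 1:6, ] <- ep6$data
  ep11 <- epochs_set(d11, c(default_channels(), extra),
                     ep6$sampling_rate_hz, ep6$time_ms, ep6$condition)
  expect_equal(roi_mean(ep11), roi_mean(ep6), ignore_attr = TRUE)
})

test_that("identical sets yield no significant samples", {
  set.seed(3)
  a <- matrix(rnorm(8 * 40), 8, 40)
  pr <- perm_ttest_serial(a, a, design = "paired", tail = "negative",
                          seed = 5, time_ms = seq(0, 390, by = 10))
  expect_equal(nrow(pr$significant_intervals), 0)
  expect_true(all(pr$p_corr >= 1 / 1001))
})

test_that("paired MC p-values match exhaustive 2^6 enumeration", {
  set.seed(11)
  n <- 6; S <- 25
  t_ms <- seq(0, 240, by = 10)
  D <- matrix(rnorm(n * S), n, S) - 0.8 * matrix(rep(exp(-((1:S) - 12)^2 / 18),
                                                     each = n), n, S)
  a <- D; b <- matrix(0, n, S)
  p_ex <- oracle_paired_tmax(D, "negative")
  pr <- perm_ttest_serial(a, b, design = "paired", tail = "negative",
                          n_permutations = 1000, seed = 42, time_ms = t_ms)
  se <- sqrt(p_ex * (1 - p_ex) / 1000)
  expect_true(all(abs(pr$p_corr - p_ex) <= 2 * se + 1e-12))
  # exhaustive mode reproduces the oracle exactly
  pe <- perm_ttest_serial(a, b, design = "paired", tail = "negative",
                          exhaustive = TRUE, time_ms = t_ms)
  expect_equal(pe$p_corr, p_ex, tolerance = 1e-12)
})

test_that("independent MC p-values match exhaustive relabeling on small groups", {
  set.seed(13)
  S <- 15
  a <- matrix(rnorm(4 * S, -1), 4, S)
  b <- matrix(rnorm(6 * S), 6, S)
  t_ms <- seq(0, 140, by = 10)
  p_ex <- oracle_independent_tmax(a, b, "negative")
  pr <- perm_ttest_serial(a, b, design = "independent", tail = "negative",
                          n_permutations = 2000, seed = 17, time_ms = t_ms)
  se <- sqrt(p_ex * (1 - p_ex) / 2000)
  expect_true(all(abs(pr$p_corr - p_ex) <= 2.5 * se + 2 / 2001))
})

test_that("Tmax-corrected p dominates the uncorrected p everywhere", {
  for (tail in c("negative", "positive")) {
    set.seed(7)
    a <- matrix(rnorm(10 * 30), 10, 30)
    b <- matrix(rnorm(10 * 30, -0.4), 10, 30)
    pr <- perm_ttest_serial(a, b, design = "paired", tail = tail, seed = 9,
                            time_ms = seq(0, 290, by = 10))
    expect_true(all(pr$p_corr >= pr$p_uncorr - 1e-12))
  }
})

test_that("permutation p-values are seed-reproducible", {
  set.seed(19)
  a <- matrix(rnorm(5 * 20), 5, 20); b <- matrix(rnorm(5 * 20), 5, 20)
  p1 <- perm_ttest_serial(a, b, design = "paired", seed = 4)$p_corr
  p2 <- perm_ttest_serial(a, b, design = "paired", seed = 4)$p_corr
  expect_identical(p1, p2)
})

test_that("degenerate inputs are refused", {
  a <- matrix(rnorm(10), 1, 10)
  expect_error(perm_ttest_serial(a, a, design = "paired"), "at least 2")
  b <- matrix(rnorm(20), 2, 10)
  expect_error(perm_ttest_serial(b, b[1, , drop = FALSE], design = "paired"),
               "equal size")
  expect_error(perm_ttest_serial(a, b, design = "independent"), "at least 2")
})

test_that("find_peak honours polarity, window, and the earliest-tie rule", {
  t_ms <- seq(0, 400, by = 10)
  w <- component_window("MMN", c(100, 200), "negative")
  ramp <- -seq_along(t_ms)         # monotone decreasing
  pk <- find_peak(ramp, w, t_ms)
  expect_equal(pk$peak_latency_ms, 200)  # smaller value at the late edge
  flat <- rep(1, length(t_ms))
  expect_equal(find_peak(flat, w, t_ms)$peak_latency_ms, 100)  # tie: earliest
  v <- rep(0, length(t_ms)); v[16] <- 5
  wp <- component_window("P3a", c(100, 250), "positive")
  expect_equal(find_peak(v, wp, t_ms),
               list(peak_latency_ms = 150, peak_amplitude_uV = 5))
})

test_that("noiseless duration fixture peaks at the configured MMN latency", {
  cfg <- quick_config(n_tones = 40, fs = 512, seed = 3)
  ep <- baseline_correct(simulate_block(cfg, noise = noiseless(), seed = 3))
  ev <- average_by_condition(ep)
  dfw <- roi_mean(ev$duration) - roi_mean(ev$standard)
  pk <- find_peak(dfw, component_window("MMN"), ep$time_ms)
  expect_lte(abs(pk$peak_latency_ms - 205), 1000 / 512)
})

test_that("cohens_d reproduces hand-computed values and degenerate cases", {
  t_ms <- c(0, 10)
  mk <- function(v) matrix(v, length(v), 2)
  # paired diffs {-3,-1,-2,-2}: d = -2 / 0.8165
  e <- cohens_d(mk(c(-3, -1, -2, -2)), mk(c(0, 0, 0, 0)), "paired",
                c(0, 10), t_ms)
  expect_equal(e$d, -2 / sd(c(-3, -1, -2, -2)), tolerance = 1e-12)
  expect_equal(e$d, -2.449, tolerance = 1e-3)
  expect_equal(e$hedges_g, e$d * (1 - 3 / (4 * 3 - 1)))
  # zero variance: signed infinity with a warning
  expect_warning(
    e0 <- cohens_d(mk(c(-2, -2, -2, -2)), mk(rep(0, 4)), "paired",
                   c(0, 10), t_ms),
    "zero variance")
  expect_identical(e0$d, -Inf)
  expect_true(e0$zero_variance)
  # a = b
  x <- mk(rnorm(5))
  expect_equal(suppressWarnings(cohens_d(x, x, "paired", c(0, 10), t_ms)$d),
               NaN)
  expect_equal(suppressWarnings(
    cohens_d(mk(1:4), mk(1:4), "independent", c(0, 10), t_ms)$d), 0)
})

test_that("windows clipped at the epoch edge are flagged", {
  t_ms <- seq(0, 100, by = 10)
  a <- matrix(rnorm(44), 4, 11); b <- matrix(rnorm(44), 4, 11)
  e <- cohens_d(a, b, "paired", c(80, 150), t_ms)
  expect_true(e$clipped)
  expect_equal(e$window_ms, c(80, 100))
})
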