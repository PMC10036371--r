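test_that("band-pass preserves 10 Hz and attenuates 50 Hz by >= 20 dB", {
  fs <- 512
  t <- seq(0, 10, by = 1 / fs)
  mid <- seq(2 * fs, 8 * fs)  # central portion, away from edge transients
  x10 <- sin(2 * pi * 10 * t)
  x50 <- sin(2 * pi * 50 * t)
  y10 <- bandpass(x10, sampling_rate_hz = fs)
  y50 <- bandpass(x50, sampling_rate_hz = fs)
  amp <- function(y) sqrt(2 * mean(y[mid]^2))
  expect_equal(amp(y10), 1, tolerance = 0.05)
  expect_lt(20 * log10(amp(y50)), -20)
  expect_true(all(bandpass(rep(0, 1000), sampling_rate_hz = fs) == 0))
})

test_that("band edges above Nyquist are refused", {
  expect_error(bandpass(rnorm(100), high_hz = 60, sampling_rate_hz = 100),
               "Nyquist")
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  cfg <- quick_config(n_tones = 40, fs = 250, seed = 2)
  ep <- simulate_block(cfg, seed = 5)
  bc <- baseline_correct(ep)
  idx <- which(bc$time_ms >= -100 & bc$time_ms <= 0)
  bl <- apply(bc$data[, , idx], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-9)
  # constant offset is removed entirely
  ep$data[] <- 7
  z <- baseline_correct(ep)
  expect_lt(max(abs(z$data)), 1e-12)
  # idempotent on already-corrected data
  expect_equal(baseline_correct(bc)$data, bc$data, tolerance = 1e-12)
  expect_error(baseline_correct(bc, c(-500, -400)), "no samples")
})

test_that("peak-to-peak artifact rejection flags exactly the bad trials", {
  cfg <- quick_config(n_tones = 30, seed = 4)
  ep <- simulate_block(cfg, noise = noiseless(), seed = 4)
  ep$data[7, 2, 10] <- 500
  ep$data[7, 2, 11] <- -500
  r <- reject_artifacts(ep, 200)
  expect_equal(which(r$rejected), 7L)
  expect_equal(sum(reject_artifacts(ep, Inf)$rejected), 0)
  clean <- simulate_block(cfg, noise = noiseless(), seed = 4)
  expect_equal(sum(reject_artifacts(clean, 200)$rejected), 0)
  log <- attr(r, "rejection_log")
  expect_equal(sum(log$n_rejected), 1L)
  expect_equal(sum(log$n_total), 30L)
})

test_that("condition averages are means over unrejected trials", {
  cfg <- quick_config(n_tones = 20, seed = 5)
  ep <- simulate_block(cfg, noise = noiseless(), seed = 5)
  # two synthetic trials +1/-1 average to zero
  ep$data[1, , ] <- 1; ep$data[2, , ] <- -1
  ep$condition[1:2] <- "pairtest"
  ev <- average_by_condition(ep, "pairtest")
  expect_true(all(ev$pairtest$data == 0))
  expect_equal(ev$pairtest$n_trials_averaged, 2L)
  # noiseless evoked equals the template
  tpl <- condition_templates(cfg)
  ev2 <- average_by_condition(ep, "standard")$standard
  expect_lt(max(abs(ev2$data - tpl$standard$obligatory)), 1e-12)
})

test_that("fully rejected conditions stop the pipeline with a named error", {
  cfg <- quick_config(n_tones = 20, seed = 6)
  ep <- simulate_block(cfg, noise = noiseless(), seed = 6)
  ep$rejected[ep$condition == "duration"] <- TRUE
  expect_error(average_by_condition(ep, "duration"), "duration")
})

test_that("trial bookkeeping: averaged + rejected = total per condition", {
  ep <- simulate_block(quick_config(n_tones = 100, seed = 7), seed = 7)
  ep <- reject_artifacts(baseline_correct(ep), threshold_uV = 45)
  expect_gt(sum(ep$rejected), 0)   # threshold chosen to reject some trials
  expect_lt(sum(ep$rejected), n_trials(ep))
  ev <- average_by_condition(ep)
  for (cond in names(ev)) {
    expect_equal(ev[[cond]]$n_trials_averaged +
                   sum(ep$rejected & ep$condition == cond),
                 sum(ep$condition == cond))
  }
})

test_that("group evoked converges to the template at CLT rate", {
  cfg <- paradigm_config(n_tones = 400, p_standard = 1,
                         p_deviant = c(duration = 0), sampling_rate_hz = 100)
  nm <- noise_model(4, 6, 0, 1)
  ep <- simulate_block(cfg, noise = nm, seed = 9)
  ev <- average_by_condition(ep)$standard
  tpl <- condition_templates(cfg)$standard$obligatory
  roi_err <- abs(roi_mean(ev) - colMeans(tpl))
  noise_sd <- sqrt(4^2 + 6^2) / sqrt(6)   # per-sample ROI noise SD
  expect_lt(max(roi_err), 3.5 * noise_sd / sqrt(400))
})
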