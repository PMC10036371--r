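test_that("rendered peaks sit at their configured latencies", {
  cfg <- quick_config(fs = 512)
  t_ms <- epoch_times(cfg)
  dt <- 1000 / cfg$sampling_rate_hz
  for (comp in list(component_spec("N1", "negative", 100, 22, -2),
                    component_spec("MMN", "negative", 205, 22, -3),
                    component_spec("P3a", "positive", 300, 35, 3))) {
    tm <- render_template("x", list(comp), cfg)
    v <- tm["Fz", ]
    k <- if (comp$amplitude_uV < 0) which.min(v) else which.max(v)
    expect_lte(abs(t_ms[k] - comp$peak_latency_ms), dt)
    expect_equal(max(abs(v)), abs(comp$amplitude_uV), tolerance = 1e-3)
  }
})

test_that("empty component list renders an all-zero waveform", {
  tm <- render_template("standard", list(), quick_config())
  expect_true(all(tm == 0))
})

test_that("duration-deviant template has MMN/P3a extremes in their windows", {
  cfg <- quick_config(fs = 512)
  tpl <- condition_templates(cfg)
  diffw <- colMeans(tpl$duration$deviance)  # ROI mean of deviance part
  t_ms <- epoch_times(cfg)
  expect_true(t_ms[which.min(diffw)] >= 180 && t_ms[which.min(diffw)] <= 230)
  expect_true(t_ms[which.max(diffw)] >= 250 && t_ms[which.max(diffw)] <= 350)
})

test_that("component latency outside the epoch is a rendering error", {
  expect_error(
    render_template("x", list(component_spec("P3a", "positive", 900, 35, 1)),
                    quick_config()),
    "outside the epoch")
})

test_that("component polarity constraints are enforced", {
  expect_error(component_spec("MMN", "negative", 200, 22, 3), "<= 0")
  expect_error(component_spec("P3a", "positive", 300, 35, -3), ">= 0")
  expect_error(component_spec("MMN", "negative", 200, 0, -3), "width")
})

test_that("noiseless epochs equal their condition template exactly", {
  cfg <- quick_config(n_tones = 50, seed = 2)
  ep <- simulate_block(cfg, noise = noiseless(), seed = 7)
  tpl <- condition_templates(cfg)
  for (cond in unique(ep$condition)) {
    i <- which(ep$condition == cond)[1]
    full <- tpl[[cond]]$obligatory + tpl[[cond]]$deviance
    expect_lt(max(abs(ep$data[i, , ] - full)), 1e-12)
  }
})

test_that("white-noise SD is reproduced on generated standards", {
  cfg <- paradigm_config(n_tones = 1000, p_standard = 1,
                         p_deviant = c(duration = 0), sampling_rate_hz = 100)
  s <- 4
  ep <- simulate_block(cfg, noise = noise_model(s, 0, 0, 1), seed = 3)
  tpl <- condition_templates(cfg)
  resid <- sweep(ep$data, c(2, 3), tpl$standard$obligatory)
  sd_hat <- apply(resid[, 1, ], 2, sd)      # per-sample SD across trials
  expect_lt(max(abs(sd_hat - s) / s), 0.05)
})

test_that("averaging N epochs shrinks residual RMS like 1/sqrt(N)", {
  cfg <- paradigm_config(n_tones = 400, p_standard = 1,
                         p_deviant = c(duration = 0), sampling_rate_hz = 100)
  ep <- simulate_block(cfg, noise = noise_model(4, 6, 0, 1), seed = 8)
  tpl <- condition_templates(cfg)$standard$obligatory
  rms <- vapply(c(25, 100, 400), function(N) {
    avg <- apply(ep$data[1:N, , , drop = FALSE], c(2, 3), mean)
    sqrt(mean((avg - tpl)^2))
  }, numeric(1))
  # ratios follow sqrt(100/25) = 2 and sqrt(400/100) = 2 within MC slack
  expect_equal(rms[1] / rms[2], 2, tolerance = 0.25)
  expect_equal(rms[2] / rms[3], 2, tolerance = 0.25)
})

test_that("per-condition epoch counts equal sequence counts and seeds reproduce", {
  cfg <- quick_config(n_tones = 200, seed = 6)
  sq <- generate_sequence(cfg, seed = derive_seed(21, 1L))
  ep1 <- simulate_block(cfg, seed = 21)
  ep2 <- simulate_block(cfg, seed = 21)
  expect_identical(ep1$data, ep2$data)
  expect_equal(table(ep1$condition), table(as.character(sq$condition)))
  expect_equal(n_trials(ep1), nrow(sq))
})

test_that("pink noise carries a falling spectrum and the target SD", {
  set.seed(1)
  pk <- pink_noise(512, 400, sd_uV = 6)
  expect_equal(sd(as.vector(pk)), 6, tolerance = 0.05)
  spec <- rowMeans(abs(mvfft(pk))^2)
  lo <- mean(spec[2:6]); hi <- mean(spec[50:54])
  expect_gt(lo / hi, 5)  # ~1/f power: ratio of band powers ~ f2/f1
})

test_that("presence gain scales deviance components only", {
  cfg <- quick_config(n_tones = 60, seed = 3)
  ep0 <- simulate_block(cfg, noise = noiseless(), seed = 4, deviance_gain = 0)
  tpl <- condition_templates(cfg)
  i <- which(ep0$condition == "duration")[1]
  expect_lt(max(abs(ep0$data[i, , ] - tpl$standard$obligatory)), 1e-12)
})
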