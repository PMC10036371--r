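test_that("window_mean_amplitude is an exact window mean", {
  t_ms <- seq(0, 500, by = 10)
  v <- rep(-2, length(t_ms))
  expect_equal(window_mean_amplitude(v, c(180, 230), t_ms), -2)
  expect_equal(window_mean_amplitude(v, c(100, 100), t_ms), -2) # one sample
  v2 <- seq_along(t_ms)
  expect_equal(window_mean_amplitude(v2, c(0, 20), t_ms), 2)
  expect_error(window_mean_amplitude(v, c(400, 700), t_ms), "outside")
})

test_that("noiseless duration window mean matches the Gaussian integral", {
  cfg <- quick_config(n_tones = 40, fs = 512, seed = 4)
  ep <- baseline_correct(simulate_block(cfg, noise = noiseless(), seed = 4))
  ev <- average_by_condition(ep)
  dfw <- roi_mean(ev$duration) - roi_mean(ev$standard)
  got <- window_mean_amplitude(dfw, c(180, 230), ep$time_ms)
  # analytic superposition of the MMN and P3a pulses over 180-230 ms
  want <- oracle_gaussian_window_mean(-3, 205, 22, 180, 230) +
    oracle_gaussian_window_mean(3, 300, 35, 180, 230)
  # 2% slack: sample-mean over ~26 grid points vs the continuous integral
  expect_equal(got, want, tolerance = 0.02)
})

test_that("rm_anova reproduces the published degrees-of-freedom structure", {
  set.seed(41)
  tb <- expand.grid(subject_id = sprintf("S%02d", 1:13),
                    deviant = c("duration", "frequency", "intensity"),
                    block = 1:5)
  tb$mean_amplitude_uV <- rnorm(nrow(tb))
  a <- rm_anova(tb)
  expect_equal(a$df_num[a$effect == "deviant"], 2)
  expect_equal(a$df_den[a$effect == "deviant"], 24)
  expect_equal(a$df_num[a$effect == "block"], 4)
  expect_equal(a$df_den[a$effect == "block"], 48)
  expect_equal(a$df_num[a$effect == "deviant:block"], 8)
  expect_equal(a$df_den[a$effect == "deviant:block"], 96)
  expect_equal(attr(a, "n_subjects"), 13)
})

test_that("rm_anova matches the brute-force sums-of-squares oracle", {
  set.seed(43)
  for (rep_i in 1:20) {
    n <- sample(4:8, 1); ka <- sample(2:3, 1); kb <- sample(2:4, 1)
    tb <- expand.grid(subject_id = sprintf("S%02d", 1:n),
                      deviant = letters[1:ka], block = 1:kb)
    tb$mean_amplitude_uV <- rnorm(nrow(tb)) +
      rep(rnorm(n), ka * kb) + 0.5 * as.integer(factor(tb$deviant))
    a <- rm_anova(tb)
    Y <- matrix(tb$mean_amplitude_uV[order(tb$subject_id, tb$deviant,
                                           tb$block)], n, byrow = TRUE)
    o <- oracle_rm_anova(Y, ka, kb)
    for (pair in list(c("deviant", "A"), c("block", "B"),
                      c("deviant:block", "AB"))) {
      row <- a[a$effect == pair[1], ]
      ora <- o[[pair[2]]]
      expect_equal(row$F, ora$F, tolerance = 1e-8)
      expect_equal(row$df_num, ora$df1)
      expect_equal(row$df_den, ora$df2)
      if (ora$df1 > 1) expect_equal(row$epsilon_gg, ora$eps, tolerance = 1e-8)
      expect_equal(row$eta_p_sq, ora$eta_p, tolerance = 1e-8)
    }
  }
})

test_that("sums of squares decompose the total (conservation)", {
  set.seed(47)
  n <- 10; ka <- 3; kb <- 5
  tb <- expand.grid(subject_id = sprintf("S%02d", 1:n),
                    deviant = letters[1:ka], block = 1:kb)
  tb$mean_amplitude_uV <- rnorm(nrow(tb), sd = 2) + rep(rnorm(n), ka * kb)
  a <- rm_anova(tb)
  Y <- matrix(tb$mean_amplitude_uV[order(tb$subject_id, tb$deviant,
                                         tb$block)], n, byrow = TRUE)
  o <- oracle_rm_anova(Y, ka, kb)
  ss_subject <- ka * kb * sum((rowMeans(Y) - mean(Y))^2)
  ss_cells <- with(o, A$ss_eff * kb + B$ss_eff * ka + AB$ss_eff +
                     A$ss_err * kb + B$ss_err * ka + AB$ss_err)
  ss_total <- sum((Y - mean(Y))^2)
  expect_equal(ss_subject + ss_cells, ss_total, tolerance = 1e-8)
})

test_that("flat data yield zero F throughout", {
  tb <- expand.grid(subject_id = sprintf("S%02d", 1:6),
                    deviant = c("a", "b", "c"), block = 1:5)
  tb$mean_amplitude_uV <- rep(rnorm(6), 15)  # subject offsets only
  a <- rm_anova(tb)
  expect_true(all(a$F == 0))
  expect_true(all(a$p_gg == 1))
})

test_that("incomplete designs drop subjects and tiny designs error", {
  tb <- expand.grid(subject_id = sprintf("S%02d", 1:5),
                    deviant = c("a", "b"), block = 1:3)
  tb$mean_amplitude_uV <- rnorm(nrow(tb))
  tb2 <- tb[!(tb$subject_id == "S05" & tb$block == 3), ]
  a <- rm_anova(tb2)
  expect_equal(attr(a, "dropped_subjects"), "S05")
  expect_equal(attr(a, "n_subjects"), 4)
  expect_error(rm_anova(tb[tb$deviant == "a", ]), "2 levels")
  expect_error(rm_anova(tb[tb$subject_id %in% c("S01", "S02"), ]),
               "at least 3")
})

test_that("detection rates count presence per available subjects", {
  led <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:17),
                            block_id = 1:5, deviant = "duration",
                            component = "MMN", method = "permutation")
  led$present <- TRUE
  r <- detection_rates(led)
  expect_true(all(r$proportion_present == 1))
  led$present[led$subject_id %in% sprintf("S%02d", 1:9)] <- FALSE
  r2 <- detection_rates(led)
  expect_equal(unique(r2$proportion_present), 8 / 17, tolerance = 1e-12)
  # subject without block 5 leaves the denominator
  led3 <- led[!(led$subject_id == "S01" & led$block_id == 5), ]
  r3 <- detection_rates(led3)
  expect_equal(r3$n_subjects[r3$block_id == 5], 16)
  expect_equal(r3$n_subjects[r3$block_id == 1], 17)
})

test_that("amplitude_table assembles rows from difference series", {
  t_ms <- seq(-100, 600, by = 10)
  mk <- function(x) { v <- rep(x, length(t_ms)); attr(v, "time_ms") <- t_ms; v }
  diffs <- list(S01 = list(`1` = list(duration = mk(-2), frequency = mk(-1))),
                S02 = list(`1` = list(duration = mk(-3), frequency = mk(-2))))
  tb <- amplitude_table(diffs)
  expect_equal(nrow(tb), 4)
  expect_equal(tb$mean_amplitude_uV[tb$subject_id == "S01" &
                                      tb$deviant == "duration"], -2)
})
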