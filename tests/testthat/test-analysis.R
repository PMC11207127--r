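test_that("LFP assembly is a negated linear sum of cell currents", {
  x <- matrix(c(1, 2, 3, 1, 2, 3), ncol = 2)
  expect_equal(compute_lfp(x), -c(2, 4, 6))
  expect_equal(compute_lfp(x[, 1]), compute_lfp(x) / 2)
  expect_equal(compute_lfp(matrix(0, 5, 3)), rep(0, 5))
  expect_error(compute_lfp(NULL))
  expect_error(compute_lfp(matrix(c(1, NA), 1, 2)))
})

test_that("Welch PSD localizes tones and concentrates their power", {
  fs <- 200
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 13 * t)
  p <- welch_psd(x, fs)
  expect_equal(p$freq[which.max(p$power)], 13, tolerance = 0.3)
  # >= 95% of power within +/- 1 Hz of the tone (Parseval concentration)
  inband <- band_power(p, c(12, 14))
  expect_gt(inband / band_power(p, c(0, fs / 2)), 0.95)
  # two tones are ordered by their input amplitude
  x2 <- 2 * sin(2 * pi * 1 * t) + sin(2 * pi * 13 * t)
  p2 <- welch_psd(x2, fs)
  pk1 <- max(p2$power[abs(p2$freq - 1) <= 0.5])
  pk13 <- max(p2$power[abs(p2$freq - 13) <= 0.5])
  expect_gt(pk1, pk13)
  expect_gt(pk13, max(p2$power[p2$freq > 20]) * 10)
  expect_error(welch_psd(x[1:100], fs), "two analysis windows")
})

test_that("white-noise PSD is approximately flat", {
  set.seed(21)
  fs <- 100
  p <- welch_psd(rnorm(fs * 120), fs)
  keep <- p$freq > 2 & p$freq < 48
  fit <- lm(log(p$power[keep]) ~ p$freq[keep])
  expect_lt(abs(coef(fit)[2]), 0.01)    # negligible spectral slope
})

test_that("spectrogram localizes energy in time and frequency", {
  fs <- 100
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 12 * t)
  sg <- lfp_spectrogram(x, fs)
  peak_f <- sg$freq[apply(sg$power, 1, which.max)]
  expect_true(all(abs(peak_f - 12) <= 1))
  # burst at 2-3 s only
  xb <- ifelse(t >= 2 & t < 3, sin(2 * pi * 12 * t), 0)
  sgb <- lfp_spectrogram(xb, fs)
  rowpow <- rowSums(sgb$power)
  expect_gt(min(rowpow[sgb$t > 2.2 & sgb$t < 2.8]),
            10 * max(rowpow[sgb$t > 4 | sgb$t < 1]))
  sg0 <- lfp_spectrogram(rep(0, fs * 3), fs)
  expect_true(all(sg0$power == 0))
})

test_that("the spindle detector is exact on constructed burst fixtures", {
  fx <- make_burst_trace()
  ev <- detect_spindles(fx$x, fx$fs)
  expect_equal(nrow(ev), 5)
  expect_equal(ev$t_start, c(4, 9, 14, 19, 24), tolerance = 0.1)
  expect_true(all(abs(ev$freq - 13) < 1.5))
  # at an absurd threshold nothing is detected
  expect_equal(nrow(detect_spindles(fx$x, fx$fs, k = 1e9)), 0)
  # two bursts separated by 0.05 s merge into one event (merge rule
  # checked with a short envelope smoother so the gap stays visible)
  fx2 <- make_burst_trace(burst_times = c(10, 10.55), burst_dur = 0.5)
  ev2 <- detect_spindles(fx2$x, fx2$fs, smooth_s = 0.05)
  expect_equal(nrow(ev2), 1)
  expect_gt(ev2$t_end[1] - ev2$t_start[1], 0.9)
})

test_that("densities and intervals are exact arithmetic on event lists", {
  ev <- data.frame(t_start = c(0, 7, 14, 21), t_end = c(1, 8, 15, 22))
  expect_equal(spindle_density(ev, 60), 4)
  isi <- inter_spindle_intervals(ev)
  expect_equal(isi$mean_s, 7)
  expect_equal(isi$sd_s, 0)
  expect_equal(spindle_density(ev[0, ], 60), 0)
  expect_true(is.na(inter_spindle_intervals(ev[1, , drop = FALSE])$mean_s))
  expect_equal(spindle_density(data.frame(t_start = 1:23), 300), 4.6)
})

test_that("condition comparison reports effects and degenerate cases", {
  same <- compare_conditions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  set.seed(2)
  a <- rnorm(20); b <- a + 100
  expect_lt(compare_conditions(a, b)$p_value, 1e-6)
  expect_equal(compare_conditions(a, b)$mean_diff, -100, tolerance = 1e-9)
  expect_error(compare_conditions(1, c(1, 2)), "two samples")
})
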