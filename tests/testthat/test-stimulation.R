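test_that("the slow-oscillation detector applies the silence and count rules", {
  # 120 ms of silence, then 75 spikes at 1 ms spacing: detection at the
  # 75th spike
  spk <- c(100, 220 + 0:80)
  det <- so_detect(spk)
  expect_equal(nrow(det), 1)
  expect_equal(det$t_ms, 220 + 74)
  expect_equal(det$down_ms, 120)
  # 80 ms of silence never arms the detector
  spk2 <- c(seq(0, 1040, by = 80), 1100 + 0:200)
  expect_equal(nrow(so_detect(spk2)), 0)
  # 74 spikes then renewed silence: no detection
  spk3 <- c(100, 300 + 0:73, 1000 + 0:73)
  expect_equal(nrow(so_detect(spk3)), 0)
  # counting includes spikes while armed even across short pauses
  spk4 <- c(100, 300 + 0:40, 380 + 0:40)
  expect_equal(nrow(so_detect(spk4)), 1)
})

test_that("CLS cues two successive triggers then pauses", {
  cues <- cls_schedule(1:6, delay = 0, pause = 2.5)
  expect_equal(cues, c(1, 2, 5, 6))
  expect_equal(cls_schedule(numeric(0)), numeric(0))
  # delayed points shift cue times, pause anchored at the second cue
  cues2 <- cls_schedule(c(1, 2, 3, 4.55, 6), delay = 0.12, pause = 2.5)
  expect_equal(cues2[1:2], c(1.12, 2.12))
  expect_equal(cues2[3], 6.12)   # 3 and 4.55 fall inside the pause (to 4.62)
})

test_that("sCLS pauses after every cue", {
  cues <- scls_schedule(c(1, 2, 3, 4, 6), delay = 0, pause = 2.5)
  expect_equal(cues, c(1, 4))    # 6 falls inside the pause started at 4
})

test_that("DSt follows the Down-state duration rule", {
  # cues on short-Down triggers, pause triggered by a long Down state
  cues <- dst_schedule(c(1, 2, 3, 4, 5, 6), c(0.3, 0.4, 0.7, 0.3, 0.3, 0.3),
                       pause = 2.5, limit = 0.5)
  expect_equal(cues, c(1, 2, 6))   # 3 starts pause (to 5.5); 6 resumes
  # all Down states short: every trigger cued
  expect_equal(dst_schedule(1:5, rep(0.2, 5)), 1:5)
  # all Down states long: alternating single-cue / pause pattern
  cues3 <- dst_schedule(seq(1, 20, by = 1), rep(0.8, 20), pause = 2.5)
  expect_equal(cues3[1:4], c(1, 5, 9, 13))
})

test_that("Point-4 triggers on the falling half-peak crossing", {
  t <- seq(0, 2, by = 0.01)
  rate <- approx(c(0, 0.3, 0.5, 1.0, 1.3, 2), c(0, 0, 400, 400, 0, 0),
                 xout = t)$y
  tc <- point4_trigger(rate, t, frac = 0.5, min_peak = 100)
  # falling edge crosses 200 spikes/s halfway down, at ~1.15 s
  expect_equal(tc, 1.15, tolerance = 0.02)
  expect_true(is.na(point4_trigger(seq(0, 400, by = 1), 0.01,
                                   min_peak = 500)))
  expect_true(is.na(point4_trigger(rep(1, 100), 0.01, min_peak = 100)))
})

test_that("event-log helpers count cues and detections", {
  ev <- data.frame(t_ms = c(100, 200, 300, 400),
                   kind = c("SO_DETECT", "CUE", "SO_DETECT", "PAUSE_START"))
  expect_equal(count_cues(ev), 1)
  expect_equal(count_sos(ev, 60), 2)
  expect_error(count_sos(ev, 0))
})
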