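test_that("a run is bit-identical under the same seed and configuration", {
  cfg <- quick_config(duration_s = 4, seed = 77)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$spikes, r2$spikes)
  expect_identical(r1$lfp, r2$lfp)
  expect_identical(r1$events, r2$events)
  # a different seed gives a different trajectory
  r3 <- run_simulation(quick_config(duration_s = 4, seed = 78))
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("zero-duration runs return empty, well-formed streams", {
  rec <- run_simulation(quick_config(duration_s = 0))
  expect_equal(nrow(rec$spikes), 0)
  expect_equal(nrow(rec$events), 0)
  expect_s3_class(rec, "tc_recording")
})

test_that("a silent stimulation pathway leaves dynamics bitwise unchanged", {
  ctl <- run_simulation(quick_config(duration_s = 6, seed = 5,
                                     protocol = "control"))
  cls0 <- run_simulation(quick_config(duration_s = 6, seed = 5,
                                      protocol = "cls", g_sn = 0))
  expect_identical(ctl$spikes, cls0$spikes)
  expect_identical(ctl$lfp, cls0$lfp)
})

test_that("the engine's event log matches the offline detector replay", {
  rec <- shared_control_run()
  py <- sort(rec$spikes$t_ms[rec$spikes$layer == "PY"])
  det_off <- so_detect(py)
  det_on <- rec$events[rec$events$kind == "SO_DETECT", ]
  expect_equal(det_on$t_ms, det_off$t_ms, tolerance = 1e-9)
  expect_equal(det_on$aux, det_off$down_ms, tolerance = 1e-9)
  expect_gt(nrow(det_on), 2)
})

test_that("protocol cue logs replay from the pure schedule functions", {
  rec <- run_simulation(quick_config(duration_s = 20, seed = 31,
                                     protocol = "cls", point = 1))
  det <- rec$events$t_ms[rec$events$kind == "SO_DETECT"]
  cues <- rec$events$t_ms[rec$events$kind == "CUE"]
  expect_equal(cues, cls_schedule(det, delay = 0, pause = 2500))
  # no cue falls inside a pause window
  ps <- rec$events[rec$events$kind == "PAUSE_START", "t_ms"]
  pe <- rec$events[rec$events$kind == "PAUSE_END", "t_ms"]
  for (i in seq_along(ps))
    expect_false(any(cues > ps[i] + 1e-9 & cues < pe[i] - 1e-9))
  # P2/P3 latency is exactly the configured delay
  rec2 <- run_simulation(quick_config(duration_s = 16, seed = 31,
                                      protocol = "scls", point = 2))
  det2 <- rec2$events$t_ms[rec2$events$kind == "SO_DETECT"]
  cues2 <- rec2$events$t_ms[rec2$events$kind == "CUE"]
  expect_equal(cues2, scls_schedule(det2, delay = 120, pause = 2500))
  if (length(cues2)) {
    lat <- sapply(cues2, function(cc) min(cc - det2[det2 <= cc]))
    expect_true(all(abs(lat - 120) < 1e-9))
  }
})

test_that("DSt cue log replays from the Down-state rule", {
  rec <- run_simulation(quick_config(duration_s = 20, seed = 13,
                                     protocol = "dst", point = 1))
  det <- rec$events[rec$events$kind == "SO_DETECT", ]
  cues <- rec$events$t_ms[rec$events$kind == "CUE"]
  expect_equal(cues,
               dst_schedule(det$t_ms, det$aux, delay = 0, pause = 2500,
                            limit = 500))
})

test_that("network voltages stay within the physiological envelope", {
  rec <- run_simulation(quick_config(duration_s = 5, seed = 9,
                                     record = list(PY = c(1, 100),
                                                   TC = 7, RE = 7)))
  expect_true(all(is.finite(rec$traces)))
  expect_true(all(rec$traces > -120 & rec$traces < 60))
})
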