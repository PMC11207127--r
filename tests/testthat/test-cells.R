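test_that("passive cells relax to their leak equilibria", {
  tc0 <- thalamic_cell_params("TC", g_na = 0, g_k = 0, g_t = 0, g_h = 0,
                              g_kl = 0)
  tr <- sim_current_clamp(tc0, 400, v0 = -30)
  expect_equal(tail(tr$V, 1), tc0$EL, tolerance = 1e-2)
  # closed-form exponential relaxation, dt = 0.025 ms
  tau <- tc0$Cm / tc0$gL
  expect_equal(tr$V, tc0$EL + (-30 - tc0$EL) * exp(-tr$t / tau),
               tolerance = 1e-4)
  # with the potassium leak included the equilibrium is the conductance-
  # weighted mix of E_L and E_K
  tc1 <- thalamic_cell_params("TC", g_na = 0, g_k = 0, g_t = 0, g_h = 0)
  v_eq <- (tc1$gL * tc1$EL + tc1$g_kl * tc1$EK) / (tc1$gL + tc1$g_kl)
  tr1 <- sim_current_clamp(tc1, 1000)
  expect_equal(tail(tr1$V, 1), v_eq, tolerance = 1e-2)
})

test_that("dt refinement leaves single-cell spike times nearly unchanged", {
  tc <- thalamic_cell_params("TC")
  s1 <- spike_detect(sim_current_clamp(tc, 1000, I = 3, dt = 0.025)$V,
                     0.025)
  s2 <- spike_detect(sim_current_clamp(tc, 1000, I = 3, dt = 0.0125)$V,
                     0.0125)
  expect_gt(length(s1), 10)
  expect_lt(abs(length(s1) - length(s2)), 3)
  expect_lt(abs(s1[1] - s2[1]), 0.5)
  expect_lt(max(abs(s1[1:5] - s2[1:5])), 3)
})

test_that("pyramidal cells fire tonically with rate increasing in drive", {
  py <- cortical_cell_params("PY")
  rates <- sapply(c(0.1, 0.2, 0.4), function(amp) {
    tr <- sim_current_clamp(py, 1500, I = amp, t_on = 200, t_off = 1500)
    length(spike_detect(tr$V_soma, tr$t))
  })
  expect_gt(rates[1], 2)
  expect_true(all(diff(rates) > 0))
  # resting cell is silent and sits near the leak reversal
  tr0 <- sim_current_clamp(py, 1000)
  expect_length(spike_detect(tr0$V_soma, tr0$t), 0)
  expect_lt(abs(tail(tr0$V_dend, 1) - py$EL), 6)
})

test_that("interneurons differ from pyramidal cells only by Nap and g_Km", {
  inn <- cortical_cell_params("IN")
  expect_equal(inn$g_nap_dend, 0)
  expect_equal(inn$g_nap_soma, 0)
  expect_equal(inn$g_km, 0.03)
  py <- cortical_cell_params("PY")
  expect_equal(py$g_km, 0.014)
  # zeroing the PY Nap conductances reproduces IN dynamics at IN geometry
  py_as_in <- cortical_cell_params("PY", g_nap_dend = 0, g_nap_soma = 0,
                                   g_km = 0.03, rho = 50)
  tr_a <- sim_current_clamp(py_as_in, 500, I = 0.1)
  tr_b <- sim_current_clamp(inn, 500, I = 0.1)
  expect_equal(tr_a$V_dend, tr_b$V_dend, tolerance = 1e-12)
})

test_that("thalamic cells produce low-threshold rebound bursts", {
  # TC: brief hyperpolarization then release -> burst within 400 ms
  tc <- thalamic_cell_params("TC")
  tr <- sim_current_clamp(tc, 2500, I = -1, t_on = 1000, t_off = 1200)
  s <- spike_detect(tr$V, tr$t)
  expect_gte(sum(s > 1200 & s < 1600), 2)
  # RE held near -75 mV by a depolarizing bias, hyperpolarizing step,
  # release -> rebound burst
  re <- thalamic_cell_params("RE")
  n <- round(1500 / 0.025); tt <- (seq_len(n) - 1) * 0.025
  inj <- rep(0.6, n); inj[tt >= 500 & tt < 700] <- 0.6 - 2
  tr2 <- sim_current_clamp(re, 1500, I_trace = inj)
  s2 <- spike_detect(tr2$V, tr2$t)
  expect_gte(sum(s2 > 700 & s2 < 900), 2)
  # voltages stay in the physiological envelope
  expect_true(all(tr2$V > -120 & tr2$V < 60))
})

test_that("spike detection finds threshold crossings with refractoriness", {
  expect_length(spike_detect(rep(-65, 1000), 0.1), 0)
  # synthetic three-spike waveform
  t <- seq(0, 100, by = 0.1)
  V <- -65 + 100 * (exp(-(t - 20)^2 / 0.5) + exp(-(t - 50)^2 / 0.5) +
                    exp(-(t - 80)^2 / 0.5))
  s <- spike_detect(V, t)
  expect_length(s, 3)
  expect_equal(s, c(20, 50, 80), tolerance = 1)
  expect_length(spike_detect(V, t, threshold = max(V) + 1), 0)
})
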