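test_that("rate functions hit their printed values and singular limits", {
  # delayed-rectifier alpha at its pole V = 25 mV: limit 0.02 * 9 = 0.18
  k <- eval_kinetics("PY_K", 25)
  expect_equal(rate_alpha(k, slot = "h"), 0.18, tolerance = 1e-6)
  # reticular T-current activation midpoint
  expect_equal(eval_kinetics("RE_T", -52)$m_inf, 0.5, tolerance = 1e-9)
  # h-current voltage activation midpoint
  expect_equal(eval_kinetics("TC_h", -75)$m_inf, 0.5, tolerance = 1e-9)
  # calcium-gated K at [Ca] = 0.02 mM: m_inf = 0.0002/0.0202
  expect_equal(eval_kinetics("PY_KCa", -60, Ca_i = 0.02)$m_inf,
               0.0002 / 0.0202, tolerance = 1e-9)
  # fast-sodium activation guard constants: alpha(-25) = 0.182*9,
  # beta(-25) = 0.124*9 (printed fallbacks 1.638 and 1.116)
  k <- eval_kinetics("PY_Na_dend", -25)
  ab <- 1 / (k$tau_m * 2.9529)
  expect_equal(k$m_inf * ab, 1.638, tolerance = 1e-5)
  expect_equal((1 - k$m_inf) * ab, 1.116, tolerance = 1e-5)
})

test_that("kinetics are continuous across every singularity guard", {
  poles <- list(PY_Na_dend = c(-25, -40, -85), PY_K = 25, PY_Km = -30,
                PY_HVA = -27, TC_Na = c(-37, 0 - 50 + 40), TC_K = -35)
  for (ch in names(poles)) for (p in poles[[ch]]) {
    lo <- eval_kinetics(ch, p - 1e-7)
    hi <- eval_kinetics(ch, p + 1e-7)
    for (f in c("m_inf", "h_inf")) {
      expect_lt(abs(lo[[f]] - hi[[f]]), 1e-6)
    }
    for (f in c("tau_m", "tau_h")) {
      if (is.finite(lo[[f]]))
        expect_lt(abs(lo[[f]] - hi[[f]]) / lo[[f]], 1e-5)
    }
  }
})

test_that("steady states and time constants are well formed over the range", {
  for (ch in c("PY_Na_dend", "PY_K", "PY_Km", "PY_HVA", "TC_Na", "TC_K",
               "TC_T", "RE_T", "TC_h")) {
    for (V in seq(-120, 50, by = 7.3)) {
      k <- eval_kinetics(ch, V)
      expect_gte(k$m_inf, 0); expect_lte(k$m_inf, 1)
      expect_gte(k$h_inf, 0); expect_lte(k$h_inf, 1)
      expect_gt(k$tau_m, 0); expect_gt(k$tau_h, 0)
    }
  }
})

test_that("channel current follows I = g m^M h^N (V - E)", {
  reg <- channel_registry()
  # zero current at reversal for every channel
  for (i in seq_len(nrow(reg))) {
    expect_identical(channel_current(reg$g_max[i], 0.5, 0.5, reg$M[i],
                                     reg$N[i], reg$E_rev[i], reg$E_rev[i]),
                     0)
  }
  # dendritic potassium leak at -65 mV: 0.0033 * 30 uA/cm^2
  expect_equal(channel_current(0.0033, 1, 1, 0, 0, -65, -95), 0.099,
               tolerance = 1e-12)
  # closed activation gate conducts nothing
  expect_identical(channel_current(10, 0, 1, 3, 1, 0, -95), 0)
})

test_that("exponential gating update is exact against a sub-stepped oracle", {
  expect_equal(step_gating(0.3, 0.3, 5, 0.1), 0.3)            # fixed point
  expect_equal(step_gating(0, 1, 0.025, 0.025), 1 - exp(-1),
               tolerance = 1e-12)
  expect_equal(step_gating(0.2, 0.9, 3, 1e9), 0.9)            # dt -> inf
  expect_error(step_gating(0.2, 0.9, -1, 0.1), "time constant")
  set.seed(7)
  for (rep in 1:20) {
    x <- runif(1); xi <- runif(1); tau <- runif(1, 0.5, 50)
    dt <- runif(1, 0.01, 0.1)
    expect_equal(step_gating(x, xi, tau, dt),
                 euler_gate(x, xi, tau, dt), tolerance = 1e-6)
  }
})

test_that("h-current scheme conserves its state fractions", {
  set.seed(11)
  s <- list(O = 0.3, P1 = 0.1, OL = 0.05)
  for (i in 1:2000) {
    V <- runif(1, -100, -50); ca <- runif(1, 0, 0.01)
    s <- step_ih(s, V, ca, dt = 0.025)
    expect_true(all(unlist(s[c("O", "P1", "OL")]) >= 0))
    expect_true(all(unlist(s[c("O", "P1", "OL")]) <= 1))
    expect_lt(abs(s$C + s$O + s$OL - 1), 1e-8)
  }
})

test_that("h-current equilibrates to its voltage steady state without calcium", {
  s <- list(O = 0, P1 = 0, OL = 0)
  for (i in 1:80000) s <- step_ih(s, -75, 0, dt = 0.25)
  expect_equal(s$O, 0.5, tolerance = 1e-3)   # h_inf(-75) = 0.5
  expect_equal(s$OL, 0)                      # no locking without calcium
  # k3 = 0 freezes the locked fraction
  s2 <- step_ih(list(O = 0.4, P1 = 0.5, OL = 0.2), -75, 0.01, 0.025, k3 = 0)
  expect_equal(s2$OL, 0.2 * (1 - 0.001 * 0.025), tolerance = 1e-12)
})

test_that("calcium pool relaxes and saturates as advertised", {
  expect_equal(step_calcium(2.4e-4, 0, 0.025), 2.4e-4)
  ca <- 0.01
  for (i in 1:4000) {
    ca_new <- step_calcium(ca, 0, 1)
    expect_lte(ca_new, ca)       # monotone decay toward rest
    ca <- ca_new
  }
  expect_equal(ca, 2.4e-4, tolerance = 1e-6)
  # constant inward current: fixed point Ca_rest + scale*|I|*tau
  ca <- 2.4e-4
  for (i in 1:40000) ca <- step_calcium(ca, -2, 1, influx_scale = 5.18e-4,
                                        tau_decay = 5)
  expect_equal(ca, 2.4e-4 + 5.18e-4 * 2 * 5, tolerance = 1e-6)
})
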