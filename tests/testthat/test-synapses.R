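test_that("transmitter pulse is a rectangle of amplitude A", {
  expect_equal(transmitter_pulse(0.15, 0, A = 0.5, t_max = 0.3), 0.5)
  expect_equal(transmitter_pulse(-0.01, 0), 0)
  expect_equal(transmitter_pulse(0.301, 0, t_max = 0.3), 0)
  expect_equal(transmitter_pulse(0.015, 0, t_max = 0.03), 0.5)
})

test_that("first-order receptor kinetics match the brute-force oracle", {
  expect_equal(step_first_order(0, 0, 1.1, 0.19, 1), 0)
  # sustained transmitter: fixed point alpha*T/(alpha*T + beta)
  O <- 0
  for (i in 1:8000) O <- step_first_order(O, 0.5, 1.1, 0.19, 0.1)
  expect_equal(O, 1.1 * 0.5 / (1.1 * 0.5 + 0.19), tolerance = 1e-9)
  # random pulse trains against sub-stepped integration
  set.seed(3)
  for (r in c("AMPA", "GABA_A", "NMDA")) {
    p <- receptor_params(r)
    O1 <- O2 <- 0
    for (i in 1:40) {
      T_conc <- sample(c(0, 0.5), 1)
      dt <- runif(1, 0.02, 0.3)
      O1 <- step_first_order(O1, T_conc, p$alpha, p$beta, dt)
      O2 <- euler_first_order(O2, T_conc, p$alpha, p$beta, dt)
      expect_gte(O1, 0); expect_lte(O1, 1)
    }
    expect_equal(O1, O2, tolerance = 1e-6)
  }
})

test_that("NMDA voltage gate is the printed sigmoid", {
  expect_equal(nmda_gate(-25), 0.5)
  expect_equal(nmda_gate(1e6), 1)
  expect_equal(nmda_gate(-50), 1 / (1 + exp(2)), tolerance = 1e-12)
  V <- seq(-90, 30, by = 5)
  expect_true(all(diff(nmda_gate(V)) > 0))
})

test_that("depression recursion depletes and recovers correctly", {
  expect_equal(depression_update(1, 0, U = 0.07), 0.93)
  expect_equal(depression_update(0.4, 1e9), 1)
  # iterated recursion converges to the algebraic fixed point
  for (isi in c(50, 200, 700)) for (U in c(0.07, 0.073)) {
    D <- 1
    for (i in 1:500) D <- depression_update(D, isi, U)
    expect_equal(D, depression_fixed_point(isi, U), tolerance = 1e-10)
    expect_gt(D, 0); expect_lt(D, 1)
  }
})

test_that("depression stays in (0, 1] under arbitrary spike trains", {
  set.seed(5)
  D <- 1
  for (i in 1:500) {
    D <- depression_update(D, rexp(1, 1 / 100), U = 0.073)
    expect_gt(D, 0); expect_lte(D, 1)
  }
})

test_that("GABA_B cascade integrates exactly and saturates correctly", {
  p <- receptor_params("GABA_B")
  s <- list(R = 0, G = 0)
  s2 <- step_gabab(s$R, s$G, 0, 1, p)
  expect_equal(s2, list(R = 0, G = 0))
  # pure decay of R at rate K2
  s3 <- step_gabab(0.8, 0, 0, 100, p)
  expect_equal(s3$R, 0.8 * exp(-p$K2 * 100), tolerance = 1e-12)
  # sustained transmitter: R -> K1 T/(K1 T + K2), G -> K3 R / K4
  R <- 0; G <- 0
  for (i in 1:60000) { s <- step_gabab(R, G, 0.5, 1, p); R <- s$R; G <- s$G }
  R_inf <- p$K1 * 0.5 / (p$K1 * 0.5 + p$K2)
  expect_equal(R, R_inf, tolerance = 1e-6)
  expect_equal(G, p$K3 * R_inf / p$K4, tolerance = 1e-4)
  # exact update matches the brute-force oracle on random drive
  set.seed(13)
  R1 <- R2 <- 0.2; G1 <- G2 <- 0.5
  for (i in 1:30) {
    T_conc <- sample(c(0, 0.5), 1); dt <- runif(1, 0.05, 0.5)
    s <- step_gabab(R1, G1, T_conc, dt, p); R1 <- s$R; G1 <- s$G
    o <- euler_gabab(R2, G2, T_conc, dt, p); R2 <- o$R; G2 <- o$G
  }
  expect_equal(R1, R2, tolerance = 1e-6)
  expect_equal(G1, G2, tolerance = 1e-6)
})

test_that("synaptic currents follow the receptor-specific forms", {
  am <- receptor_params("AMPA"); nm <- receptor_params("NMDA")
  gb <- receptor_params("GABA_B")
  # zero at reversal
  expect_equal(synaptic_current(list(O = 0.7, D = 0.9), am, 0.025, 0), 0)
  expect_equal(synaptic_current(list(O = 0.7), nm, 0.01, 0), 0)
  # half-maximal GABA_B conductance at G^4 = Kd
  i_half <- synaptic_current(list(G = gb$Kd^0.25), gb, 0.02, -75)
  expect_equal(i_half, 0.5 * 0.02 * (-75 + 95), tolerance = 1e-12)
  # intracortical AMPA example: g 0.025 uS, O 0.5, V -60 -> -0.75 nA inward
  expect_equal(synaptic_current(list(O = 0.5, D = 1), am, 0.025, -60),
               -0.75, tolerance = 1e-12)
  # with depression disabled the current equals the undepressed form
  expect_equal(synaptic_current(list(O = 0.31, D = 1), am, 0.025, -55),
               0.025 * 0.31 * (-55 - 0), tolerance = 1e-12)
  # GABA_B conductance is monotone in G and bounded by g_syn
  gs <- sapply(seq(0, 20, by = 0.5), function(G)
    synaptic_current(list(G = G), gb, 0.02, -94))
  expect_true(all(diff(gs) >= 0))      # conductance grows with G
  expect_true(all(abs(gs) <= 0.02 * abs(-94 + 95)))
})
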