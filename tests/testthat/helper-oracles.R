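# Brute-force reference integrators and shared fixtures for the suite.

# sub-stepped explicit Euler for dx/dt = -(x - xinf)/tau with piecewise-
# constant kinetics; the independent oracle for the exponential update
euler_gate <- function(x, x_inf, tau, dt, nsub = 2000) {
  h <- dt / nsub
  for (i in seq_len(nsub)) x <- x + h * (x_inf - x) / tau
  x
}

# sub-stepped Euler for dO/dt = alpha (1-O) T - beta O
euler_first_order <- function(O, T_conc, alpha, beta, dt, nsub = 2000) {
  h <- dt / nsub
  f <- function(O) alpha * (1 - O) * T_conc - beta * O
  for (i in seq_len(nsub)) {          # Heun (explicit trapezoid)
    k1 <- f(O); k2 <- f(O + h * k1)
    O <- O + h * (k1 + k2) / 2
  }
  O
}

# sub-stepped Euler for the GABA_B cascade
euler_gabab <- function(R, G, T_conc, dt, p, nsub = 2000) {
  h <- dt / nsub
  for (i in seq_len(nsub)) {
    dR <- p$K1 * T_conc * (1 - R) - p$K2 * R
    dG <- p$K3 * R - p$K4 * G
    R <- R + h * dR; G <- G + h * dG
  }
  list(R = R, G = G)
}

# algebraic fixed point of the depression recursion at fixed interval
depression_fixed_point <- function(dt, U, tau_rec = 700) {
  E <- exp(-dt / tau_rec)
  (1 - E) / (1 - (1 - U) * E)
}

# rate constants recovered from eval_kinetics output (alpha = xinf/tau,
# with the temperature factor folded back in where the channel applies it)
rate_alpha <- function(k, QT = 2.9529, slot = c("m", "h")) {
  slot <- match.arg(slot)
  if (slot == "m") k$m_inf / (k$tau_m * QT) else k$h_inf / (k$tau_h * QT)
}

# small network configuration used by the integration tests; kept short so
# the suite stays fast.  Calibrated defaults of the package are used.
quick_config <- function(duration_s = 6, seed = 42, ...) {
  sim_config(duration_s = duration_s, seed = seed, ...)
}

# one shared short control recording, computed lazily
.fixture_env <- new.env()
shared_control_run <- function() {
  if (is.null(.fixture_env$rec)) {
    .fixture_env$rec <- run_simulation(quick_config(duration_s = 12,
                                                    seed = 1234))
  }
  .fixture_env$rec
}

# synthetic spindle fixture: bursts of a tone embedded in 1/f-ish noise
make_burst_trace <- function(fs = 200, dur_s = 30, f_tone = 13,
                             burst_times = c(4, 9, 14, 19, 24),
                             burst_dur = 0.5, snr = 10, seed = 99) {
  set.seed(seed)
  n <- fs * dur_s
  t <- (seq_len(n) - 1) / fs
  noise <- as.numeric(stats::filter(rnorm(n), 0.95, method = "recursive"))
  noise <- noise / sd(noise)
  x <- noise
  for (b in burst_times) {
    idx <- t >= b & t < b + burst_dur
    win <- sin(pi * (t[idx] - b) / burst_dur)^2      # waxing-waning
    x[idx] <- x[idx] + snr * win * sin(2 * pi * f_tone * t[idx])
  }
  list(t = t, x = x, fs = fs)
}
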