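# Receptor kinetics: first-order AMPA/NMDA/GABA_A channels driven by a
# brief transmitter pulse, short-term depression of the intracortical
# synapses, and the second-order GABA_B G-protein cascade.

#' Default receptor parameters
#'
#' Binding/unbinding rates, reversal potentials and pulse parameters for the
#' four receptor models.  `alpha` is the transmitter binding rate
#' (mM^-1 ms^-1), `beta` the unbinding rate (ms^-1).  The transmitter pulse
#' is a rectangle of amplitude `A` (mM) and duration `t_max` (ms).
#'
#' @param receptor one of `"AMPA"`, `"NMDA"`, `"GABA_A"`, `"GABA_B"`.
#' @return list of parameters; for GABA_B the kinetic constants `K1..K4`
#'   (activation/deactivation of receptor and G protein) and the
#'   dissociation constant `Kd` of the G-protein gate.
#' @export
receptor_params <- function(receptor = c("AMPA", "NMDA", "GABA_A",
                                         "GABA_B")) {
  receptor <- match.arg(receptor)
  base <- list(A = 0.5, t_max = 0.3)
  switch(receptor,
    AMPA = c(base, list(receptor = "AMPA", alpha = 1.1, beta = 0.19,
                        E_syn = 0, U = 0.07, tau_rec = 700)),
    NMDA = c(base, list(receptor = "NMDA", alpha = 1, beta = 0.0067,
                        E_syn = 0, nmda_sigma = 12.5, nmda_Vth = -25)),
    GABA_A = c(base, list(receptor = "GABA_A", alpha = 10.5, beta = 0.166,
                          E_syn = -70, U = 0.073, tau_rec = 700)),
    GABA_B = c(base, list(receptor = "GABA_B", E_syn = -95,
                          K1 = 0.052, K2 = 0.0013, K3 = 0.098, K4 = 0.033,
                          Kd = 100, n = 4)))
}

#' Rectangular transmitter pulse
#'
#' `T(t) = A` while `t0 <= t <= t0 + t_max`, else 0 (product of two
#' Heaviside functions).
#'
#' @param t time (ms).
#' @param t0 activation time of the most recent presynaptic spike (ms).
#' @param A pulse amplitude (mM).
#' @param t_max pulse duration (ms).
#' @export
transmitter_pulse <- function(t, t0, A = 0.5, t_max = 0.3) {
  ifelse(t >= t0 & t <= t0 + t_max, A, 0)
}

#' First-order receptor update
#'
#' Advances the open fraction under `dO/dt = alpha (1-O) T - beta O` with
#' `T` held constant over the step (exact exponential update).
#'
#' @param O open fraction in `[0, 1]`.
#' @param T_conc transmitter concentration (mM) during the step.
#' @param alpha,beta rate constants.
#' @param dt step (ms).
#' @export
step_first_order <- function(O, T_conc, alpha, beta, dt) {
  stopifnot(all(O >= 0), all(O <= 1), dt > 0)
  k <- alpha * T_conc + beta
  O_inf <- alpha * T_conc / k
  O_inf + (O - O_inf) * exp(-k * dt)
}

#' NMDA voltage gate
#'
#' Sigmoidal magnesium-block relief `f(V) = 1/(1 + exp(-(V - Vth)/sigma))`.
#' For AMPA and GABA_A the gate is identically 1.
#'
#' @param V postsynaptic potential (mV).
#' @param Vth half-activation voltage (mV).
#' @param sigma slope (mV).
#' @export
nmda_gate <- function(V, Vth = -25, sigma = 12.5) {
  1 / (1 + exp(-(V - Vth) / sigma))
}

#' Short-term depression update
#'
#' Applied once per presynaptic spike:
#' `D' = 1 - (1 - D (1-U)) exp(-dt/tau_rec)`, where `dt` is the interval
#' since the previous spike.  The spike's efficacy is the updated `D'`
#' (resources recovered over the interval, then the per-spike use fraction
#' `U` has been consumed by the previous spike).
#'
#' @param D available resources in `(0, 1]`.
#' @param dt_since_spike inter-spike interval (ms).
#' @param U use fraction per spike (AMPA 0.07, GABA_A 0.073).
#' @param tau_rec recovery time constant (ms).
#' @export
depression_update <- function(D, dt_since_spike, U = 0.07, tau_rec = 700) {
  stopifnot(all(D > 0), all(D <= 1), U > 0, U < 1)
  1 - (1 - D * (1 - U)) * exp(-dt_since_spike / tau_rec)
}

#' GABA_B receptor/G-protein update
#'
#' Integrates the second-order cascade
#' `dR/dt = K1 T (1-R) - K2 R`, `dG/dt = K3 R - K4 G`
#' over a step with `T` constant (exact linear update).
#'
#' @param R activated receptor fraction.
#' @param G G-protein concentration.
#' @param T_conc transmitter (mM) during the step.
#' @param dt step (ms).
#' @param params GABA_B parameter list ([receptor_params]`("GABA_B")`).
#' @return list with updated `R` and `G`.
#' @export
step_gabab <- function(R, G, T_conc, dt, params = receptor_params("GABA_B")) {
  stopifnot(R >= 0, R <= 1, G >= 0)
  K1 <- params$K1; K2 <- params$K2; K3 <- params$K3; K4 <- params$K4
  kr <- K1 * T_conc + K2
  R_inf <- K1 * T_conc / kr
  er <- exp(-kr * dt); e4 <- exp(-K4 * dt)
  R_new <- R_inf + (R - R_inf) * er
  # G driven by R(t) = R_inf + (R0 - R_inf) e^{-kr t}
  G_new <- G * e4 + K3 * R_inf / K4 * (1 - e4) +
    K3 * (R - R_inf) * (er - e4) / (K4 - kr)
  list(R = R_new, G = max(G_new, 0))
}

#' Synaptic current
#'
#' Evaluates the receptor current at the postsynaptic potential:
#' AMPA/GABA_A `I = D g O (V - E)`; NMDA `I = g O f(V) (V - E)` (no
#' depression); GABA_B `I = g G^4/(G^4 + Kd) (V - E_K)`.
#'
#' @param state list with the fields the receptor uses: `O` and `D`
#'   (AMPA/GABA_A), `O` (NMDA), `G` (GABA_B).
#' @param params receptor parameter list, see [receptor_params()].
#' @param g_syn maximal conductance (uS).
#' @param V_post postsynaptic potential (mV).
#' @return current in nA (positive outward).
#' @export
synaptic_current <- function(state, params, g_syn, V_post) {
  r <- params$receptor
  if (r == "AMPA" || r == "GABA_A") {
    D <- if (is.null(state$D)) 1 else state$D
    D * g_syn * state$O * (V_post - params$E_syn)
  } else if (r == "NMDA") {
    g_syn * state$O * nmda_gate(V_post, params$nmda_Vth, params$nmda_sigma) *
      (V_post - params$E_syn)
  } else {
    g4 <- state$G^params$n
    g_syn * g4 / (g4 + params$Kd) * (V_post - params$E_syn)
  }
}
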