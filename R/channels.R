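# Intrinsic-current kinetics: the channel registry and the elementary
# operations on gating variables, the calcium-regulated h-current scheme and
# the intracellular calcium pool.  The same C++ rate functions back both
# these exported operations and the network engine (which tabulates them).

.channel_ids <- c("PY_Na_soma", "PY_Na_dend", "PY_K", "PY_Nap", "PY_Km",
                  "PY_KCa", "PY_HVA", "PY_KL", "TC_Na", "TC_K", "TC_h",
                  "TC_T", "TC_KL", "RE_Na", "RE_K", "RE_T", "RE_KL", "leak")

#' Registry of intrinsic membrane currents
#'
#' One row per channel: gate powers (`M` activation, `N` inactivation, the
#' convention of the single-gate potassium currents is that their gate sits
#' in the `N` slot), default maximal conductance with its units, and reversal
#' potential.  Conductances are densities (mS/cm^2); dendritic values are
#' listed for the cortical channels that exist in both compartments.
#'
#' @param class optional filter: one of `"PY"`, `"IN"`, `"TC"`, `"RE"`.
#' @return a data.frame with columns `channel_id`, `M`, `N`, `g_max`,
#'   `units`, `E_rev`, `Q_T`.
#' @export
channel_registry <- function(class = NULL) {
  d <- data.frame(
    channel_id = c("PY_Na_soma", "PY_Na_dend", "PY_K", "PY_Nap", "PY_Km",
                   "PY_KCa", "PY_HVA", "PY_KL", "TC_Na", "TC_K", "TC_h",
                   "TC_T", "TC_KL", "RE_Na", "RE_K", "RE_T", "RE_KL",
                   "leak"),
    M    = c(3, 3, 0, 1, 1, 1, 2, 0, 3, 0, 1, 2, 0, 3, 0, 2, 0, 0),
    N    = c(1, 1, 1, 0, 0, 0, 1, 0, 1, 4, 0, 1, 0, 1, 4, 1, 0, 0),
    g_max = c(2000, 1.3, 200, 15, 0.014, 0.4, 0.01, 0.0033,
              90, 10, 0.011, 1.1, 0.03, 100, 10, 2, 0.03, 0.033),
    units = "mS/cm^2",
    E_rev = c(50, 50, -95, 50, -95, -95, 140, -95,
              50, -95, -40, 140, -95, 50, -95, 140, -95, -68),
    Q_T  = c(2.9529, 2.9529, 2.9529, NA, 2.9529, 2.9529, 2.9529, NA,
             1, 1, 1, 3.7372, NA, 1, 1, NA, NA, NA),
    stringsAsFactors = FALSE)
  if (!is.null(class)) {
    keep <- switch(class,
      PY = c("PY_Na_soma", "PY_Na_dend", "PY_K", "PY_Nap", "PY_Km",
             "PY_KCa", "PY_HVA", "PY_KL", "leak"),
      IN = c("PY_Na_soma", "PY_Na_dend", "PY_K", "PY_Km", "PY_KCa",
             "PY_HVA", "PY_KL", "leak"),
      TC = c("TC_Na", "TC_K", "TC_h", "TC_T", "TC_KL", "leak"),
      RE = c("RE_Na", "RE_K", "RE_T", "RE_KL", "leak"),
      stop("unknown cell class '", class, "'"))
    d <- d[d$channel_id %in% keep, ]
  }
  d
}

#' Steady states and time constants of a channel's gates
#'
#' Evaluates the voltage- (and, for the calcium-dependent potassium current,
#' calcium-) dependent rate functions of one intrinsic current and returns
#' the steady-state activation/inactivation and their relaxation time
#' constants.  Removable singularities of the x/(1-exp(-x/k)) rate forms are
#' evaluated by their analytic limits; the temperature factor divides the
#' time constants exactly where the channel definitions apply it.
#'
#' @param channel_id one of the ids in [channel_registry()].
#' @param V membrane potential (mV).
#' @param Ca_i intracellular calcium (mM); used only by `PY_KCa`.
#' @param na_vtr voltage shift of the thalamic fast-sodium rate functions
#'   (mV).
#' @return list with `m_inf`, `tau_m`, `h_inf`, `tau_h` (ms).  A gate that
#'   does not exist reports steady state 1 and `tau = Inf` (frozen); the
#'   persistent-sodium activation is instantaneous and reports `tau_m = 0`.
#' @export
eval_kinetics <- function(channel_id, V, Ca_i = 0, na_vtr = -50) {
  stopifnot(is.finite(V), Ca_i >= 0)
  channel_id <- match.arg(channel_id, .channel_ids)
  k <- cpp_eval_kinetics(channel_id, V, Ca_i, na_vtr)
  tm <- if (k[2] < 0) Inf else k[2]
  th <- if (k[4] < 0) Inf else k[4]
  list(m_inf = k[1], tau_m = tm, h_inf = k[3], tau_h = th)
}

#' Ohmic channel current
#'
#' `I = g * m^M * h^N * (V - E)`.  Positive values are outward currents and
#' enter the membrane equation with a minus sign.
#'
#' @param g_max maximal conductance (mS/cm^2 for density currents).
#' @param m,h gating variables in `[0, 1]`.
#' @param M,N gate powers.
#' @param V membrane potential (mV).
#' @param E_rev reversal potential (mV).
#' @return current (uA/cm^2 when `g_max` is a density).
#' @export
channel_current <- function(g_max, m, h, M, N, V, E_rev) {
  stopifnot(m >= 0, m <= 1, h >= 0, h <= 1, g_max >= 0)
  g_max * m^M * h^N * (V - E_rev)
}

#' Exact exponential gating update
#'
#' Advances a gating variable by `x <- x_inf + (x - x_inf) exp(-dt/tau)`,
#' the exact solution of `dx/dt = -(x - x_inf)/tau` over a step with frozen
#' kinetics.
#'
#' @param x current value in `[0, 1]`.
#' @param x_inf steady state.
#' @param tau time constant (ms), must be positive (`Inf` freezes the gate).
#' @param dt step (ms).
#' @export
step_gating <- function(x, x_inf, tau, dt) {
  if (any(tau <= 0)) stop("non-positive time constant")
  stopifnot(dt > 0)
  x_inf + (x - x_inf) * exp(-dt / tau)
}

#' One step of the calcium-regulated h-current scheme
#'
#' Mass-action update of the h-current state: voltage-dependent opening
#' C -> O (rates `alpha = h_inf/tau_s`, `beta = (1-h_inf)/tau_s`), calcium
#' binding of the regulator (`P0 + 4Ca <-> P1`, rates `k1*Ca^4`, `k2`) and
#' open-channel locking (`O + P1 <-> OL`, rates `k3`, `k4`).  `C = 1-O-OL`
#' and `P0 = 1-P1` are derived, so both conservations hold by construction.
#'
#' @param state list or numeric with `O`, `P1`, `OL`.
#' @param V membrane potential (mV).
#' @param Ca_i intracellular calcium (mM).
#' @param dt step (ms).
#' @param k1,k2,k3,k4 rate constants (mM^-4 ms^-1, ms^-1, ms^-1, ms^-1).
#' @return list with updated `O`, `P1`, `OL` and derived `C`.
#' @export
step_ih <- function(state, V, Ca_i, dt, k1 = 2.5e7, k2 = 4e-4, k3 = 0.1,
                    k4 = 0.001) {
  s <- unlist(state)[c("O", "P1", "OL")]
  stopifnot(all(s >= 0), all(s <= 1), s[["O"]] + s[["OL"]] <= 1)
  out <- cpp_step_ih(s[["O"]], s[["P1"]], s[["OL"]], V, Ca_i, dt,
                     k1, k2, k3, k4)
  list(O = out[1], P1 = out[2], OL = out[3], C = 1 - out[1] - out[3])
}

#' Intracellular calcium pool update
#'
#' First-order pool: inward calcium current raises `[Ca]`, which relaxes
#' back to the resting level.  `Ca' = Ca + dt*(-influx_scale*I_Ca -
#' (Ca - Ca_rest)/tau_decay)`, clipped at zero.
#'
#' @param Ca_i current concentration (mM).
#' @param I_Ca_total total calcium current density (uA/cm^2; inward
#'   currents are negative and increase the pool).
#' @param dt step (ms).
#' @param influx_scale conversion mM cm^2 / (uA ms).
#' @param tau_decay removal time constant (ms).
#' @param Ca_rest resting concentration (mM).
#' @export
step_calcium <- function(Ca_i, I_Ca_total, dt, influx_scale = 5.18e-4,
                         tau_decay = 5, Ca_rest = 2.4e-4) {
  stopifnot(dt > 0, Ca_i >= 0)
  out <- Ca_i + dt * (-influx_scale * I_Ca_total - (Ca_i - Ca_rest) /
                        tau_decay)
  max(out, 0)
}
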