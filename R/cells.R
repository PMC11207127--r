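# Cell models: two-compartment cortical (PY, IN) and single-compartment
# thalamic (TC, RE) parameter sets, current-clamp fixtures, and spike
# detection on voltage traces.

#' Cortical cell parameters
#'
#' Two-compartment pyramidal (PY) or interneuron (IN) cell.  The dendritic
#' compartment carries Na, persistent Na (PY only), Km, KCa, HVA calcium,
#' potassium-leak and leak currents; the axosomatic compartment (fast Na,
#' persistent Na, delayed rectifier) is quasi-stationary: its voltage
#' solves the algebraic balance between its intrinsic currents and the
#' dendro-somatic coupling each step.  The dendrite-to-soma area ratio is
#' 165 (PY) or 50 (IN).
#'
#' @param class `"PY"` or `"IN"`.
#' @param ... overrides of individual parameters.
#' @return named list of parameters (conductances mS/cm^2, areas cm^2,
#'   coupling conductance uS).
#' @export
cortical_cell_params <- function(class = c("PY", "IN"), ...) {
  class <- match.arg(class)
  p <- list(
    class = class,
    rho = if (class == "PY") 165 else 50,
    area_soma = 1.0e-6,
    Cm = 0.75,
    gL = 0.033, EL = -68,
    g_kl = 0.0033,
    g_na_dend = 1.3,
    g_nap_dend = if (class == "PY") 2.5 else 0,
    nap_cap = 0.04,
    g_hva = 0.01, g_kca = 0.4,
    g_km = if (class == "PY") 0.014 else 0.03,
    g_na_soma = 2000,
    g_nap_soma = if (class == "PY") 15 else 0,
    g_k_soma = 200,
    g_couple = 0.025,         # uS dendro-somatic coupling (calibrated)
    ENa = 50, EK = -95, ECa = 140,
    ca_rest = 2.4e-4, ca_tau = 500, ca_influx = 1e-2,
    soma_iter = 8)
  modifyList(p, list(...))
}

#' Thalamic cell parameters
#'
#' Single-compartment thalamocortical relay (TC) or reticular (RE) cell.
#' TC carries fast Na/K, potassium leak, low-threshold calcium (I_T) and
#' the calcium-regulated h-current; RE carries fast Na/K, potassium leak
#' and its own I_T.
#'
#' @param class `"TC"` or `"RE"`.
#' @param ... overrides.
#' @export
thalamic_cell_params <- function(class = c("TC", "RE"), ...) {
  class <- match.arg(class)
  p <- list(
    class = class,
    area = if (class == "TC") 2.9e-4 else 1.43e-4,
    Cm = 1,
    gL = if (class == "TC") 0.028 else 0.08,
    EL = if (class == "TC") -70 else -77,
    g_kl = 0.03,
    g_na = if (class == "TC") 90 else 100,
    g_k = 10,
    g_t = if (class == "TC") 1.1 else 2,
    g_h = if (class == "TC") 0.011 else 0,
    gh_ginc = 2,
    ih_k1 = 2.5e7, ih_k2 = 4e-4, ih_k3 = 0.1, ih_k4 = 0.001,
    na_vtr = -50,
    ENa = 50, EK = -95, ECa = 140, Eh = -40,
    ca_rest = 2.4e-4, ca_tau = 5,
    ca_influx = if (class == "TC") 9e-4 else 5.18e-4)
  modifyList(p, list(...))
}

#' Current-clamp simulation of a single cell
#'
#' Runs one isolated cell under a step (or arbitrary) current injection and
#' returns its voltage trace.  This is the test rig used to verify firing,
#' rebound bursting and passive behaviour of each cell class.
#'
#' @param params from [cortical_cell_params()] or [thalamic_cell_params()].
#' @param duration_ms total time (ms).
#' @param dt step (ms).
#' @param I amplitude of the injected step.  For thalamic cells a current
#'   density (uA/cm^2); for cortical cells a dendritic injection in nA.
#' @param t_on,t_off start/end of the step (ms).
#' @param I_trace optional full per-step injection vector overriding the
#'   step protocol.
#' @param v0 initial potential (mV).
#' @return data.frame with `t` (ms) and voltage column(s) (`V` for thalamic
#'   cells; `V_dend`, `V_soma` for cortical cells).
#' @export
sim_current_clamp <- function(params, duration_ms, dt = 0.025, I = 0,
                              t_on = 0, t_off = duration_ms,
                              I_trace = NULL, v0 = NULL) {
  n <- round(duration_ms / dt)
  tt <- (seq_len(n) - 1) * dt
  inj <- if (is.null(I_trace)) ifelse(tt >= t_on & tt < t_off, I, 0)
         else rep_len(I_trace, n)
  if (params$class %in% c("TC", "RE")) {
    if (is.null(v0)) v0 <- params$EL
    v <- cpp_sim_thalamic(params$class, params, inj, dt, v0)
    data.frame(t = tt, V = v)
  } else {
    if (is.null(v0)) v0 <- params$EL
    out <- cpp_sim_cortical(params, inj, numeric(n), dt, v0)
    data.frame(t = tt, V_dend = out$V_dend, V_soma = out$V_soma)
  }
}

#' Spike times from a voltage trace
#'
#' Upward threshold crossings with refractory de-duplication.
#'
#' @param V voltage trace (mV), uniformly sampled.
#' @param t time base (ms) of the same length, or a scalar sampling step.
#' @param threshold crossing threshold (mV).
#' @param refractory_ms minimum separation between detected spikes (ms).
#' @return numeric vector of spike times (ms).
#' @export
spike_detect <- function(V, t, threshold = 0, refractory_ms = 1) {
  if (length(t) == 1) t <- (seq_along(V) - 1) * t
  stopifnot(length(t) == length(V))
  up <- which(V[-1] >= threshold & V[-length(V)] < threshold) + 1
  if (!length(up)) return(numeric(0))
  ts <- t[up]
  keep <- c(TRUE, diff(ts) > refractory_ms)
  # enforce refractory sequentially (diff alone can chain-admit)
  out <- ts[1]
  for (x in ts[-1]) if (x - out[length(out)] > refractory_ms) out <- c(out, x)
  out
}
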