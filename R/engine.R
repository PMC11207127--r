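# Simulation configuration and the fixed-step network integrator front-end.

.protocol_codes <- c(control = 0L, cls = 1L, scls = 2L, dst = 3L)
.event_kinds <- c("SO_DETECT", "CUE", "PAUSE_START", "PAUSE_END", "UP_FALL")

#' Simulation configuration
#'
#' Assembles a complete, reproducible run configuration: network and cell
#' parameters, receptor kinetics, the miniature-EPSP drive, the online
#' slow-oscillation detector, and the stimulation protocol.
#'
#' The two corticothalamic presets reproduce the fast- and slow-spindle
#' regimes: `"fast"` drives the TC layer more strongly than the RE layer
#' (PY->TC 0.003 uS, PY->RE 0.0015 uS); `"slow"` flips the balance
#' (PY->RE 0.0021 uS, PY->TC 0.001 uS), so the reticular layer transiently
#' suppresses the relay layer and spindles emerge later and slower.
#'
#' @param duration_s simulated time (s).
#' @param dt integration step (ms), in (0, 0.1].
#' @param seed integer seed for the run's single random stream.
#' @param preset `"fast"` or `"slow"` corticothalamic weighting.
#' @param protocol `"control"`, `"cls"`, `"scls"` or `"dst"`.
#' @param point stimulation point 1-4: cue at slow-oscillation detection
#'   (1), 120 ms (2) or 180 ms (3) after it, or at the Up-to-Down
#'   transition (4).
#' @param pause_s detection pause after a cue pair (CLS), single cue
#'   (sCLS) or long Down state (DSt), in seconds.
#' @param N cells per non-PY layer (PY layer has 5N).
#' @param g_sn sensory-neuron to TC AMPA conductance (uS).
#' @param mini miniature-EPSP drive parameters ([mini_drive()]).
#' @param record named list of 1-based cell indices whose voltages to
#'   record at the trace sample rate, e.g. `list(PY = c(1, 100))`.
#' @param fs_record sample rate (Hz) of the LFP and voltage traces.
#' @param overrides named list of parameter overrides; sublists `py`,
#'   `in_`, `tc`, `re`, `syn`, `stim`, `detector`, `reversal` are merged
#'   into the corresponding blocks.
#' @return object of class `tc_config`.
#' @export
sim_config <- function(duration_s = 60, dt = 0.025, seed = 1,
                       preset = c("fast", "slow"),
                       protocol = c("control", "cls", "scls", "dst"),
                       point = 1, pause_s = 2.5, N = 40, g_sn = 0.1,
                       mini = mini_drive(), record = list(),
                       fs_record = 1000, overrides = list()) {
  preset <- match.arg(preset)
  protocol <- match.arg(protocol)
  stopifnot(dt > 0, dt <= 0.1, duration_s >= 0, pause_s > 0,
            point %in% 1:4)
  proj <- projection_table()
  if (preset == "slow") {
    proj$g[proj$src == "PY" & proj$tgt == "TC"] <- 0.001
    proj$g[proj$src == "PY" & proj$tgt == "RE"] <- 0.0021
  }
  net <- build_network(N, projections = proj)
  delay <- c(0, 120, 180, 0)[point]
  cfg <- list(
    dt = dt, duration_ms = duration_s * 1000, seed = as.integer(seed) %% 2^31,
    fs_record = fs_record, heterogeneity = 0.13,
    preset = preset,
    layers = as.list(net$sizes),
    reversal = list(ENa = 50, EK = -95, ECa = 140, Eh = -40,
                    E_ampa = 0, E_gabaa = -70, E_gabaa_tc = -83),
    py = cortical_cell_params("PY"),
    "in" = cortical_cell_params("IN"),
    tc = thalamic_cell_params("TC"),
    re = thalamic_cell_params("RE"),
    syn = list(tau_rec = 700, A = 0.5, t_max = 0.3,
               alpha_ampa = 1.1, beta_ampa = 0.19,
               alpha_gabaa = 10.5, beta_gabaa = 0.166,
               alpha_nmda = 1, beta_nmda = 0.0067,
               gabab_K1 = 0.052, gabab_K2 = 0.0013, gabab_K3 = 0.098,
               gabab_K4 = 0.033, gabab_Kd = 100),
    projections = net$projections,
    mini = mini,
    stim = list(protocol = .protocol_codes[[protocol]],
                point = as.integer(point), delay_ms = delay,
                pause_ms = pause_s * 1000, dst_limit_ms = 500,
                cue_ms = 20, sn_rate = 200, g_sn = g_sn,
                p4_frac = 0.8, p4_min_rate = 400, p4_smooth_ms = 20L),
    detector = list(silence_ms = 100, n_spikes = 75L,
                    term_silence_ms = 50, rearm_ms = 100),
    record = list(PY = as.integer((record$PY %||% integer(0)) - 1L),
                  IN = as.integer((record$IN %||% integer(0)) - 1L),
                  TC = as.integer((record$TC %||% integer(0)) - 1L),
                  RE = as.integer((record$RE %||% integer(0)) - 1L)))
  for (blk in intersect(names(overrides),
                        c("py", "in", "tc", "re", "syn", "stim",
                          "detector", "reversal", "mini"))) {
    cfg[[blk]] <- modifyList(cfg[[blk]], overrides[[blk]])
  }
  extra <- setdiff(names(overrides),
                   c("py", "in", "tc", "re", "syn", "stim", "detector",
                     "reversal", "mini"))
  for (nm in extra) cfg[[nm]] <- overrides[[nm]]
  structure(cfg, class = "tc_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a network simulation
#'
#' Integrates the full thalamocortical network with the configured
#' stimulation protocol attached.  Identical configuration and seed give a
#' bit-identical recording.
#'
#' @param config a [sim_config()] object.
#' @return object of class `tc_recording` with elements:
#' \describe{
#'   \item{lfp}{cortical LFP (negated sum of all AMPA, NMDA and GABA_A
#'     postsynaptic currents of PY cells, nA; Up states are positive
#'     deflections), sampled at `fs`.}
#'   \item{fs}{trace sample rate (Hz).}
#'   \item{spikes}{data.frame `t_ms`, `layer`, `cell` (1-based).}
#'   \item{events}{data.frame `t_ms`, `kind`, `protocol`, `point`, `aux`:
#'     SO detections (`aux` = preceding Down-state duration, ms), cues,
#'     pause windows, Up-state fall (Point-4 trigger) events.}
#'   \item{traces}{matrix of recorded cell voltages (columns named
#'     `PY1`, `TC3`, ...), or NULL.}
#'   \item{config}{the configuration echo.}
#' }
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "tc_config"))
  out <- cpp_run_network(unclass(config))
  layer_names <- c("PY", "IN", "TC", "RE")
  spikes <- data.frame(t_ms = out$spike_t,
                       layer = layer_names[out$spike_layer + 1L],
                       cell = out$spike_idx + 1L)
  events <- data.frame(t_ms = out$event_t,
                       kind = .event_kinds[out$event_kind],
                       protocol = rep(names(.protocol_codes)[
                         config$stim$protocol + 1L],
                         length(out$event_t)),
                       point = out$event_point,
                       aux = out$event_aux)
  events <- events[order(events$t_ms), , drop = FALSE]
  rownames(events) <- NULL
  traces <- NULL
  nrec <- vapply(config$record, length, 1L)
  if (sum(nrec) > 0) {
    traces <- do.call(cbind, out$traces)
    colnames(traces) <- unlist(lapply(names(config$record), function(l)
      if (length(config$record[[l]]))
        paste0(l, config$record[[l]] + 1L) else character(0)))
  }
  structure(list(lfp = out$lfp, fs = config$fs_record, spikes = spikes,
                 events = events, traces = traces, config = config,
                 duration_s = config$duration_ms / 1000),
            class = "tc_recording")
}

#' @export
print.tc_config <- function(x, ...) {
  cat(sprintf(
    "tc_config: %.4g s, dt=%.3g ms, preset=%s, protocol=%s (point %d), seed=%d\n",
    x$duration_ms / 1000, x$dt, x$preset,
    names(.protocol_codes)[x$stim$protocol + 1L], x$stim$point, x$seed))
  invisible(x)
}

#' @export
print.tc_recording <- function(x, ...) {
  nso <- sum(x$events$kind == "SO_DETECT")
  ncue <- sum(x$events$kind == "CUE")
  cat(sprintf(
    "tc_recording: %.4g s %s run, %d spikes, %d SO detections, %d cues\n",
    x$duration_s, names(.protocol_codes)[x$config$stim$protocol + 1L],
    nrow(x$spikes), nso, ncue))
  invisible(x)
}

#' @export
summary.tc_recording <- function(object, band = c(10, 16), ...) {
  sp <- detect_spindles(object$lfp, object$fs, band = band)
  so_rate <- count_sos(object$events, object$duration_s)
  dens <- spindle_density(sp, object$duration_s)
  isi <- inter_spindle_intervals(sp)
  out <- list(duration_s = object$duration_s, so_per_min = so_rate,
              spindles_per_min = dens, isi_mean_s = isi$mean_s,
              isi_sd_s = isi$sd_s, n_cues = count_cues(object$events))
  class(out) <- "summary.tc_recording"
  out
}

#' @export
print.summary.tc_recording <- function(x, ...) {
  cat(sprintf("%.4g s simulation\n", x$duration_s))
  cat(sprintf("  slow oscillations : %.2f /min\n", x$so_per_min))
  cat(sprintf("  spindles          : %.2f /min\n", x$spindles_per_min))
  if (is.finite(x$isi_mean_s))
    cat(sprintf("  inter-spindle     : %.2f +/- %.2f s\n", x$isi_mean_s,
                x$isi_sd_s))
  cat(sprintf("  stimulation cues  : %d\n", x$n_cues))
  invisible(x)
}

#' Raster-and-LFP plot of a recording
#'
#' @param x a `tc_recording`.
#' @param t_lim optional time window (s).
#' @param ... ignored.
#' @export
plot.tc_recording <- function(x, t_lim = NULL, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  sp <- x$spikes
  offs <- c(PY = 0, IN = 210, TC = 260, RE = 310)
  y <- offs[sp$layer] + sp$cell
  tx <- sp$t_ms / 1000
  if (is.null(t_lim)) t_lim <- c(0, x$duration_s)
  keep <- tx >= t_lim[1] & tx <= t_lim[2]
  graphics::plot(tx[keep], y[keep], pch = ".", col = "grey20",
                 xlab = "", ylab = "cell", xlim = t_lim)
  cues <- x$events$t_ms[x$events$kind == "CUE"] / 1000
  graphics::abline(v = cues[cues >= t_lim[1] & cues <= t_lim[2]],
                   col = "red", lty = 3)
  tt <- seq_along(x$lfp) / x$fs
  keep <- tt >= t_lim[1] & tt <= t_lim[2]
  graphics::plot(tt[keep], x$lfp[keep], type = "l", xlab = "time (s)",
                 ylab = "LFP (a.u.)", xlim = t_lim)
  invisible(x)
}
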