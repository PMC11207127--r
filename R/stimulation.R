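# Online slow-oscillation detection and the closed-loop protocol state
# machines.  These pure-R implementations operate on event streams (spike
# times, detection times) and mirror the controllers that run online inside
# the network engine; they are the standalone surface for analysing
# recorded data and the reference against which the engine's event log is
# checked.

#' Slow-oscillation detector on a spike stream
#'
#' Replays the online detection rule over a time-ordered stream of PY spike
#' times: after every period of network-wide silence longer than
#' `silence_ms` the detector arms and counts subsequent spikes; the
#' `n_spikes`-th spike marks the end of the Down state and the start of the
#' Down-to-Up transition (a detection).  The detector then re-arms only
#' after a new silent period.
#'
#' @param spike_times sorted PY spike times (ms), pooled over the layer.
#' @param silence_ms minimum silent period (ms) required to arm.
#' @param n_spikes number of counted spikes that triggers a detection.
#' @return data.frame with `t_ms` (detection times) and `down_ms` (length
#'   of the silent period preceding each detection's arming).
#' @export
so_detect <- function(spike_times, silence_ms = 100, n_spikes = 75) {
  stopifnot(!is.unsorted(spike_times))
  det_t <- numeric(0); det_down <- numeric(0)
  last <- 0; armed <- FALSE; cnt <- 0   # the stream starts silent at t = 0
  silence_from <- NA_real_; first_cnt <- NA_real_
  for (s in spike_times) {
    if (s - last > silence_ms) {
      # a (renewed) silent period: (re)arm and restart the count
      armed <- TRUE; cnt <- 0; silence_from <- last
    }
    if (armed) {
      cnt <- cnt + 1
      if (cnt == 1) first_cnt <- s
      if (cnt >= n_spikes) {
        det_t <- c(det_t, s)
        det_down <- c(det_down, first_cnt - silence_from)
        armed <- FALSE; cnt <- 0
      }
    }
    last <- s
  }
  data.frame(t_ms = det_t, down_ms = det_down)
}

#' Closed-loop stimulation schedules
#'
#' Replays a protocol controller over a time-ordered stream of trigger
#' events (slow-oscillation detections for Points 1-3, Up-state fall events
#' for Point 4) and returns the cue times.
#'
#' `cls_schedule`: a cue on each of two successive triggers, then
#' detection pauses for `pause_s`; triggers inside a pause are ignored.
#' `scls_schedule`: a pause after every single cue.
#' `dst_schedule`: a cue on every successive trigger while the preceding
#' Down state is shorter than `limit_s`; a longer Down state starts a
#' `pause_s` pause (no cue), and stimulation resumes on the first trigger
#' after the pause.
#'
#' @param trigger_t trigger times (s or ms; units are preserved).
#' @param delay cue delay after the trigger (same units; 0 for Points 1
#'   and 4, 0.12/0.18 s for Points 2/3).
#' @param pause pause duration (same units).
#' @return numeric vector of cue times.
#' @export
cls_schedule <- function(trigger_t, delay = 0, pause = 2.5) {
  cues <- numeric(0); pause_until <- -Inf; pair <- 0
  for (tt in trigger_t) {
    if (tt < pause_until) next
    cue <- tt + delay
    cues <- c(cues, cue)
    pair <- pair + 1
    if (pair == 2) { pause_until <- cue + pause; pair <- 0 }
  }
  cues
}

#' @rdname cls_schedule
#' @export
scls_schedule <- function(trigger_t, delay = 0, pause = 2.5) {
  cues <- numeric(0); pause_until <- -Inf
  for (tt in trigger_t) {
    if (tt < pause_until) next
    cue <- tt + delay
    cues <- c(cues, cue)
    pause_until <- cue + pause
  }
  cues
}

#' @rdname cls_schedule
#' @param down_dur Down-state duration preceding each trigger (same units
#'   as `trigger_t`).
#' @param limit Down-state duration threshold (same units).
#' @export
dst_schedule <- function(trigger_t, down_dur, delay = 0, pause = 2.5,
                         limit = 0.5) {
  stopifnot(length(trigger_t) == length(down_dur))
  cues <- numeric(0); pause_until <- -Inf; resume <- TRUE
  for (i in seq_along(trigger_t)) {
    tt <- trigger_t[i]
    if (tt < pause_until) next
    if (resume || down_dur[i] < limit) {
      cues <- c(cues, tt + delay)
      resume <- FALSE
    } else {
      pause_until <- tt + pause
      resume <- TRUE
    }
  }
  cues
}

#' Up-to-Down transition (Point 4) trigger on a population-rate trace
#'
#' The Point-4 cue time is the first falling crossing of
#' `frac * peak` by the smoothed population firing rate after the rate has
#' exceeded `min_peak` (an Up state): the moment the cortical LFP amplitude
#' starts dropping back towards the Down state.
#'
#' @param rate smoothed population firing rate, uniformly sampled.
#' @param t time base of `rate` (same length), or scalar step.
#' @param frac fraction of the running Up-state peak (default 0.5).
#' @param min_peak minimum peak rate for an Up state to qualify.
#' @return the crossing time, or `NA` if no qualifying Up state falls.
#' @export
point4_trigger <- function(rate, t, frac = 0.5, min_peak = 0) {
  if (length(t) == 1) t <- (seq_along(rate) - 1) * t
  peak <- -Inf
  for (i in seq_along(rate)) {
    if (rate[i] > peak) peak <- rate[i]
    if (peak >= min_peak && peak > 0 && rate[i] < frac * peak)
      return(t[i])
  }
  NA_real_
}

#' Cue and detection counts from an event log
#'
#' @param events event log of a recording (`rec$events`).
#' @return `count_cues`: number of CUE entries.
#' @export
count_cues <- function(events) sum(events$kind == "CUE")

#' @rdname count_cues
#' @param duration_s run duration (s).
#' @return `count_sos`: slow-oscillation detections per minute.
#' @export
count_sos <- function(events, duration_s) {
  stopifnot(duration_s > 0)
  sum(events$kind == "SO_DETECT") / (duration_s / 60)
}
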