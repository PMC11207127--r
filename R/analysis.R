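# Analysis of the cortical LFP and the event logs: Welch power spectra,
# moving-window spectrogram, sigma-band spindle detection, event densities
# and condition comparisons.

#' Cortical LFP from per-cell synaptic currents
#'
#' The LFP proxy is the pointwise sum of the AMPA, NMDA and GABA_A
#' postsynaptic currents of all pyramidal cells, negated so that Up states
#' (net inward synaptic current) are positive deflections.  The network
#' engine computes this online; this function applies the same convention
#' to a matrix of recorded per-cell current traces.
#'
#' @param currents numeric matrix (samples x cells) of summed synaptic
#'   currents per PY cell (nA, positive outward), or a vector for a single
#'   cell.
#' @return numeric LFP trace.
#' @export
compute_lfp <- function(currents) {
  if (is.null(currents)) stop("missing synaptic current streams")
  m <- as.matrix(currents)
  if (!is.numeric(m) || any(!is.finite(m))) stop("non-finite currents")
  -rowSums(m)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann-windowed, mean-detrended segments
#' with overlap.  The normalization (power density per Hz) is constant
#' across conditions; only relative comparisons are meaningful.
#'
#' @param x trace.
#' @param fs sample rate (Hz).
#' @param window_s segment length (s).
#' @param overlap fractional overlap in `[0, 1)`.
#' @return data.frame with `freq` (Hz) and `power`.
#' @export
welch_psd <- function(x, fs, window_s = 4, overlap = 0.5) {
  nseg <- round(window_s * fs)
  if (length(x) < 2 * nseg)
    stop("trace shorter than two analysis windows")
  hop <- max(1, round(nseg * (1 - overlap)))
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  starts <- seq(1, length(x) - nseg + 1, by = hop)
  acc <- numeric(nseg %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_along(acc)]
    acc <- acc + Re(X * Conj(X))
  }
  scale <- 1 / (fs * sum(w^2) * length(starts))
  p <- acc * scale
  # one-sided: double all bins except DC (and Nyquist if present)
  p[-1] <- 2 * p[-1]
  if (nseg %% 2 == 0) p[length(p)] <- p[length(p)] / 2
  data.frame(freq = (seq_along(p) - 1) * fs / nseg, power = p)
}

#' Band-integrated power
#'
#' Trapezoidal integral of a PSD over a frequency band (used for sigma
#' power, 10-16 Hz).
#'
#' @param psd data.frame from [welch_psd()].
#' @param band length-2 Hz range.
#' @export
band_power <- function(psd, band = c(10, 16)) {
  keep <- psd$freq >= band[1] & psd$freq <= band[2]
  f <- psd$freq[keep]; p <- psd$power[keep]
  if (length(f) < 2) return(sum(p))
  sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
}

#' Moving-window spectrogram
#'
#' Short-time Fourier magnitude over a sliding window, reported over a
#' clipped frequency band (default 0.1-18 Hz, the slow-oscillation and
#' spindle range).
#'
#' @param x trace.
#' @param fs sample rate (Hz).
#' @param window_s window length (s).
#' @param hop_s hop between windows (s).
#' @param f_lim reported frequency range (Hz).
#' @return list with `t` (window centres, s), `freq` (Hz) and `power`
#'   (time x frequency matrix).
#' @export
lfp_spectrogram <- function(x, fs, window_s = 1, hop_s = 0.1,
                            f_lim = c(0.1, 18)) {
  nseg <- round(window_s * fs)
  if (length(x) < nseg) stop("trace shorter than one window")
  hop <- max(1, round(hop_s * fs))
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  starts <- seq(1, length(x) - nseg + 1, by = hop)
  freqs <- (seq_len(nseg %/% 2 + 1) - 1) * fs / nseg
  keep <- freqs >= f_lim[1] & freqs <= f_lim[2]
  out <- matrix(0, length(starts), sum(keep))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_along(freqs)][keep]
    out[i, ] <- Re(X * Conj(X))
  }
  list(t = (starts - 1 + nseg / 2) / fs, freq = freqs[keep], power = out)
}

# analytic-signal magnitude (Hilbert envelope) via FFT
.envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Sigma-band spindle detection
#'
#' Band-passes the trace to the spindle band, takes the analytic-signal
#' envelope (smoothed over `smooth_s`), and marks events where the
#' envelope exceeds `k` times its median for at least `min_dur_s`;
#' events separated by less than `merge_gap_s` are merged.
#'
#' @param x LFP trace.
#' @param fs sample rate (Hz).
#' @param band spindle band (Hz); 10-16 for the fast regime, 8-11 for the
#'   slow preset.
#' @param k threshold as a multiple of the median envelope.
#' @param min_dur_s minimum event duration (s).
#' @param merge_gap_s events closer than this are merged (s).
#' @param smooth_s envelope smoothing window (s).
#' @return data.frame of events: `t_start`, `t_end` (s), `peak_env`, and
#'   `freq` (dominant frequency of the band-passed segment, Hz).
#' @export
detect_spindles <- function(x, fs, band = c(10, 16), k = 2,
                            min_dur_s = 0.3, merge_gap_s = 0.1,
                            smooth_s = 0.15) {
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      peak_env = numeric(0), freq = numeric(0))
  if (length(x) < fs) return(empty)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x - mean(x))
  env <- .envelope(xf)
  nw <- max(1, round(smooth_s * fs))
  env <- as.numeric(stats::filter(env, rep(1 / nw, nw), sides = 2))
  env[is.na(env)] <- 0
  thr <- k * median(env)
  above <- env > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ev <- cbind(starts[r$values], ends[r$values])
  # merge gaps
  if (nrow(ev) > 1) {
    merged <- list(ev[1, ])
    for (i in 2:nrow(ev)) {
      lastv <- merged[[length(merged)]]
      if ((ev[i, 1] - lastv[2]) / fs < merge_gap_s)
        merged[[length(merged)]] <- c(lastv[1], ev[i, 2])
      else merged[[length(merged) + 1]] <- ev[i, ]
    }
    ev <- do.call(rbind, merged)
  }
  dur <- (ev[, 2] - ev[, 1]) / fs
  ev <- ev[dur >= min_dur_s, , drop = FALSE]
  if (!nrow(ev)) return(empty)
  peak <- apply(ev, 1, function(e) max(env[e[1]:e[2]]))
  dfreq <- apply(ev, 1, function(e) {
    seg <- xf[e[1]:e[2]]
    n <- length(seg)
    X <- Mod(fft(seg))[1:(n %/% 2 + 1)]
    (which.max(X) - 1) * fs / n
  })
  data.frame(t_start = (ev[, 1] - 1) / fs, t_end = (ev[, 2] - 1) / fs,
             peak_env = peak, freq = dfreq)
}

#' Spindle density
#'
#' @param events data.frame from [detect_spindles()].
#' @param duration_s trace duration (s).
#' @return events per minute.
#' @export
spindle_density <- function(events, duration_s) {
  stopifnot(duration_s > 0)
  nrow(events) / (duration_s / 60)
}

#' Inter-spindle intervals
#'
#' Intervals between consecutive event onsets.
#'
#' @param events data.frame from [detect_spindles()].
#' @return list with `mean_s`, `sd_s` and the `intervals_s` vector; with
#'   fewer than two events all are empty/NA.
#' @export
inter_spindle_intervals <- function(events) {
  if (nrow(events) < 2)
    return(list(mean_s = NA_real_, sd_s = NA_real_,
                intervals_s = numeric(0)))
  iv <- diff(events$t_start)
  list(mean_s = mean(iv), sd_s = sd(iv), intervals_s = iv)
}

#' Two-sample condition comparison
#'
#' Routine two-sample t test plus effect summary for comparing a metric
#' (sigma power, spindle density, ...) between two conditions.
#'
#' @param a,b numeric samples (>= 2 each).
#' @return list with `mean_diff`, `sd_pooled`, `t`, `p_value`, `n`.
#' @export
compare_conditions <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("need at least two samples per condition")
  if (sd(a) == 0 && sd(b) == 0) {
    return(list(mean_diff = mean(a) - mean(b), sd_pooled = 0,
                t = if (mean(a) == mean(b)) 0 else Inf,
                p_value = if (mean(a) == mean(b)) 1 else 0,
                n = c(length(a), length(b))))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  list(mean_diff = mean(a) - mean(b),
       sd_pooled = sqrt((var(a) * (length(a) - 1) +
                         var(b) * (length(b) - 1)) /
                        (length(a) + length(b) - 2)),
       t = unname(tt$statistic), p_value = tt$p.value,
       n = c(length(a), length(b)))
}

#' @importFrom stats var
NULL

#' Latency from slow-oscillation detection to thalamic activation
#'
#' For each slow-oscillation detection, the delay until the relay (TC)
#' layer first bursts (at least `min_spikes` TC spikes within
#' `burst_win_ms`).  In the fast-spindle regime the thalamus engages
#' 50-100 ms after the cortical cycle starts; in the slow-spindle preset
#' reticular inhibition postpones it by roughly 400 ms.
#'
#' @param rec a `tc_recording`.
#' @param max_ms longest latency considered (ms).
#' @param min_spikes,burst_win_ms burst criterion.
#' @return numeric vector, one latency (ms) per detection with a
#'   qualifying burst.
#' @export
tc_onset_latency <- function(rec, max_ms = 1500, min_spikes = 3,
                             burst_win_ms = 30) {
  det <- rec$events$t_ms[rec$events$kind == "SO_DETECT"]
  tc <- sort(rec$spikes$t_ms[rec$spikes$layer == "TC"])
  out <- numeric(0)
  for (d in det) {
    w <- tc[tc >= d & tc <= d + max_ms]
    if (length(w) < min_spikes) next
    lat <- NA_real_
    for (i in seq_len(length(w) - min_spikes + 1)) {
      if (w[i + min_spikes - 1] - w[i] <= burst_win_ms) {
        lat <- w[i] - d
        break
      }
    }
    if (!is.na(lat)) out <- c(out, lat)
  }
  out
}
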