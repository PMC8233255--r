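# Conventional envelope-threshold ripple detector: the front-end of the
# manual curation workflow, and the comparison detector for the network.

#' Settings for the envelope-threshold baseline detector
#'
#' @param band band-pass range in Hz (default 150-250).
#' @param fir_order FIR filter order (default 600).
#' @param smooth_sigma_ms Gaussian smoothing SD in ms (default 40).
#' @param smooth_points Gaussian kernel length (default 1052).
#' @param threshold_sd detection threshold in SDs above the moving mean
#'   (default 3).
#' @param sd_window_s moving-statistics window (s, default 1).
#' @param min_width_ms minimum peak width at half height (ms, default 15).
#' @param min_distance_ms minimum inter-peak distance (ms, default 25).
#' @return Object of class `baseline_spec`.
#' @export
baseline_spec <- function(band = c(150, 250), fir_order = 600,
                          smooth_sigma_ms = 40, smooth_points = 1052,
                          threshold_sd = 3, sd_window_s = 1,
                          min_width_ms = 15, min_distance_ms = 25) {
  stopifnot(all(c(band, fir_order, smooth_sigma_ms, smooth_points,
                  threshold_sd, sd_window_s, min_width_ms) > 0),
            min_distance_ms >= 0)
  structure(list(band = band, fir_order = fir_order,
                 smooth_sigma_ms = smooth_sigma_ms,
                 smooth_points = smooth_points, threshold_sd = threshold_sd,
                 sd_window_s = sd_window_s, min_width_ms = min_width_ms,
                 min_distance_ms = min_distance_ms),
            class = "baseline_spec")
}

#' Centered moving mean and standard deviation
#'
#' O(n) cumulative-sum implementation; windows at the signal edges are
#' truncated to the available samples rather than padded.
#'
#' @param x numeric signal.
#' @param fs sampling frequency (Hz).
#' @param window_s window duration (s).
#' @return List with numeric vectors `mean` and `sd` (sample SD), same
#'   length as `x`.
#' @export
moving_mean_sd <- function(x, fs, window_s = 1) {
  n <- length(x)
  w <- round(window_s * fs)
  if (w > n) stop_invalid("window longer than the signal")
  half <- floor(w / 2)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  cnt <- hi - lo + 1
  m <- (cs[hi + 1L] - cs[lo]) / cnt
  ss <- (cs2[hi + 1L] - cs2[lo]) - cnt * m^2
  ss[ss < 0] <- 0                             # numerical guard
  s <- sqrt(ss / pmax(cnt - 1, 1))
  list(mean = m, sd = s)
}

#' Envelope-threshold ripple detection
#'
#' The conventional pipeline: zero-phase FIR band-pass (150-250 Hz, order
#' 600) -> Hilbert envelope -> Gaussian smoothing (1052 points, sigma
#' 40 ms) -> peak finding on the smoothed envelope with a time-varying
#' threshold mu(t) + k sigma(t) computed over a centered moving 1 s window,
#' requiring a peak width at half prominence of at least 15 ms and an
#' inter-peak distance of at least 25 ms.
#'
#' @param recording an [lfp_recording()] of at least 3 s.
#' @param spec a [baseline_spec()].
#' @return An [event_series()] with `source = "baseline"`.
#' @export
detect_baseline <- function(recording, spec = baseline_spec()) {
  stopifnot(inherits(recording, "lfp_recording"),
            inherits(spec, "baseline_spec"))
  fs <- recording$fs
  if (duration(recording) < max(3, spec$sd_window_s))
    stop_invalid("recording shorter than the detector's moving window")
  bp <- bandpass_fir(recording$samples, fs, order = spec$fir_order,
                     band = spec$band)
  env <- hilbert_envelope(bp)
  sm <- gaussian_smooth(env, fs, sigma_ms = spec$smooth_sigma_ms,
                        n_points = spec$smooth_points)
  ms <- moving_mean_sd(sm, fs, window_s = spec$sd_window_s)
  thr <- ms$mean + spec$threshold_sd * ms$sd
  pk <- find_peaks(sm, height = thr,
                   distance = spec$min_distance_ms / 1000 * fs,
                   min_width = spec$min_width_ms / 1000 * fs)
  event_series((pk$idx - 1) / fs, duration = 0.05, source = "baseline")
}

#' Export per-event review snippets
#'
#' Replaces the manual inspection step of the curation workflow with a
#' reviewable table: for each detected event, a 1 s window of the raw LFP,
#' band-pass trace and smoothed envelope.
#'
#' @param recording an [lfp_recording()].
#' @param events an [event_series()].
#' @param spec a [baseline_spec()].
#' @return List of per-event data.frames (`time_s`, `raw`, `bandpass`,
#'   `envelope`).
#' @export
review_snippets <- function(recording, events, spec = baseline_spec()) {
  fs <- recording$fs
  bp <- bandpass_fir(recording$samples, fs, order = spec$fir_order,
                     band = spec$band)
  env <- gaussian_smooth(hilbert_envelope(bp), fs,
                         sigma_ms = spec$smooth_sigma_ms,
                         n_points = spec$smooth_points)
  lapply(events$times, function(tc) {
    i0 <- max(1L, floor((tc - 0.5) * fs) + 1L)
    i1 <- min(length(bp), floor((tc + 0.5) * fs))
    idx <- i0:i1
    data.frame(time_s = (idx - 1) / fs, raw = recording$samples[idx],
               bandpass = bp[idx], envelope = env[idx])
  })
}
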