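# Filtering, resampling, envelope and band-energy primitives.
#
# All filters are zero-phase (forward-backward application), so none of them
# shifts event times -- a requirement for every downstream detector.

#' Decimate a recording to a lower sampling frequency
#'
#' Anti-aliased integer-factor downsampling (IIR low-pass + forward-backward
#' filtering before subsampling, via [signal::decimate()]), as used to bring
#' acquisition-rate LFP down to the common working rate of 1250 Hz.
#'
#' @param recording an [lfp_recording()].
#' @param fs_target target sampling frequency; `recording$fs` must be an
#'   integer multiple of it.
#' @return The decimated [lfp_recording()] (movement intervals, which are in
#'   seconds, are unchanged).
#' @export
decimate_lfp <- function(recording, fs_target) {
  stopifnot(inherits(recording, "lfp_recording"))
  q <- recording$fs / fs_target
  if (abs(q - round(q)) > 1e-9)
    stop_invalid("fs (", recording$fs, ") is not an integer multiple of fs_target (",
                 fs_target, "); resample to a common multiple first, then decimate")
  q <- as.integer(round(q))
  x <- if (q == 1L) recording$samples else signal::decimate(recording$samples, q)
  lfp_recording(x, fs = fs_target, session_id = recording$session_id,
                movement_intervals = if (nrow(recording$movement_intervals))
                  recording$movement_intervals else NULL)
}

#' Zero-phase Butterworth band-pass filter
#'
#' 2nd-order Butterworth coefficients for the ripple band (150-250 Hz by
#' default), applied forward-backward so the output has zero phase shift.
#'
#' @param x numeric signal.
#' @param fs sampling frequency (Hz).
#' @param f_lo,f_hi critical frequencies (Hz), `0 < f_lo < f_hi < fs/2`.
#' @param order filter order (default 2).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_butter <- function(x, fs, f_lo = 150, f_hi = 250, order = 2) {
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < fs / 2))
    stop_invalid("need 0 < f_lo < f_hi < fs/2")
  if (length(x) <= 3 * (2 * order + 1))
    stop_invalid("signal too short for the filter's edge padding")
  bf <- signal::butter(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-windowed FIR design of high order (600 by default), applied
#' forward-backward; the front-end filter of the conventional envelope
#' detection pipeline.
#'
#' @inheritParams bandpass_butter
#' @param order FIR filter order (number of taps minus one).
#' @param band `c(f_lo, f_hi)` in Hz.
#' @export
bandpass_fir <- function(x, fs, order = 600, band = c(150, 250)) {
  if (length(x) <= 3 * order)
    stop_invalid("signal must be longer than 3x the FIR order (", 3 * order, ")")
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2))
    stop_invalid("band must lie within (0, fs/2)")
  h <- signal::fir1(order, band / (fs / 2), type = "pass")  # Hamming window
  as.numeric(signal::filtfilt(h, x))
}

#' Instantaneous amplitude via the analytic signal
#'
#' Magnitude of the Hilbert analytic signal, computed in the frequency
#' domain: positive frequencies doubled, negative zeroed.
#'
#' @param x numeric signal (finite).
#' @return Non-negative envelope, same length as `x`.
#' @export
hilbert_envelope <- function(x) {
  if (any(!is.finite(x))) stop_invalid("signal must be finite")
  n <- length(x)
  if (n == 0L) return(numeric(0))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}

#' Gaussian smoothing
#'
#' Convolution with a unit-sum sampled Gaussian kernel (default: 1052 points,
#' sigma = 40 ms), cropped back to the input length ('same' convolution).
#' Near the edges the output is renormalized by the kernel mass actually
#' overlapping the signal, so constant inputs are preserved everywhere.
#'
#' @param x numeric signal.
#' @param fs sampling frequency (Hz).
#' @param sigma_ms kernel standard deviation in milliseconds.
#' @param n_points number of kernel points.
#' @export
gaussian_smooth <- function(x, fs, sigma_ms = 40, n_points = 1052) {
  if (sigma_ms <= 0) stop_invalid("sigma_ms must be > 0")
  sigma <- sigma_ms / 1000 * fs                    # in samples
  g <- seq_len(n_points) - (n_points + 1) / 2
  k <- exp(-0.5 * (g / sigma)^2)
  k <- k / sum(k)
  n <- length(x)
  full <- convolve_full(x, k)
  mass <- convolve_full(rep(1, n), k)         # kernel mass inside the signal
  left <- floor((n_points - 1) / 2)
  idx <- (left + 1):(left + n)
  full[idx] / mass[idx]
}

# full linear convolution via FFT (zero-padded), real signals
convolve_full <- function(x, k) {
  n <- length(x) + length(k) - 1L
  nf <- stats::nextn(n, 2)
  xr <- c(x, numeric(nf - length(x)))
  kr <- c(k, numeric(nf - length(k)))
  out <- Re(fft(fft(xr) * fft(kr), inverse = TRUE) / nf)
  out[seq_len(n)]
}

#' Band-pass signal energy around an event
#'
#' Sum of squared band-pass samples over a window of +/- `half_window_ms`
#' around the event time; the conventional per-event 'ripple strength'.
#' A window extending past the signal is truncated and flagged with the
#' `"truncated"` attribute.
#'
#' @param bp_signal band-pass filtered signal (mV).
#' @param fs sampling frequency (Hz).
#' @param center_s event time (s); must lie inside the signal.
#' @param half_window_ms half window width in ms (default 100).
#' @return Energy in mV^2.
#' @export
signal_energy <- function(bp_signal, fs, center_s, half_window_ms = 100) {
  n <- length(bp_signal)
  if (center_s < 0 || center_s >= n / fs)
    stop_invalid("event center lies outside the signal")
  w <- half_window_ms / 1000
  i0 <- floor((center_s - w) * fs) + 1   # 1-based; sample i covers [(i-1)/fs, i/fs)
  i1 <- floor((center_s + w) * fs)
  truncated <- i0 < 1L || i1 > n
  i0 <- max(i0, 1L)
  i1 <- min(i1, n)
  e <- sum(bp_signal[i0:i1]^2)
  attr(e, "truncated") <- truncated
  e
}
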