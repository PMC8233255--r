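# Complex Morlet wavelet bank and spectrogram.
#
# The wavelet at fundamental frequency f is
#   Psi_f = pi^-(1/4) exp(-x^2/2) (exp(i w x) - exp(-w^2/2)),
# sampled on M_f = floor(2 s fs w / f) points spanning [-2 pi s, 2 pi s];
# the additive correction term enforces (approximately) zero mean, i.e.
# admissibility. Power is the squared magnitude of the full convolution,
# cropped back to the signal length with center alignment.

#' Build a complex Morlet wavelet bank
#'
#' @param fs sampling frequency (Hz).
#' @param freqs fundamental frequencies (Hz), default 100-250 Hz in steps
#'   of 10; all must be below `fs/2`.
#' @param omega center-frequency parameter (default 6).
#' @param s scaling factor (default 1).
#' @return Object of class `wavelet_bank`: list with `wavelets` (complex
#'   vectors), `freqs`, `lengths` (`M_f`), `omega`, `s`, `fs`.
#' @export
morlet_bank <- function(fs, freqs = seq(100, 250, by = 10), omega = 6, s = 1) {
  if (any(freqs >= fs / 2))
    stop_invalid("all frequencies must be below fs/2")
  lengths <- floor(2 * s * fs * omega / freqs)
  wavelets <- lapply(seq_along(freqs), function(i) {
    M <- lengths[i]
    x <- seq(-2 * pi * s, 2 * pi * s, length.out = M)
    pi^-0.25 * exp(-0.5 * x^2) * (exp(1i * omega * x) - exp(-0.5 * omega^2))
  })
  structure(list(wavelets = wavelets, freqs = freqs, lengths = lengths,
                 omega = omega, s = s, fs = fs),
            class = "wavelet_bank")
}

#' Morlet wavelet spectrogram
#'
#' Computes `S_f(t) = |(x * Psi_f)(t)|^2` for every wavelet in the bank via
#' full-mode convolution, cropping `(M_f - 1) / 2` samples from each end so
#' every row is aligned with the input. Each row is normalized by the
#' wavelet's squared coherent gain (its L1 norm), so rows of different
#' wavelet lengths are comparable and a pure tone's power peaks at the
#' row nearest its frequency; without this the raw convolution power
#' grows with the wavelet length, biasing cross-frequency comparisons
#' low.
#'
#' @param x numeric signal, longer than the longest wavelet.
#' @param bank a [morlet_bank()].
#' @return Object of class `spectrogram`: list with `power`
#'   (`length(freqs) x length(x)` matrix, mV^2), `freqs`, `fs`, `alignment`
#'   (sample index of t = 0, always 1 after cropping).
#' @export
wavelet_spectrogram <- function(x, bank) {
  stopifnot(inherits(bank, "wavelet_bank"))
  n <- length(x)
  if (n <= max(bank$lengths))
    stop_invalid("signal must be longer than the longest wavelet (",
                 max(bank$lengths), " samples)")
  power <- matrix(0, nrow = length(bank$freqs), ncol = n)
  for (i in seq_along(bank$freqs)) {
    psi <- bank$wavelets[[i]]
    M <- length(psi)
    nf <- stats::nextn(n + M - 1L, 2)
    conv <- fft(fft(c(x, numeric(nf - n))) *
                fft(c(psi, numeric(nf - M))), inverse = TRUE) / nf
    full <- conv[seq_len(n + M - 1L)]
    left <- floor((M - 1) / 2)
    power[i, ] <- Mod(full[(left + 1):(left + n)])^2 / sum(Mod(psi))^2
  }
  structure(list(power = power, freqs = bank$freqs, fs = bank$fs,
                 alignment = 1L),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram: %d frequencies (%g-%g Hz) x %d time steps>\n",
              length(x$freqs), min(x$freqs), max(x$freqs), ncol(x$power)))
  invisible(x)
}
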