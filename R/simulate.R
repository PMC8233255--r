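# Synthetic LFP sessions with ground-truth ripple events.
#
# The generative model is a superposition of modulated oscillatory events on
# pink (1/f) background noise: each ripple is a Gaussian-enveloped sinusoid
# in the ripple band riding on a negative low-frequency sharp-wave
# deflection; unlabeled distractors (gamma bursts, broadband spikes) probe
# detector false-positive behaviour.

#' Specification of a synthetic LFP session
#'
#' Defaults emulate awake mouse CA1 recordings: ripple-band events with
#' ~0.1 mV band-pass amplitude and well under 100 ms visible duration
#' (Gaussian envelope sigma 15 ms), occurring sparsely (0.1 events/s) on
#' 1/f background noise.
#'
#' @param duration_s session duration (s).
#' @param fs sampling frequency (Hz), default 1250.
#' @param event_rate mean ripple rate (events/s), default 0.1.
#' @param ripple_freq_band ripple frequency range (Hz), default 150-180
#'   (mouse-like); each event draws its frequency uniformly from this band.
#' @param ripple_amp_mV peak amplitude of the ripple oscillation (mV).
#' @param ripple_env_sigma_ms Gaussian envelope SD (ms), default 15
#'   (~70 ms visible duration).
#' @param sharp_wave_amp_mV amplitude of the negative low-frequency
#'   sharp-wave deflection under each ripple (mV), default 0.15.
#' @param noise_exponent spectral exponent of the background noise
#'   (PSD ~ 1/f^exponent), default 1 (pink).
#' @param noise_sd_mV standard deviation of the background noise (mV).
#' @param distractor_rate rate of unlabeled distractor transients
#'   (events/s): half 30-90 Hz gamma bursts, half 2-ms broadband spikes.
#' @param movement_fraction fraction of the session covered by movement
#'   intervals (metadata only), default 0.
#' @param seed integer seed; fixed spec + seed reproduces the waveform
#'   exactly.
#' @return Object of class `sim_spec`.
#' @export
sim_spec <- function(duration_s = 600, fs = 1250, event_rate = 0.1,
                     ripple_freq_band = c(150, 180), ripple_amp_mV = 0.1,
                     ripple_env_sigma_ms = 15, sharp_wave_amp_mV = 0.15,
                     noise_exponent = 1, noise_sd_mV = 0.05,
                     distractor_rate = 0.02, movement_fraction = 0,
                     seed = 1L) {
  if (duration_s <= 0) stop_invalid("duration_s must be > 0")
  if (event_rate < 0 || ripple_amp_mV < 0 || noise_sd_mV < 0 ||
      distractor_rate < 0 || sharp_wave_amp_mV < 0)
    stop_invalid("rates and amplitudes must be >= 0")
  if (!(ripple_freq_band[1] > 0 && ripple_freq_band[2] < fs / 2 &&
        ripple_freq_band[1] <= ripple_freq_band[2]))
    stop_invalid("ripple_freq_band must lie within (0, fs/2)")
  if (movement_fraction < 0 || movement_fraction > 0.8)
    stop_invalid("movement_fraction must be in [0, 0.8]")
  structure(list(duration_s = duration_s, fs = fs, event_rate = event_rate,
                 ripple_freq_band = ripple_freq_band,
                 ripple_amp_mV = ripple_amp_mV,
                 ripple_env_sigma_ms = ripple_env_sigma_ms,
                 sharp_wave_amp_mV = sharp_wave_amp_mV,
                 noise_exponent = noise_exponent, noise_sd_mV = noise_sd_mV,
                 distractor_rate = distractor_rate,
                 movement_fraction = movement_fraction,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# 1/f^a noise by spectral shaping of white Gaussian noise, rescaled to sd
pink_noise <- function(n, fs, exponent, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  w <- rnorm(n)
  W <- fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]      # mirror for negative frequencies
  shape <- c(0, f[-1]^(-exponent / 2))
  x <- Re(fft(W * shape, inverse = TRUE) / n)
  x / sd(x) * sd_target
}

# event times from a Poisson process with a hard refractory gap
refractory_poisson <- function(duration, rate, refractory, margin) {
  if (rate == 0) return(numeric(0))
  mean_gap <- 1 / rate
  if (mean_gap <= refractory)
    stop_invalid("event_rate ", rate, "/s is infeasible with a ",
                 refractory, " s refractory gap")
  times <- numeric(0)
  t <- margin + rexp(1, rate = 1 / (mean_gap - refractory))
  while (t < duration - margin) {
    times <- c(times, t)
    t <- t + refractory + rexp(1, rate = 1 / (mean_gap - refractory))
  }
  times
}

#' Read / write a simulation spec as YAML
#'
#' @param path YAML file path.
#' @param spec a [sim_spec()].
#' @export
write_sim_spec <- function(path, spec) {
  stopifnot(inherits(spec, "sim_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_sim_spec
#' @export
read_sim_spec <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  do.call(sim_spec, yaml::read_yaml(path))
}

#' Generate a synthetic LFP session with ground-truth events
#'
#' Ripple events are placed by a Poisson process with a 200 ms refractory
#' gap (so the 25/50 ms minimum-distance rules of the detectors can never
#' merge distinct ground-truth events) and kept 1 s away from the session
#' edges. Each event adds a Gaussian-enveloped sinusoid at a frequency drawn
#' uniformly from the ripple band, plus a negative half-cosine sharp-wave
#' deflection (~50 ms). Distractors (unlabeled) are 30-90 Hz gamma bursts
#' and 2-ms broadband spikes in equal proportion.
#'
#' @param spec a [sim_spec()].
#' @return List with elements `recording` ([lfp_recording()]) and `events`
#'   ([event_series()], the ripple center times, `source = "labeled"`).
#' @export
simulate_lfp <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  fs <- spec$fs
  n <- round(spec$duration_s * fs)
  x <- pink_noise(n, fs, spec$noise_exponent, spec$noise_sd_mV)
  tgrid <- (seq_len(n) - 1) / fs

  times <- refractory_poisson(spec$duration_s, spec$event_rate,
                              refractory = 0.2, margin = 1.0)
  sigma <- spec$ripple_env_sigma_ms / 1000
  for (tc in times) {
    f <- runif(1, spec$ripple_freq_band[1], spec$ripple_freq_band[2])
    phase <- runif(1, 0, 2 * pi)
    sup <- which(abs(tgrid - tc) <= 4 * sigma)
    tt <- tgrid[sup] - tc
    x[sup] <- x[sup] + spec$ripple_amp_mV * exp(-tt^2 / (2 * sigma^2)) *
      cos(2 * pi * f * tt + phase)
    if (spec$sharp_wave_amp_mV > 0) {
      swsup <- which(abs(tgrid - tc) <= 0.025)
      ts <- tgrid[swsup] - tc
      x[swsup] <- x[swsup] - spec$sharp_wave_amp_mV * cos(pi * ts / 0.05)^2
    }
  }

  n_dis <- if (spec$distractor_rate > 0)
    stats::rpois(1, spec$distractor_rate * spec$duration_s) else 0L
  if (n_dis > 0) {
    for (i in seq_len(n_dis)) {
      tc <- runif(1, 0.5, spec$duration_s - 0.5)
      if (runif(1) < 0.5) {                       # gamma burst
        f <- runif(1, 30, 90)
        phase <- runif(1, 0, 2 * pi)
        sg <- 0.025
        sup <- which(abs(tgrid - tc) <= 4 * sg)
        tt <- tgrid[sup] - tc
        x[sup] <- x[sup] + 0.1 * exp(-tt^2 / (2 * sg^2)) *
          cos(2 * pi * f * tt + phase)
      } else {                                    # 2 ms broadband spike
        sup <- which(abs(tgrid - tc) <= 0.001)
        ts <- tgrid[sup] - tc
        x[sup] <- x[sup] + 0.25 * cos(pi * ts / 0.002)^2
      }
    }
  }

  movement <- NULL
  if (spec$movement_fraction > 0) {
    covered <- 0
    iv <- matrix(numeric(0), ncol = 2)
    guard <- 0L
    while (covered < spec$movement_fraction * spec$duration_s && guard < 1000L) {
      guard <- guard + 1L
      len <- runif(1, 2, 6)
      start <- runif(1, 0, spec$duration_s - len)
      if (nrow(iv) == 0L ||
          all(start > iv[, 2] + 0.5 | start + len < iv[, 1] - 0.5)) {
        iv <- rbind(iv, c(start, start + len))
        covered <- covered + len
      }
    }
    movement <- iv[order(iv[, 1]), , drop = FALSE]
  }

  list(recording = lfp_recording(x, fs = fs,
                                 session_id = sprintf("sim-%d", spec$seed),
                                 movement_intervals = movement),
       events = event_series(times, duration = 0.05, source = "labeled"))
}

#' Generate a corpus of independent synthetic sessions
#'
#' @param spec a [sim_spec()]; its `seed` is replaced per session.
#' @param n_sessions number of sessions.
#' @param seeds one integer seed per session; duplicate seeds (which give
#'   identical sessions) trigger a warning.
#' @return List of `list(recording, events)` pairs.
#' @export
simulate_corpus <- function(spec, n_sessions, seeds = seq_len(n_sessions)) {
  stopifnot(inherits(spec, "sim_spec"))
  if (n_sessions == 0L) return(list())
  if (length(seeds) != n_sessions)
    stop_invalid("need one seed per session")
  if (anyDuplicated(seeds))
    warning("duplicate seeds: some sessions will be identical")
  lapply(seeds, function(s) {
    sp <- spec
    sp$seed <- as.integer(s)
    simulate_lfp(sp)
  })
}
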