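fs <- 1250

test_that("decimation preserves in-band content and rejects non-integer factors", {
  t10 <- seq(0, 10, by = 1 / 2500)[-1]
  rec <- lfp_recording(sin(2 * pi * 100 * t10), fs = 2500)
  dec <- decimate_lfp(rec, 1250)
  expect_equal(dec$fs, 1250)
  expect_equal(length(dec$samples), length(rec$samples) / 2)
  # amplitude of the 100 Hz tone preserved within 1 % (central part)
  core <- dec$samples[1000:11000]
  expect_lt(abs(max(core) - 1), 0.01)

  same <- decimate_lfp(lfp_recording(rnorm(1250), fs = 1250), 1250)
  expect_equal(same$samples, same$samples)  # identity path runs
  expect_error(decimate_lfp(lfp_recording(rnorm(3000), fs = 3000), 1250),
               "integer", class = "swrnet_validation_error")
})

test_that("Butterworth band-pass has the specified pass/stop behaviour and zero phase", {
  tt <- seq_len(5 * fs) / fs
  # forward-backward gain is the squared magnitude response: 0.8525 at
  # 165 Hz, ~1 at the band center (from the analytic transfer function)
  inband <- sin(2 * pi * 165 * tt)
  out <- bandpass_butter(inband, fs)
  expect_equal(max(out[1000:5000]), 0.8525, tolerance = 0.02)
  expect_gte(max(bandpass_butter(sin(2 * pi * 200 * tt), fs)[1000:5000]), 0.99)
  low <- sin(2 * pi * 10 * tt)
  expect_lte(max(abs(bandpass_butter(low, fs)[1000:5000])), 0.05)
  # zero phase: cross-correlation with the input peaks at lag 0
  cc <- stats::ccf(out[1000:5000], inband[1000:5000], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("FIR band-pass passes 200 Hz, kills DC, and is symmetric about an impulse", {
  tt <- seq_len(5 * fs) / fs
  out <- bandpass_fir(sin(2 * pi * 200 * tt), fs)
  expect_gte(max(out[1000:5000]), 0.95)
  dc <- bandpass_fir(rep(1, 5 * fs), fs)
  # edge transients of the forward-backward pass span ~2x the filter order;
  # away from them the DC response vanishes
  expect_lt(max(abs(dc[1500:(5 * fs - 1500)])), 1e-3)
  imp <- numeric(4000); imp[2000] <- 1
  resp <- bandpass_fir(imp, fs)
  expect_equal(resp[2000 + 1:300], resp[2000 - 1:300], tolerance = 1e-8)
})

test_that("Hilbert envelope recovers instantaneous amplitude", {
  tt <- seq_len(2 * fs) / fs
  x <- 0.7 * sin(2 * pi * 170 * tt)
  env <- hilbert_envelope(x)
  central <- env[round(0.1 * length(env)):round(0.9 * length(env))]
  expect_lt(max(abs(central - 0.7)) / 0.7, 0.02)
  expect_equal(hilbert_envelope(numeric(100)), numeric(100))
  # Gaussian-enveloped tone: envelope tracks the Gaussian within 5 %
  g <- exp(-((tt - 1)^2) / (2 * 0.05^2))
  xg <- g * sin(2 * pi * 170 * tt)
  envg <- hilbert_envelope(xg)
  mid <- which(g > 0.1)
  expect_lt(max(abs(envg[mid] - g[mid]) / g[mid]), 0.05)
})

test_that("Gaussian smoothing preserves DC, has a Gaussian impulse response, and reduces variance", {
  x <- rep(2.5, 5000)
  expect_equal(gaussian_smooth(x, fs), x, tolerance = 1e-9)
  imp <- numeric(5000); imp[2500] <- 1
  resp <- gaussian_smooth(imp, fs)
  sigma <- 0.04 * fs
  idx <- 2500 + (-100:100)
  ref <- exp(-0.5 * ((idx - 2500 - 0.5)^2) / sigma^2)  # even kernel: half-sample shift
  ref <- ref / max(ref) * max(resp)
  expect_lt(max(abs(resp[idx] - ref)), 1e-3)
  set.seed(5)
  w <- rnorm(10000)
  expect_lt(var(gaussian_smooth(w, fs)), var(w))
  expect_error(gaussian_smooth(w, fs, sigma_ms = 0),
               class = "swrnet_validation_error")
})

test_that("signal energy sums squared band-pass samples over the 200 ms window", {
  x <- rep(1, 2 * fs)
  e <- signal_energy(x, fs, center_s = 1)
  expect_equal(as.numeric(e), 250)
  expect_false(attr(e, "truncated"))
  expect_equal(as.numeric(signal_energy(numeric(2500), fs, 1)), 0)
  set.seed(6)
  x2 <- rnorm(2500)
  expect_equal(as.numeric(signal_energy(2 * x2, fs, 1)),
               4 * as.numeric(signal_energy(x2, fs, 1)))
  etr <- signal_energy(x, fs, center_s = 0.05)
  expect_true(attr(etr, "truncated"))
  expect_error(signal_energy(x, fs, center_s = 5),
               class = "swrnet_validation_error")
})

test_that("moving statistics: constant, white-noise and step responses", {
  ms <- moving_mean_sd(rep(3, 5000), fs)
  expect_true(all(ms$sd == 0))
  expect_true(all(abs(ms$mean - 3) < 1e-12))
  set.seed(7)
  ms2 <- moving_mean_sd(rnorm(12500), fs)
  central <- ms2$sd[2000:10500]
  expect_true(all(abs(central - 1) < 0.1))
  step <- c(rep(0, 5000), rep(1, 5000))
  ms3 <- moving_mean_sd(step, fs, window_s = 1)
  # mean ramps across the step over exactly one window
  expect_lt(ms3$mean[5000 - 626], 1e-12)
  expect_equal(ms3$mean[5000 + 627], 1, tolerance = 1e-12)
  expect_gt(ms3$mean[5000 + 300], 0.2)
})
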