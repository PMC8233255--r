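test_that("simulation is bit-deterministic and seeds differentiate sessions", {
  spec <- sim_spec(duration_s = 30, seed = 5)
  a <- simulate_lfp(spec)
  b <- simulate_lfp(spec)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$events$times, b$events$times)
  corpus <- simulate_corpus(sim_spec(duration_s = 10), 3, seeds = 1:3)
  expect_length(corpus, 3)
  expect_false(identical(corpus[[1]]$recording$samples,
                         corpus[[2]]$recording$samples))
  expect_warning(simulate_corpus(sim_spec(duration_s = 5), 2, seeds = c(1, 1)),
                 "duplicate")
  expect_identical(simulate_corpus(sim_spec(), 0), list())
})

test_that("zero event rate gives pure noise with no labels", {
  sim <- simulate_lfp(sim_spec(duration_s = 20, event_rate = 0, seed = 2))
  expect_length(sim$events$times, 0)
  expect_equal(sd(sim$recording$samples), 0.05, tolerance = 1e-6)
})

test_that("infeasible event rates under the refractory gap are rejected", {
  expect_error(simulate_lfp(sim_spec(duration_s = 10, event_rate = 6, seed = 1)),
               "refractory", class = "swrnet_validation_error")
})

test_that("generated events carry ripple-band amplitude near the nominal 0.1 mV", {
  sim <- simulate_lfp(sim_spec(duration_s = 600, seed = 1))
  rec <- sim$recording
  expect_gt(length(sim$events$times), 30)
  bp <- bandpass_butter(rec$samples, rec$fs)
  amps <- vapply(sim$events$times, function(tc) {
    idx <- round((tc - 0.05) * rec$fs):round((tc + 0.05) * rec$fs)
    max(abs(bp[idx]))
  }, 1)
  expect_gte(mean(amps >= 0.05 & amps <= 0.2), 0.9)
})

test_that("noise spectrum follows the configured 1/f^a slope", {
  for (expo in c(1, 1.5)) {
    sim <- simulate_lfp(sim_spec(duration_s = 120, event_rate = 0,
                                 distractor_rate = 0, noise_exponent = expo,
                                 seed = 3))
    x <- sim$recording$samples
    ps <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) * 1250 / length(x)
    sel <- f >= 1 & f <= 100
    fit <- stats::lm(log(ps[sel]) ~ log(f[sel]))
    expect_lt(abs(coef(fit)[2] + expo), 0.3)
  }
})

test_that("band energy scales quadratically with the ripple amplitude", {
  energies <- vapply(c(0.05, 0.1, 0.2), function(a) {
    sim <- simulate_lfp(sim_spec(duration_s = 30, noise_sd_mV = 0,
                                 distractor_rate = 0, sharp_wave_amp_mV = 0,
                                 ripple_amp_mV = a, seed = 4))
    bp <- bandpass_butter(sim$recording$samples, 1250)
    signal_energy(bp, 1250, sim$events$times[1])
  }, 1)
  expect_equal(energies[2] / energies[1], 4, tolerance = 0.05)
  expect_equal(energies[3] / energies[2], 4, tolerance = 0.05)
})

test_that("a clean event's spectrogram peaks near the drawn ripple frequency", {
  sim <- simulate_lfp(sim_spec(duration_s = 12, event_rate = 0.1,
                               noise_sd_mV = 0, distractor_rate = 0,
                               sharp_wave_amp_mV = 0, seed = 8))
  expect_gte(length(sim$events$times), 1)
  tc <- sim$events$times[1]
  fs <- 1250
  idx <- round((tc - 0.5) * fs):round((tc + 0.5) * fs)
  bank <- morlet_bank(fs, freqs = seq(100, 250, by = 5))
  sp <- wavelet_spectrogram(sim$recording$samples[idx], bank)
  peak_f <- bank$freqs[which.max(sp$power[, round(0.5 * fs)])]
  # independent estimate of the drawn frequency: FFT peak of the clean
  # event snippet
  snip <- sim$recording$samples[round((tc - 0.06) * fs):round((tc + 0.06) * fs)]
  spec_f <- (seq_along(snip) - 1) / length(snip) * fs
  sel <- spec_f > 100 & spec_f < 250
  drawn <- spec_f[sel][which.max(Mod(fft(snip))[sel])]
  expect_lt(abs(peak_f - drawn), 10)
  expect_gte(drawn, 140)                     # inside the configured band
  expect_lte(drawn, 190)
})

test_that("movement intervals cover roughly the requested fraction", {
  sim <- simulate_lfp(sim_spec(duration_s = 120, movement_fraction = 0.2,
                               seed = 9))
  iv <- sim$recording$movement_intervals
  expect_gt(nrow(iv), 0)
  covered <- sum(iv[, 2] - iv[, 1])
  expect_gt(covered, 0.15 * 120)
  expect_true(all(iv[, 1] < iv[, 2]))
})

test_that("simulation specs round-trip through YAML", {
  spec <- sim_spec(duration_s = 45, event_rate = 0.2, seed = 12)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_spec(path, spec)
  back <- read_sim_spec(path)
  expect_equal(back, spec)
})
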