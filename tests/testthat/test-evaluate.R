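fs <- 1250

test_that("detection scoring follows the per-peak / per-run rule", {
  y <- one_hot_encode(0.5, fs, fs)
  inside <- classify_detections(0.5, y, fs)
  expect_equal(c(inside$tp, inside$fp, inside$fn), c(1, 0, 0))
  outside <- classify_detections(0.6, y, fs)   # 100 ms off: both FP and FN
  expect_equal(c(outside$tp, outside$fp, outside$fn), c(0, 1, 1))
  # wide toy boxcar, two predictions inside score independently
  ywide <- one_hot_encode(event_series(0.5, duration = 0.12), fs, fs)
  both <- classify_detections(c(0.47, 0.53), ywide, fs)
  expect_equal(c(both$tp, both$fp, both$fn), c(2, 0, 0))
  none <- classify_detections(numeric(0), y, fs)
  expect_equal(c(none$tp, none$fp, none$fn), c(0, 0, 1))
})

test_that("detection scoring matches the brute-force oracle on random traces", {
  set.seed(71)
  for (rep in 1:1000) {
    n <- 200
    y <- integer(n)
    for (k in seq_len(sample(0:3, 1))) {
      s <- sample(1:(n - 20), 1)
      y[s:(s + sample(5:20, 1))] <- 1L
    }
    idx <- sort(sample(seq_len(n), sample(0:5, 1)))
    got <- classify_detections((idx - 1) / fs, y, fs)
    want <- oracle_classify(idx, y)
    expect_identical(c(got$tp, got$fp, got$fn), as.integer(want),
                     label = paste("rep", rep))
  }
})

test_that("precision, recall and F1 reproduce the published benchmark counts", {
  counts <- rbind(
    c(512, 83, 47, 0.861, 0.916, 0.887),
    c(477, 57, 81, 0.893, 0.855, 0.874),
    c(495, 61, 63, 0.890, 0.887, 0.889),
    c(522, 43, 36, 0.924, 0.935, 0.930),
    c(499, 36, 57, 0.933, 0.897, 0.915),
    c(497, 28, 60, 0.947, 0.892, 0.919),
    c(518, 71, 38, 0.879, 0.932, 0.905),
    c(78, 85, 8, 0.479, 0.907, 0.627))
  # rows 1-6: the two seed triplets at default detector settings; row 7: a
  # well-performing causal instance; row 8: the continuous hold-out session
  for (r in seq_len(nrow(counts))) {
    prf <- precision_recall_f1(counts[r, 1], counts[r, 2], counts[r, 3])
    expect_equal(round(prf$precision, 3), counts[r, 4])
    expect_equal(round(prf$recall, 3), counts[r, 5])
    expect_equal(round(prf$f1, 3), counts[r, 6])
  }
  # ensemble rows: means of the per-instance metrics at printed precision
  uni <- round(precision_recall_f1(counts[1:3, 1], counts[1:3, 2], counts[1:3, 3]), 3)
  bi <- round(precision_recall_f1(counts[4:6, 1], counts[4:6, 2], counts[4:6, 3]), 3)
  expect_equal(round(colMeans(uni), 3),
               c(precision = 0.881, recall = 0.886, f1 = 0.883))
  expect_equal(round(colMeans(bi), 3),
               c(precision = 0.935, recall = 0.908, f1 = 0.921))
})

test_that("metrics are undefined (not zero) when their denominators vanish", {
  prf <- precision_recall_f1(0, 0, 0)
  expect_true(is.na(prf$precision) && is.na(prf$recall) && is.na(prf$f1))
  perfect <- precision_recall_f1(7, 0, 0)
  expect_equal(unlist(perfect), c(precision = 1, recall = 1, f1 = 1))
  expect_error(precision_recall_f1(-1, 0, 0))
})

test_that("F1 equals the harmonic mean of precision and recall to 1e-12", {
  set.seed(73)
  for (rep in 1:50) {
    tp <- sample(1:500, 1); fp <- sample(0:100, 1); fn <- sample(0:100, 1)
    prf <- precision_recall_f1(tp, fp, fn)
    expect_equal(prf$f1,
                 2 * prf$precision * prf$recall / (prf$precision + prf$recall),
                 tolerance = 1e-12)
  }
})

test_that("detection reports keep counts and metrics consistent", {
  rep <- detection_report(522, 43, 36)
  expect_equal(rep$precision, 522 / 565, tolerance = 1e-12)
  expect_equal(rep$recall, 522 / 558, tolerance = 1e-12)
  expect_output(print(rep), "TP 522")
  path <- withr::local_tempfile(fileext = ".json")
  write_report(path, rep)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$tp, 522)
  expect_equal(parsed$f1, rep$f1, tolerance = 1e-9)
})

test_that("cross-correlogram peaks at zero lag for identical trains and follows shifts", {
  ev <- event_series(sort(runif(40, 1, 590)), source = "labeled")
  cc <- cross_correlogram(ev, ev, 600)
  expect_equal(cc$lag_s[which.max(cc$rho)], 0)
  shifted <- event_series(ev$times + 0.010, source = "predicted")
  cc2 <- cross_correlogram(shifted, ev, 600)
  expect_equal(cc2$lag_s[which.max(cc2$rho)], 0.010, tolerance = 1e-9)
  expect_error(cross_correlogram(event_series(numeric(0)), ev, 600),
               class = "swrnet_validation_error")
})

test_that("independent Poisson trains decorrelate under the Pearson binning", {
  set.seed(77)
  for (s in 1:10) {
    a <- event_series(sort(runif(60, 0, 600)))
    b <- event_series(sort(runif(60, 0, 600)), source = "predicted")
    cc <- cross_correlogram(b, a, 600, normalization = "bins")
    expect_lt(max(abs(cc$rho)), 0.1)
  }
})

test_that("cumulative counts track identity, doubling and empty predictions", {
  lab <- event_series(c(1, 2, 3))
  cid <- cumulative_counts(lab, lab)
  expect_equal(cid$n_labeled, cid$n_predicted)
  pred2 <- event_series(sort(c(lab$times, lab$times + 0.4)),
                        source = "predicted")
  c2 <- cumulative_counts(pred2, lab)
  expect_equal(max(c2$n_predicted), 2 * max(c2$n_labeled))
  c0 <- cumulative_counts(event_series(numeric(0), source = "predicted"), lab)
  expect_true(all(c0$n_predicted == 0))
})

test_that("per-event energy scales quadratically and tracks ripple amplitude", {
  sim <- simulate_lfp(sim_spec(duration_s = 40, seed = 81))
  rec <- sim$recording
  yhat <- rep(0.5, length(rec$samples))
  tab <- energy_probability_table(rec, sim$events, yhat)
  rec2 <- lfp_recording(2 * rec$samples, fs = rec$fs)
  tab2 <- energy_probability_table(rec2, sim$events, yhat)
  expect_equal(tab2$energy_mV2, 4 * tab$energy_mV2, tolerance = 1e-6)
  zero <- lfp_recording(numeric(10 * 1250), fs = 1250)
  tz <- energy_probability_table(zero, event_series(5), rep(0.1, 12500))
  expect_equal(tz$energy_mV2, 0)
  # generator-amplitude recovery across sessions
  amps <- seq(0.05, 0.3, by = 0.05)
  med_e <- vapply(seq_along(amps), function(i) {
    s <- simulate_lfp(sim_spec(duration_s = 60, ripple_amp_mV = amps[i],
                               noise_sd_mV = 0.01, distractor_rate = 0,
                               seed = 300 + i))
    bp <- bandpass_butter(s$recording$samples, 1250)
    median(vapply(s$events$times, function(tc)
      as.numeric(signal_energy(bp, 1250, tc)), 1))
  }, 1)
  expect_gt(cor(amps, med_e, method = "spearman"), 0.9)
})
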