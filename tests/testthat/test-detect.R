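fs <- 1250

test_that("find_events handles flat, single-bump and competing-bump traces", {
  expect_length(find_events(numeric(2000), fs)$times, 0)
  tt <- seq_len(2000)
  bump <- 0.9 * exp(-((tt - 800)^2) / (2 * (0.017 * fs)^2))  # FWHM ~40 ms
  ev <- find_events(bump, fs)
  expect_length(ev$times, 1)
  expect_lt(abs(ev$times - 799 / fs), 1.5 / fs)
  b1 <- 0.9 * exp(-((tt - 800)^2) / (2 * 12^2))
  b2 <- 0.5 * exp(-((tt - 800 - round(0.03 * fs))^2) / (2 * 12^2))
  ev2 <- find_events(b1 + b2, fs)            # 30 ms apart, min distance 50 ms
  expect_length(ev2$times, 1)
  expect_lt(abs(ev2$times - 799 / fs), 2.5 / fs)  # higher bump kept
})

test_that("returned event sets always respect the minimum distance", {
  for (s in 1:30) {
    x <- random_bumpy_trace(3000, seed = 1000 + s)
    ev <- find_events(x, fs, detector_spec(threshold = 0.3))
    if (length(ev$times) > 1)
      expect_true(all(diff(ev$times) >= 0.05 - 1e-9))
  }
})

test_that("grid search ties resolve to the highest threshold and smallest width", {
  set.seed(61)
  y <- matrix(0L, 4, 1250)
  for (i in 1:4) y[i, (200 * i):(200 * i + 61)] <- 1L
  gs <- grid_search(y, y, fs)               # perfect predictions
  expect_equal(gs$best_threshold, 0.95)
  expect_equal(gs$best_width_ms, 0)
  expect_equal(gs$best_f1, 1)
  sub <- gs$grid[gs$grid$width_ms <= 45, ]
  expect_true(all(sub$f1 == 1))
})

test_that("all-zero predictions give an all-zero TP grid", {
  y <- matrix(0L, 2, 1250)
  y[, 300:361] <- 1L
  gs <- grid_search(matrix(0, 2, 1250), y, fs)
  expect_true(all(gs$grid$tp == 0))
  expect_true(all(gs$grid$fp == 0))
  expect_true(all(is.na(gs$grid$f1)))
  expect_error(grid_search(y, y, fs, thresholds = numeric(0)),
               class = "swrnet_validation_error")
})

test_that("TP and FP counts are non-increasing in the threshold at fixed width", {
  set.seed(62)
  yhat <- t(vapply(1:6, function(s) random_bumpy_trace(1250, seed = 70 + s),
                   numeric(1250)))
  y <- matrix(0L, 6, 1250); y[, 400:461] <- 1L
  gs <- grid_search(yhat, y, fs)
  for (w in unique(gs$grid$width_ms)) {
    sub <- gs$grid[gs$grid$width_ms == w, ]
    sub <- sub[order(sub$threshold), ]
    expect_true(all(diff(sub$tp) <= 0))
    expect_true(all(diff(sub$fp) <= 0))
  }
})

test_that("chunked median prediction preserves length for all offset counts", {
  m <- swrnet_init(seed = 13, lstm_units = 3, conv_filters = c(4, 3))
  for (dur in c(2.3, 3.0)) {
    rec <- lfp_recording(rnorm(round(dur * fs), sd = 0.05), fs = fs)
    for (k in c(1, 2, 5)) {
      pc <- predict_continuous(m, rec, n_offsets = k)
      expect_length(pc$yhat, length(rec$samples))
    }
  }
})

test_that("single-offset prediction equals plain chunked prediction", {
  m <- swrnet_init(seed = 14, lstm_units = 3, conv_filters = c(4, 3))
  rec <- lfp_recording(rnorm(2500, sd = 0.05), fs = fs)
  pc <- predict_continuous(m, rec, n_offsets = 1)
  chunks <- matrix(rec$samples, ncol = 625, byrow = TRUE)
  plain <- as.numeric(t(predict(m, chunks)))
  expect_equal(pc$yhat, plain, tolerance = 1e-12)
})

test_that("movement masking removes events inside the closed margin", {
  ev <- event_series(c(1.0, 2.0, 4.0, 7.5), duration = 0.05,
                     source = "predicted")
  iv <- rbind(c(3.0, 4.5))
  out <- mask_movement(ev, iv, margin_s = 1.0)
  expect_equal(out$times, c(1.0, 7.5))
  expect_equal(mask_movement(ev, NULL)$times, ev$times)
  # event exactly margin before the interval start is removed
  ev2 <- event_series(2.0, source = "predicted")
  expect_length(mask_movement(ev2, rbind(c(3.0, 3.5)), 1.0)$times, 0)
  # 1.5 s after the interval end is kept
  ev3 <- event_series(5.0, source = "predicted")
  expect_length(mask_movement(ev3, rbind(c(3.0, 3.5)), 1.0)$times, 1)
})
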