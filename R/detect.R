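# From probability traces to event times: thresholded peak detection,
# threshold x width grid search, chunked median prediction on continuous
# signals, movement masking.

#' Peak-detector settings for probability traces
#'
#' @param threshold detection threshold in (0, 1), default 0.5.
#' @param min_distance_ms minimum peak inter-distance (ms), default 50
#'   (the boxcar width D).
#' @param min_width_ms minimum peak width at half prominence (ms),
#'   default 20.
#' @return Object of class `detector_spec`.
#' @export
detector_spec <- function(threshold = 0.5, min_distance_ms = 50,
                          min_width_ms = 20) {
  if (threshold <= 0 || threshold >= 1)
    stop_invalid("threshold must be in (0, 1)")
  if (min_distance_ms < 0 || min_width_ms < 0)
    stop_invalid("distances must be >= 0")
  structure(list(threshold = threshold, min_distance_ms = min_distance_ms,
                 min_width_ms = min_width_ms),
            class = "detector_spec")
}

#' Extract candidate event times from a probability trace
#'
#' Local maxima of `yhat` with height at or above the threshold, pairwise
#' separation of at least `min_distance_ms` (ties keep the higher peak) and
#' width at half prominence of at least `min_width_ms`.
#'
#' @param yhat probability trace in `[0, 1]`.
#' @param fs sampling frequency (Hz).
#' @param spec a [detector_spec()].
#' @return An [event_series()] with `source = "predicted"`.
#' @export
find_events <- function(yhat, fs, spec = detector_spec()) {
  stopifnot(inherits(spec, "detector_spec"))
  pk <- find_peaks(as.numeric(yhat), height = spec$threshold,
                   distance = spec$min_distance_ms / 1000 * fs,
                   min_width = spec$min_width_ms / 1000 * fs)
  event_series((pk$idx - 1) / fs, duration = 0.05, source = "predicted")
}

#' Grid search over detection threshold and width
#'
#' Evaluates TP/FP/FN (via [classify_detections()]) and
#' precision/recall/F1 on aligned prediction and label traces at every
#' (threshold, width) combination, and returns the F1-maximizing pair;
#' ties resolve to the highest threshold, then the smallest width.
#'
#' @param yhat_set predictions: `n x T` matrix (or [sample_set()]-shaped
#'   array).
#' @param y_set binary labels, same shape.
#' @param fs sampling frequency (Hz).
#' @param thresholds threshold grid (default 0.1 to 0.95 in steps of 0.05).
#' @param widths_ms width grid in ms (default 0 to 50 in steps of 5).
#' @param min_distance_ms fixed minimum inter-peak distance (default 50,
#'   the boxcar width).
#' @return List with `best_threshold`, `best_width_ms`, `best_f1` and
#'   `grid`, a data.frame of TP/FP/FN/precision/recall/F1 per combination.
#' @export
grid_search <- function(yhat_set, y_set, fs,
                        thresholds = seq(0.1, 0.95, by = 0.05),
                        widths_ms = seq(0, 50, by = 5),
                        min_distance_ms = 50) {
  if (!length(thresholds) || !length(widths_ms))
    stop_invalid("threshold and width grids must be non-empty")
  yhat_set <- as_trace_matrix(yhat_set)
  y_set <- as_trace_matrix(if (inherits(y_set, "sample_set")) y_set$y else y_set)
  stopifnot(identical(dim(yhat_set), dim(y_set)))
  n <- nrow(yhat_set)
  dist_samp <- min_distance_ms / 1000 * fs
  cands <- lapply(seq_len(n), function(i) peak_candidates(yhat_set[i, ]))
  runs <- lapply(seq_len(n), function(i) label_runs(y_set[i, ]))
  grid <- expand.grid(threshold = thresholds, width_ms = widths_ms)
  counts <- vapply(seq_len(nrow(grid)), function(g) {
    thr <- grid$threshold[g]
    wd <- grid$width_ms[g] / 1000 * fs
    tp <- fp <- fn <- 0L
    for (i in seq_len(n)) {
      sel <- select_peaks(cands[[i]], height = thr, distance = dist_samp,
                          min_width = wd)
      cl <- classify_idx(sel$idx, y_set[i, ], runs[[i]])
      tp <- tp + cl[1L]; fp <- fp + cl[2L]; fn <- fn + cl[3L]
    }
    c(tp, fp, fn)
  }, integer(3))
  grid$tp <- counts[1L, ]; grid$fp <- counts[2L, ]; grid$fn <- counts[3L, ]
  prf <- precision_recall_f1(grid$tp, grid$fp, grid$fn)
  grid$precision <- prf$precision
  grid$recall <- prf$recall
  grid$f1 <- prf$f1
  f1cmp <- ifelse(is.na(grid$f1), -Inf, grid$f1)
  best <- which(f1cmp == max(f1cmp))
  best <- best[order(-grid$threshold[best], grid$width_ms[best])][1L]
  list(best_threshold = grid$threshold[best],
       best_width_ms = grid$width_ms[best],
       best_f1 = grid$f1[best], grid = grid)
}

#' Chunked median prediction on a continuous recording
#'
#' Runs the network over `n_offsets` zero-pad-shifted segmentations of the
#' signal into `chunk_s` chunks (offset k shifts by `k * chunk_len /
#' n_offsets` samples), realigns the concatenated per-chunk predictions,
#' takes the elementwise median across offsets, and runs a single final
#' peak detection on the median trace.
#'
#' @param model a fitted `swrnet`.
#' @param recording an [lfp_recording()] at the model's sampling rate.
#' @param chunk_s chunk duration (s), default 0.5.
#' @param n_offsets number of shifted segmentations, default 5
#'   (`n_offsets = 1` reduces to plain chunked prediction).
#' @param spec [detector_spec()] for the final peak detection.
#' @param batch_size prediction batch size.
#' @return List with `yhat` (probability trace, same length as the
#'   recording) and `events` (an [event_series()]).
#' @export
predict_continuous <- function(model, recording, chunk_s = 0.5, n_offsets = 5,
                               spec = detector_spec(), batch_size = 128) {
  stopifnot(inherits(model, "swrnet"), inherits(recording, "lfp_recording"))
  fs <- recording$fs
  x <- recording$samples
  n <- length(x)
  chunk_len <- round(chunk_s * fs)
  if (n < chunk_len) stop_invalid("recording shorter than one chunk")
  traces <- matrix(0, nrow = n_offsets, ncol = n)
  for (k in seq_len(n_offsets) - 1L) {
    pad_left <- round(k * chunk_len / n_offsets)
    padded <- c(numeric(pad_left), x)
    pad_right <- (-length(padded)) %% chunk_len
    padded <- c(padded, numeric(pad_right))
    chunks <- matrix(padded, ncol = chunk_len, byrow = TRUE)
    yh <- .net_forward(model$params, chunks, batch_size = as.integer(batch_size))
    flat <- as.numeric(t(yh))
    traces[k + 1L, ] <- flat[(pad_left + 1):(pad_left + n)]
  }
  med <- apply(traces, 2L, median)
  list(yhat = med, events = find_events(med, fs, spec))
}

#' Remove events near movement intervals
#'
#' Drops every event within `margin_s` of any movement interval, measuring
#' distance to the interval as a set (zero inside); the boundary is closed,
#' so an event exactly `margin_s` away is removed.
#'
#' @param events an [event_series()].
#' @param movement_intervals two-column `(start_s, stop_s)` matrix.
#' @param margin_s exclusion margin (s), default 1.
#' @export
mask_movement <- function(events, movement_intervals, margin_s = 1.0) {
  stopifnot(inherits(events, "event_series"))
  if (is.null(movement_intervals) || NROW(movement_intervals) == 0L)
    return(events)
  iv <- matrix(as.numeric(movement_intervals), ncol = 2L)
  keep <- vapply(events$times, function(t) {
    d <- pmax(iv[, 1] - t, t - iv[, 2])
    d[d < 0] <- 0
    all(d > margin_s)
  }, TRUE)
  event_series(events$times[keep], duration = events$duration,
               source = events$source)
}
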