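# Matching predicted events to one-hot labels and the derived metrics:
# precision/recall/F1, binned cross-correlogram, cumulative counts, and
# per-event band-pass signal energy.

# event time -> 1-based sample index; the small tolerance keeps times that
# sit exactly on a sample's left edge (as detector outputs do) from falling
# into the previous sample through floating-point round-off
time_index <- function(t, fs) as.integer(floor(t * fs + 1e-6)) + 1L

# maximal runs of y == 1 as a (start, end) index matrix (1-based, inclusive)
label_runs <- function(y) {
  r <- rle(as.integer(y))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- r$values == 1L
  cbind(start = starts[on], end = ends[on])
}

# core counting rule; idx are 1-based predicted sample indices
classify_idx <- function(idx, y, runs = label_runs(y)) {
  tp <- sum(y[idx] == 1L)
  fp <- length(idx) - tp
  fn <- 0L
  if (nrow(runs))
    fn <- sum(vapply(seq_len(nrow(runs)), function(r)
      !any(idx >= runs[r, 1L] & idx <= runs[r, 2L]), TRUE))
  c(tp = tp, fp = fp, fn = as.integer(fn))
}

#' Score predicted event times against a one-hot label trace
#'
#' Each predicted time is scored independently: a true positive if the
#' label trace is 1 at its sample, a false positive otherwise. Each maximal
#' run of `y = 1` containing no predicted time contributes one false
#' negative. (A prediction falling just outside a label boxcar therefore
#' produces both an FP and an FN; true negatives are not defined for sparse
#' event detection.)
#'
#' @param pred an [event_series()] (or numeric times, seconds).
#' @param y binary label trace.
#' @param fs sampling frequency (Hz).
#' @return A `detection_report`: list with counts `tp`, `fp`, `fn`,
#'   metrics `precision`, `recall`, `f1` (NA when undefined), and `pairs`,
#'   a data.frame pairing each predicted time with the center of its label
#'   run (NA for false positives).
#' @export
classify_detections <- function(pred, y, fs) {
  times <- if (inherits(pred, "event_series")) pred$times else as.numeric(pred)
  y <- as.integer(y)
  idx <- time_index(times, fs)
  if (length(idx) && (any(idx < 1L) || any(idx > length(y))))
    stop_invalid("predicted time outside the label trace")
  runs <- label_runs(y)
  cl <- classify_idx(idx, y, runs)
  pairs <- data.frame(predicted_time = times,
                      label_time = rep(NA_real_, length(times)))
  if (length(idx) && nrow(runs)) {
    for (j in seq_along(idx)) {
      r <- which(idx[j] >= runs[, 1L] & idx[j] <= runs[, 2L])
      if (length(r))
        pairs$label_time[j] <- (runs[r[1L], 1L] - 1 +
                                  (runs[r[1L], 2L] - runs[r[1L], 1L] + 1) / 2) / fs
    }
  }
  detection_report(cl[["tp"]], cl[["fp"]], cl[["fn"]], pairs = pairs)
}

#' Precision, recall and F1 from detection counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, `F1` the
#' harmonic mean of the two. A metric whose denominator is zero is
#' undefined and reported as `NA`, not 0.
#'
#' @param tp,fp,fn non-negative counts (vectorized).
#' @return data.frame with columns `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(all(tp >= 0), all(fp >= 0), all(fn >= 0))
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  data.frame(precision = precision, recall = recall, f1 = f1)
}

#' Assemble a detection report
#' @param tp,fp,fn detection counts.
#' @param pairs optional predicted/label time pairing.
#' @export
detection_report <- function(tp, fp, fn, pairs = NULL) {
  prf <- precision_recall_f1(tp, fp, fn)
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                 precision = prf$precision, recall = prf$recall, f1 = prf$f1,
                 pairs = pairs),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("<detection_report: TP %d, FP %d, FN %d | precision %.3f, recall %.3f, F1 %.3f>\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Binned cross-correlogram of two event series
#'
#' Bins both series at `bin_width_s` over the session and computes the lag
#' cross-correlation of the binned counts. `normalization = "printed"`
#' follows the source convention exactly (raw lagged product summed and
#' divided by `N = N_labeled + N_predicted`, centered by
#' `N_labeled N_predicted / N`); `"bins"` is the textbook Pearson
#' coefficient of the binned trains (`N` = number of time bins), bounded by
#' `[-1, 1]`. Both are affine in the raw lagged pair count, so the argmax
#' lag is identical under either.
#'
#' @param pred,labels non-empty [event_series()] objects.
#' @param total_duration_s session duration (s).
#' @param bin_width_s bin width Delta (s), default 0.002.
#' @param max_lag_s maximum lag (s), default 0.1; multiple of the bin.
#' @param normalization `"printed"` (default) or `"bins"`.
#' @return data.frame with columns `lag_s` and `rho`.
#' @export
cross_correlogram <- function(pred, labels, total_duration_s,
                              bin_width_s = 0.002, max_lag_s = 0.1,
                              normalization = c("printed", "bins")) {
  normalization <- match.arg(normalization)
  tp <- if (inherits(pred, "event_series")) pred$times else as.numeric(pred)
  tl <- if (inherits(labels, "event_series")) labels$times else as.numeric(labels)
  if (!length(tp) || !length(tl))
    stop_invalid("cross-correlogram undefined for empty event series")
  if (abs(max_lag_s / bin_width_s - round(max_lag_s / bin_width_s)) > 1e-9)
    stop_invalid("max_lag_s must be a multiple of bin_width_s")
  L <- round(max_lag_s / bin_width_s)
  bl <- floor(tl / bin_width_s)              # label bins
  bp <- floor(tp / bin_width_s)              # prediction bins
  lags <- (-L):L
  # raw count of (label, prediction) pairs at each bin lag
  dif <- as.vector(outer(bl, bp, function(a, b) b - a))
  raw <- vapply(lags, function(k) sum(dif == k), 1)
  n_bins <- ceiling(total_duration_s / bin_width_s)
  Nl <- length(tl); Np <- length(tp)
  if (normalization == "printed") {
    N <- Nl + Np
    rho <- (raw / N - Nl * Np / N) / sqrt((1 - Nl / N) * (1 - Np / N))
  } else {
    N <- n_bins
    rho <- (raw - Nl * Np / N) /
      sqrt(Nl * Np * (1 - Nl / N) * (1 - Np / N))
  }
  data.frame(lag_s = lags * bin_width_s, rho = rho)
}

#' Cumulative predicted vs labeled event counts
#'
#' Step functions of both counts over session time, sampled at the union
#' of event times; plotting predicted against labeled counts shows whether
#' the detector over- or under-reports proportionally.
#'
#' @param pred,labels [event_series()] objects.
#' @return data.frame with columns `time_s`, `n_labeled`, `n_predicted`.
#' @export
cumulative_counts <- function(pred, labels) {
  tp <- if (inherits(pred, "event_series")) pred$times else as.numeric(pred)
  tl <- if (inherits(labels, "event_series")) labels$times else as.numeric(labels)
  tt <- sort(unique(c(tp, tl)))
  data.frame(time_s = tt,
             n_labeled = vapply(tt, function(t) sum(tl <= t), 1),
             n_predicted = vapply(tt, function(t) sum(tp <= t), 1))
}

#' Per-event band-pass energy and predicted probability
#'
#' Band-pass filters the recording (Butterworth, 150-250 Hz), computes the
#' signal energy over +/- 100 ms around each event, and pairs it with the
#' peak of the prediction trace within the event's boxcar; the standard
#' summary relating ripple strength to detector confidence.
#'
#' @param recording an [lfp_recording()].
#' @param events an [event_series()].
#' @param yhat probability trace over the full recording.
#' @param fs sampling frequency (Hz).
#' @return data.frame with `time_s`, `energy_mV2`, `prob` (peak prediction
#'   in the boxcar), `one_minus_prob`, `truncated` (window clipped at an
#'   edge).
#' @export
energy_probability_table <- function(recording, events, yhat, fs = recording$fs) {
  stopifnot(inherits(recording, "lfp_recording"),
            inherits(events, "event_series"))
  bp <- bandpass_butter(recording$samples, fs)
  n <- length(recording$samples)
  D <- events$duration
  rows <- lapply(events$times, function(tc) {
    e <- signal_energy(bp, fs, tc)
    i0 <- max(1L, floor((tc - D / 2) * fs) + 1L)
    i1 <- min(n, floor((tc + D / 2) * fs) + 1L)
    p <- max(yhat[i0:i1])
    data.frame(time_s = tc, energy_mV2 = as.numeric(e), prob = p,
               one_minus_prob = 1 - p, truncated = attr(e, "truncated"))
  })
  do.call(rbind, rows)
}
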