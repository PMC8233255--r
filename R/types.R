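#' @useDynLib swrnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef fft median predict quantile rexp rnorm runif sd
#' @importFrom utils read.csv write.csv head
#' @keywords internal
"_PACKAGE"

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("swrnet_format_error", "error")))
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("swrnet_validation_error", "error")))
}

#' Single-channel LFP recording
#'
#' Container for a continuous single-channel local field potential trace
#' \eqn{\phi(t)} in millivolts, its sampling frequency, and optional
#' movement intervals (used to suppress detections near locomotion or
#' grooming artifacts).
#'
#' Time convention: seconds, 0-based; sample `i` (0-based) covers the
#' half-open interval `[i/fs, (i+1)/fs)`.
#'
#' @param samples numeric vector of voltages (mV); must be finite.
#' @param fs sampling frequency in Hz (> 0).
#' @param session_id character label identifying the session.
#' @param movement_intervals two-column matrix of `(start_s, stop_s)` rows,
#'   or `NULL` for none. Intervals must satisfy `start < stop` and lie
#'   within the recording.
#' @return An object of class `lfp_recording`.
#' @export
lfp_recording <- function(samples, fs, session_id = "session",
                          movement_intervals = NULL) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_invalid("fs must be a single positive number")
  samples <- as.numeric(samples)
  if (any(!is.finite(samples)))
    stop_invalid("samples contain non-finite values")
  dur <- length(samples) / fs
  if (is.null(movement_intervals) || NROW(movement_intervals) == 0L) {
    movement_intervals <- matrix(numeric(0), ncol = 2L)
  } else {
    movement_intervals <- matrix(as.numeric(movement_intervals), ncol = 2L)
    if (any(movement_intervals[, 1] >= movement_intervals[, 2]))
      stop_invalid("movement intervals must have start < stop")
    if (any(movement_intervals < 0) || any(movement_intervals > dur))
      stop_invalid("movement intervals must lie within [0, duration]")
  }
  colnames(movement_intervals) <- c("start_s", "stop_s")
  structure(
    list(samples = samples, fs = fs, session_id = as.character(session_id),
         movement_intervals = movement_intervals),
    class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording '%s': %.1f s at %g Hz (%d samples), %d movement interval(s)>\n",
              x$session_id, duration(x), x$fs, length(x$samples),
              nrow(x$movement_intervals)))
  invisible(x)
}

#' Recording duration in seconds
#' @param x an `lfp_recording`.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "lfp_recording"))
  length(x$samples) / x$fs
}

#' Series of SPW-R event times
#'
#' Labeled, predicted or baseline-detected sharp-wave ripple event times in
#' seconds, together with the boxcar label duration `D` used for one-hot
#' encoding (default 50 ms).
#'
#' @param times numeric vector of event times in seconds, strictly ascending.
#' @param duration boxcar width D in seconds (> 0), default 0.05.
#' @param source one of `"labeled"`, `"predicted"`, `"baseline"`.
#' @return An object of class `event_series`.
#' @export
event_series <- function(times, duration = 0.05,
                         source = c("labeled", "predicted", "baseline")) {
  source <- match.arg(source)
  times <- as.numeric(times)
  if (any(!is.finite(times))) stop_invalid("event times must be finite")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop_invalid("event times must be strictly ascending")
  if (!is.numeric(duration) || duration <= 0)
    stop_invalid("duration must be > 0")
  structure(list(times = times, duration = duration, source = source),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series (%s): %d events, D = %g ms>\n",
              x$source, length(x$times), 1000 * x$duration))
  invisible(x)
}

#' @export
length.event_series <- function(x) length(x$times)

#' Aligned sample arrays for training and validation
#'
#' Fixed-duration LFP segments `X` and their binary one-hot label traces
#' `y`, both of shape `(n, T, 1)`, as consumed by [swrnet()].
#'
#' @param X numeric array of shape `(n, T, 1)` (or `n x T` matrix), mV.
#' @param y binary array of the same shape.
#' @param fs sampling frequency (Hz).
#' @param sample_ids character provenance keys, `"<session>#<event>"`.
#' @return An object of class `sample_set`.
#' @export
sample_set <- function(X, y, fs, sample_ids = NULL) {
  X <- as_samples_array(X)
  y <- as_samples_array(y)
  if (!identical(dim(X), dim(y)))
    stop_invalid("X and y must have identical shapes")
  if (length(y) && !all(y %in% c(0, 1)))
    stop_invalid("y must be binary (0/1)")
  if (!is.numeric(fs) || fs <= 0) stop_invalid("fs must be positive")
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(dim(X)[1L]))
  if (length(sample_ids) != dim(X)[1L])
    stop_invalid("sample_ids length must equal the number of samples")
  structure(list(X = X, y = y, fs = fs, sample_ids = as.character(sample_ids)),
            class = "sample_set")
}

as_samples_array <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(nrow(x), ncol(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3L] != 1L)
    stop_invalid("samples must be an (n, T, 1) array")
  storage.mode(x) <- "double"
  x
}

#' @export
print.sample_set <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("<sample_set: %d samples x %d time steps at %g Hz>\n",
              d[1L], d[2L], x$fs))
  invisible(x)
}

# internal: n x T matrix view of a sample_set / array / vector
as_trace_matrix <- function(x) {
  if (inherits(x, "sample_set")) x <- x$X
  if (is.array(x) && length(dim(x)) == 3L) x <- matrix(x, nrow = dim(x)[1L])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (is.data.frame(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}
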