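# Turning (recording, events) pairs into fixed-duration training samples
# with boxcar one-hot labels.

#' Sample extraction settings
#'
#' Each labeled event yields one `T_sample` segment whose position is
#' jittered by a uniform offset bounded by `(T_sample - 3 D) / 2`, which
#' guarantees the generating event's full boxcar stays inside the segment.
#'
#' @param T_sample_s segment duration (s), default 1.
#' @param duration_D_s boxcar label width D (s), default 0.05.
#' @param seed integer seed for the offset draws.
#' @return Object of class `extraction_spec` (with the derived
#'   `offset_bound_s`).
#' @export
extraction_spec <- function(T_sample_s = 1.0, duration_D_s = 0.05, seed = 1L) {
  if (T_sample_s <= 3 * duration_D_s)
    stop_invalid("T_sample must exceed 3 * D")
  structure(list(T_sample_s = T_sample_s, duration_D_s = duration_D_s,
                 offset_bound_s = (T_sample_s - 3 * duration_D_s) / 2,
                 seed = as.integer(seed)),
            class = "extraction_spec")
}

#' One-hot encode event times as a binary boxcar trace
#'
#' `y(t) = 1` on the union of boxcars `[t_i - D/2, t_i + D/2)`; overlapping
#' boxcars are clipped at 1. Discretization: sample `i` (0-based, covering
#' `[i/fs, (i+1)/fs)`) is set when it lies fully inside the boxcar, i.e.
#' `i` in `[ceil((t - D/2) fs), floor((t + D/2) fs))`; at `fs` = 1250 and
#' D = 50 ms an isolated event yields a 62- or 63-sample boxcar depending
#' on its phase relative to the grid.
#'
#' @param events an [event_series()] (or numeric times).
#' @param n_samples length of the output trace.
#' @param fs sampling frequency (Hz).
#' @param D boxcar width (s); defaults to the series' `duration`.
#' @return Integer vector in \{0, 1\} of length `n_samples`.
#' @export
one_hot_encode <- function(events, n_samples, fs, D = NULL) {
  times <- if (inherits(events, "event_series")) events$times else as.numeric(events)
  if (is.null(D))
    D <- if (inherits(events, "event_series")) events$duration else 0.05
  y <- integer(n_samples)
  if (!length(times)) return(y)
  if (any(times < 0 | times > n_samples / fs))
    stop_invalid("event outside the trace duration")
  i0 <- ceiling((times - D / 2) * fs)          # 0-based, inclusive
  i1 <- floor((times + D / 2) * fs)            # 0-based, exclusive
  i0 <- pmax(i0, 0)
  i1 <- pmin(i1, n_samples)
  for (k in seq_along(times))
    if (i1[k] > i0[k]) y[(i0[k] + 1):i1[k]] <- 1L
  y
}

#' Decode event centers from a one-hot trace
#'
#' Inverse of [one_hot_encode()] for isolated boxcars: each maximal run of
#' ones maps to its center time. Recovers the encoded times to within
#' `1/fs`.
#'
#' @param y binary trace.
#' @param fs sampling frequency (Hz).
#' @param D boxcar width used for the returned series.
#' @export
decode_events <- function(y, fs, D = 0.05) {
  r <- rle(as.integer(y))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values == 1L)
  centers <- (starts[on] - 1 + r$lengths[on] / 2) / fs
  event_series(centers, duration = D, source = "labeled")
}

#' Extract fixed-duration training samples around labeled events
#'
#' One `(X, y)` segment per labeled event, on the window
#' `[t - offset - T_sample/2, t - offset + T_sample/2)` with the offset
#' drawn uniformly from the spec's bound. The label trace is the session's
#' full one-hot encoding sliced to the window, so neighboring events inside
#' the window are labeled too. Events closer than `T_sample` to a session
#' edge are skipped with a warning.
#'
#' @param recording an [lfp_recording()].
#' @param events an [event_series()].
#' @param spec an [extraction_spec()].
#' @return A [sample_set()]; deterministic for a fixed spec seed.
#' @export
extract_samples <- function(recording, events, spec = extraction_spec()) {
  stopifnot(inherits(recording, "lfp_recording"),
            inherits(events, "event_series"),
            inherits(spec, "extraction_spec"))
  fs <- recording$fs
  Tn <- round(spec$T_sample_s * fs)
  dur <- duration(recording)
  set.seed(spec$seed)
  ok <- events$times >= spec$T_sample_s & events$times <= dur - spec$T_sample_s
  if (any(!ok))
    warning(sum(!ok), " event(s) within T_sample of a session edge skipped")
  times <- events$times[ok]
  n <- length(times)
  yfull <- one_hot_encode(events, length(recording$samples), fs,
                          D = spec$duration_D_s)
  X <- array(0, dim = c(n, Tn, 1L))
  y <- array(0L, dim = c(n, Tn, 1L))
  b <- spec$offset_bound_s
  for (j in seq_len(n)) {
    off <- if (b > 0) runif(1, -b, b) else 0
    s0 <- floor((times[j] - off - spec$T_sample_s / 2) * fs)   # 0-based
    idx <- (s0 + 1):(s0 + Tn)
    X[j, , 1L] <- recording$samples[idx]
    y[j, , 1L] <- yfull[idx]
  }
  sample_set(X, y, fs = fs,
             sample_ids = sprintf("%s#%d", recording$session_id, which(ok)))
}

#' Shuffle and split a sample set into train / validation / holdout
#'
#' Samples from `holdout_session_ids` are removed before the shuffle; the
#' remainder is shuffled deterministically under `seed` and split into
#' `n - n_val` training and `n_val` validation samples.
#'
#' @param sampleset a [sample_set()].
#' @param n_val number of validation samples (`< n` after holdout removal).
#' @param holdout_session_ids character session ids to set aside entirely.
#' @param seed shuffle seed.
#' @return List with `train`, `val`, `holdout` (all [sample_set()]).
#' @export
split_dataset <- function(sampleset, n_val, holdout_session_ids = character(0),
                          seed = 1L) {
  stopifnot(inherits(sampleset, "sample_set"))
  sessions <- sub("#.*$", "", sampleset$sample_ids)
  hold <- sessions %in% holdout_session_ids
  if (all(hold)) stop_invalid("all sessions held out; nothing to train on")
  take <- function(i) sample_set(
    sampleset$X[i, , , drop = FALSE], sampleset$y[i, , , drop = FALSE],
    fs = sampleset$fs, sample_ids = sampleset$sample_ids[i])
  pool <- which(!hold)
  if (n_val >= length(pool)) stop_invalid("n_val must be < number of samples")
  set.seed(seed)
  perm <- sample(pool)
  list(train = take(perm[(n_val + 1):length(perm)]),
       val = take(perm[seq_len(n_val)]),
       holdout = take(which(hold)))
}

#' Combine sample sets
#' @param ... [sample_set()] objects with matching `T` and `fs`.
#' @export
bind_samplesets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !inherits(sets[[1L]], "sample_set"))
    sets <- sets[[1L]]
  stopifnot(all(vapply(sets, inherits, TRUE, "sample_set")))
  Ts <- vapply(sets, function(s) dim(s$X)[2L], 1)
  fss <- vapply(sets, function(s) s$fs, 1)
  if (length(unique(Ts)) != 1L || length(unique(fss)) != 1L)
    stop_invalid("sample sets must share T and fs")
  X <- do.call(abind3, lapply(sets, function(s) s$X))
  y <- do.call(abind3, lapply(sets, function(s) s$y))
  sample_set(X, y, fs = fss[1L],
             sample_ids = unlist(lapply(sets, function(s) s$sample_ids)))
}

# bind (n, T, 1) arrays along the first axis
abind3 <- function(...) {
  parts <- list(...)
  Tn <- dim(parts[[1L]])[2L]
  m <- do.call(rbind, lapply(parts, function(a) matrix(a, nrow = dim(a)[1L])))
  array(m, dim = c(nrow(m), Tn, 1L))
}
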