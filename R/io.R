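# HDF5 session/sample containers and CSV/JSON side files.
#
# Session files:  dataset "lfp" (float, mV) with attribute "fs" (Hz) and
#                 "session_id"; optional dataset "movement" (n x 2, seconds).
# Sample files:   datasets "X" and "y", shape (n, T, 1); attribute "fs".
# Event files:    CSV with header, columns time_s, duration_s.

h5_datasets <- function(path) {
  info <- rhdf5::h5ls(path)
  info$name[info$otype == "H5I_DATASET"]
}

#' Write an LFP session to HDF5
#'
#' @param path output file path (overwritten if present).
#' @param recording an [lfp_recording()].
#' @export
write_session <- function(path, recording) {
  stopifnot(inherits(recording, "lfp_recording"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(recording$samples, path, "lfp")
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "lfp")
  rhdf5::h5writeAttribute(recording$fs, did, "fs")
  rhdf5::h5writeAttribute(recording$session_id, did, "session_id")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  if (nrow(recording$movement_intervals) > 0L)
    rhdf5::h5write(recording$movement_intervals, path, "movement")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read an LFP session from HDF5
#'
#' @param path an HDF5 file written by [write_session()] (dataset `lfp` with
#'   `fs` attribute, optional `movement` dataset).
#' @return An [lfp_recording()].
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  ds <- h5_datasets(path)
  if (!"lfp" %in% ds) stop_format("missing dataset 'lfp' in ", path)
  samples <- as.numeric(rhdf5::h5read(path, "lfp"))
  att <- rhdf5::h5readAttributes(path, "lfp")
  if (is.null(att$fs)) stop_format("dataset 'lfp' lacks required attribute 'fs'")
  session_id <- if (is.null(att$session_id)) "session" else as.character(att$session_id)
  movement <- NULL
  if ("movement" %in% ds) movement <- rhdf5::h5read(path, "movement")
  rhdf5::h5closeAll()
  if (any(!is.finite(samples)))
    stop_invalid("session contains non-finite samples: ", path)
  lfp_recording(samples, fs = as.numeric(att$fs), session_id = session_id,
                movement_intervals = movement)
}

#' Write a sample set to HDF5
#'
#' Stores `X` and `y` as `(n, T, 1)` arrays plus the `fs` attribute, the
#' standard layout for training/validation files.
#'
#' @param path output file path.
#' @param sampleset a [sample_set()].
#' @export
write_sampleset <- function(path, sampleset) {
  stopifnot(inherits(sampleset, "sample_set"))
  if (file.exists(path)) unlink(path)
  d <- dim(sampleset$X)
  rhdf5::h5createFile(path)
  # rhdf5 cannot create zero-extent datasets portably; record shape instead
  if (d[1L] > 0L) {
    rhdf5::h5write(sampleset$X, path, "X")
    rhdf5::h5write(sampleset$y, path, "y")
  }
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(sampleset$fs, fid, "fs")
  rhdf5::h5writeAttribute(d, fid, "shape")
  if (length(sampleset$sample_ids))
    rhdf5::h5writeAttribute(sampleset$sample_ids, fid, "sample_ids")
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a sample set from HDF5
#' @param path a file written by [write_sampleset()].
#' @return A [sample_set()].
#' @export
read_sampleset <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  att <- rhdf5::h5readAttributes(path, "/")
  if (is.null(att$fs)) stop_format("sample file lacks required attribute 'fs'")
  d <- as.integer(att$shape)
  if (d[1L] == 0L) {
    X <- array(numeric(0), dim = d)
    y <- X
  } else {
    X <- rhdf5::h5read(path, "X")
    y <- rhdf5::h5read(path, "y")
  }
  ids <- if (is.null(att$sample_ids)) NULL else as.character(att$sample_ids)
  rhdf5::h5closeAll()
  sample_set(X, y, fs = as.numeric(att$fs), sample_ids = ids)
}

#' Write event times to CSV
#'
#' Two-column dialect `time_s, duration_s` with a header row; the duration
#' column carries the boxcar width `D` (rat-style labels store durations,
#' mouse-style labels do not, so a constant column keeps both readable).
#'
#' @param path output CSV path.
#' @param events an [event_series()].
#' @export
write_events <- function(path, events) {
  stopifnot(inherits(events, "event_series"))
  df <- data.frame(time_s = events$times,
                   duration_s = rep(events$duration, length(events$times)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read event times from CSV
#' @param path CSV with header columns `time_s` and optionally `duration_s`.
#' @param source event provenance tag, see [event_series()].
#' @export
read_events <- function(path, source = "labeled") {
  if (!file.exists(path)) stop_format("no such file: ", path)
  df <- read.csv(path)
  if (!"time_s" %in% names(df))
    stop_format("event CSV must have a 'time_s' column with header")
  dur <- if ("duration_s" %in% names(df) && nrow(df) > 0L &&
             all(is.finite(df$duration_s))) df$duration_s[1L] else 0.05
  event_series(sort(df$time_s), duration = dur, source = source)
}

#' Write a detection report to JSON
#' @param path output path.
#' @param report a `detection_report` from [classify_detections()].
#' @export
write_report <- function(path, report) {
  stopifnot(inherits(report, "detection_report"))
  x <- unclass(report)
  x$pairs <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
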