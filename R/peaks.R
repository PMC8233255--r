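# Peak finding on 1-D traces, following the conventions of the peak finder
# used throughout this field's detection pipelines: local maxima with plateau
# midpoints, prominence measured against the surrounding higher terrain,
# width measured at half prominence with linear interpolation, and a
# minimum-distance constraint resolved by keeping higher peaks first.

#' Locate candidate peaks and their properties
#'
#' Finds all interior local maxima of `x` (plateaus reduce to their midpoint
#' sample) and computes height, prominence and width at half prominence for
#' each. Used by [find_events()], [detect_baseline()] and [grid_search()];
#' exposed for diagnostics.
#'
#' @param x numeric trace.
#' @return data.frame with columns `idx` (1-based sample index), `height`,
#'   `prominence`, `width` (samples, interpolated), `left_base`, `right_base`.
#' @export
peak_candidates <- function(x) {
  n <- length(x)
  empty <- data.frame(idx = integer(0), height = numeric(0),
                      prominence = numeric(0), width = numeric(0),
                      left_base = integer(0), right_base = integer(0))
  if (n < 3L) return(empty)
  r <- rle(as.numeric(x))
  k <- length(r$values)
  if (k < 3L) return(empty)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mid <- 2:(k - 1L)
  is_peak <- r$values[mid] > r$values[mid - 1L] & r$values[mid] > r$values[mid + 1L]
  runs <- mid[is_peak]
  if (!length(runs)) return(empty)
  idx <- as.integer(floor((starts[runs] + ends[runs]) / 2))
  height <- x[idx]
  m <- length(idx)
  prominence <- numeric(m)
  left_base <- integer(m)
  right_base <- integer(m)
  width <- numeric(m)
  for (p in seq_len(m)) {
    i <- idx[p]; h <- height[p]
    # leftward: scan until a strictly higher sample or the signal edge;
    # base is the minimum over the scanned range
    lb <- i; lmin <- h
    j <- i - 1L
    while (j >= 1L && x[j] <= h) {
      if (x[j] < lmin) { lmin <- x[j]; lb <- j }
      j <- j - 1L
    }
    rb <- i; rmin <- h
    j <- i + 1L
    while (j <= n && x[j] <= h) {
      if (x[j] < rmin) { rmin <- x[j]; rb <- j }
      j <- j + 1L
    }
    prom <- h - max(lmin, rmin)
    prominence[p] <- prom
    left_base[p] <- lb
    right_base[p] <- rb
    # width at half prominence
    heval <- h - 0.5 * prom
    j <- i
    while (j > lb && x[j] > heval) j <- j - 1L
    lip <- j
    if (x[j] < heval) lip <- j + (heval - x[j]) / (x[j + 1L] - x[j])
    j <- i
    while (j < rb && x[j] > heval) j <- j + 1L
    rip <- j
    if (x[j] < heval) rip <- j - (heval - x[j]) / (x[j - 1L] - x[j])
    width[p] <- rip - lip
  }
  data.frame(idx = idx, height = height, prominence = prominence,
             width = width, left_base = left_base, right_base = right_base)
}

# Apply the selection chain to precomputed candidates, in the peak-finder's
# canonical order: height, then distance (priority to higher peaks), then
# width. `height` may be a scalar or a per-sample threshold trace evaluated
# at the peak position.
select_peaks <- function(cands, height = NULL, distance = 1,
                         min_width = 0) {
  if (!is.null(height)) {
    thr <- if (length(height) > 1L) height[cands$idx] else height
    cands <- cands[cands$height >= thr, , drop = FALSE]
  }
  if (distance > 1 && nrow(cands) > 1L) {
    keep <- rep(TRUE, nrow(cands))
    priority <- order(cands$height, decreasing = TRUE)
    pos <- cands$idx
    for (p in priority) {
      if (!keep[p]) next
      j <- p - 1L
      while (j >= 1L && pos[p] - pos[j] < distance) { keep[j] <- FALSE; j <- j - 1L }
      j <- p + 1L
      while (j <= length(pos) && pos[j] - pos[p] < distance) { keep[j] <- FALSE; j <- j + 1L }
    }
    cands <- cands[keep, , drop = FALSE]
  }
  if (min_width > 0) cands <- cands[cands$width >= min_width, , drop = FALSE]
  cands[order(cands$idx), , drop = FALSE]
}

find_peaks <- function(x, height = NULL, distance = 1, min_width = 0) {
  select_peaks(peak_candidates(x), height = height, distance = distance,
               min_width = min_width)
}
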