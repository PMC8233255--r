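# Brute-force oracles, written as direct, naive enumerations so they stay
# independent of the package's implementations.

# naive peak finder: scan for local maxima (plateau midpoints), then filter
# by height, by distance (greedy, highest first), then by width at half
# prominence -- each property computed by whole-vector scans
oracle_find_peaks <- function(x, height = -Inf, distance = 1, min_width = 0) {
  n <- length(x)
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) peaks <- c(peaks, floor((i + j) / 2))
      i <- j + 1L
    } else i <- i + 1L
  }
  thr <- if (length(height) > 1L) height[peaks] else rep(height, length(peaks))
  peaks <- peaks[x[peaks] >= thr]
  # distance: repeatedly keep the highest remaining, drop all closer ones
  if (length(peaks) > 1L && distance > 1) {
    remaining <- peaks[order(-x[peaks])]
    kept <- integer(0)
    removed <- integer(0)
    for (p in remaining) {
      if (p %in% removed) next
      kept <- c(kept, p)
      removed <- c(removed, setdiff(
        peaks[abs(peaks - p) < distance & peaks != p], kept))
    }
    peaks <- sort(kept)
  }
  if (min_width > 0 && length(peaks)) {
    widths <- vapply(peaks, function(p) oracle_peak_width(x, p), 1)
    peaks <- peaks[widths >= min_width]
  }
  sort(peaks)
}

oracle_peak_width <- function(x, p) {
  n <- length(x)
  # prominence bases: nearest strictly higher point on each side bounds the
  # search range; the minimum in each range is the base
  lrange <- p; while (lrange > 1L && x[lrange - 1L] <= x[p]) lrange <- lrange - 1L
  rrange <- p; while (rrange < n && x[rrange + 1L] <= x[p]) rrange <- rrange + 1L
  lmin_i <- (lrange:p)[which.min(x[lrange:p])]
  rmin_i <- (p:rrange)[which.min(x[p:rrange])]
  prom <- x[p] - max(x[lmin_i], x[rmin_i])
  heval <- x[p] - 0.5 * prom
  i <- p
  while (i > lmin_i && x[i] > heval) i <- i - 1L
  left <- if (x[i] < heval) i + (heval - x[i]) / (x[i + 1L] - x[i]) else i
  i <- p
  while (i < rmin_i && x[i] > heval) i <- i + 1L
  right <- if (x[i] < heval) i - (heval - x[i]) / (x[i - 1L] - x[i]) else i
  right - left
}

# naive detection scoring: loop over predictions, then walk the label runs
oracle_classify <- function(pred_idx, y) {
  tp <- 0L; fp <- 0L
  for (i in pred_idx) {
    if (y[i] == 1L) tp <- tp + 1L else fp <- fp + 1L
  }
  fn <- 0L
  n <- length(y)
  i <- 1L
  while (i <= n) {
    if (y[i] == 1L) {
      j <- i
      while (j < n && y[j + 1L] == 1L) j <- j + 1L
      if (!any(pred_idx >= i & pred_idx <= j)) fn <- fn + 1L
      i <- j + 1L
    } else i <- i + 1L
  }
  c(tp = tp, fp = fp, fn = fn)
}

# a smooth random trace with a handful of bumps, for property tests
random_bumpy_trace <- function(n = 2000, seed = 1) {
  set.seed(seed)
  x <- numeric(n)
  for (k in seq_len(sample(2:6, 1))) {
    c0 <- sample(seq(50, n - 50), 1)
    w <- runif(1, 5, 60)
    a <- runif(1, 0.2, 1)
    x <- x + a * exp(-((seq_len(n) - c0)^2) / (2 * w^2))
  }
  pmin(x + abs(rnorm(n, sd = 0.02)), 1)
}

make_toy_sampleset <- function(n = 8, T = 200, fs = 1250, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * T, sd = 0.05), n, T)
  y <- matrix(0L, n, T)
  for (i in seq_len(n)) {
    c0 <- sample(seq(60, T - 60), 1)
    y[i, c0:(c0 + 30)] <- 1L
    X[i, c0:(c0 + 30)] <- X[i, c0:(c0 + 30)] +
      0.1 * sin(2 * pi * 0.13 * seq_len(31))
  }
  sample_set(array(X, c(n, T, 1)), array(y, c(n, T, 1)), fs = fs)
}
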