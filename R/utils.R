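# Internal helpers shared across modules.

# Classed conditions so callers can distinguish config errors, degenerate
# inputs and session-exclusion signals from generic failures.
stop_custom <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "photomotor_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_custom("invalid_config", sprintf("`%s` must be a positive finite scalar", name))
  }
  invisible(x)
}

# Derive a reproducible sub-stream seed for one named component so that the
# single config seed governs every draw without coupling the components.
substream_seed <- function(seed, k) {
  (as.integer(seed) %% 100000L) * 13L + 7L * as.integer(k)
}

#' Centered moving average with shrinking edge windows
#'
#' Boxcar smoother used throughout the pipeline (0.5 s transient
#' pre-smoothing, 2 s speed smoothing). The window is truncated at the
#' series boundaries rather than padded, so a constant series is preserved
#' exactly everywhere including the edges.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param width_s window width in seconds; must span at least one sample.
#' @return numeric series, same length as `x`.
#' @export
moving_average <- function(x, fs, width_s = 0.5) {
  assert_positive(fs, "fs")
  assert_positive(width_s, "width_s")
  n <- length(x)
  w <- max(1L, round(width_s * fs))
  if (w <= 1L || n <= 1L) return(x)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Running percentile over a centered window, evaluated on a stride and
# linearly interpolated between evaluation points (exact when the window
# covers the whole series). Used for the 8th-percentile baseline.
running_percentile <- function(x, window_samples, q, stride = NULL) {
  n <- length(x)
  w <- min(window_samples, n)
  if (w < 3L) stop_custom("invalid_window", "percentile window must span at least 3 samples")
  if (w >= n) return(rep(stats::quantile(x, q / 100, names = FALSE), n))
  if (is.null(stride)) stride <- max(1L, w %/% 10L)
  h <- w %/% 2L
  at <- unique(c(seq(1L, n, by = stride), n))
  vals <- vapply(at, function(i) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    stats::quantile(x[lo:hi], q / 100, names = FALSE)
  }, numeric(1))
  if (length(at) == 1L) return(rep(vals, n))
  stats::approx(at, vals, xout = seq_len(n), rule = 2)$y
}

# Interior local extrema of a series; returns indices. A plateau reports its
# first sample. Boundaries are never extrema.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  d_sign <- sign(d)
  # carry the sign of the last non-flat step through plateaus
  for (i in seq_along(d_sign)[-1]) {
    if (d_sign[i] == 0) d_sign[i] <- d_sign[i - 1L]
  }
  which(diff(d_sign) < 0) + 1L
}

local_minima <- function(x) local_maxima(-x)

percent_round1 <- function(x) {
  # half-away-from-zero at one decimal
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}
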