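# Dual-channel photometry processing: session container, downsampling,
# isosbestic baseline fit, dFF, robust z, percentile baseline, transients.

#' Construct a photometry session
#'
#' Holds the raw two-channel fluorescence stream (465 nm calcium-dependent
#' signal and 405 nm isosbestic control) on a uniform time grid, plus any
#' behavioral / laser event timestamps.
#'
#' @param time_s sample times in seconds, strictly increasing and uniform.
#' @param f465,f405 fluorescence (arbitrary units), same length as `time_s`.
#' @param fs sampling rate in Hz; inferred from `time_s` when `NULL`.
#' @param events optional `event_set` (see [event_set()]).
#' @return object of class `photometry_session`.
#' @export
photometry_session <- function(time_s, f465, f405, fs = NULL, events = NULL) {
  if (length(time_s) < 2L) stop_custom("invalid_config", "session needs >= 2 samples")
  if (length(f465) != length(time_s) || length(f405) != length(time_s)) {
    stop_custom("invalid_config", "f465/f405 must match time_s in length")
  }
  dt <- diff(time_s)
  if (any(dt <= 0)) stop_custom("invalid_config", "time_s must be strictly increasing")
  if (diff(range(dt)) > 1e-9 * max(dt)) {
    stop_custom("invalid_config", "time_s must be uniform within 1e-9 relative tolerance")
  }
  if (is.null(fs)) fs <- 1 / mean(dt)
  structure(list(time_s = time_s, f465 = f465, f405 = f405,
                 fs = fs, events = events),
            class = "photometry_session")
}

#' @export
print.photometry_session <- function(x, ...) {
  cat(sprintf("<photometry_session> %d samples @ %.4g Hz, %.1f-%.1f s\n",
              length(x$time_s), x$fs, x$time_s[1], x$time_s[length(x$time_s)]))
  invisible(x)
}

#' Downsample and trim a photometry session
#'
#' Decimation is by block means (each output sample is the mean of `factor`
#' consecutive input samples), which anti-aliases at the same stroke. The
#' initial `trim_s` seconds -- dominated by fast bleaching and settling --
#' are then discarded. Event timestamps keep their absolute times; events
#' falling in the trimmed span are dropped.
#'
#' @param session a `photometry_session`.
#' @param factor integer decimation factor (>= 1).
#' @param trim_s seconds to discard from the start (default 180 s).
#' @return a new `photometry_session` at `fs / factor`.
#' @export
downsample_and_trim <- function(session, factor = 10L, trim_s = 180) {
  stopifnot(inherits(session, "photometry_session"))
  factor <- as.integer(factor)
  if (factor < 1L) stop_custom("invalid_config", "factor must be >= 1")
  dur <- session$time_s[length(session$time_s)] - session$time_s[1]
  if (trim_s >= dur) stop_custom("empty_session", "trim_s >= session duration")
  n <- length(session$time_s)
  nb <- n %/% factor
  if (factor > 1L) {
    idx <- seq_len(nb * factor)
    g <- rep(seq_len(nb), each = factor)
    time_s <- tapply(session$time_s[idx], g, mean)
    f465 <- tapply(session$f465[idx], g, mean)
    f405 <- tapply(session$f405[idx], g, mean)
  } else {
    time_s <- session$time_s; f465 <- session$f465; f405 <- session$f405
  }
  keep <- time_s >= session$time_s[1] + trim_s
  ev <- session$events
  if (!is.null(ev)) ev <- ev[ev$time_s >= session$time_s[1] + trim_s, , drop = FALSE]
  photometry_session(as.numeric(time_s[keep]), as.numeric(f465[keep]),
                     as.numeric(f405[keep]), fs = session$fs / factor,
                     events = ev)
}

#' Least-squares isosbestic fit
#'
#' Fits the 405 nm control channel to the 465 nm signal channel by ordinary
#' least squares, yielding the activity-independent baseline
#' `F0 = slope * f405 + intercept`. The fit span can be restricted (e.g. to
#' rest epochs flanking a rotarod run) while `F0` is still predicted over
#' the full series.
#'
#' @param f465,f405 numeric series of equal length (>= 2).
#' @param span optional integer indices to restrict the fitting span.
#' @return list with `fit` (class `control_fit`: slope, intercept,
#'   residual_rms) and `f0` (fitted baseline over the full series).
#' @export
fit_isosbestic <- function(f465, f405, span = NULL) {
  if (length(f465) != length(f405) || length(f465) < 2L) {
    stop_custom("invalid_config", "f465/f405 must have equal length >= 2")
  }
  xs <- if (is.null(span)) f405 else f405[span]
  ys <- if (is.null(span)) f465 else f465[span]
  if (stats::sd(xs) == 0) stop_custom("degenerate_fit", "f405 is constant over the fitting span")
  slope <- stats::cov(xs, ys) / stats::var(xs)
  intercept <- mean(ys) - slope * mean(xs)
  f0 <- slope * f405 + intercept
  resid <- ys - (slope * xs + intercept)
  fit <- structure(list(slope = slope, intercept = intercept,
                        residual_rms = sqrt(mean(resid^2))),
                   class = "control_fit")
  list(fit = fit, f0 = f0)
}

#' Fractional fluorescence change (dFF, percent)
#'
#' `dff[i] = 100 * (f[i] - f0[i]) / f0[i]`.
#'
#' @param f signal series (465 nm).
#' @param f0 fitted baseline, strictly positive elementwise.
#' @return dFF in percent.
#' @export
compute_dff <- function(f, f0) {
  if (length(f) != length(f0)) stop_custom("invalid_config", "f and f0 lengths differ")
  bad <- which(f0 <= 0)
  if (length(bad)) {
    stop_custom("division_guard",
                sprintf("f0 <= 0 at %d sample(s), first indices: %s",
                        length(bad), paste(head(bad, 5L), collapse = ", ")),
                indices = bad)
  }
  100 * (f - f0) / f0
}

#' Robust (MAD) z-score
#'
#' Modified z-score `0.6745 * (x - median(x)) / MAD(x)` with MAD the raw
#' median absolute deviation from the median (unscaled); the 0.6745 factor
#' makes the score consistent with a standard z under normality. The median
#' of the output is exactly 0.
#'
#' @param x numeric series with non-zero MAD.
#' @return dimensionless robust z-score series.
#' @export
robust_zscore <- function(x) {
  med <- stats::median(x)
  mad_raw <- stats::median(abs(x - med))
  if (mad_raw == 0) stop_custom("degenerate_scale", "MAD is zero (constant input)")
  0.6745 * (x - med) / mad_raw
}

#' Moving-percentile baseline correction
#'
#' Subtracts a running low percentile (default the 8th) computed in a
#' centered moving window, removing slow baseline shifts while leaving fast
#' transients intact. In rest-anchored mode (`spans` given, as for rotarod
#' trials) the percentile is computed on the designated rest spans only and
#' linearly interpolated across the intervening run so the running epoch is
#' not deformed by its own activity.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param window_s moving-window width in seconds (default 30 s).
#' @param q percentile in (0, 100), default 8.
#' @param spans optional logical vector (same length as `x`) marking the
#'   rest samples the baseline may be estimated from.
#' @return baseline-corrected series.
#' @export
baseline_correct_percentile <- function(x, fs, window_s = 30, q = 8, spans = NULL) {
  assert_positive(window_s, "window_s")
  w <- round(window_s * fs)
  if (w < 3L) stop_custom("invalid_window", "window shorter than 3 samples")
  if (is.null(spans)) {
    base <- running_percentile(x, w, q)
  } else {
    stopifnot(length(spans) == length(x))
    idx <- which(spans)
    if (length(idx) < 3L) stop_custom("invalid_window", "too few baseline samples in spans")
    pct <- running_percentile(x[idx], min(w, length(idx)), q)
    base <- stats::approx(idx, pct, xout = seq_along(x), rule = 2)$y
  }
  x - base
}

#' Detect calcium transients and summarize per-epoch metrics
#'
#' Local maxima of the (typically pre-smoothed, z-scored) trace are accepted
#' as transient peaks when their amplitude relative to the nearest preceding
#' local minimum reaches `min_prominence` and consecutive peaks are at least
#' `min_separation_s` apart (the smaller of two close peaks is dropped).
#'
#' @param z z-scored (or dFF) series.
#' @param fs sampling rate in Hz.
#' @param min_prominence minimal peak height above the preceding local
#'   minimum, in units of `z` (default 0.5).
#' @param min_separation_s minimal inter-peak separation (default 0.2 s).
#' @param baseline_window_s window for the moving 8th-percentile baseline
#'   level reported alongside the peak metrics.
#' @return object of class `transient_metrics`: `peak_times_s`,
#'   `peak_amplitudes` (peak minus preceding local minimum),
#'   `interpeak_intervals_s`, `peak_frequency` (peaks per second),
#'   `auc_per_s` (trapezoidal area divided by epoch duration) and
#'   `baseline_level` (mean moving 8th percentile).
#' @export
detect_transients <- function(z, fs, min_prominence = 0.5, min_separation_s = 0.2,
                              baseline_window_s = 30) {
  n <- length(z)
  if (n < 3L) {
    return(structure(list(peak_times_s = numeric(0), peak_amplitudes = numeric(0),
                          interpeak_intervals_s = numeric(0), peak_frequency = 0,
                          auc_per_s = NA_real_, baseline_level = NA_real_),
                     class = "transient_metrics"))
  }
  t_s <- (seq_len(n) - 1L) / fs
  dur <- t_s[n] - t_s[1]
  maxi <- local_maxima(z)
  mini <- local_minima(z)
  amp <- vapply(maxi, function(i) {
    prev_min <- mini[mini < i]
    ref <- if (length(prev_min)) z[prev_min[length(prev_min)]] else z[1]
    z[i] - ref
  }, numeric(1))
  keep <- amp >= min_prominence
  maxi <- maxi[keep]; amp <- amp[keep]
  # enforce separation, dropping the smaller of any close pair
  if (length(maxi) > 1L) {
    ord <- order(z[maxi], decreasing = TRUE)
    sel <- logical(length(maxi))
    taken <- numeric(0)
    for (j in ord) {
      if (!length(taken) || all(abs(t_s[maxi[j]] - taken) >= min_separation_s)) {
        sel[j] <- TRUE
        taken <- c(taken, t_s[maxi[j]])
      }
    }
    maxi <- maxi[sel]; amp <- amp[sel]
  }
  o <- order(maxi)
  maxi <- maxi[o]; amp <- amp[o]
  base <- if (n >= 3L && round(baseline_window_s * fs) >= 3L) {
    mean(running_percentile(z, round(baseline_window_s * fs), 8))
  } else NA_real_
  structure(list(
    peak_times_s = t_s[maxi],
    peak_amplitudes = amp,
    interpeak_intervals_s = diff(t_s[maxi]),
    peak_frequency = if (dur > 0) length(maxi) / dur else 0,
    auc_per_s = if (dur > 0) pracma::trapz(t_s, z) / dur else NA_real_,
    baseline_level = base
  ), class = "transient_metrics")
}

#' Full photometry preprocessing chain
#'
#' Convenience wrapper: decimate and trim, fit the isosbestic baseline,
#' compute dFF (percent) and the robust z-score.
#'
#' @param session a `photometry_session`.
#' @param factor decimation factor (default 10).
#' @param trim_s initial trim (default 180 s).
#' @param fit_span optional indices (post-decimation) restricting the
#'   isosbestic fit span.
#' @return object of class `dff_trace`: `time_s`, `f0`, `dff` (percent),
#'   `z` (robust z of dFF), `fs`, `control_fit`.
#' @export
process_photometry <- function(session, factor = 10L, trim_s = 180, fit_span = NULL) {
  ds <- downsample_and_trim(session, factor = factor, trim_s = trim_s)
  fit <- fit_isosbestic(ds$f465, ds$f405, span = fit_span)
  dff <- compute_dff(ds$f465, fit$f0)
  structure(list(time_s = ds$time_s, f0 = fit$f0, dff = dff,
                 z = robust_zscore(dff), fs = ds$fs,
                 control_fit = fit$fit, events = ds$events),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("<dff_trace> %d samples @ %.4g Hz; slope %.3g, intercept %.3g\n",
              length(x$time_s), x$fs, x$control_fit$slope, x$control_fit$intercept))
  invisible(x)
}
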