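# Event-aligned calcium statistics: trial matrices, peri-event extrema,
# amplitude changes, duration coupling, lagged correlations and
# phase-randomized surrogate testing.

#' Align a trace to behavioral events
#'
#' Builds a trial-by-time matrix of trace values in a `(-pre_s, +post_s)`
#' window around each event. Events whose window leaves the trace span are
#' dropped (and reported). With `baseline_window` set, each row has the
#' mean over that relative window subtracted, so baseline-normalized rows
#' average exactly zero there (e.g. (-5, -1) s before jump onsets; (-15,
#' -5) s before opto trials).
#'
#' @param trace a `dff_trace` (or any list with `time_s`, `fs` and the
#'   field named by `value`).
#' @param events event times in seconds (numeric) or an [event_set()]
#'   together with `kind`.
#' @param pre_s,post_s window extent before/after the event (s).
#' @param baseline_window optional c(lo, hi) relative window for baseline
#'   subtraction.
#' @param value trace field to align (default `"z"`).
#' @param kind event kind to extract when `events` is an `event_set`.
#' @return object of class `event_matrix`: `mat` (trials x time), `t_rel`,
#'   `event_times_s`, `dropped`, `fs`, `baseline_window`.
#' @export
align_to_events <- function(trace, events, pre_s, post_s,
                            baseline_window = NULL, value = "z", kind = NULL) {
  ev <- if (inherits(events, "event_set")) {
    if (is.null(kind)) stop_custom("invalid_config", "kind required with an event_set")
    event_times(events, kind)
  } else as.numeric(events)
  x <- trace[[value]]
  ts <- trace$time_s
  fs <- trace$fs
  n_pre <- round(pre_s * fs); n_post <- round(post_s * fs)
  t_rel <- (seq(-n_pre, n_post)) / fs
  rows <- list(); used <- numeric(0); dropped <- numeric(0)
  for (e in ev) {
    i0 <- round((e - ts[1]) * fs) + 1L
    lo <- i0 - n_pre; hi <- i0 + n_post
    if (lo < 1L || hi > length(x)) {
      dropped <- c(dropped, e)
      next
    }
    row <- x[lo:hi]
    if (!is.null(baseline_window)) {
      bsel <- t_rel >= baseline_window[1] & t_rel <= baseline_window[2]
      if (!any(bsel)) stop_custom("invalid_config", "baseline window outside alignment window")
      row <- row - mean(row[bsel])
    }
    rows[[length(rows) + 1L]] <- row
    used <- c(used, e)
  }
  if (!length(rows)) stop_custom("empty_matrix", "no event window fits inside the trace")
  structure(list(mat = do.call(rbind, rows), t_rel = t_rel,
                 event_times_s = used, dropped = dropped, fs = fs,
                 baseline_window = baseline_window),
            class = "event_matrix")
}

#' Per-trial post-event local extremum
#'
#' Within `search_window` after the event, returns for each trial the
#' interior local extremum closest to the event, with its latency. A
#' monotone row without an interior extremum yields the boundary value,
#' flagged.
#'
#' @param m an `event_matrix`.
#' @param search_window c(lo, hi) in seconds relative to the event.
#' @param mode `"max"` or `"min"`.
#' @return data.frame: `trial`, `value`, `latency_s`, `boundary`.
#' @export
post_event_extremum <- function(m, search_window = c(0, 5), mode = c("max", "min")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "event_matrix"))
  sel <- which(m$t_rel >= search_window[1] & m$t_rel <= search_window[2])
  if (!length(sel)) stop_custom("invalid_config", "search window outside matrix window")
  res <- lapply(seq_len(nrow(m$mat)), function(i) {
    seg <- m$mat[i, sel]
    idx <- if (mode == "max") local_maxima(seg) else local_minima(seg)
    if (length(idx)) {
      j <- idx[which.min(abs(m$t_rel[sel][idx] - 0))]
      data.frame(trial = i, value = seg[j], latency_s = m$t_rel[sel][j],
                 boundary = FALSE)
    } else {
      j <- if (mode == "max") which.max(seg) else which.min(seg)
      data.frame(trial = i, value = seg[j], latency_s = m$t_rel[sel][j],
                 boundary = TRUE)
    }
  })
  do.call(rbind, res)
}

#' Per-trial amplitude change across a bout or opto window
#'
#' Bout rule: the local extremum nearest the bout offset minus the local
#' extremum nearest the bout onset (each searched in a `(0, search_s)`
#' window after its landmark, maxima at offsets / minima at onsets by
#' default for onset-rising transients). Opto rule: trace value at the
#' stimulus offset minus value at onset, read directly off the aligned
#' row.
#'
#' @param trace a `dff_trace`.
#' @param onsets,offsets paired landmark times (s), equal length.
#' @param rule `"bout"` or `"opto"`.
#' @param value trace field (default `"z"`).
#' @param search_s extremum search span after each landmark (bout rule).
#' @param onset_mode,offset_mode extremum type at each landmark (bout
#'   rule).
#' @return data.frame: `trial`, `delta`; trials lacking coverage are
#'   dropped (attribute `dropped`).
#' @export
amplitude_change <- function(trace, onsets, offsets, rule = c("bout", "opto"),
                             value = "z", search_s = 5,
                             onset_mode = "min", offset_mode = "max") {
  rule <- match.arg(rule)
  stopifnot(length(onsets) == length(offsets))
  x <- trace[[value]]; ts <- trace$time_s; fs <- trace$fs
  at <- function(tt) {
    i <- round((tt - ts[1]) * fs) + 1L
    if (i < 1L || i > length(x)) NA_real_ else x[i]
  }
  res <- list(); dropped <- integer(0)
  for (k in seq_along(onsets)) {
    if (rule == "opto") {
      a <- at(onsets[k]); b <- at(offsets[k])
      if (is.na(a) || is.na(b)) { dropped <- c(dropped, k); next }
      res[[length(res) + 1L]] <- data.frame(trial = k, delta = b - a)
    } else {
      seg_ext <- function(tt, mode) {
        i0 <- round((tt - ts[1]) * fs) + 1L
        i1 <- min(length(x), i0 + round(search_s * fs))
        if (i0 < 1L || i0 >= i1) return(NA_real_)
        seg <- x[i0:i1]
        idx <- if (mode == "max") local_maxima(seg) else local_minima(seg)
        if (length(idx)) seg[idx[1L]] else if (mode == "max") max(seg) else min(seg)
      }
      a <- seg_ext(onsets[k], onset_mode)
      b <- seg_ext(offsets[k], offset_mode)
      if (is.na(a) || is.na(b)) { dropped <- c(dropped, k); next }
      res[[length(res) + 1L]] <- data.frame(trial = k, delta = b - a)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else data.frame(trial = integer(0), delta = numeric(0))
  attr(out, "dropped") <- dropped
  out
}

#' Correlate behavioral event durations with transient durations
#'
#' Durations are peak-to-peak intervals: consecutive jump onsets give the
#' jump durations, consecutive calcium-peak times the transient durations.
#' Pairs are matched in order over the common count and pooled into one
#' Pearson correlation.
#'
#' @param jump_times jump landmark times (s), or precomputed durations
#'   with `as_durations = TRUE`.
#' @param peak_times calcium transient peak times (s), or durations.
#' @param as_durations interpret inputs as durations directly.
#' @return list: `pairs` (data.frame jump_duration, transient_duration),
#'   `r` (Pearson), `n`.
#' @export
duration_correlation <- function(jump_times, peak_times, as_durations = FALSE) {
  jd <- if (as_durations) jump_times else diff(sort(jump_times))
  td <- if (as_durations) peak_times else diff(sort(peak_times))
  n <- min(length(jd), length(td))
  if (n < 3L) stop_custom("insufficient_data", "fewer than 3 duration pairs")
  jd <- jd[seq_len(n)]; td <- td[seq_len(n)]
  r <- if (stats::sd(jd) == 0 || stats::sd(td) == 0) NA_real_ else stats::cor(jd, td)
  list(pairs = data.frame(jump_duration = jd, transient_duration = td),
       r = r, n = n)
}

#' Lagged Pearson correlation
#'
#' Pearson r between `x` and `y` at every integer-sample lag within
#' `max_lag_s`, each computed on the overlapping (shift-trimmed) span --
#' never zero-padded. The reported best is the maximum of `|r|`, returned
#' with its signed value and lag. Positive lag means `y` is shifted later
#' (x leads y).
#'
#' @param x,y numeric series on the same uniform grid.
#' @param fs sampling rate (Hz).
#' @param max_lag_s lag range (default 5 s).
#' @param min_overlap minimal overlap after shifting (default 30 samples).
#' @return object of class `lagged_correlation`: `r_by_lag`, `lags_s`,
#'   `best_r` (signed), `best_lag_s`, `n_samples`.
#' @export
lagged_pearson <- function(x, y, fs, max_lag_s = 5, min_overlap = 30) {
  if (length(x) != length(y)) stop_custom("invalid_config", "x and y lengths differ")
  n <- length(x)
  L <- round(max_lag_s * fs)
  lags <- seq(-L, L)
  r <- rep(NA_real_, length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    if (k >= 0) { xs <- x[seq_len(n - k)]; ys <- y[seq_len(n - k) + k] }
    else { xs <- x[seq_len(n + k) - k]; ys <- y[seq_len(n + k)] }
    if (length(xs) < min_overlap) next
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) next
    r[i] <- stats::cor(xs, ys)
  }
  if (all(is.na(r))) stop_custom("undefined_correlation", "no lag has a defined correlation")
  best <- which.max(abs(r))
  structure(list(r_by_lag = r, lags_s = lags / fs,
                 best_r = r[best], best_lag_s = lags[best] / fs,
                 n_samples = n),
            class = "lagged_correlation")
}

#' Phase-randomized surrogate of a series
#'
#' Fourier amplitudes are preserved exactly; the phases of all non-DC,
#' non-Nyquist bins are replaced by i.i.d. uniform draws with conjugate
#' symmetry enforced, so the surrogate is real, keeps the mean, the
#' amplitude spectrum and (by Wiener-Khinchin) the autocorrelation, but
#' destroys any phase-locked relation to other series. Uses the current
#' RNG state; seed upstream for determinism.
#'
#' @param x numeric series, length >= 4.
#' @return surrogate series, same length.
#' @export
phase_shuffle <- function(x) {
  n <- length(x)
  if (n < 4L) stop_custom("invalid_config", "need length >= 4")
  X <- stats::fft(x)
  half <- (n - 1L) %/% 2L              # bins 2..half+1 are free phases
  ph <- stats::runif(half, 0, 2 * pi)
  X2 <- X
  idx <- seq_len(half) + 1L
  X2[idx] <- Mod(X[idx]) * exp(1i * ph)
  X2[n + 2L - idx] <- Conj(X2[idx])
  # DC (bin 1) and, for even n, the Nyquist bin (n/2+1) are left untouched
  Re(stats::fft(X2, inverse = TRUE)) / n
}

#' Real-vs-surrogate lagged-correlation test
#'
#' Per subject, the strongest lagged correlation between its `x` and `y`
#' series; then `n_shuffle` surrogate values obtained by phase-shuffling
#' `y` (subjects visited round-robin in pooled mode, or `n_shuffle` per
#' subject in per-subject mode) and recomputing the best lag. The two
#' populations of best |r| are compared with a two-sided rank-sum test.
#'
#' @param x_list,y_list lists of per-subject series (equal grids within a
#'   subject).
#' @param fs sampling rate (Hz).
#' @param n_shuffle number of surrogate datasets (default 1000).
#' @param max_lag_s lag range for [lagged_pearson()].
#' @param mode `"pooled"` (default; one surrogate population across
#'   subjects) or `"per_subject"`.
#' @return object of class `surrogate_test`: `real_values`,
#'   `surrogate_values`, `p_value`, `n_shuffle`, `mode`.
#' @export
shuffle_correlation_test <- function(x_list, y_list, fs, n_shuffle = 1000,
                                     max_lag_s = 5,
                                     mode = c("pooled", "per_subject")) {
  mode <- match.arg(mode)
  if (n_shuffle < 1L) stop_custom("invalid_config", "n_shuffle must be >= 1")
  ns <- length(x_list)
  if (ns < 1L || length(y_list) != ns) {
    stop_custom("invalid_config", "need matching non-empty subject lists")
  }
  real <- vapply(seq_len(ns), function(i) {
    abs(lagged_pearson(x_list[[i]], y_list[[i]], fs, max_lag_s)$best_r)
  }, numeric(1))
  surr <- if (mode == "pooled") {
    vapply(seq_len(n_shuffle), function(k) {
      i <- (k - 1L) %% ns + 1L
      abs(lagged_pearson(x_list[[i]], phase_shuffle(y_list[[i]]), fs,
                         max_lag_s)$best_r)
    }, numeric(1))
  } else {
    as.numeric(vapply(seq_len(ns), function(i) {
      vapply(seq_len(n_shuffle), function(k) {
        abs(lagged_pearson(x_list[[i]], phase_shuffle(y_list[[i]]), fs,
                           max_lag_s)$best_r)
      }, numeric(1))
    }, numeric(n_shuffle)))
  }
  p <- stats::wilcox.test(real, surr, exact = FALSE)$p.value
  structure(list(real_values = real, surrogate_values = surr,
                 p_value = p, n_shuffle = n_shuffle, mode = mode),
            class = "surrogate_test")
}

#' Epoch-wise lagged correlation between two traces
#'
#' Runs [lagged_pearson()] on the common samples of each named epoch (e.g.
#' pre / during / post a rotarod run). Epochs shorter than the minimal
#' overlap, or with zero variance, are skipped with a message.
#'
#' @param x_trace,y_trace `dff_trace`s on a common grid.
#' @param epochs named list of c(start_s, end_s) windows.
#' @param value trace field (default `"z"`).
#' @param max_lag_s lag range.
#' @param min_overlap minimal epoch length in samples.
#' @return data.frame: `epoch`, `best_r`, `best_lag_s`, `n`.
#' @export
epoch_correlation <- function(x_trace, y_trace, epochs, value = "z",
                              max_lag_s = 5, min_overlap = 30) {
  out <- list()
  for (nm in names(epochs)) {
    w <- epochs[[nm]]
    sel <- x_trace$time_s >= w[1] & x_trace$time_s <= w[2]
    if (sum(sel) < min_overlap) {
      message(sprintf("epoch '%s' shorter than minimal overlap; skipped", nm))
      next
    }
    res <- tryCatch(
      lagged_pearson(x_trace[[value]][sel], y_trace[[value]][sel],
                     x_trace$fs, max_lag_s, min_overlap),
      photomotor_error = function(e) NULL)
    if (is.null(res)) {
      message(sprintf("epoch '%s' has undefined correlation; skipped", nm))
      next
    }
    out[[length(out) + 1L]] <- data.frame(epoch = nm, best_r = res$best_r,
                                          best_lag_s = res$best_lag_s,
                                          n = res$n_samples)
  }
  if (!length(out)) return(data.frame(epoch = character(0), best_r = numeric(0),
                                      best_lag_s = numeric(0), n = integer(0)))
  do.call(rbind, out)
}
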