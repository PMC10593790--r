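# End-to-end assay runners and small worked-example summaries. These
# orchestrate the photometry, kinematics, aligned-stats and ephys modules
# over one session's inputs; cohort-level surrogate testing is done by
# calling shuffle_correlation_test() over per-subject results.

#' Summarize a tracing count as a percentage
#'
#' Cell-count worked example: `percent = 100 * numerator / denominator`,
#' rounded half away from zero at one decimal.
#'
#' @param numerator count of co-labeled cells.
#' @param denominator total cells counted (> 0).
#' @return list of class `count_summary`: `numerator`, `denominator`,
#'   `percent`.
#' @export
summarize_tracing_counts <- function(numerator, denominator) {
  if (denominator <= 0) stop_custom("invalid_input", "denominator must be > 0")
  if (numerator < 0 || numerator > denominator) {
    stop_custom("invalid_input", "numerator must lie in [0, denominator]")
  }
  structure(list(numerator = numerator, denominator = denominator,
                 percent = percent_round1(100 * numerator / denominator)),
            class = "count_summary")
}

#' @export
print.count_summary <- function(x, ...) {
  cat(sprintf("%d / %d = %.1f%%\n", x$numerator, x$denominator, x$percent))
  invisible(x)
}

#' Run the open-field analysis on one session
#'
#' Photometry: decimate, trim, isosbestic fit, dFF, robust z. Tracking:
#' likelihood interpolation, calibration to cm at 100 Hz, 2 s-smoothed
#' body-center speed, locomotor bout detection, motor-state frames.
#' Aligned statistics: bout-onset-aligned z matrix and the strongest
#' lagged speed-dFF Pearson correlation.
#'
#' @param session a [photometry_session()].
#' @param tracking a [tracking_table()] (pixels).
#' @param known_distance_cm,known_distance_px arena calibration (42 cm
#'   corner span by default; px span from the data when `NULL`).
#' @param factor,trim_s photometry decimation and trim.
#' @param pre_s,post_s bout alignment window.
#' @param max_lag_s lag range of the speed-dFF correlation.
#' @return list: `dff` (dff_trace), `speed` (speed_trace), `bouts`
#'   (event_set), `motor` (motor_state_frames), `bout_matrix`
#'   (event_matrix or NULL), `lag` (lagged_correlation), and
#'   `speed_on_dff_grid`.
#' @export
run_open_field <- function(session, tracking, known_distance_cm = 42,
                           known_distance_px = NULL, factor = 10L,
                           trim_s = 180, pre_s = 5, post_s = 5,
                           max_lag_s = 5) {
  dff <- process_photometry(session, factor = factor, trim_s = trim_s)
  tr <- interpolate_low_likelihood(tracking, threshold = 0.9)
  if (is.null(known_distance_px)) {
    bc <- part_coords(tr, "body_center")
    known_distance_px <- max(max(bc$x) - min(bc$x), max(bc$y) - min(bc$y))
  }
  trc <- calibrate_and_upsample(tr, known_distance_cm, known_distance_px,
                                target_fs = 100)
  sp <- compute_speed(trc, smooth_window_s = 2)
  bouts <- detect_locomotor_bouts(sp)
  motor <- classify_motor_state(trc, sp)
  bout_matrix <- NULL
  on_times <- event_times(bouts, "bout_onset")
  if (length(on_times)) {
    bout_matrix <- tryCatch(
      align_to_events(dff, on_times, pre_s, post_s),
      photomotor_error = function(e) NULL)
  }
  sp_grid <- stats::approx(sp$time_s, sp$speed_cm_s, xout = dff$time_s,
                           rule = 2)$y
  lag <- lagged_pearson(dff$z, sp_grid, dff$fs, max_lag_s)
  list(dff = dff, speed = sp, bouts = bouts, motor = motor,
       bout_matrix = bout_matrix, lag = lag, speed_on_dff_grid = sp_grid)
}

#' Run the rotarod analysis on one session
#'
#' The isosbestic fit and the moving 8th-percentile baseline are anchored
#' to the pre/post rest epochs so the running epoch is not deformed; jumps
#' are detected from the lower-body Y position under the 0.95-likelihood
#' session gate; the z trace is aligned to jump onsets with a (-5, -1) s
#' baseline; transient metrics are computed per epoch; jump durations are
#' correlated with transient durations.
#'
#' @param session a [photometry_session()].
#' @param tracking a [tracking_table()] (pixels, rotarod parts).
#' @param run_window c(start_s, end_s) of the rotarod run; the remainder
#'   of the session is rest.
#' @param known_distance_cm,known_distance_px rod calibration (3 cm).
#' @param factor,trim_s photometry decimation and trim.
#' @param baseline_window_s moving-percentile window (default 30 s).
#' @return list: `dff`, `jumps`, `jump_matrix`, `epoch_metrics` (list of
#'   transient_metrics for pre/during/post), `duration_r`
#'   (duration_correlation result or NULL), `excluded` (FALSE, or the
#'   session-exclusion condition message).
#' @export
run_rotarod <- function(session, tracking, run_window,
                        known_distance_cm = 3, known_distance_px = 90,
                        factor = 10L, trim_s = 0, baseline_window_s = 30) {
  ds <- downsample_and_trim(session, factor = factor, trim_s = trim_s)
  rest <- ds$time_s < run_window[1] | ds$time_s > run_window[2]
  fit <- fit_isosbestic(ds$f465, ds$f405, span = which(rest))
  dffv <- compute_dff(ds$f465, fit$f0)
  dffv <- baseline_correct_percentile(dffv, ds$fs, window_s = baseline_window_s,
                                      spans = rest)
  dff <- structure(list(time_s = ds$time_s, f0 = fit$f0, dff = dffv,
                        z = robust_zscore(dffv), fs = ds$fs,
                        control_fit = fit$fit, events = ds$events),
                   class = "dff_trace")

  tr <- interpolate_low_likelihood(tracking, threshold = 0.9)
  trc <- calibrate_and_upsample(tr, known_distance_cm, known_distance_px,
                                target_fs = 100)
  jumps <- tryCatch(detect_jumps(trc), session_excluded = function(e) e)
  if (inherits(jumps, "condition")) {
    return(list(dff = dff, jumps = NULL, jump_matrix = NULL,
                epoch_metrics = NULL, duration_r = NULL,
                excluded = conditionMessage(jumps)))
  }
  on_times <- event_times(jumps, "jump_onset")
  jump_matrix <- if (length(on_times)) {
    tryCatch(align_to_events(dff, on_times, pre_s = 5, post_s = 5,
                             baseline_window = c(-5, -1)),
             photomotor_error = function(e) NULL)
  } else NULL

  epochs <- list(pre = c(dff$time_s[1], run_window[1]),
                 during = run_window,
                 post = c(run_window[2], dff$time_s[length(dff$time_s)]))
  sm <- moving_average(dff$z, dff$fs, 0.5)
  epoch_metrics <- lapply(epochs, function(w) {
    sel <- dff$time_s >= w[1] & dff$time_s <= w[2]
    detect_transients(sm[sel], dff$fs)
  })
  peaks_during <- epoch_metrics$during$peak_times_s + run_window[1]
  duration_r <- tryCatch(
    duration_correlation(on_times[on_times >= run_window[1] &
                                    on_times <= run_window[2]], peaks_during),
    photomotor_error = function(e) NULL)
  list(dff = dff, jumps = jumps, jump_matrix = jump_matrix,
       epoch_metrics = epoch_metrics, duration_r = duration_r,
       excluded = FALSE)
}

#' Run the ephys classification on a recording set
#'
#' Builds every PSTH, applies both classification criteria, and tabulates
#' inhibited proportions per region x drug x stimulation duration with
#' Fisher's exact tests.
#'
#' @param units a `unit_recording_set`.
#' @param window `"full_stim"` or `"first_50ms"`.
#' @return list: `classifications` (data.frame), `population`
#'   ([population_summary()] output), `basal_hz` (named vector).
#' @export
run_ephys <- function(units, window = "full_stim") {
  if (!length(units)) stop_custom("input_error", "empty unit list")
  cls <- classify_units(units, window)
  list(classifications = cls,
       population = population_summary(cls),
       basal_hz = stats::setNames(cls$basal_hz,
                                  paste0(cls$unit_id, "_d", cls$stim_duration_ms)))
}
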