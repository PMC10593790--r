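# Tracking post-processing and behavior segmentation: likelihood-gated
# interpolation, calibration/upsampling, speed, locomotor bouts, rotarod
# jumps, motor-state frames, rotations, trial-relative speed.

#' Interpolate low-likelihood tracking points
#'
#' Coordinates whose tracking likelihood falls below `threshold` (default
#' 0.9) are replaced by interpolation over the surrounding valid frames:
#' piecewise-cubic spline for interior gaps, nearest-valid at the edges.
#' Likelihoods are preserved unchanged for audit.
#'
#' @param t a [tracking_table()].
#' @param threshold likelihood gate (default 0.9).
#' @return a [tracking_table()] with cleaned coordinates.
#' @export
interpolate_low_likelihood <- function(t, threshold = 0.9) {
  parts <- tracking_parts(t)
  out <- t
  for (p in parts) {
    lk <- t[[paste0(p, "_likelihood")]]
    valid <- lk >= threshold
    if (sum(valid) < 2L) {
      stop_custom("part_unusable",
                  sprintf("part '%s' has < 2 frames at likelihood >= %g", p, threshold))
    }
    if (all(valid)) next
    for (ax in c("_x", "_y")) {
      v <- t[[paste0(p, ax)]]
      iv <- which(valid)
      filled <- v
      interior <- which(!valid & seq_along(v) > iv[1] & seq_along(v) < iv[length(iv)])
      if (length(interior)) {
        filled[interior] <- if (length(iv) >= 4L) {
          stats::spline(iv, v[iv], xout = interior, method = "natural")$y
        } else {
          stats::approx(iv, v[iv], xout = interior)$y
        }
      }
      edges <- which(!valid & (seq_along(v) < iv[1] | seq_along(v) > iv[length(iv)]))
      if (length(edges)) {
        filled[edges] <- stats::approx(iv, v[iv], xout = edges, rule = 2)$y
      }
      out[[paste0(p, ax)]] <- filled
    }
  }
  out
}

#' Calibrate tracking to centimeters and upsample
#'
#' Converts pixel coordinates to y-up centimeters using a known physical
#' distance (42 cm open-field corner span or 3 cm rotarod height) and the
#' corresponding pixel span, then resamples every coordinate to
#' `target_fs` by linear interpolation (likelihoods by nearest-frame).
#' The y-axis is flipped once here (`y_cm = (max(y_px) - y_px) *
#' cm_per_px`); all downstream kinematics assume y-up.
#'
#' @param t a [tracking_table()] in pixel units.
#' @param known_distance_cm physical reference distance (cm).
#' @param known_distance_px the same distance in pixels.
#' @param target_fs output frame rate (default 100 Hz, the calcium grid).
#' @return a [tracking_table()] in cm at `target_fs`.
#' @export
calibrate_and_upsample <- function(t, known_distance_cm, known_distance_px,
                                   target_fs = 100) {
  if (known_distance_px <= 0) stop_custom("calibration_error", "pixel span must be > 0")
  assert_positive(known_distance_cm, "known_distance_cm")
  cm_per_px <- known_distance_cm / known_distance_px
  parts <- tracking_parts(t)
  y_ref <- max(vapply(parts, function(p) max(t[[paste0(p, "_y")]]), numeric(1)))
  t_old <- t$time_s
  t_new <- seq(t_old[1], t_old[length(t_old)], by = 1 / target_fs)
  plist <- list()
  for (p in parts) {
    x_cm <- t[[paste0(p, "_x")]] * cm_per_px
    y_cm <- (y_ref - t[[paste0(p, "_y")]]) * cm_per_px
    lk <- t[[paste0(p, "_likelihood")]]
    plist[[p]] <- list(
      x = stats::approx(t_old, x_cm, xout = t_new)$y,
      y = stats::approx(t_old, y_cm, xout = t_new)$y,
      likelihood = stats::approx(t_old, lk, xout = t_new, method = "constant",
                                 rule = 2)$y
    )
  }
  tracking_table(t_new, plist, fs_video = target_fs, units = "cm",
                 cm_per_px = cm_per_px)
}

#' Construct a speed trace directly from a speed series
#'
#' Wraps an already-computed (and, if applicable, already-smoothed)
#' body-center speed series for use with [detect_locomotor_bouts()],
#' [speed_trigger()] or [relative_speed()].
#'
#' @param time_s sample times (s), uniform.
#' @param speed_cm_s body-center speed (cm/s), non-negative.
#' @param fs sampling rate (Hz); inferred when `NULL`.
#' @param part_speeds optional matrix of per-part speeds (columns named).
#' @param smoothed whether the series is already smoothed.
#' @return object of class `speed_trace`.
#' @export
speed_trace <- function(time_s, speed_cm_s, fs = NULL, part_speeds = NULL,
                        smoothed = TRUE) {
  if (length(time_s) != length(speed_cm_s)) {
    stop_custom("invalid_config", "time_s and speed_cm_s lengths differ")
  }
  if (any(speed_cm_s < 0)) stop_custom("invalid_config", "speeds must be >= 0")
  if (is.null(fs)) fs <- 1 / mean(diff(time_s))
  if (is.null(part_speeds)) {
    part_speeds <- matrix(speed_cm_s, ncol = 1,
                          dimnames = list(NULL, "body_center"))
  }
  structure(list(time_s = time_s, speed_cm_s = speed_cm_s,
                 part_speeds = part_speeds, fs = fs, smoothed = smoothed,
                 smooth_window_s = NA_real_),
            class = "speed_trace")
}

#' Per-part speed and smoothed body-center speed
#'
#' Finite-difference displacement over the frame interval for every part;
#' the body-center speed is additionally smoothed with a centered moving
#' mean (default 2 s). The first frame repeats the second's speed.
#'
#' @param t a calibrated [tracking_table()] (cm units).
#' @param smooth_window_s body-center smoothing window (s); 0 disables.
#' @param center_part the part treated as body center.
#' @return object of class `speed_trace`: `time_s`, `speed_cm_s`
#'   (smoothed body center), `part_speeds` (matrix, unsmoothed), `fs`,
#'   `smoothed`, `smooth_window_s`.
#' @export
compute_speed <- function(t, smooth_window_s = 2, center_part = "body_center") {
  if (attr(t, "units") != "cm") {
    warning("compute_speed called on uncalibrated (pixel) coordinates")
  }
  if (nrow(t) < 2L) stop_custom("invalid_config", "need >= 2 frames")
  parts <- tracking_parts(t)
  dt <- diff(t$time_s)
  sp <- sapply(parts, function(p) {
    dx <- diff(t[[paste0(p, "_x")]])
    dy <- diff(t[[paste0(p, "_y")]])
    v <- sqrt(dx^2 + dy^2) / dt
    c(v[1], v)
  })
  colnames(sp) <- parts
  if (!center_part %in% parts) {
    stop_custom("configuration_error", sprintf("no '%s' part in table", center_part))
  }
  fs <- attr(t, "fs_video")
  body <- sp[, center_part]
  smoothed <- smooth_window_s > 0 && round(smooth_window_s * fs) > 1
  if (smoothed) body <- moving_average(body, fs, smooth_window_s)
  structure(list(time_s = t$time_s, speed_cm_s = body, part_speeds = sp,
                 fs = fs, smoothed = smoothed, smooth_window_s = smooth_window_s),
            class = "speed_trace")
}

#' Detect locomotor bouts from smoothed speed
#'
#' Candidate epochs are runs where speed exceeds `enter` (5 cm/s);
#' epochs separated by troughs that never fall below `sustain` (3 cm/s)
#' are merged. The bout onset is the last local speed minimum before the
#' upward `sustain` crossing; the offset is the last local maximum before
#' the downward `enter` crossing on the descending phase. The look-back
#' search for either extremum is bounded to `lookback_s`.
#'
#' @param s a `speed_trace` (smoothed; a contract warning is raised
#'   otherwise).
#' @param enter bout-entry threshold (cm/s, default 5).
#' @param sustain onset/offset search threshold (cm/s, default 3).
#' @param lookback_s bound on the local-extremum look-back (default 2 s).
#' @return an [event_set()] of paired `bout_onset` / `bout_offset` events;
#'   attribute `censored` flags a bout already in progress at frame 1.
#' @export
detect_locomotor_bouts <- function(s, enter = 5, sustain = 3, lookback_s = 2) {
  stopifnot(inherits(s, "speed_trace"))
  if (!isTRUE(s$smoothed)) warning("speed trace is unsmoothed; bout rules assume smoothing")
  v <- s$speed_cm_s
  t <- s$time_s
  n <- length(v)
  if (n == 0L || !any(v > enter)) return(event_set())
  lb <- max(1L, round(lookback_s * s$fs))
  mins <- local_minima(v)
  maxs <- local_maxima(v)

  above <- v > enter
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs whose gap never drops below `sustain`
  if (nrow(runs) > 1L) {
    keep <- list(runs[1L, ])
    for (i in 2:nrow(runs)) {
      last <- keep[[length(keep)]]
      gap <- v[(last[2] + 1L):(runs[i, 1] - 1L)]
      if (length(gap) && all(gap >= sustain)) {
        keep[[length(keep)]] <- c(last[1], runs[i, 2])
      } else {
        keep[[length(keep) + 1L]] <- runs[i, ]
      }
    }
    runs <- do.call(rbind, keep)
  }

  onsets <- offsets <- numeric(0)
  censored <- logical(0)
  prev_off_idx <- 0L
  for (i in seq_len(nrow(runs))) {
    i0 <- runs[i, 1]; i1 <- runs[i, 2]
    # upward sustain crossing at/before the run start
    up <- which(v[seq_len(i0)] < sustain)
    cens <- FALSE
    if (!length(up)) {
      on_idx <- 1L
      cens <- TRUE
    } else {
      cross_up <- up[length(up)] + 1L
      cand <- mins[mins <= cross_up & mins >= max(cross_up - lb, prev_off_idx + 1L)]
      on_idx <- if (length(cand)) cand[length(cand)] else max(cross_up - 1L, 1L)
    }
    # downward enter crossing = end of the run; offset = last local max before it
    cross_dn <- i1
    cand <- maxs[maxs <= cross_dn & maxs >= max(cross_dn - lb, i0)]
    off_idx <- if (length(cand)) cand[length(cand)] else cross_dn
    if (off_idx <= on_idx) off_idx <- min(on_idx + 1L, n)
    onsets <- c(onsets, t[on_idx])
    offsets <- c(offsets, t[off_idx])
    censored <- c(censored, cens)
    prev_off_idx <- off_idx
  }
  ev <- event_set(kind = rep(c("bout_onset", "bout_offset"), length(onsets)),
                  time_s = as.numeric(rbind(onsets, offsets)),
                  pair_id = rep(seq_along(onsets), each = 2L))
  attr(ev, "censored") <- censored
  ev
}

#' Detect rotarod jumps from lower-body Y position
#'
#' Applies the session quality gate first: frames with likelihood below
#' `like_thresh` (0.95) are excluded, as is any low-likelihood epoch of at
#' least `exclude_epoch_s`; a session with under `min_valid_frac` valid
#' frames is rejected outright (condition class `session_excluded`). The
#' surviving Y positions are robust-z-scored; jump onsets are the local
#' minima of the z (the animal at the lowest rod point, about to jump) and
#' offsets the local maxima.
#'
#' @param t a calibrated [tracking_table()] (cm, y-up).
#' @param part body part carrying the jump signal (default `lower_body`).
#' @param like_thresh likelihood gate (default 0.95).
#' @param min_valid_frac minimal fraction of valid frames (default 0.5).
#' @param exclude_epoch_s low-likelihood epoch length that voids its
#'   frames (default 1 s; subsumed by the frame gate, kept for audit).
#' @param min_prominence_z minimal extremum prominence in z units.
#' @return an [event_set()] of `jump_onset` / `jump_offset` events;
#'   attribute `interjump_intervals_s` holds consecutive onset-to-onset
#'   intervals.
#' @export
detect_jumps <- function(t, part = "lower_body", like_thresh = 0.95,
                         min_valid_frac = 0.5, exclude_epoch_s = 1,
                         min_prominence_z = 0.3) {
  pc <- part_coords(t, part)
  valid <- pc$likelihood >= like_thresh
  if (mean(valid) < min_valid_frac) {
    stop_custom("session_excluded",
                sprintf("only %.0f%% of frames reach likelihood %g",
                        100 * mean(valid), like_thresh))
  }
  y <- pc$y[valid]
  ts <- pc$time_s[valid]
  z <- robust_zscore(y)   # degenerate_scale error on flat Y
  mins <- local_minima(z)
  maxs <- local_maxima(z)
  # prominence gate against the opposite extrema
  amp_ok <- function(idx, opp, sgn) {
    idx[vapply(idx, function(i) {
      prev <- opp[opp < i]
      ref <- if (length(prev)) z[prev[length(prev)]] else z[1]
      sgn * (z[i] - ref) >= min_prominence_z
    }, logical(1))]
  }
  mins <- amp_ok(mins, maxs, -1)
  maxs <- amp_ok(maxs, mins, 1)
  ev <- event_set(kind = c(rep("jump_onset", length(mins)),
                           rep("jump_offset", length(maxs))),
                  time_s = c(ts[mins], ts[maxs]))
  attr(ev, "interjump_intervals_s") <- diff(sort(ts[mins]))
  ev
}

#' Classify motor state and arena zone per frame
#'
#' A frame is `locomotion` when body-center speed exceeds `loco_thresh`
#' (4.5 cm/s), `motionless` when every part's speed is at or below
#' `still_thresh` (0.8 cm/s), and `other_movement` otherwise. The zone is
#' `periphery` inside the outermost `border_cm` band of the arena, else
#' `center`.
#'
#' @param t a calibrated [tracking_table()] (cm).
#' @param s the matching `speed_trace`.
#' @param loco_thresh locomotion threshold (cm/s).
#' @param still_thresh motionless threshold (cm/s).
#' @param border_cm periphery band width (default 10 cm).
#' @param arena_cm arena side (default 42 cm).
#' @param arena_origin c(x, y) of the arena's lower-left corner in the
#'   calibrated coordinate frame (default c(0, 0)).
#' @return data.frame of class `motor_state_frames` with `time_s`,
#'   `state`, `zone`.
#' @export
classify_motor_state <- function(t, s, loco_thresh = 4.5, still_thresh = 0.8,
                                 border_cm = 10, arena_cm = 42,
                                 arena_origin = c(0, 0)) {
  stopifnot(inherits(s, "speed_trace"))
  if (!"body_center" %in% tracking_parts(t)) {
    stop_custom("configuration_error", "tracking table lacks a body_center part")
  }
  all_still <- apply(s$part_speeds <= still_thresh, 1L, all)
  state <- ifelse(s$speed_cm_s > loco_thresh, "locomotion",
                  ifelse(all_still, "motionless", "other_movement"))
  bc <- part_coords(t, "body_center")
  x0 <- arena_origin[1]; y0 <- arena_origin[2]
  periph <- bc$x < x0 + border_cm | bc$x > x0 + arena_cm - border_cm |
    bc$y < y0 + border_cm | bc$y > y0 + arena_cm - border_cm
  out <- data.frame(time_s = t$time_s, state = state,
                    zone = ifelse(periph, "periphery", "center"))
  class(out) <- c("motor_state_frames", "data.frame")
  out
}

#' Percent time per motor state and zone
#' @param m a `motor_state_frames` table.
#' @return list with `state_frac` and `zone_frac` (fractions summing to 1).
#' @export
motor_state_summary <- function(m) {
  list(state_frac = prop.table(table(factor(m$state, levels = c(
    "locomotion", "motionless", "other_movement")))),
    zone_frac = prop.table(table(factor(m$zone, levels = c("center", "periphery")))))
}

#' Signed body-rotation angles and cumulative rotation
#'
#' The body vector is snout minus lower body, normalized. For each
#' consecutive frame pair (v1, v2) the signed angle is
#' `atan2(x1*y2 - y1*x2, x1*x2 + y1*y2)` converted to degrees
#' (counter-clockwise positive in y-up coordinates); the cumulative sum
#' runs from `reference_event_s` (e.g. opto-stimulation onset).
#'
#' @param snout,lower_body data.frames with `x`, `y` per frame (cm, y-up).
#' @param time_s frame times.
#' @param reference_event_s cumulative-sum origin (default first frame).
#' @return data.frame of class `rotation_record` with `time_s`,
#'   `angle_deg` (per frame-pair, first frame NA), `cumulative_deg`.
#'   Frames with a degenerate (zero-length) body vector get `angle_deg`
#'   NA and are skipped in the cumulative sum; their count is in attribute
#'   `n_degenerate`.
#' @export
rotation_angles <- function(snout, lower_body, time_s,
                            reference_event_s = time_s[1]) {
  vx <- snout$x - lower_body$x
  vy <- snout$y - lower_body$y
  nrm <- sqrt(vx^2 + vy^2)
  degen <- nrm == 0
  vx <- vx / ifelse(degen, NA, nrm)
  vy <- vy / ifelse(degen, NA, nrm)
  n <- length(vx)
  x1 <- vx[-n]; y1 <- vy[-n]; x2 <- vx[-1]; y2 <- vy[-1]
  ang <- atan2(x1 * y2 - y1 * x2, x1 * x2 + y1 * y2) * 180 / pi
  angle_deg <- c(NA_real_, ang)
  inc <- ifelse(is.na(angle_deg), 0, angle_deg)
  inc[time_s < reference_event_s] <- 0
  out <- data.frame(time_s = time_s, angle_deg = angle_deg,
                    cumulative_deg = cumsum(inc))
  attr(out, "n_degenerate") <- sum(degen)
  class(out) <- c("rotation_record", "data.frame")
  out
}

#' Trial-relative speed around stimulation onsets
#'
#' Per trial, extracts speed in `window` around the onset and subtracts
#' that trial's own baseline mean computed over `baseline` (default -60 to
#' -5 s before onset). Trials whose baseline window is not fully inside
#' the recording are dropped.
#'
#' @param s a `speed_trace`.
#' @param stim_onsets trial onset times (s).
#' @param baseline baseline window relative to onset, c(lo, hi) in s.
#' @param window extraction window relative to onset, c(lo, hi) in s.
#' @return list with `t_rel` (relative time grid), `trials` (matrix,
#'   one row per surviving trial) and `dropped` (onset times dropped).
#' @export
relative_speed <- function(s, stim_onsets, baseline = c(-60, -5),
                           window = c(-60, 30)) {
  stopifnot(inherits(s, "speed_trace"))
  dt <- 1 / s$fs
  t_rel <- seq(window[1], window[2], by = dt)
  rows <- list(); dropped <- numeric(0)
  for (on in stim_onsets) {
    if (on + baseline[1] < s$time_s[1] || on + window[2] > s$time_s[length(s$time_s)]) {
      dropped <- c(dropped, on)
      next
    }
    tr <- stats::approx(s$time_s, s$speed_cm_s, xout = on + t_rel)$y
    bl <- stats::approx(s$time_s, s$speed_cm_s,
                        xout = seq(on + baseline[1], on + baseline[2], by = dt))$y
    rows[[length(rows) + 1L]] <- tr - mean(bl)
  }
  list(t_rel = t_rel,
       trials = if (length(rows)) do.call(rbind, rows) else matrix(numeric(0), 0, length(t_rel)),
       dropped = dropped)
}
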