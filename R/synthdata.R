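# Seeded synthetic photometry / tracking / spike-train generators with
# known ground truth. These stand in for raw recordings: every downstream
# stage can be exercised against construction-time truth.

#' Simulation configuration
#'
#' One config drives all three generators. A single integer seed governs
#' every stochastic draw; each generator derives deterministic sub-streams
#' from it, so identical configs yield bit-identical outputs.
#'
#' Defaults follow the recording conditions the pipeline targets: 15 min
#' sessions, two-channel photometry at 1017.3 Hz, 30 Hz video, a
#' GCaMP-like difference-of-exponentials transient kernel (rise 0.07 s,
#' decay 0.8 s), slow shared photobleaching, and optional motion artifact
#' injected (scaled) into both channels so the control-channel regression
#' is meaningfully exercised.
#'
#' @param seed integer master seed.
#' @param duration_s session duration (s).
#' @param fs_photometry photometry sampling rate (Hz).
#' @param fs_video video frame rate (Hz).
#' @param transient_rate baseline calcium-transient rate (events/s).
#' @param tau_rise,tau_decay transient kernel time constants (s).
#' @param bleach_tau photobleaching time constant (s); `Inf` disables.
#' @param noise_sd white measurement noise SD (fluorescence a.u.).
#' @param coupling_gain dimensionless speed-to-transient drive; the
#'   transient rate is `transient_rate * (1 + coupling_gain * speed / 5)`
#'   with speed in cm/s (5 cm/s is the locomotor-bout scale).
#' @param artifact_gain amplitude of the shared motion artifact (a.u.);
#'   injected at full gain into the 465 channel and at 0.8x into the 405.
#' @param amp_mean,amp_cv mean and coefficient of variation of the
#'   log-normal single-transient amplitude distribution (a.u.). The
#'   amplitude distribution is deliberately a parameter, not a constant.
#' @param bout_schedule data.frame with `onset_s`, `offset_s`,
#'   `peak_speed` (cm/s); bouts must be disjoint and inside the session.
#'   `NULL` means no scheduled bouts.
#' @param baseline_speed resting body-center speed (cm/s), below 3 cm/s.
#' @param inhibition_depth fractional firing-rate suppression inside the
#'   stimulation window for inhibited units, in \[0, 1\].
#' @param baseline_rate_hz baseline unit firing rate (Hz).
#' @param excited_gain multiplicative in-stimulus rate gain for excited
#'   units.
#' @param dropout_frac fraction of tracking frames whose likelihood falls
#'   below 0.9 (per part, independently).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       duration_s = 900,
                       fs_photometry = 1017.3,
                       fs_video = 30,
                       transient_rate = 0.4,
                       tau_rise = 0.07,
                       tau_decay = 0.8,
                       bleach_tau = 600,
                       noise_sd = 0.05,
                       coupling_gain = 2,
                       artifact_gain = 0,
                       amp_mean = 3,
                       amp_cv = 0.3,
                       bout_schedule = NULL,
                       baseline_speed = 0.5,
                       inhibition_depth = 0.9,
                       baseline_rate_hz = 30,
                       excited_gain = 2,
                       dropout_frac = 0) {
  for (nm in c("duration_s", "fs_photometry", "fs_video", "tau_rise",
               "tau_decay", "baseline_rate_hz")) {
    assert_positive(get(nm), nm)
  }
  if (!is.numeric(bleach_tau) || length(bleach_tau) != 1L ||
      is.na(bleach_tau) || bleach_tau <= 0) {   # Inf allowed: no bleaching
    stop_custom("invalid_config", "`bleach_tau` must be positive (Inf disables bleaching)")
  }
  for (nm in c("transient_rate", "noise_sd", "coupling_gain", "artifact_gain",
               "amp_mean", "baseline_speed", "excited_gain", "dropout_frac")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop_custom("invalid_config", sprintf("`%s` must be non-negative", nm))
    }
  }
  if (inhibition_depth < 0 || inhibition_depth > 1) {
    stop_custom("invalid_config", "inhibition_depth must lie in [0, 1]")
  }
  if (!is.null(bout_schedule)) {
    bs <- bout_schedule[order(bout_schedule$onset_s), , drop = FALSE]
    if (any(bs$offset_s <= bs$onset_s)) {
      stop_custom("invalid_config", "bout offsets must follow onsets")
    }
    if (any(bs$onset_s < 0) || any(bs$offset_s > duration_s)) {
      stop_custom("invalid_config", "bouts must lie inside the session")
    }
    if (nrow(bs) > 1L && any(bs$onset_s[-1L] < bs$offset_s[-nrow(bs)])) {
      stop_custom("invalid_config", "bout intervals overlap")
    }
    bout_schedule <- bs
  }
  structure(list(
    seed = as.integer(seed), duration_s = duration_s,
    fs_photometry = fs_photometry, fs_video = fs_video,
    transient_rate = transient_rate, tau_rise = tau_rise,
    tau_decay = tau_decay, bleach_tau = bleach_tau, noise_sd = noise_sd,
    coupling_gain = coupling_gain, artifact_gain = artifact_gain,
    amp_mean = amp_mean, amp_cv = amp_cv, bout_schedule = bout_schedule,
    baseline_speed = baseline_speed, inhibition_depth = inhibition_depth,
    baseline_rate_hz = baseline_rate_hz, excited_gain = excited_gain,
    dropout_frac = dropout_frac
  ), class = "sim_config")
}

#' Regular bout schedule helper
#'
#' Evenly spaced locomotor bouts: one `bout_dur_s` bout every `every_s`
#' seconds starting at `first_s`, all at `peak_speed`.
#'
#' @param duration_s session duration (s).
#' @param every_s inter-bout spacing (s).
#' @param bout_dur_s bout plateau duration (s).
#' @param peak_speed bout peak speed (cm/s).
#' @param first_s time of the first bout onset (s).
#' @return data.frame usable as `bout_schedule`.
#' @export
regular_bouts <- function(duration_s, every_s = 60, bout_dur_s = 10,
                          peak_speed = 10, first_s = 30) {
  onsets <- seq(first_s, duration_s - bout_dur_s - 5, by = every_s)
  data.frame(onset_s = onsets, offset_s = onsets + bout_dur_s,
             peak_speed = peak_speed)
}

# Trapezoidal speed profile implied by the schedule, evaluated on grid t.
# Rise starts at onset_s, plateau from onset_s + ramp_s to offset_s, fall
# ends at offset_s + ramp_s. Ground-truth bout landmarks are therefore the
# rise foot (onset_s) and plateau end (offset_s).
speed_profile <- function(cfg, t, ramp_s = 1) {
  v <- rep(cfg$baseline_speed, length(t))
  bs <- cfg$bout_schedule
  if (is.null(bs)) return(v)
  for (i in seq_len(nrow(bs))) {
    on <- bs$onset_s[i]; off <- bs$offset_s[i]; pk <- bs$peak_speed[i]
    rise <- t >= on & t < on + ramp_s
    v[rise] <- cfg$baseline_speed + (pk - cfg$baseline_speed) * (t[rise] - on) / ramp_s
    v[t >= on + ramp_s & t <= off] <- pk
    fall <- t > off & t < off + ramp_s
    v[fall] <- pk - (pk - cfg$baseline_speed) * (t[fall] - off) / ramp_s
  }
  v
}

#' Simulate a two-channel photometry session
#'
#' The 465 channel is bleaching drift plus a kernel-convolved transient
#' train (rate modulated by speed when `coupling_gain > 0`) plus shared
#' motion artifact plus white noise; the 405 control carries the same drift
#' and (scaled) artifact but no transients.
#'
#' @param cfg a [sim_config()].
#' @param speed optional data.frame (`time_s`, `speed_cm_s`) driving the
#'   transient rate; defaults to the trapezoid profile implied by
#'   `cfg$bout_schedule`.
#' @return list with `session` (a [photometry_session()]) and `truth`
#'   (class `ground_truth`: `transient_times_s`, `transient_amplitudes`,
#'   `true_coupling`, `true_lag_s` -- the kernel's time-to-peak).
#' @export
simulate_photometry <- function(cfg, speed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- round(cfg$duration_s * cfg$fs_photometry)
  dt <- 1 / cfg$fs_photometry
  t <- (seq_len(n) - 1L) * dt

  sp <- if (!is.null(speed)) {
    stats::approx(speed$time_s, speed$speed_cm_s, xout = t, rule = 2)$y
  } else {
    speed_profile(cfg, t)
  }
  rate <- cfg$transient_rate * (1 + cfg$coupling_gain * sp / 5)

  set.seed(substream_seed(cfg$seed, 1L))
  fire <- stats::runif(n) < rate * dt
  k_times <- t[fire]
  set.seed(substream_seed(cfg$seed, 5L))
  sdlog <- sqrt(log(1 + cfg$amp_cv^2))
  amps <- if (length(k_times)) {
    stats::rlnorm(length(k_times), log(cfg$amp_mean) - sdlog^2 / 2, sdlog)
  } else numeric(0)

  impulses <- numeric(n)
  if (length(k_times)) impulses[which(fire)] <- amps
  tk <- seq(0, 6 * cfg$tau_decay, by = dt)
  kern <- exp(-tk / cfg$tau_decay) - exp(-tk / cfg$tau_rise)
  if (max(kern) > 0) kern <- kern / max(kern)
  transients <- if (any(impulses != 0)) {
    as.numeric(stats::filter(c(impulses, numeric(length(kern))), kern,
                             method = "convolution", sides = 1))[seq_len(n)]
  } else numeric(n)
  transients[is.na(transients)] <- 0

  bleach <- exp(-t / cfg$bleach_tau)
  artifact <- if (cfg$artifact_gain > 0) {
    set.seed(substream_seed(cfg$seed, 4L))
    a <- moving_average(stats::rnorm(n), cfg$fs_photometry, 0.2)
    a / max(stats::sd(a), .Machine$double.eps)
  } else numeric(n)

  set.seed(substream_seed(cfg$seed, 2L))
  n465 <- if (cfg$noise_sd > 0) stats::rnorm(n, sd = cfg$noise_sd) else numeric(n)
  set.seed(substream_seed(cfg$seed, 3L))
  n405 <- if (cfg$noise_sd > 0) stats::rnorm(n, sd = cfg$noise_sd) else numeric(n)

  f465 <- 100 * bleach + transients + cfg$artifact_gain * artifact + n465
  f405 <- 80 * bleach + 0.8 * cfg$artifact_gain * artifact + n405

  tpk <- log(cfg$tau_decay / cfg$tau_rise) /
    (1 / cfg$tau_rise - 1 / cfg$tau_decay)
  truth <- structure(list(transient_times_s = k_times,
                          transient_amplitudes = amps,
                          true_coupling = cfg$coupling_gain,
                          true_lag_s = tpk,
                          drift = bleach),
                     class = "ground_truth")
  list(session = photometry_session(t, f465, f405, fs = cfg$fs_photometry),
       truth = truth)
}

# Rigid body-part offsets (cm, body frame: +x ahead, +y left of heading).
.open_field_parts <- list(
  snout = c(2.5, 0), ear_left = c(1.8, 0.8), ear_right = c(1.8, -0.8),
  body_center = c(0, 0), lateral_left = c(0, 1.2), lateral_right = c(0, -1.2),
  tail_base = c(-2.2, 0), tail_end = c(-4.5, 0)
)

#' Simulate an open-field tracking table
#'
#' The body center follows a smooth path whose speed is the trapezoid
#' profile of `cfg$bout_schedule` over a resting baseline; heading drifts
#' as a slow random walk and the path reflects off the 42 cm arena walls.
#' Eight body parts ride rigidly on the body frame. A `dropout_frac`
#' fraction of frames (per part) receives likelihood below 0.9 with
#' corrupted coordinates. Output is in image pixels (y down), 0.1 cm/px.
#'
#' @param cfg a [sim_config()].
#' @param arena_cm arena side (default 42 cm).
#' @return list with `tracking` (a [tracking_table()], units px) and
#'   `truth` (`true_bouts`: an [event_set()] of scheduled bout landmarks;
#'   `speed_cm_s`: the noiseless body-center speed per frame).
#' @export
simulate_tracking <- function(cfg, arena_cm = 42) {
  stopifnot(inherits(cfg, "sim_config"))
  dt <- 1 / cfg$fs_video
  t <- seq(0, cfg$duration_s, by = dt)
  n <- length(t)
  v <- speed_profile(cfg, t)

  set.seed(substream_seed(cfg$seed, 11L))
  heading <- cumsum(stats::rnorm(n, sd = 0.3 * dt * pi))
  x <- numeric(n); y <- numeric(n)
  x[1] <- arena_cm / 2; y[1] <- arena_cm / 2
  for (i in 2:n) {
    x[i] <- x[i - 1] + v[i] * dt * cos(heading[i])
    y[i] <- y[i - 1] + v[i] * dt * sin(heading[i])
    # reflect off walls, keeping a body-length margin
    if (x[i] < 5 || x[i] > arena_cm - 5) {
      heading[i:n] <- pi - heading[i:n]
      x[i] <- min(max(x[i], 5), arena_cm - 5)
    }
    if (y[i] < 5 || y[i] > arena_cm - 5) {
      heading[i:n] <- -heading[i:n]
      y[i] <- min(max(y[i], 5), arena_cm - 5)
    }
  }

  cm_per_px <- 0.1
  parts <- list()
  set.seed(substream_seed(cfg$seed, 12L))
  for (p in names(.open_field_parts)) {
    off <- .open_field_parts[[p]]
    px <- x + off[1] * cos(heading) - off[2] * sin(heading)
    py <- y + off[1] * sin(heading) + off[2] * cos(heading)
    lk <- rep(1, n)
    if (cfg$dropout_frac > 0) {
      drop <- stats::runif(n) < cfg$dropout_frac
      lk[drop] <- stats::runif(sum(drop), 0.2, 0.89)
      px[drop] <- px[drop] + stats::runif(sum(drop), -3, 3)
      py[drop] <- py[drop] + stats::runif(sum(drop), -3, 3)
    }
    parts[[p]] <- list(x = px / cm_per_px,
                       y = (arena_cm - py) / cm_per_px,
                       likelihood = lk)
  }

  bs <- cfg$bout_schedule
  truth_ev <- if (!is.null(bs) && nrow(bs)) {
    event_set(kind = rep(c("bout_onset", "bout_offset"), nrow(bs)),
              time_s = as.numeric(rbind(bs$onset_s, bs$offset_s)),
              pair_id = rep(seq_len(nrow(bs)), each = 2L))
  } else event_set()
  truth <- structure(list(true_bouts = truth_ev, speed_cm_s = v),
                     class = "ground_truth")
  list(tracking = tracking_table(t, parts, fs_video = cfg$fs_video,
                                 units = "px", cm_per_px = NA_real_),
       truth = truth)
}

#' Simulate a rotarod tracking table
#'
#' The lower body oscillates in Y between 0 and 3 cm (triangular wave of
#' period `jump_period_s`): the animal repeatedly jumps up the rod and
#' slides back down. The wave starts mid-rise so every minimum (jump onset)
#' and maximum (jump offset) is an interior sample. Output is in image
#' pixels (y down) calibrated by the 3 cm rod height (1/30 cm/px).
#'
#' @param cfg a [sim_config()].
#' @param jump_period_s jump cycle period (s). May be a vector of one
#'   period per trial segment of equal lengths.
#' @return list with `tracking` (parts `lower_body`, `tail_base`,
#'   `paw_left`, `paw_right`) and `truth` (`true_jumps` event_set with
#'   minima as onsets / maxima as offsets; `period_s`).
#' @export
simulate_rotarod_tracking <- function(cfg, jump_period_s = 2) {
  stopifnot(inherits(cfg, "sim_config"))
  dt <- 1 / cfg$fs_video
  t <- seq(0, cfg$duration_s, by = dt)
  n <- length(t)
  n_seg <- length(jump_period_s)
  seg <- pmin(floor(t / (cfg$duration_s / n_seg)) + 1L, n_seg)
  period <- jump_period_s[seg]
  # phase advances at 1/period per second; start mid-rise (phase 1/4 of a
  # 0-min triangle) so extrema are interior
  phase <- cumsum(c(1 / 4, dt / period[-1L])) %% 1
  tri <- function(ph) 3 * (1 - 2 * abs(ph - 0.5))   # 0 at ph 0/1, 3 at 0.5
  ycm <- tri(phase)

  onsets <- offsets <- numeric(0)
  if (n_seg == 1L) {
    T0 <- jump_period_s
    onsets <- seq(0.75 * T0, cfg$duration_s - dt, by = T0)
    offsets <- seq(0.25 * T0, cfg$duration_s - dt, by = T0)
  } else {
    ph_unwrapped <- cumsum(c(1 / 4, dt / period[-1L]))
    for (k in seq_len(floor(max(ph_unwrapped)))) {
      i_on <- which(ph_unwrapped >= k)[1]          # phase k = minimum
      i_off <- which(ph_unwrapped >= k - 0.5)[1]   # phase k - 1/2 = maximum
      if (!is.na(i_on)) onsets <- c(onsets, t[i_on])
      if (!is.na(i_off)) offsets <- c(offsets, t[i_off])
    }
  }
  cm_per_px <- 1 / 30
  mk <- function(dx_cm, dy_cm) {
    lk <- rep(1, n)
    px <- rep(50 + dx_cm / cm_per_px, n)
    py <- (3 - (ycm + dy_cm)) / cm_per_px
    if (cfg$dropout_frac > 0) {
      drop <- stats::runif(n) < cfg$dropout_frac
      lk[drop] <- stats::runif(sum(drop), 0.2, 0.94)
    }
    list(x = px, y = py, likelihood = lk)
  }
  set.seed(substream_seed(cfg$seed, 13L))
  parts <- list(lower_body = mk(0, 0), tail_base = mk(-1, 0.2),
                paw_left = mk(0.5, -0.5), paw_right = mk(-0.5, -0.5))
  kinds <- c(rep("jump_onset", length(onsets)), rep("jump_offset", length(offsets)))
  truth <- structure(list(
    true_jumps = event_set(kind = kinds, time_s = c(onsets, offsets)),
    period_s = jump_period_s), class = "ground_truth")
  list(tracking = tracking_table(t, parts, fs_video = cfg$fs_video,
                                 units = "px", cm_per_px = NA_real_),
       truth = truth)
}

#' Simulate peri-stimulus spike trains
#'
#' Homogeneous Poisson firing at `cfg$baseline_rate_hz` over each sweep's
#' (-1000, +2000) ms window; inside the stimulation window \[0, duration)
#' the rate is multiplied by `1 - inhibition_depth` for inhibited units or
#' by `excited_gain` for excited units.
#'
#' @param cfg a [sim_config()].
#' @param stim_durations_ms stimulation durations (ms); 0 means no light.
#' @param n_sweeps sweeps per unit per duration (default 10).
#' @param n_units number of units.
#' @param unit_labels per-unit truth labels among `inhibited`, `excited`,
#'   `none`; recycled. Default all `inhibited`.
#' @return list with `units` (class `unit_recording_set`: one
#'   `unit_recording` per unit x stimulus duration) and `truth`
#'   (`true_unit_class` per unit).
#' @export
simulate_spike_trains <- function(cfg, stim_durations_ms = c(0, 250, 500, 1000),
                                  n_sweeps = 10L, n_units = 1L,
                                  unit_labels = "inhibited") {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_sweeps < 1L) stop_custom("invalid_config", "n_sweeps must be >= 1")
  if (any(stim_durations_ms < 0)) stop_custom("invalid_config", "stim durations must be >= 0")
  labels <- rep_len(unit_labels, n_units)
  set.seed(substream_seed(cfg$seed, 21L))
  recs <- list()
  for (u in seq_len(n_units)) {
    gain <- switch(labels[u],
                   inhibited = 1 - cfg$inhibition_depth,
                   excited = cfg$excited_gain,
                   none = 1,
                   stop_custom("invalid_config", "labels must be inhibited/excited/none"))
    for (d in stim_durations_ms) {
      sweeps <- lapply(seq_len(n_sweeps), function(s) {
        draw <- function(t0, t1, rate) {
          len_s <- (t1 - t0) / 1000
          k <- stats::rpois(1L, rate * len_s)
          sort(stats::runif(k, t0, t1))
        }
        r0 <- cfg$baseline_rate_hz
        if (d > 0) {
          c(draw(-1000, 0, r0), draw(0, d, r0 * gain), draw(d, 2000, r0))
        } else {
          draw(-1000, 2000, r0)
        }
      })
      recs[[length(recs) + 1L]] <- unit_recording(
        unit_id = paste0("u", u), sweeps = sweeps, stim_duration_ms = d)
    }
  }
  truth <- structure(list(true_unit_class = stats::setNames(labels, paste0("u", seq_len(n_units)))),
                     class = "ground_truth")
  list(units = structure(recs, class = "unit_recording_set"), truth = truth)
}

#' Simulate a pure rotation trajectory
#'
#' The snout revolves around a fixed lower-body point at a constant angular
#' velocity; used to exercise the signed rotation-angle computation.
#' Coordinates are emitted directly in y-up centimeters (`units = "cm"`).
#'
#' @param angular_velocity_dps angular velocity (degrees/s; sign = CCW+).
#' @param duration_s trajectory length (s).
#' @param fs_video frame rate (Hz).
#' @param radius_cm snout-to-lower-body distance (default 2.5 cm).
#' @return a [tracking_table()] with parts `snout` and `lower_body`.
#' @export
simulate_rotation_trajectory <- function(angular_velocity_dps, duration_s,
                                         fs_video, radius_cm = 2.5) {
  assert_positive(fs_video, "fs_video")
  assert_positive(duration_s, "duration_s")
  t <- seq(0, duration_s, by = 1 / fs_video)
  th <- angular_velocity_dps * pi / 180 * t
  parts <- list(
    snout = list(x = radius_cm * cos(th), y = radius_cm * sin(th),
                 likelihood = rep(1, length(t))),
    lower_body = list(x = rep(0, length(t)), y = rep(0, length(t)),
                      likelihood = rep(1, length(t)))
  )
  tracking_table(t, parts, fs_video = fs_video, units = "cm", cm_per_px = 1)
}
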