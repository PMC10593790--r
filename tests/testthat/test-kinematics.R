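# Tracking ingestion, cleaning, calibration and behavior segmentation.

make_line_table <- function(n = 100, fs = 30, vx_cm_s = 5, cm_per_px = 0.1) {
  t <- (seq_len(n) - 1) / fs
  x_px <- (10 + vx_cm_s * t) / cm_per_px
  parts <- list(body_center = list(x = x_px, y = rep(100, n),
                                   likelihood = rep(1, n)))
  tracking_table(t, parts, fs_video = fs)
}

test_that("DLC-dialect round trip preserves values; malformed headers rejected", {
  cfg <- sim_config(seed = 3, duration_s = 10, dropout_frac = 0.1)
  tk <- simulate_tracking(cfg)$tracking
  path <- tempfile(fileext = ".csv")
  write_tracking_csv(tk, path)
  rt <- read_tracking(path, fs_video = 30)
  expect_equal(tracking_parts(rt), tracking_parts(tk))
  expect_equal(ncol(rt) - 1L, 24L)  # 8 parts x 3 columns
  for (p in tracking_parts(tk)) {
    expect_equal(rt[[paste0(p, "_x")]], tk[[paste0(p, "_x")]], tolerance = 1e-9)
    expect_equal(rt[[paste0(p, "_likelihood")]],
                 tk[[paste0(p, "_likelihood")]], tolerance = 1e-9)
  }
  lines <- readLines(path)
  bad <- tempfile(fileext = ".csv")
  writeLines(c(lines[2], lines[1], lines[3:length(lines)]), bad)
  expect_error(read_tracking(bad, fs_video = 30), class = "malformed_input")
})

test_that("likelihood interpolation restores dropped points", {
  n <- 50
  t <- (0:(n - 1)) / 30
  x <- seq(0, 49, length.out = n)
  lk <- rep(1, n)
  tt <- tracking_table(t, list(p = list(x = x, y = 2 * x, likelihood = lk)), 30)
  expect_identical(interpolate_low_likelihood(tt)$p_x, tt$p_x)

  lk2 <- lk; lk2[25] <- 0.1
  x2 <- x; x2[25] <- 999
  tt2 <- tracking_table(t, list(p = list(x = x2, y = 2 * x, likelihood = lk2)), 30)
  out <- interpolate_low_likelihood(tt2)
  expect_equal(out$p_x[25], x[25], tolerance = 1e-9)

  # block dropout inside a quadratic path restored near a spline oracle
  xq <- (t - 0.5)^2 * 40
  lk3 <- rep(1, n); lk3[20:26] <- 0.5
  xq_broken <- xq; xq_broken[20:26] <- -50
  tt3 <- tracking_table(t, list(p = list(x = xq_broken, y = x, likelihood = lk3)), 30)
  out3 <- interpolate_low_likelihood(tt3)
  oracle <- spline((1:n)[-(20:26)], xq[-(20:26)], xout = 20:26,
                   method = "natural")$y
  expect_equal(out3$p_x[20:26], oracle, tolerance = 1e-6)
  expect_lt(max(abs(out3$p_x[20:26] - xq[20:26])), 0.5)

  lk4 <- rep(0.1, n); lk4[1] <- 1
  tt4 <- tracking_table(t, list(p = list(x = x, y = x, likelihood = lk4)), 30)
  expect_error(interpolate_low_likelihood(tt4), class = "part_unusable")
})

test_that("calibration scales, flips y and preserves linear motion", {
  n <- 90
  t <- (0:(n - 1)) / 30
  parts <- list(body_center = list(x = seq(0, 420, length.out = n),
                                   y = rep(210, n), likelihood = rep(1, n)))
  tt <- tracking_table(t, parts, fs_video = 30)
  cal <- calibrate_and_upsample(tt, 42, 420, target_fs = 100)
  expect_equal(attr(cal, "cm_per_px"), 0.1)
  expect_equal(attr(cal, "units"), "cm")

  # constant position stays constant after upsampling
  parts2 <- list(body_center = list(x = rep(37, n), y = rep(99, n),
                                    likelihood = rep(1, n)))
  cal2 <- calibrate_and_upsample(tracking_table(t, parts2, 30), 42, 420)
  expect_equal(diff(range(cal2$body_center_x)), 0)

  # linear motion: speed unchanged by upsampling
  sp30 <- compute_speed(calibrate_and_upsample(tt, 42, 420, target_fs = 30),
                        smooth_window_s = 0)
  sp100 <- compute_speed(cal, smooth_window_s = 0)
  expect_equal(median(sp100$speed_cm_s), median(sp30$speed_cm_s),
               tolerance = 1e-6)
  expect_error(calibrate_and_upsample(tt, 42, 0), class = "calibration_error")
})

test_that("speed computation: stationary, straight line, trapezoid recovery", {
  n <- 200; fs <- 30
  t <- (0:(n - 1)) / fs
  still <- tracking_table(t, list(body_center = list(
    x = rep(5, n), y = rep(5, n), likelihood = rep(1, n))), fs,
    units = "cm", cm_per_px = 1)
  attr(still, "units") <- "cm"
  expect_true(all(compute_speed(still)$speed_cm_s == 0))

  line <- make_line_table(n = 300, fs = fs, vx_cm_s = 5)
  cal <- calibrate_and_upsample(line, 42, 420, target_fs = fs)
  sp <- compute_speed(cal, smooth_window_s = 2)
  interior <- 100:200
  expect_equal(unname(sp$speed_cm_s[interior]), rep(5, length(interior)),
               tolerance = 1e-6)

  sched <- data.frame(onset_s = 20, offset_s = 35, peak_speed = 9)
  cfg <- sim_config(seed = 5, duration_s = 60, bout_schedule = sched,
                    dropout_frac = 0)
  tk <- simulate_tracking(cfg)
  cal2 <- calibrate_and_upsample(interpolate_low_likelihood(tk$tracking),
                                 42, 420, target_fs = 30)
  sp2 <- compute_speed(cal2, smooth_window_s = 0.5)
  expect_lt(abs(max(sp2$speed_cm_s) - 9) / 9, 0.02)
})

test_that("bout detection on analytic trapezoids", {
  fs <- 30
  t <- seq(0, 60, by = 1 / fs)
  expect_equal(nrow(detect_locomotor_bouts(
    speed_trace(t, rep(0, length(t)), fs))), 0)

  v <- trapezoid_speed(t, onset = 20, offset = 35, peak = 8)
  b <- detect_locomotor_bouts(speed_trace(t, v, fs))
  expect_equal(sum(b$kind == "bout_onset"), 1)
  expect_lt(abs(event_times(b, "bout_onset") - 20), 1 / fs + 1e-9)
  expect_lt(abs(event_times(b, "bout_offset") - 35), 1 / fs + 1e-9)

  v2 <- trapezoid_speed(t, 10, 20, 8) + trapezoid_speed(t, 35, 45, 8, base = 0)
  b2 <- detect_locomotor_bouts(speed_trace(t, v2, fs))
  expect_equal(sum(b2$kind == "bout_onset"), 2)

  # trough that stays above the sustain threshold merges the two epochs
  v3 <- pmax(trapezoid_speed(t, 10, 20, 8, base = 3.5),
             trapezoid_speed(t, 22, 30, 8, base = 3.5))
  b3 <- detect_locomotor_bouts(speed_trace(t, v3, fs))
  expect_equal(sum(b3$kind == "bout_onset"), 1)

  # every bout contains speed above the entry threshold; pairing holds
  on <- event_times(b2, "bout_onset"); off <- event_times(b2, "bout_offset")
  expect_true(all(off > on))
  for (i in seq_along(on)) {
    expect_gt(max(v2[t >= on[i] & t <= off[i]]), 5)
  }
})

test_that("jump detection: period recovery, session gate, degenerate Y", {
  cfg <- sim_config(seed = 6, duration_s = 40, fs_video = 30)
  rr <- simulate_rotarod_tracking(cfg, jump_period_s = 2)
  cal <- calibrate_and_upsample(rr$tracking, 3, 90, target_fs = 30)
  j <- detect_jumps(cal)
  truth_on <- sort(event_times(rr$truth$true_jumps, "jump_onset"))
  det_on <- sort(event_times(j, "jump_onset"))
  expect_equal(length(det_on), length(truth_on))
  expect_lt(max(abs(det_on - truth_on)), 1 / 30 + 1e-9)
  iv <- attr(j, "interjump_intervals_s")
  expect_lt(max(abs(iv - 2)), 1 / 30 + 1e-9)

  cfg2 <- sim_config(seed = 6, duration_s = 40, fs_video = 30,
                     dropout_frac = 0.6)
  rr2 <- simulate_rotarod_tracking(cfg2, jump_period_s = 2)
  expect_error(detect_jumps(rr2$tracking), class = "session_excluded")

  n <- 100
  flat <- tracking_table((0:(n - 1)) / 30, list(lower_body = list(
    x = rep(1, n), y = rep(2, n), likelihood = rep(1, n))), 30)
  expect_error(detect_jumps(flat), class = "degenerate_scale")
})

test_that("motor-state rules and exhaustive partition", {
  n <- 300; fs <- 30
  t <- (0:(n - 1)) / fs
  # three regimes: fast, frozen, slow-with-one-moving-part
  body_speed <- c(rep(10, 100), rep(0, 100), rep(2, 100))
  part_speed <- cbind(body_center = body_speed,
                      snout = c(rep(10, 100), rep(0, 100), rep(1.5, 100)))
  s <- speed_trace(t, body_speed, fs, part_speeds = part_speed)
  tt <- tracking_table(t, list(body_center = list(
    x = c(rep(21, 150), rep(3, 150)), y = rep(21, n),
    likelihood = rep(1, n))), fs, units = "cm", cm_per_px = 1)
  m <- classify_motor_state(tt, s)
  expect_equal(unique(m$state[1:100]), "locomotion")
  expect_equal(unique(m$state[101:200]), "motionless")
  expect_equal(unique(m$state[201:300]), "other_movement")
  sm <- motor_state_summary(m)
  expect_equal(sum(sm$state_frac), 1, tolerance = 1e-12)
  expect_equal(sum(sm$zone_frac), 1, tolerance = 1e-12)
  expect_equal(unique(m$zone[1:150]), "center")
  expect_equal(unique(m$zone[151:300]), "periphery")
})

test_that("rotation angles: quadrant case, identity, antisymmetry", {
  sn <- data.frame(x = c(1, 0), y = c(0, 1))
  lb <- data.frame(x = c(0, 0), y = c(0, 0))
  ra <- rotation_angles(sn, lb, time_s = c(0, 0.1))
  expect_equal(ra$angle_deg[2], 90, tolerance = 1e-12)

  sn2 <- data.frame(x = c(1, 1), y = c(1, 1))
  ra2 <- rotation_angles(sn2, lb, time_s = c(0, 0.1))
  expect_equal(ra2$angle_deg[2], 0)

  rt <- simulate_rotation_trajectory(45, 8, fs_video = 20)
  fwd <- rotation_angles(part_coords(rt, "snout"),
                         part_coords(rt, "lower_body"), rt$time_s)
  rev_idx <- rev(seq_len(nrow(rt)))
  bwd <- rotation_angles(part_coords(rt, "snout")[rev_idx, ],
                         part_coords(rt, "lower_body")[rev_idx, ], rt$time_s)
  expect_equal(bwd$cumulative_deg[nrow(bwd)], -fwd$cumulative_deg[nrow(fwd)],
               tolerance = 1e-9)

  # coincident snout/lower-body frames are skipped and counted
  sn3 <- data.frame(x = c(1, 0, 0), y = c(0, 0, 1))
  lb3 <- data.frame(x = c(0, 0, 0), y = c(0, 0, 0))
  ra3 <- rotation_angles(sn3, lb3, time_s = c(0, 0.1, 0.2))
  expect_equal(attr(ra3, "n_degenerate"), 1)
  expect_true(is.na(ra3$angle_deg[2]))
})

test_that("trial-relative speed subtracts per-trial baselines and drops edge trials", {
  fs <- 20
  t <- seq(0, 400, by = 1 / fs)
  v <- rep(3, length(t))
  s <- speed_trace(t, v, fs)
  rs <- relative_speed(s, stim_onsets = c(100, 200), baseline = c(-60, -5),
                       window = c(-60, 30))
  expect_equal(max(abs(rs$trials)), 0)

  v2 <- ifelse(t >= 200, 7, 3)
  rs2 <- relative_speed(speed_trace(t, v2, fs), 200)
  in_stim <- rs2$t_rel > 0.5
  expect_equal(unique(rs2$trials[1, in_stim]), 4)

  rs3 <- relative_speed(s, stim_onsets = c(30, 200))
  expect_equal(rs3$dropped, 30)
  expect_equal(nrow(rs3$trials), 1)
})
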