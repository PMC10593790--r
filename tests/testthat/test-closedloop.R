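# Online dFF replay and the two trigger rules: constructed pass/fail
# cases, causality, determinism.

# Session with constant baselines plus optional additive signals.
make_cl_session <- function(dur = 400, fs = 20, sig465 = 0, sig405 = 0) {
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  photometry_session(t, 100 + rep_len(sig465, n), 80 + rep_len(sig405, n), fs = fs)
}

test_that("online dFF: constant channels give zero; shared transients cancel", {
  s <- make_cl_session()
  o <- online_dff_stream(s)
  expect_lt(max(abs(o$dff_online[o$warm])), 1e-12)

  # identical fractional transient on both channels cancels exactly
  n <- 400 * 20
  t <- (seq_len(n) - 1) / 20
  bump <- 5 * exp(-((t - 200)^2) / 4)
  s2 <- photometry_session(t, 100 * (1 + bump / 100), 80 * (1 + bump / 100), fs = 20)
  o2 <- online_dff_stream(s2)
  expect_lt(max(abs(o2$dff_online[o2$warm])), 1e-10)

  expect_error(online_dff_stream(make_cl_session(dur = 60)),
               class = "invalid_config")
})

test_that("online dFF step response matches a direct recurrence oracle", {
  fs <- 20; dur <- 400
  n <- dur * fs
  t <- (seq_len(n) - 1) / fs
  step <- ifelse(t >= 250, 10, 0)   # +10% step in 465 only
  s <- photometry_session(t, 100 + step, rep(80, n), fs = fs)
  o <- online_dff_stream(s, window_s = 120, lowpass_hz = 1)

  # oracle: trailing means and first-order low-pass, sample by sample
  w <- round(120 * fs)
  f465 <- 100 + step; f405 <- rep(80, n)
  d0 <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - w + 1)
    fo465 <- mean(f465[lo:i]); fo405 <- mean(f405[lo:i])
    d0[i] <- (f465[i] - fo465) / fo465 - (f405[i] - fo405) / fo405
  }
  rc <- 1 / (2 * pi * 1)
  alpha <- (1 / fs) / (rc + 1 / fs)
  y <- numeric(n); y[1] <- d0[1]
  for (i in 2:n) y[i] <- (1 - alpha) * y[i - 1] + alpha * d0[i]
  expect_equal(o$dff_online, y, tolerance = 1e-10)
  # deflection is positive right after the step and relaxes toward zero
  i_step <- which(t >= 250)[1]
  expect_gt(o$dff_online[i_step + fs], 0.05)
  expect_lt(o$dff_online[n], o$dff_online[i_step + 2 * fs])
})

# Online-dFF-like object built directly for trigger-rule unit tests.
make_online <- function(x, fs = 100) {
  structure(list(time_s = (seq_along(x) - 1) / fs, dff_online = x,
                 warm = rep(TRUE, length(x)), fs = fs),
            class = "online_dff")
}

test_that("calcium-peak trigger: pass case, sustain fail, sub-threshold fail", {
  fs <- 100
  rule <- trigger_rule("calcium_peak", threshold = 2, sustain_s = 0.25,
                       latency_s = 0.2, refractory_s = 5)
  t <- (0:999) / fs

  # never crosses threshold
  expect_equal(nrow(calcium_peak_trigger(make_online(rep(1.5, 1000), fs), rule)), 0)

  # bump above threshold for ~0.4 s (sigma 0.3: width 1.336*sigma = 0.40 s),
  # peaking 0.2 s after the crossing: detection at crossing + sustain,
  # trigger 0.2 s later
  bump <- 2.5 * exp(-((t - 3.2)^2) / (2 * 0.3^2))
  cross <- t[which(bump >= 2)[1]]
  log1 <- calcium_peak_trigger(make_online(bump, fs), rule)
  expect_equal(nrow(log1), 1)
  expect_equal(log1$trigger_time_s, cross + 0.25 + 0.2, tolerance = 1 / fs + 1e-9)

  # above threshold for only ~0.1 s: sustain unmet
  narrow <- 2.2 * exp(-((t - 3)^2) / (2 * 0.04^2))
  expect_gt(sum(narrow >= 2), 2)           # it does cross
  expect_lt(sum(narrow >= 2) / fs, 0.25)   # but too briefly
  expect_equal(nrow(calcium_peak_trigger(make_online(narrow, fs), rule)), 0)

  # refractory: two well-separated bumps but refractory 60 s -> 1 trigger
  t2 <- (0:2999) / fs
  two <- 2.5 * exp(-((t2 - 5)^2) / 0.18) + 2.5 * exp(-((t2 - 20)^2) / 0.18)
  rule_long <- trigger_rule("calcium_peak", threshold = 2, refractory_s = 60)
  expect_equal(nrow(calcium_peak_trigger(make_online(two, fs), rule_long)), 1)
  rule_short <- trigger_rule("calcium_peak", threshold = 2, refractory_s = 5)
  expect_equal(nrow(calcium_peak_trigger(make_online(two, fs), rule_short)), 2)
})

test_that("speed trigger: rest + sustained mobility fires once; violations do not", {
  fs <- 20
  rule <- trigger_rule("speed", rest_required_s = 5, rise_thresh_cms = 8,
                       floor_thresh_cms = 3, sustain_s = 5, avg_window_s = 1,
                       refractory_s = 30)
  t <- seq(0, 59.95, by = 1 / fs)

  expect_equal(nrow(speed_trigger(speed_trace(t, rep(0, length(t)), fs), rule)), 0)

  # rest 10 s then 10 cm/s held: the 1 s trailing mean reaches 8 cm/s
  # 0.8 s after the step; trigger 5 s later
  v <- ifelse(t >= 10, 10, 0)
  log1 <- speed_trigger(speed_trace(t, v, fs), rule)
  expect_equal(nrow(log1), 1)
  t_rise <- 10 + 0.8
  expect_equal(log1$trigger_time_s, t_rise + 5, tolerance = 2 / fs)

  # dip below the floor 3 s into the bout: no trigger
  v2 <- ifelse(t >= 10 & t < 13, 10, ifelse(t >= 13 & t < 16, 0, ifelse(t >= 16, 0, 0)))
  expect_equal(nrow(speed_trigger(speed_trace(t, v2, fs), rule)), 0)

  # no rest before the bout: no trigger (rest accrues only below floor)
  v3 <- ifelse(t < 10, 5, 10)
  expect_equal(nrow(speed_trigger(speed_trace(t, v3, fs), rule)), 0)

  # 2 s rest variant (slow-opsin assay) fires where the 5 s rule would too
  rule2 <- trigger_rule("speed", rest_required_s = 2, refractory_s = 30)
  expect_equal(nrow(speed_trigger(speed_trace(t, v, fs), rule2)), 1)
})

test_that("causality: future samples cannot affect past outputs or triggers", {
  fs <- 20
  s <- make_cl_session(dur = 300, fs = fs,
                       sig465 = 3 * sin(2 * pi * 0.01 * (0:5999) / fs))
  o1 <- online_dff_stream(s)
  t_cut <- 200
  idx_future <- s$time_s > t_cut
  s2 <- photometry_session(s$time_s,
                           replace(s$f465, idx_future, 500),
                           replace(s$f405, idx_future, 10), fs = fs)
  o2 <- online_dff_stream(s2)
  past <- s$time_s <= t_cut
  expect_identical(o1$dff_online[past], o2$dff_online[past])

  rule <- trigger_rule("calcium_peak", threshold = 0.005, refractory_s = 20)
  l1 <- calcium_peak_trigger(o1, rule)
  l2 <- calcium_peak_trigger(o2, rule)
  keep <- l1$trigger_time_s <= t_cut
  expect_identical(l1$trigger_time_s[keep],
                   l2$trigger_time_s[l2$trigger_time_s <= t_cut][seq_len(sum(keep))])
})

test_that("trigger logs honor refractory spacing; replay is deterministic", {
  fs <- 50
  t <- (0:9999) / fs
  sig <- 3 * (sin(2 * pi * 0.05 * t) > 0.5)
  o <- make_online(moving_average(sig, fs, 1), fs)
  rule <- trigger_rule("calcium_peak", threshold = 1.5, refractory_s = 12)
  log <- calcium_peak_trigger(o, rule)
  expect_gt(nrow(log), 1)
  expect_true(all(diff(log$trigger_time_s) >= 12 - 1e-9))
  expect_identical(log, calcium_peak_trigger(o, rule))
})

test_that("trial scheduler caps, spaces and deterministically assigns trials", {
  log <- structure(data.frame(trigger_time_s = seq(0, 3600, by = 400),
                              cause = "speed"),
                   class = c("trigger_log", "data.frame"))
  sch <- trial_scheduler(log, max_trials = 4, iti_s = 360)
  expect_equal(nrow(sch), 4)
  expect_true(all(diff(sch$trigger_time_s) >= 360))
  expect_equal(sch$condition, c("on", "off", "on", "off"))

  sch2 <- trial_scheduler(log, max_trials = 10, iti_s = 360, session_cap_s = 1300)
  expect_true(all(sch2$trigger_time_s <= 1300))

  set.seed(5); r1 <- trial_scheduler(log, 6, 360, assignment = "random")
  set.seed(5); r2 <- trial_scheduler(log, 6, 360, assignment = "random")
  expect_identical(r1, r2)
  expect_error(trial_scheduler(log, 4, iti_s = -1), class = "invalid_config")
})
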