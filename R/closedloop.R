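# Offline replay of the online closed-loop trigger rules: the causal
# online-dFF stream, the calcium-peak trigger, the speed trigger, and the
# trial scheduler. Strictly causal throughout -- no output at time t uses
# any sample after t.

#' Causal online dFF stream
#'
#' Replays the online estimate
#' `[(F - Fo)/Fo]_465 - [(F - Fo)/Fo]_405`, with each `Fo` a trailing mean
#' over the past `window_s` (120 s) of its own channel, followed by a
#' causal first-order low-pass at `lowpass_hz` (1 Hz) to suppress peaks
#' too fast to be behaviorally relevant. During warm-up the trailing
#' window shrinks to the available past; `warm` flags samples past one
#' full window.
#'
#' @param session a [photometry_session()].
#' @param window_s trailing baseline window (default 120 s).
#' @param lowpass_hz low-pass cutoff (default 1 Hz; 0 disables).
#' @return object of class `online_dff`: `time_s`, `dff_online`, `warm`,
#'   `fs`.
#' @export
online_dff_stream <- function(session, window_s = 120, lowpass_hz = 1) {
  stopifnot(inherits(session, "photometry_session"))
  n <- length(session$time_s)
  fs <- session$fs
  dur <- session$time_s[n] - session$time_s[1]
  if (dur <= window_s) stop_custom("invalid_config", "session shorter than baseline window")
  w <- round(window_s * fs)
  trail_mean <- function(x) {
    cs <- cumsum(x)
    i <- seq_along(x)
    lo <- pmax(i - w + 1L, 1L)
    (cs - c(0, cs)[lo]) / (i - lo + 1L)
  }
  fo465 <- trail_mean(session$f465)
  fo405 <- trail_mean(session$f405)
  if (any(fo465 <= 0) || any(fo405 <= 0)) {
    stop_custom("division_guard", "trailing baseline Fo <= 0")
  }
  d <- (session$f465 - fo465) / fo465 - (session$f405 - fo405) / fo405
  if (lowpass_hz > 0) {
    rc <- 1 / (2 * pi * lowpass_hz)
    alpha <- (1 / fs) / (rc + 1 / fs)
    d <- as.numeric(stats::filter(alpha * d, 1 - alpha, method = "recursive",
                                  init = d[1]))
  }
  structure(list(time_s = session$time_s, dff_online = d,
                 warm = session$time_s >= session$time_s[1] + window_s,
                 fs = fs),
            class = "online_dff")
}

#' Trigger-rule parameters
#'
#' @param kind `"calcium_peak"` or `"speed"`.
#' @param threshold online-dFF threshold (calcium rule).
#' @param sustain_s supra-threshold (calcium, 0.25 s) or above-floor
#'   mobility (speed, 5 s) duration requirement.
#' @param latency_s fixed detection-to-light latency (0.2 s models the
#'   mean online compute delay; the speed interface fires immediately).
#' @param refractory_s minimal spacing between triggers.
#' @param rest_required_s required pre-bout rest (speed rule: 5 s, or 2 s
#'   for the slow-opsin assay).
#' @param rise_thresh_cms mobility-entry threshold (8 cm/s = 0.08 m/s).
#' @param floor_thresh_cms mobility floor (3 cm/s = 0.03 m/s).
#' @param avg_window_s trailing averaging window applied to speed before
#'   thresholding (1 s).
#' @param require_peak calcium rule: also require a local peak before
#'   detection (default TRUE; the conjunction of peak and sustained
#'   supra-threshold signal).
#' @return object of class `trigger_rule`.
#' @export
trigger_rule <- function(kind = c("calcium_peak", "speed"),
                         threshold = 2, sustain_s = if (kind[1] == "speed") 5 else 0.25,
                         latency_s = if (kind[1] == "speed") 0 else 0.2,
                         refractory_s = 10,
                         rest_required_s = 5,
                         rise_thresh_cms = 8, floor_thresh_cms = 3,
                         avg_window_s = 1, require_peak = TRUE) {
  kind <- match.arg(kind)
  if (sustain_s < 0 || latency_s < 0) {
    stop_custom("invalid_config", "sustain_s and latency_s must be >= 0")
  }
  structure(list(kind = kind, threshold = threshold, sustain_s = sustain_s,
                 latency_s = latency_s, refractory_s = refractory_s,
                 rest_required_s = rest_required_s,
                 rise_thresh_cms = rise_thresh_cms,
                 floor_thresh_cms = floor_thresh_cms,
                 avg_window_s = avg_window_s, require_peak = require_peak),
            class = "trigger_rule")
}

new_trigger_log <- function(times, causes, refractory_s) {
  if (length(times) > 1L && any(diff(times) < refractory_s - 1e-9)) {
    stop_custom("invalid_config", "trigger log violates refractory spacing")
  }
  structure(data.frame(trigger_time_s = times, cause = causes),
            class = c("trigger_log", "data.frame"))
}

#' Calcium-peak trigger replay
#'
#' Fires when the online dFF has stayed above `threshold` continuously
#' for `sustain_s` and (by default) a local peak has occurred within the
#' supra-threshold run; the logged trigger time is the detection time
#' plus `latency_s`. After a trigger the signal must drop below threshold
#' and `refractory_s` must elapse before re-arming. Only warm samples are
#' eligible.
#'
#' @param o an [online_dff_stream()] result.
#' @param rule a [trigger_rule()] with `kind = "calcium_peak"`.
#' @return a `trigger_log` data.frame (`trigger_time_s`, `cause`).
#' @export
calcium_peak_trigger <- function(o, rule) {
  stopifnot(inherits(o, "online_dff"), rule$kind == "calcium_peak")
  x <- o$dff_online
  t <- o$time_s
  n <- length(x)
  times <- numeric(0)
  run_start <- NA_real_
  peak_seen <- FALSE
  rearm_at <- -Inf
  for (i in seq_len(n)) {
    if (!o$warm[i] || t[i] < rearm_at) next
    if (x[i] >= rule$threshold) {
      if (is.na(run_start)) { run_start <- t[i]; peak_seen <- FALSE }
      if (i > 2L && x[i - 1L] >= x[i] && x[i - 1L] > x[i - 2L] &&
          !is.na(run_start) && t[i - 1L] >= run_start) {
        peak_seen <- TRUE
      }
      if (t[i] - run_start >= rule$sustain_s &&
          (!rule$require_peak || peak_seen)) {
        times <- c(times, t[i] + rule$latency_s)
        rearm_at <- t[i] + rule$refractory_s
        run_start <- NA_real_
      }
    } else {
      run_start <- NA_real_
    }
  }
  new_trigger_log(times, rep("calcium_peak", length(times)), rule$refractory_s)
}

#' Speed trigger replay
#'
#' Replays the mobility rule: after the (1 s trailing-averaged) speed has
#' stayed below `floor_thresh_cms` for `rest_required_s`, a bout starts
#' when it reaches `rise_thresh_cms`; the trigger fires at the end of a
#' `sustain_s` window during which the averaged speed never falls back
#' below the floor. A floor violation aborts the bout (the dip itself
#' begins a new rest period). Refractory spacing is honored.
#'
#' @param s a `speed_trace` (cm/s).
#' @param rule a [trigger_rule()] with `kind = "speed"`.
#' @return a `trigger_log` data.frame.
#' @export
speed_trigger <- function(s, rule) {
  stopifnot(inherits(s, "speed_trace"), rule$kind == "speed")
  fs <- s$fs
  w <- max(1L, round(rule$avg_window_s * fs))
  cs <- cumsum(s$speed_cm_s)
  i <- seq_along(cs)
  lo <- pmax(i - w + 1L, 1L)
  v <- (cs - c(0, cs)[lo]) / (i - lo + 1L)
  t <- s$time_s
  n <- length(v)
  times <- numeric(0)
  rest_run <- 0
  armed <- FALSE
  t_rise <- NA_real_
  rearm_at <- -Inf
  dt <- 1 / fs
  for (k in seq_len(n)) {
    if (t[k] < rearm_at) next
    if (is.na(t_rise)) {
      if (v[k] < rule$floor_thresh_cms) {
        rest_run <- rest_run + dt
        if (rest_run >= rule$rest_required_s) armed <- TRUE
      }
      if (armed && v[k] >= rule$rise_thresh_cms) {
        t_rise <- t[k]
      }
    } else {
      if (v[k] < rule$floor_thresh_cms) {      # floor violated: abort bout
        t_rise <- NA_real_
        armed <- FALSE
        rest_run <- dt
      } else if (t[k] - t_rise >= rule$sustain_s) {
        times <- c(times, t[k] + rule$latency_s)
        rearm_at <- t[k] + rule$refractory_s
        t_rise <- NA_real_
        armed <- FALSE
        rest_run <- 0
      }
    }
  }
  new_trigger_log(times, rep("speed", length(times)), rule$refractory_s)
}

#' Schedule stimulation trials from a trigger log
#'
#' Accepts triggers only when the inter-trial interval and per-condition
#' caps permit, assigns laser-on / laser-off conditions (alternating, or
#' randomized using the current RNG state), and stops at the session cap.
#'
#' @param log a `trigger_log`.
#' @param max_trials maximal number of scheduled trials (default 10,
#'   i.e. 5 laser-on plus 5 laser-off).
#' @param iti_s minimal inter-trial interval (default 360 s).
#' @param session_cap_s latest admissible trigger time (default Inf).
#' @param assignment `"alternating"` or `"random"`.
#' @return data.frame: `trigger_time_s`, `condition` (`on` / `off`).
#' @export
trial_scheduler <- function(log, max_trials = 10, iti_s = 360,
                            session_cap_s = Inf,
                            assignment = c("alternating", "random")) {
  assignment <- match.arg(assignment)
  if (iti_s < 0) stop_custom("invalid_config", "iti_s must be >= 0")
  acc <- numeric(0)
  last <- -Inf
  for (tt in log$trigger_time_s) {
    if (tt > session_cap_s) break
    if (length(acc) >= max_trials) break
    if (tt - last >= iti_s) {
      acc <- c(acc, tt)
      last <- tt
    }
  }
  cond <- if (assignment == "alternating") {
    rep_len(c("on", "off"), length(acc))
  } else {
    sample(rep_len(c("on", "off"), length(acc)))
  }
  data.frame(trigger_time_s = acc, condition = cond)
}
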