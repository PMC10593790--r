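# Peri-stimulus spike analysis: PSTH construction, normalized rate, the
# one-third and z-score classification criteria, basal rates and
# population contingency tables.

#' Construct a unit recording
#'
#' Per-sweep spike times in milliseconds relative to laser onset, recorded
#' at one stimulation duration. Spikes outside (-1000, +2000) ms are
#' discarded at construction.
#'
#' @param unit_id unit identifier.
#' @param sweeps list of numeric spike-time vectors (ms), one per sweep.
#' @param stim_duration_ms stimulation duration (ms); 0 = no light.
#' @param region,drug optional grouping tags.
#' @return object of class `unit_recording`.
#' @export
unit_recording <- function(unit_id, sweeps, stim_duration_ms,
                           region = NA_character_, drug = NA_character_) {
  if (!length(sweeps)) stop_custom("invalid_input", "no sweeps")
  if (stim_duration_ms < 0) stop_custom("invalid_config", "stim duration must be >= 0")
  sweeps <- lapply(sweeps, function(s) sort(s[s >= -1000 & s < 2000]))
  structure(list(unit_id = unit_id, sweeps = sweeps,
                 stim_duration_ms = stim_duration_ms,
                 region = region, drug = drug),
            class = "unit_recording")
}

#' Build a peri-stimulus time histogram
#'
#' Spikes are binned at 1 ms from -1000 to +2000 ms around laser onset
#' (half-open bins `[t, t+1)`), summed over sweeps and converted to Hz:
#' `rate = count / (n_sweeps * 0.001 s)`. Baseline mean and SD are taken
#' over the 1000 pre-stimulus bins of the summed PSTH.
#'
#' @param u a [unit_recording()].
#' @return object of class `psth`: `bin_left_ms` (3000 bins), `rate_hz`,
#'   `n_sweeps`, `stim_duration_ms`, `baseline_mean_hz`, `baseline_sd_hz`
#'   (SD across the 1000 baseline bins), `baseline_sd_sweeps_hz` (SD of
#'   per-sweep baseline rates), `unit_id`, `region`, `drug`.
#' @export
build_psth <- function(u) {
  stopifnot(inherits(u, "unit_recording"))
  counts <- integer(3000L)
  for (s in u$sweeps) {
    if (!length(s)) next
    idx <- floor(s) + 1001L
    tab <- tabulate(idx, nbins = 3000L)
    counts <- counts + tab
  }
  n_sweeps <- length(u$sweeps)
  rate <- counts / (n_sweeps * 0.001)
  base <- rate[1:1000]
  # per-sweep baseline rates (Hz over the 1 s pre-window)
  sweep_base <- vapply(u$sweeps, function(s) sum(s >= -1000 & s < 0), numeric(1))
  structure(list(bin_left_ms = -1000:1999, rate_hz = rate,
                 n_sweeps = n_sweeps, stim_duration_ms = u$stim_duration_ms,
                 baseline_mean_hz = mean(base), baseline_sd_hz = stats::sd(base),
                 baseline_sd_sweeps_hz = if (n_sweeps > 1L) stats::sd(sweep_base) else NA_real_,
                 unit_id = u$unit_id, region = u$region, drug = u$drug),
            class = "psth")
}

# Stimulation-window bin selection: [0, dur) ms, with the no-light (0 ms)
# condition analyzed over [0, 1000) ms; first_50ms restricts to [0, 50).
stim_window_bins <- function(p, window = c("full_stim", "first_50ms")) {
  window <- match.arg(window)
  dur <- if (p$stim_duration_ms > 0) p$stim_duration_ms else 1000
  if (window == "first_50ms") dur <- 50
  which(p$bin_left_ms >= 0 & p$bin_left_ms < dur)
}

#' Normalized spike frequency
#'
#' Mean rate in the stimulation window divided by the mean baseline rate
#' (1000 ms pre-stimulus). The 0 ms condition is analyzed over a matched
#' 1000 ms window; `first_50ms` restricts the analysis to 0-50 ms.
#'
#' @param p a [build_psth()] result.
#' @param window `"full_stim"` or `"first_50ms"`.
#' @return dimensionless normalized rate; `NA` (unanalyzable) when the
#'   baseline is silent.
#' @export
normalized_rate <- function(p, window = "full_stim") {
  if (p$baseline_mean_hz <= 0) return(NA_real_)
  mean(p$rate_hz[stim_window_bins(p, window)]) / p$baseline_mean_hz
}

#' Classify a unit by the one-third criterion
#'
#' `inhibited` when the stimulation-window mean falls to at most 2/3 of
#' baseline, `excited` at 4/3 or more, otherwise `none`; `unanalyzable`
#' on a silent baseline.
#'
#' @inheritParams normalized_rate
#' @return one of `"inhibited"`, `"excited"`, `"none"`, `"unanalyzable"`.
#' @export
classify_thirds <- function(p, window = "full_stim") {
  nr <- normalized_rate(p, window)
  if (is.na(nr)) return("unanalyzable")
  if (nr <= 2 / 3) "inhibited" else if (nr >= 4 / 3) "excited" else "none"
}

#' Classify a unit by the PSTH z-score criterion
#'
#' `z = (mean_stim - mean_baseline) / SD_baseline` with cutoffs at -2
#' (inhibited) and +2 (excited). The baseline SD is, by default, the SD of
#' the per-sweep baseline firing rates (`sd_mode = "sweeps"`): the
#' trial-to-trial variability of the 1 s pre-stimulus rate. The
#' alternative `sd_mode = "bins"` uses the SD across the 1000 one-ms
#' baseline bins of the summed PSTH; note that at 1 ms resolution a
#' Poisson baseline makes that SD several times the mean, so even complete
#' silencing cannot reach the -2 cutoff at ordinary firing rates -- it is
#' provided for audit, not as the operating criterion.
#'
#' @inheritParams normalized_rate
#' @param sd_mode `"sweeps"` (default) or `"bins"`.
#' @return list with `zscore` and `label`.
#' @export
classify_zscore <- function(p, window = "full_stim",
                            sd_mode = c("sweeps", "bins")) {
  sd_mode <- match.arg(sd_mode)
  sd_base <- if (sd_mode == "sweeps") p$baseline_sd_sweeps_hz else p$baseline_sd_hz
  if (is.na(sd_base) || sd_base <= 0) {
    return(list(zscore = NA_real_, label = "unanalyzable"))
  }
  z <- (mean(p$rate_hz[stim_window_bins(p, window)]) - p$baseline_mean_hz) /
    sd_base
  label <- if (z <= -2) "inhibited" else if (z >= 2) "excited" else "none"
  list(zscore = z, label = label)
}

#' Basal firing rate
#'
#' Mean spike frequency over the 1000 ms preceding laser onset.
#'
#' @param p a [build_psth()] result.
#' @return rate in Hz.
#' @export
basal_rate <- function(p) p$baseline_mean_hz

#' Classify every unit of a recording set
#'
#' @param units a `unit_recording_set`.
#' @param window `"full_stim"` or `"first_50ms"`.
#' @return data.frame: `unit_id`, `region`, `drug`, `stim_duration_ms`,
#'   `basal_hz`, `norm_rate`, `label_thirds`, `zscore`, `label_z`.
#' @export
classify_units <- function(units, window = "full_stim") {
  rows <- lapply(units, function(u) {
    p <- build_psth(u)
    zc <- classify_zscore(p, window)
    data.frame(unit_id = u$unit_id, region = u$region, drug = u$drug,
               stim_duration_ms = u$stim_duration_ms,
               basal_hz = basal_rate(p),
               norm_rate = normalized_rate(p, window),
               label_thirds = classify_thirds(p, window),
               zscore = zc$zscore, label_z = zc$label)
  })
  do.call(rbind, rows)
}

#' Population contingency tables and exact tests
#'
#' Counts inhibited vs non-inhibited units per region x stimulation
#' duration, and compares the two drug groups within each cell by
#' Fisher's exact test. Units labeled `unanalyzable` are excluded from the
#' tables and counted separately.
#'
#' @param cls a [classify_units()] table.
#' @param label_col which label to tabulate (`"label_thirds"` or
#'   `"label_z"`).
#' @return list with `tables` (one 2x2 matrix per region x duration),
#'   `tests` (data.frame region, stim_duration_ms, p_value),
#'   `n_unanalyzable`.
#' @export
population_summary <- function(cls, label_col = "label_thirds") {
  usable <- cls[cls[[label_col]] != "unanalyzable", , drop = FALSE]
  n_un <- nrow(cls) - nrow(usable)
  usable$inhibited <- usable[[label_col]] == "inhibited"
  tables <- list(); tests <- list()
  for (reg in unique(usable$region)) {
    for (dur in unique(usable$stim_duration_ms)) {
      sub <- usable[which(usable$region %in% reg &
                            usable$stim_duration_ms == dur), , drop = FALSE]
      if (!nrow(sub)) next
      drugs <- sort(unique(sub$drug))
      tab <- t(vapply(drugs, function(d) {
        s <- sub[which(sub$drug %in% d), ]
        c(inhibited = sum(s$inhibited), other = sum(!s$inhibited))
      }, numeric(2)))
      key <- sprintf("%s_%sms", reg, dur)
      tables[[key]] <- tab
      if (length(drugs) == 2L && all(rowSums(tab) > 0)) {
        tests[[key]] <- data.frame(region = reg, stim_duration_ms = dur,
                                   p_value = stats::fisher.test(tab)$p.value)
      }
    }
  }
  list(tables = tables,
       tests = if (length(tests)) do.call(rbind, tests) else
         data.frame(region = character(0), stim_duration_ms = numeric(0),
                    p_value = numeric(0)),
       n_unanalyzable = n_un)
}
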