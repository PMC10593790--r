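#' Typed behavioral event set
#'
#' A sorted table of timestamped behavioral events. Paired events (bout or
#' jump onsets/offsets) share a `pair_id`; each onset must precede its
#' offset.
#'
#' @param kind character vector among `bout_onset`, `bout_offset`,
#'   `jump_onset`, `jump_offset`, `trigger`, `stim_onset`, `stim_offset`,
#'   `trial_start`, `trial_end`.
#' @param time_s event times in seconds.
#' @param pair_id optional integer pairing onsets with offsets.
#' @return data.frame of class `event_set`, sorted by time.
#' @export
event_set <- function(kind = character(0), time_s = numeric(0), pair_id = NA_integer_) {
  allowed <- c("bout_onset", "bout_offset", "jump_onset", "jump_offset",
               "trigger", "stim_onset", "stim_offset", "trial_start", "trial_end")
  if (!all(kind %in% allowed)) {
    stop_custom("invalid_config",
                sprintf("unknown event kind(s): %s",
                        paste(setdiff(kind, allowed), collapse = ", ")))
  }
  df <- data.frame(kind = kind, time_s = time_s,
                   pair_id = rep_len(pair_id, length(kind)))
  df <- df[order(df$time_s), , drop = FALSE]
  rownames(df) <- NULL
  for (pid in unique(stats::na.omit(df$pair_id))) {
    sub <- df[!is.na(df$pair_id) & df$pair_id == pid, ]
    on <- sub$time_s[grepl("onset$", sub$kind)]
    off <- sub$time_s[grepl("offset$", sub$kind)]
    if (length(on) == 1L && length(off) == 1L && on >= off) {
      stop_custom("invalid_config", sprintf("pair %d: onset does not precede offset", pid))
    }
  }
  class(df) <- c("event_set", "data.frame")
  df
}

#' Extract times of one event kind
#' @param ev an `event_set`.
#' @param kind event kind to extract.
#' @return numeric vector of times in seconds.
#' @export
event_times <- function(ev, kind) ev$time_s[ev$kind == kind]
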