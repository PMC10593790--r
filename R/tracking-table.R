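#' Body-part tracking table
#'
#' Per-frame pose-estimation output: for each tracked body part an `x`, `y`
#' coordinate and a tracking-confidence `likelihood` in \[0, 1\]. Raw tables
#' are in image pixels with y increasing downward (the tracking dialect's
#' convention); [calibrate_and_upsample()] converts once to y-up centimeter
#' coordinates, which all downstream kinematics assume.
#'
#' @param time_s frame times in seconds, strictly increasing.
#' @param parts named list; each element a data.frame/list with `x`, `y`,
#'   `likelihood` per frame.
#' @param fs_video nominal frame rate in Hz.
#' @param units `"px"` or `"cm"`.
#' @param cm_per_px calibration factor (NA until calibrated).
#' @return data.frame of class `tracking_table` with columns
#'   `time_s`, then `<part>_x`, `<part>_y`, `<part>_likelihood`.
#' @export
tracking_table <- function(time_s, parts, fs_video, units = "px", cm_per_px = NA_real_) {
  if (any(diff(time_s) <= 0)) stop_custom("invalid_config", "frame times must be strictly increasing")
  cols <- list(time_s = time_s)
  for (p in names(parts)) {
    lk <- parts[[p]]$likelihood
    if (any(lk < 0 | lk > 1)) stop_custom("invalid_config", "likelihood outside [0, 1]")
    cols[[paste0(p, "_x")]] <- parts[[p]]$x
    cols[[paste0(p, "_y")]] <- parts[[p]]$y
    cols[[paste0(p, "_likelihood")]] <- lk
  }
  df <- as.data.frame(cols)
  attr(df, "parts") <- names(parts)
  attr(df, "fs_video") <- fs_video
  attr(df, "units") <- units
  attr(df, "cm_per_px") <- cm_per_px
  class(df) <- c("tracking_table", "data.frame")
  df
}

#' List tracked body parts
#' @param t a `tracking_table`.
#' @return character vector of part names.
#' @export
tracking_parts <- function(t) attr(t, "parts")

#' Extract one body part as an x/y/likelihood data.frame
#' @param t a `tracking_table`.
#' @param part part name.
#' @return data.frame with `time_s`, `x`, `y`, `likelihood`.
#' @export
part_coords <- function(t, part) {
  if (!part %in% tracking_parts(t)) {
    stop_custom("configuration_error", sprintf("body part '%s' not in table", part))
  }
  data.frame(time_s = t$time_s,
             x = t[[paste0(part, "_x")]],
             y = t[[paste0(part, "_y")]],
             likelihood = t[[paste0(part, "_likelihood")]])
}
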