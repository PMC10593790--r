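# Plain-text readers/writers for the three input streams. Tracking uses
# the DeepLabCut CSV dialect: three header rows (scorer / bodyparts /
# coords) above x, y, likelihood column triplets, first column = frame
# index.

#' Write / read a photometry session as columnar CSV
#'
#' Columns `time_s`, `f465`, `f405`.
#'
#' @param session a [photometry_session()].
#' @param path file path.
#' @return `write_photometry_csv`: `path`, invisibly.
#' @export
write_photometry_csv <- function(session, path) {
  stopifnot(inherits(session, "photometry_session"))
  utils::write.csv(data.frame(time_s = session$time_s, f465 = session$f465,
                              f405 = session$f405),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_photometry_csv
#' @param fs sampling rate; inferred from the time column when `NULL`.
#' @return `read_photometry_csv`: a [photometry_session()].
#' @export
read_photometry_csv <- function(path, fs = NULL) {
  df <- utils::read.csv(path)
  need <- c("time_s", "f465", "f405")
  if (!all(need %in% names(df))) {
    stop_custom("malformed_input", "photometry CSV must have time_s, f465, f405")
  }
  photometry_session(df$time_s, df$f465, df$f405, fs = fs)
}

#' Write a tracking table in the DeepLabCut CSV dialect
#'
#' Emits the three header rows (`scorer`, `bodyparts`, `coords`) and one
#' `x, y, likelihood` column triplet per part; first column is the frame
#' index.
#'
#' @param t a [tracking_table()].
#' @param path file path.
#' @param scorer scorer tag written to the first header row.
#' @return `path`, invisibly.
#' @export
write_tracking_csv <- function(t, path, scorer = "synthetic") {
  parts <- tracking_parts(t)
  header1 <- c("scorer", rep(scorer, 3L * length(parts)))
  header2 <- c("bodyparts", rep(parts, each = 3L))
  header3 <- c("coords", rep(c("x", "y", "likelihood"), length(parts)))
  dat <- matrix(0, nrow = nrow(t), ncol = 3L * length(parts))
  for (i in seq_along(parts)) {
    dat[, 3L * i - 2L] <- t[[paste0(parts[i], "_x")]]
    dat[, 3L * i - 1L] <- t[[paste0(parts[i], "_y")]]
    dat[, 3L * i] <- t[[paste0(parts[i], "_likelihood")]]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(header1, collapse = ","),
               paste(header2, collapse = ","),
               paste(header3, collapse = ",")), con)
  utils::write.table(cbind(seq_len(nrow(t)) - 1L, dat), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a DeepLabCut-dialect tracking CSV
#'
#' Expects the three-header-row layout written by [write_tracking_csv()]
#' (and by the tracking software itself). Frame times come from an explicit
#' `timestamps` vector when given, else from `fs_video`.
#'
#' @param path file path.
#' @param fs_video nominal frame rate (Hz); required unless `timestamps`
#'   is supplied.
#' @param timestamps optional per-frame times in seconds.
#' @return a [tracking_table()] in pixel units.
#' @export
read_tracking <- function(path, fs_video = NULL, timestamps = NULL) {
  hdr <- readLines(path, n = 3L)
  if (length(hdr) < 3L) stop_custom("malformed_input", "fewer than 3 header rows")
  h1 <- strsplit(hdr[1], ",")[[1]]
  h2 <- strsplit(hdr[2], ",")[[1]]
  h3 <- strsplit(hdr[3], ",")[[1]]
  if (tolower(h1[1]) != "scorer" || tolower(h2[1]) != "bodyparts" ||
      tolower(h3[1]) != "coords") {
    stop_custom("malformed_input",
                "header rows must be scorer / bodyparts / coords, in that order")
  }
  coords <- h3[-1]
  if (length(coords) %% 3L != 0L ||
      !all(coords == rep(c("x", "y", "likelihood"), length(coords) / 3L))) {
    stop_custom("malformed_input", "columns must be x, y, likelihood triplets")
  }
  parts_row <- h2[-1]
  part_names <- parts_row[seq(1L, length(parts_row), by = 3L)]
  dat <- utils::read.csv(path, skip = 3L, header = FALSE)
  nframes <- nrow(dat)
  if (is.null(timestamps)) {
    if (is.null(fs_video)) stop_custom("invalid_config", "need fs_video or timestamps")
    timestamps <- (seq_len(nframes) - 1L) / fs_video
  } else if (length(timestamps) != nframes) {
    stop_custom("malformed_input", "timestamps length != number of frames")
  }
  parts <- list()
  for (i in seq_along(part_names)) {
    parts[[part_names[i]]] <- list(x = dat[[3L * i - 1L]],
                                   y = dat[[3L * i]],
                                   likelihood = dat[[3L * i + 1L]])
  }
  fs <- if (is.null(fs_video)) 1 / mean(diff(timestamps)) else fs_video
  tracking_table(timestamps, parts, fs_video = fs, units = "px")
}

#' Write / read spike trains as a plain-text per-sweep list
#'
#' Spike file columns: `unit_id`, `sweep_id`, `spike_time_ms` (relative to
#' laser onset). Unit metadata (`unit_id`, `region`, `drug`,
#' `stim_duration_ms`) travels in a separate table.
#'
#' @param units a `unit_recording_set` (see [unit_recording()]).
#' @param path file path.
#' @return `write_spike_trains`: `path`, invisibly.
#' @export
write_spike_trains <- function(units, path) {
  rows <- do.call(rbind, lapply(units, function(u) {
    do.call(rbind, lapply(seq_along(u$sweeps), function(s) {
      st <- u$sweeps[[s]]
      if (!length(st)) return(NULL)
      data.frame(unit_id = paste0(u$unit_id, "_d", u$stim_duration_ms),
                 sweep_id = s, spike_time_ms = st)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @param metadata data.frame with `unit_id`, `stim_duration_ms` and
#'   optional `region`, `drug`; one row per unit id in the spike file.
#' @return `read_spike_trains`: a `unit_recording_set`.
#' @export
read_spike_trains <- function(path, metadata) {
  df <- utils::read.csv(path)
  need <- c("unit_id", "sweep_id", "spike_time_ms")
  if (!all(need %in% names(df))) {
    stop_custom("malformed_input", "spike CSV must have unit_id, sweep_id, spike_time_ms")
  }
  if (!all(df$unit_id %in% metadata$unit_id)) {
    stop_custom("input_error", "spike file contains unit ids absent from metadata")
  }
  recs <- lapply(seq_len(nrow(metadata)), function(i) {
    sub <- df[df$unit_id == metadata$unit_id[i], , drop = FALSE]
    n_sweeps <- max(sub$sweep_id, 1L)
    sweeps <- lapply(seq_len(n_sweeps),
                     function(s) sort(sub$spike_time_ms[sub$sweep_id == s]))
    unit_recording(unit_id = metadata$unit_id[i], sweeps = sweeps,
                   stim_duration_ms = metadata$stim_duration_ms[i],
                   region = if ("region" %in% names(metadata)) metadata$region[i] else NA,
                   drug = if ("drug" %in% names(metadata)) metadata$drug[i] else NA)
  })
  structure(recs, class = "unit_recording_set")
}
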