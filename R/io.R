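#' Write seizure annotations to CSV
#'
#' @param annotations data.frame with columns onset_s, offset_s, channel,
#'   label.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  req <- c("onset_s", "offset_s", "channel", "label")
  if (!all(req %in% names(annotations)))
    stopf("annotations need columns: %s", paste(req, collapse = ", "))
  utils::write.csv(annotations[, req, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read seizure annotations from CSV
#'
#' Validates intervals (offset > onset) and returns the rows ordered by
#' onset time.
#'
#' @param path CSV path with columns onset_s, offset_s, channel, label.
#' @param channels optional character vector of allowed channel labels.
#' @return annotation data.frame.
#' @export
read_annotations <- function(path, channels = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("onset_s", "offset_s", "channel", "label")
  if (!all(req %in% names(df)))
    stopf("annotation file must have columns: %s", paste(req, collapse = ", "))
  if (nrow(df) == 0) return(empty_annotations())
  bad <- which(df$offset_s <= df$onset_s)
  if (length(bad))
    stopf("annotation row %d has offset_s <= onset_s", bad[1])
  if (!is.null(channels)) {
    bad <- which(!df$channel %in% channels)
    if (length(bad))
      stopf("annotation row %d has unknown channel '%s'", bad[1],
            df$channel[bad[1]])
  }
  df <- df[order(df$onset_s), req, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Export a band-power timeline as device-report-style JSON
#'
#' The schema mimics a chronic-sensing device report: band edges, window
#' length, start time, channel, mode, and the array of per-window values.
#' It is this package's own documented schema, not a proprietary format.
#'
#' @param timeline a `band_power_timeline`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_timeline_json <- function(timeline, path) {
  stopifnot(inherits(timeline, "band_power_timeline"))
  obj <- list(
    band_low_hz = timeline$band$low_hz, band_high_hz = timeline$band$high_hz,
    window_s = timeline$window_s, t0_s = timeline$t0_s,
    channel = timeline$channel, mode = timeline$mode, fs_hz = timeline$fs_hz,
    values = timeline$values)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a band-power timeline from JSON
#'
#' @param path JSON path written by [write_timeline_json()].
#' @return a `band_power_timeline`.
#' @export
read_timeline_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_timeline(as.numeric(obj$values), obj$window_s,
               frequency_band(obj$band_low_hz, obj$band_high_hz),
               obj$channel, obj$t0_s, obj$mode, obj$fs_hz)
}

#' Write detection events to CSV
#'
#' @param events a `detection_events` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(
    as.data.frame(events)[, c("window_index", "time_s", "z", "channel")],
    path, row.names = FALSE)
  invisible(path)
}
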