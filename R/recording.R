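#' Multichannel iEEG recording container
#'
#' A minimal in-memory container for a fixed-rate multichannel intracranial
#' EEG segment. Times throughout the package are seconds from record start
#' (0-based); channels are referenced by label, never by index.
#'
#' @param samples numeric matrix, channels x time, in physical units (uV).
#' @param fs_hz sampling rate in samples/second.
#' @param channel_labels character vector of unique channel labels, one per
#'   row of `samples`.
#' @param start_time_s record start time in seconds (default 0).
#' @return an object of class `ieeg_recording`.
#' @export
ieeg_recording <- function(samples, fs_hz, channel_labels, start_time_s = 0) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stopf("`samples` must be a numeric channels x time matrix")
  if (!is_scalar_num(fs_hz) || fs_hz <= 0)
    stopf("`fs_hz` must be a positive number")
  if (length(channel_labels) != nrow(samples))
    stopf("need one channel label per row of `samples`")
  if (anyDuplicated(channel_labels))
    stopf("channel labels must be unique")
  if (!all(is.finite(samples)))
    stopf("`samples` must be finite")
  structure(
    list(samples = samples, fs_hz = fs_hz,
         channel_labels = as.character(channel_labels),
         start_time_s = start_time_s),
    class = "ieeg_recording")
}

#' @export
print.ieeg_recording <- function(x, ...) {
  cat(sprintf("<ieeg_recording> %d channel(s) [%s], %.1f s @ %g Hz\n",
              nrow(x$samples), paste(x$channel_labels, collapse = ", "),
              ncol(x$samples) / x$fs_hz, x$fs_hz))
  invisible(x)
}

# channel label -> row index, with a helpful error
channel_index <- function(recording, channel) {
  i <- match(channel, recording$channel_labels)
  if (is.na(i))
    stopf("unknown channel '%s' (have: %s)", channel,
          paste(recording$channel_labels, collapse = ", "))
  i
}

#' Duration of a recording in seconds
#' @param recording an `ieeg_recording`.
#' @return duration in seconds.
#' @export
recording_duration <- function(recording) ncol(recording$samples) / recording$fs_hz
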