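#' Detection parameters
#'
#' @param z_threshold detection threshold on the per-window statistic
#'   (default 5: a >99.99th-percentile increase over baseline).
#' @param baseline how the timeline baseline is formed: NULL (default) for a
#'   robust estimate over all windows (median and 1.4826*MAD, tolerant of
#'   rare seizure windows, as needed for ambulatory timelines with no ground
#'   truth), a length-2 numeric (start, end) in seconds selecting windows
#'   fully inside a known seizure-free interval (mean and sample SD), or an
#'   integer vector of window indices.
#' @param min_baseline_windows minimum number of windows the baseline must
#'   contain (default 10).
#' @param merge_gap_windows supra-threshold windows separated by at most
#'   this many sub-threshold windows merge into one event (default 0:
#'   only consecutive windows merge).
#' @param threshold_mode "zscore" (default) thresholds
#'   `(value - m) / s > z_threshold`; "ratio" thresholds
#'   `value > z_threshold * m` (the "x times baseline power" reading).
#' @return object of class `detection_params`.
#' @export
detection_params <- function(z_threshold = 5, baseline = NULL,
                             min_baseline_windows = 10,
                             merge_gap_windows = 0,
                             threshold_mode = c("zscore", "ratio")) {
  threshold_mode <- match.arg(threshold_mode)
  if (z_threshold <= 0) stopf("`z_threshold` must be > 0")
  structure(
    list(z_threshold = z_threshold, baseline = baseline,
         min_baseline_windows = as.integer(min_baseline_windows),
         merge_gap_windows = as.integer(merge_gap_windows),
         threshold_mode = threshold_mode),
    class = "detection_params")
}

new_timeline <- function(values, window_s, band, channel, t0_s, mode, fs_hz) {
  structure(
    list(values = values, window_s = window_s, band = band, channel = channel,
         t0_s = t0_s, mode = mode, fs_hz = fs_hz),
    class = "band_power_timeline")
}

#' @export
print.band_power_timeline <- function(x, ...) {
  cat(sprintf("<band_power_timeline> channel %s, %s mode, %.2f-%.2f Hz, %d windows of %g s\n",
              x$channel, x$mode, x$band$low_hz, x$band$high_hz,
              length(x$values), x$window_s))
  invisible(x)
}

# Hamming-windowed linear-phase FIR bandpass; order from the 3.3/(df/fs)
# rule of thumb with a 2 Hz transition band, capped so filtfilt stays valid.
design_fir_bandpass <- function(band, fs_hz, n_samples,
                                transition_hz = 2) {
  ord <- ceiling(3.3 * fs_hz / transition_hz)
  ord <- min(2L * ceiling(ord / 2), 2L * floor((n_samples - 1) / 6))
  edges <- c(band$low_hz, min(band$high_hz, 0.99 * fs_hz / 2)) / (fs_hz / 2)
  signal::fir1(ord, edges, type = "pass")
}

#' FIR band-power timeline (SEEG analysis mode)
#'
#' Bandpass filters the channel in the given band with a zero-phase
#' (forward-backward) Hamming-windowed FIR filter, squares the filtered
#' signal, and averages it over non-overlapping contiguous windows. A
#' trailing partial window is dropped.
#'
#' @param recording an [ieeg_recording()].
#' @param channel channel label.
#' @param band a [frequency_band()] (e.g. the selected 5-Hz fingerprint).
#' @param window_s window length in seconds (default 600, the device's
#'   10-minute window).
#' @param transition_hz FIR transition band width in Hz (default 2).
#' @return a `band_power_timeline` (`values` are mean squared band-limited
#'   signal per window, units uV^2).
#' @export
fir_band_power <- function(recording, channel, band, window_s = 600,
                           transition_hz = 2) {
  stopifnot(inherits(recording, "ieeg_recording"),
            inherits(band, "frequency_band"))
  fs <- recording$fs_hz
  if (band$high_hz >= fs / 2 * 1.0001)
    stopf("band upper edge %.2f Hz is not below Nyquist", band$high_hz)
  x <- recording$samples[channel_index(recording, channel), ]
  spw <- round(window_s * fs)
  nwin <- floor(length(x) / spw)
  if (nwin < 1) stopf("recording shorter than one %g-s window", window_s)
  if (all(x == 0)) {
    y <- x
  } else {
    h <- design_fir_bandpass(band, fs, length(x), transition_hz)
    y <- signal::filtfilt(h, x)
  }
  v <- colMeans(matrix(y[seq_len(nwin * spw)]^2, nrow = spw, ncol = nwin))
  new_timeline(v, window_s, band, channel, recording$start_time_s, "FIR", fs)
}

#' Percept BrainSense Timeline emulation (FFT mode)
#'
#' Emulates the chronic-sensing mode of the Percept DBS: the device samples
#' the LFP at 250 Hz, takes the Fourier transform of each non-overlapping
#' window, and stores only the power in the configured band. Per window the
#' periodogram is normalized so that summing all bins returns the window's
#' mean square (Parseval); the stored value is the sum over bins whose
#' frequency falls in `[low, high)`.
#'
#' @inheritParams fir_band_power
#' @param device_fs_hz sensing rate the device uses (default 250); inputs at
#'   other rates are resampled by linear interpolation.
#' @return a `band_power_timeline` with `mode = "FFT"`.
#' @export
percept_timeline <- function(recording, channel, band, window_s = 600,
                             device_fs_hz = 250) {
  stopifnot(inherits(recording, "ieeg_recording"),
            inherits(band, "frequency_band"))
  x <- recording$samples[channel_index(recording, channel), ]
  fs <- recording$fs_hz
  if (fs != device_fs_hz) {
    n_new <- floor(length(x) / fs * device_fs_hz)
    x <- stats::approx(x = (seq_along(x) - 1) / fs,
                       y = x, xout = (seq_len(n_new) - 1) / device_fs_hz,
                       rule = 2)$y
    fs <- device_fs_hz
  }
  if (band$high_hz > fs / 2 + 1e-9)
    stopf("band upper edge %.2f Hz above Nyquist at %g Hz", band$high_hz, fs)
  spw <- round(window_s * fs)
  nwin <- floor(length(x) / spw)
  if (nwin < 1) stopf("recording shorter than one %g-s window", window_s)
  nu <- (seq_len(spw) - 1) * fs / spw
  nu <- pmin(nu, fs - nu)                  # two-sided bin frequencies
  inband <- nu >= band$low_hz & nu < band$high_hz
  v <- vapply(seq_len(nwin), function(k) {
    w <- x[((k - 1) * spw + 1):(k * spw)]
    P <- (Re(stats::fft(w))^2 + Im(stats::fft(w))^2) / spw^2
    sum(P[inband])
  }, 0)
  new_timeline(v, window_s, band, channel, recording$start_time_s, "FFT", fs)
}

timeline_baseline <- function(timeline, params) {
  v <- timeline$values
  b <- params$baseline
  if (is.null(b)) {
    if (length(v) < params$min_baseline_windows)
      stopf("need at least %d windows to estimate a baseline, have %d",
            params$min_baseline_windows, length(v))
    m <- stats::median(v)
    s <- stats::mad(v)                     # 1.4826 * MAD
  } else {
    if (is.numeric(b) && length(b) == 2 && !is.integer(b)) {
      t0 <- timeline$t0_s
      starts <- t0 + (seq_along(v) - 1) * timeline$window_s
      idx <- which(starts >= b[1] & starts + timeline$window_s <= b[2])
    } else {
      idx <- as.integer(b)
      if (any(idx < 1 | idx > length(v))) stopf("baseline window index out of range")
    }
    if (length(idx) < params$min_baseline_windows)
      stopf("baseline has %d windows; need at least %d",
            length(idx), params$min_baseline_windows)
    m <- mean(v[idx])
    s <- stats::sd(v[idx])
  }
  list(m = m, s = s)
}

#' Detect seizures on a band-power timeline
#'
#' z-scores every window against the baseline and reports events where the
#' statistic exceeds the threshold. Consecutive supra-threshold windows
#' (allowing gaps of up to `merge_gap_windows`) merge into one event,
#' reported at its first window.
#'
#' @param timeline a `band_power_timeline`.
#' @param params a [detection_params()].
#' @return data.frame of class `detection_events`: `window_index` (1-based),
#'   `time_s` (window start), `z`, `channel`; attributes `threshold`,
#'   `baseline_mean`, `baseline_sd`.
#' @export
detect_events <- function(timeline, params = detection_params()) {
  stopifnot(inherits(timeline, "band_power_timeline"),
            inherits(params, "detection_params"))
  bl <- timeline_baseline(timeline, params)
  v <- timeline$values
  if (bl$s == 0) {
    # a constant timeline can never cross a positive threshold; any other
    # zero-spread baseline cannot support a z-score
    if (all(v == bl$m)) bl$s <- 1
    else stopf("degenerate baseline: spread is zero")
  }
  z <- (v - bl$m) / bl$s
  hit <- if (params$threshold_mode == "zscore") z > params$z_threshold
         else v > params$z_threshold * bl$m
  idx <- which(hit)
  first <- integer(0)
  if (length(idx)) {
    grp <- cumsum(c(1L, diff(idx) > params$merge_gap_windows + 1L))
    first <- idx[!duplicated(grp)]
  }
  ev <- data.frame(
    window_index = first,
    time_s = timeline$t0_s + (first - 1) * timeline$window_s,
    z = z[first],
    channel = rep(timeline$channel, length(first)),
    stringsAsFactors = FALSE)
  attr(ev, "threshold") <- params$z_threshold
  attr(ev, "baseline_mean") <- bl$m
  attr(ev, "baseline_sd") <- bl$s
  class(ev) <- c("detection_events", class(ev))
  ev
}

#' Evaluate detections against a seizure diary
#'
#' Greedy one-to-one matching of detected events to annotated seizures: an
#' event matches an annotation if it is on the same channel and its window
#' index lies within `tolerance_windows` of the annotation's window span.
#' Unmatched events are false positives.
#'
#' @param events a `detection_events` data.frame (events from one or more
#'   channels may be concatenated with `rbind`).
#' @param annotations annotation data.frame (onset_s, offset_s, channel, label).
#' @param timeline the `band_power_timeline` the events came from (provides
#'   window length and origin).
#' @param tolerance_windows matching slack in windows (default 1).
#' @return object of class `evaluation_report`: `n_true`, `n_detected`,
#'   `n_false_positive`, `n_missed`, `matches` (data.frame),
#'   `tolerance_windows`.
#' @export
evaluate_against_diary <- function(events, annotations, timeline,
                                   tolerance_windows = 1) {
  stopifnot(inherits(timeline, "band_power_timeline"))
  ws <- timeline$window_s; t0 <- timeline$t0_s
  n_true <- nrow(annotations)
  used <- rep(FALSE, nrow(events))
  matches <- data.frame(annotation = integer(0), event = integer(0),
                        window_index = integer(0))
  if (n_true > 0) {
    ord <- order(annotations$onset_s)
    for (a in ord) {
      w_on <- floor((annotations$onset_s[a] - t0) / ws) + 1L
      w_off <- floor((annotations$offset_s[a] - t0 - 1e-9) / ws) + 1L
      cand <- which(!used &
                      events$channel == annotations$channel[a] &
                      events$window_index >= w_on - tolerance_windows &
                      events$window_index <= w_off + tolerance_windows)
      if (length(cand)) {
        mid <- (w_on + w_off) / 2
        e <- cand[which.min(abs(events$window_index[cand] - mid))]
        used[e] <- TRUE
        matches <- rbind(matches, data.frame(
          annotation = a, event = e, window_index = events$window_index[e]))
      }
    }
  }
  structure(
    list(n_true = n_true, n_detected = nrow(matches),
         n_false_positive = sum(!used), n_missed = n_true - nrow(matches),
         matches = matches, tolerance_windows = tolerance_windows),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d/%d seizures detected, %d false positive(s)\n",
              x$n_detected, x$n_true, x$n_false_positive))
  invisible(x)
}
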