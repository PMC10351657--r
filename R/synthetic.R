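#' Seizure specification for the synthetic iEEG generator
#'
#' Describes one planted seizure: a narrowband ictal rhythm (band-limited
#' Gaussian noise around a dominant low-beta frequency, with cosine on/off
#' ramps and an optional slow linear frequency drift) plus an optional
#' broadband high-frequency component. Amplitudes are expressed as ratios to
#' the RMS of the background signal on the target channel, so a spec is
#' meaningful independent of the background level.
#'
#' @param onset_s seizure onset, seconds from record start.
#' @param duration_s seizure duration in seconds (default 90; clinical focal
#'   seizures typically last tens of seconds to ~2 minutes).
#' @param channel channel label the seizure is planted on ("LEFT"/"RIGHT").
#' @param ictal_center_hz dominant frequency of the ictal rhythm in Hz
#'   (default 14.65, low-beta).
#' @param ictal_bandwidth_hz full bandwidth of the ictal rhythm in Hz
#'   (default 2; a rhythmic discharge is narrowband).
#' @param ictal_amplitude RMS of the ictal rhythm as a multiple of the
#'   channel background RMS (default 3).
#' @param hfo_band_hz length-2 numeric, broadband high-frequency band in Hz
#'   (default c(61.8, 150); clipped to below Nyquist at generation time).
#' @param hfo_amplitude RMS of the broadband component as a multiple of the
#'   background RMS (default 0: off).
#' @param chirp_hz_per_s linear drift of the ictal centre frequency in Hz/s
#'   (default 0).
#' @param ramp_s cosine on/off ramp duration in seconds (default 2).
#' @return an object of class `seizure_spec`.
#' @export
seizure_spec <- function(onset_s, duration_s = 90, channel = "LEFT",
                         ictal_center_hz = 14.65, ictal_bandwidth_hz = 2,
                         ictal_amplitude = 3,
                         hfo_band_hz = c(61.8, 150), hfo_amplitude = 0,
                         chirp_hz_per_s = 0, ramp_s = 2) {
  if (!is_scalar_num(onset_s) || onset_s < 0) stopf("`onset_s` must be >= 0")
  if (!is_scalar_num(duration_s) || duration_s <= 0)
    stopf("`duration_s` must be > 0")
  if (!is_scalar_num(ictal_center_hz) || ictal_center_hz <= 0)
    stopf("`ictal_center_hz` must be > 0")
  if (ictal_bandwidth_hz < 0) stopf("`ictal_bandwidth_hz` must be >= 0")
  if (ictal_amplitude < 0 || hfo_amplitude < 0)
    stopf("amplitudes must be >= 0")
  if (length(hfo_band_hz) != 2 || hfo_band_hz[2] <= hfo_band_hz[1])
    stopf("`hfo_band_hz` must be (low, high) with high > low")
  structure(
    list(onset_s = onset_s, duration_s = duration_s, channel = channel,
         ictal_center_hz = ictal_center_hz,
         ictal_bandwidth_hz = ictal_bandwidth_hz,
         ictal_amplitude = ictal_amplitude,
         hfo_band_hz = as.numeric(hfo_band_hz), hfo_amplitude = hfo_amplitude,
         chirp_hz_per_s = chirp_hz_per_s, ramp_s = ramp_s),
    class = "seizure_spec")
}

#' Configuration of the synthetic two-channel pulvinar iEEG generator
#'
#' The generator emulates a bilateral pulvinar SEEG/LFP recording: a 1/f-like
#' interictal background on each channel plus seizures planted according to
#' `seizures`. All randomness flows from `seed`; identical configurations
#' give bit-identical signals.
#'
#' @param duration_s record duration in seconds.
#' @param fs_hz sampling rate (default 250, the rate at which the Percept
#'   device senses LFPs).
#' @param channel_labels labels for the channels (default LEFT, RIGHT).
#' @param seizures list of [seizure_spec()] objects.
#' @param background_exponent spectral slope of the background: power ~
#'   1/f^exponent (default 1).
#' @param background_rms target RMS of the background in uV (default 50,
#'   typical of depth-electrode iEEG).
#' @param background_flatten_hz frequency below which the background spectrum
#'   is flattened, emulating the acquisition highpass (default 0.5 Hz).
#' @param seed integer RNG seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(duration_s, fs_hz = 250,
                             channel_labels = c("LEFT", "RIGHT"),
                             seizures = list(),
                             background_exponent = 1, background_rms = 50,
                             background_flatten_hz = 0.5, seed = 1) {
  if (!is_scalar_num(duration_s) || duration_s <= 0)
    stopf("`duration_s` must be > 0")
  if (!is_scalar_num(fs_hz) || fs_hz <= 0) stopf("`fs_hz` must be > 0")
  if (anyDuplicated(channel_labels)) stopf("channel labels must be unique")
  if (background_rms < 0) stopf("`background_rms` must be >= 0")
  if (inherits(seizures, "seizure_spec")) seizures <- list(seizures)
  for (sp in seizures) {
    if (!inherits(sp, "seizure_spec")) stopf("`seizures` must be seizure_spec objects")
    top <- sp$ictal_center_hz + sp$ictal_bandwidth_hz / 2
    if (top >= fs_hz / 2)
      stopf("ictal band edge %.2f Hz is not below Nyquist (%g Hz)", top, fs_hz / 2)
    if (!(sp$channel %in% channel_labels))
      stopf("seizure channel '%s' is not a configured channel", sp$channel)
    if (sp$onset_s + sp$duration_s > duration_s || sp$onset_s < 0)
      stopf("seizure [%g, %g] s lies outside the record [0, %g] s",
            sp$onset_s, sp$onset_s + sp$duration_s, duration_s)
  }
  # no overlap on the same channel
  for (ch in unique(vapply(seizures, `[[`, "", "channel"))) {
    sps <- Filter(function(s) s$channel == ch, seizures)
    if (length(sps) > 1) {
      on <- vapply(sps, `[[`, 0, "onset_s")
      off <- on + vapply(sps, `[[`, 0, "duration_s")
      o <- order(on)
      if (any(on[o][-1] < off[o][-length(o)]))
        stopf("seizures overlap on channel %s", ch)
    }
  }
  structure(
    list(duration_s = duration_s, fs_hz = fs_hz,
         channel_labels = as.character(channel_labels), seizures = seizures,
         background_exponent = background_exponent,
         background_rms = background_rms,
         background_flatten_hz = background_flatten_hz,
         seed = as.integer(seed)),
    class = "synthetic_config")
}

# One channel of 1/f^a background, shaped in the frequency domain from white
# Gaussian noise; spectrum flattened below `flatten_hz` (acquisition highpass
# analogue) and DC removed. Uses the ambient RNG stream.
colored_noise <- function(n, fs, exponent, rms, flatten_hz) {
  if (rms == 0) return(numeric(n))
  w <- stats::rnorm(n)
  if (exponent != 0) {
    X <- stats::fft(w)
    f <- (seq_len(n) - 1) * fs / n
    f <- pmin(f, fs - f)               # two-sided frequency of each bin
    gain <- pmax(f, flatten_hz)^(-exponent / 2)
    gain[1] <- 0                       # remove DC
    w <- Re(stats::fft(X * gain, inverse = TRUE)) / n
  } else {
    w <- w - mean(w)
  }
  w / sqrt(mean(w^2)) * rms
}

#' Generate the interictal background recording
#'
#' Power-law (1/f^exponent) Gaussian noise on every configured channel,
#' scaled to the configured RMS. Deterministic given the config seed.
#'
#' @param config a [synthetic_config()].
#' @return an [ieeg_recording()].
#' @export
generate_background <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, background_impl(config))
}

background_impl <- function(config) {
  n <- round(config$duration_s * config$fs_hz)
  nch <- length(config$channel_labels)
  samples <- matrix(0, nrow = nch, ncol = n)
  for (i in seq_len(nch))
    samples[i, ] <- colored_noise(n, config$fs_hz, config$background_exponent,
                                  config$background_rms,
                                  config$background_flatten_hz)
  ieeg_recording(samples, config$fs_hz, config$channel_labels)
}

# Narrowband ictal waveform: lowpass-filtered white noise (baseband,
# bandwidth bw/2) heterodyned onto a carrier at the (possibly drifting)
# centre frequency, giving band-limited noise of full bandwidth bw around
# the instantaneous centre. bw = 0 degenerates to a pure sinusoid.
ictal_waveform <- function(n, fs, center, bw, chirp, ramp_s) {
  tt <- (seq_len(n) - 1) / fs
  if (bw > 0) {
    base <- stats::rnorm(n)
    ord <- min(2L * floor(max(50, 4 * fs / bw) / 2), 2L * floor((n - 1) / 6))
    h <- signal::fir1(ord, (bw / 2) / (fs / 2), type = "low")
    base <- signal::filtfilt(h, base)
  } else {
    base <- rep(1, n)
  }
  phase <- 2 * pi * (center * tt + 0.5 * chirp * tt^2) +
    stats::runif(1, 0, 2 * pi)
  x <- base * cos(phase)
  x <- x * cosine_ramp(n, fs, ramp_s)
  r <- sqrt(mean(x^2))
  if (r > 0) x / r else x
}

# Broadband component: FIR-bandpass-filtered white noise over `band`
# (clipped below Nyquist), with the same ramps.
broadband_waveform <- function(n, fs, band, ramp_s) {
  lo <- band[1]
  hi <- min(band[2], 0.98 * fs / 2)
  if (hi <= lo) stopf("broadband band [%g, %g] Hz empty below Nyquist", band[1], band[2])
  x <- stats::rnorm(n)
  ord <- min(2L * floor(max(100, 4 * fs / (hi - lo)) / 2), 2L * floor((n - 1) / 6))
  h <- signal::fir1(ord, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(h, x) * cosine_ramp(n, fs, ramp_s)
  r <- sqrt(mean(x^2))
  if (r > 0) x / r else x
}

cosine_ramp <- function(n, fs, ramp_s) {
  nr <- min(round(ramp_s * fs), floor(n / 2))
  w <- rep(1, n)
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    w[seq_len(nr)] <- ramp
    w[n + 1 - seq_len(nr)] <- rev(ramp)
  }
  w
}

#' Inject planted seizures into a recording
#'
#' Adds, on each spec's channel only and only within its interval, a
#' narrowband ictal oscillation plus an optional broadband high-frequency
#' component. Samples outside the annotated intervals are untouched.
#'
#' @param recording an [ieeg_recording()].
#' @param specs list of [seizure_spec()] objects.
#' @param seed optional seed for the waveform noise; NULL uses the ambient
#'   RNG stream.
#' @return list with elements `recording` (modified copy) and `annotations`
#'   (data.frame: onset_s, offset_s, channel, label).
#' @export
inject_seizures <- function(recording, specs, seed = NULL) {
  stopifnot(inherits(recording, "ieeg_recording"))
  if (inherits(specs, "seizure_spec")) specs <- list(specs)
  with_seed(seed, inject_impl(recording, specs))
}

inject_impl <- function(recording, specs) {
  fs <- recording$fs_hz
  ntot <- ncol(recording$samples)
  dur <- ntot / fs
  ann <- empty_annotations()
  for (sp in specs) {
    if (!inherits(sp, "seizure_spec")) stopf("specs must be seizure_spec objects")
    if (sp$onset_s < 0 || sp$onset_s + sp$duration_s > dur + 1e-9)
      stopf("seizure [%g, %g] s outside the record [0, %g] s",
            sp$onset_s, sp$onset_s + sp$duration_s, dur)
    top <- sp$ictal_center_hz + sp$ictal_bandwidth_hz / 2
    if (top >= fs / 2) stopf("ictal band edge %.2f Hz above Nyquist", top)
    ci <- channel_index(recording, sp$channel)
    i0 <- floor(sp$onset_s * fs) + 1L
    i1 <- min(floor((sp$onset_s + sp$duration_s) * fs), ntot)
    idx <- i0:i1
    ref_rms <- sqrt(mean(recording$samples[ci, ]^2))
    if (ref_rms == 0) ref_rms <- 1
    add <- numeric(length(idx))
    if (sp$ictal_amplitude > 0)
      add <- add + sp$ictal_amplitude * ref_rms *
        ictal_waveform(length(idx), fs, sp$ictal_center_hz,
                       sp$ictal_bandwidth_hz, sp$chirp_hz_per_s, sp$ramp_s)
    if (sp$hfo_amplitude > 0)
      add <- add + sp$hfo_amplitude * ref_rms *
        broadband_waveform(length(idx), fs, sp$hfo_band_hz, sp$ramp_s)
    recording$samples[ci, idx] <- recording$samples[ci, idx] + add
    ann <- rbind(ann, data.frame(
      onset_s = sp$onset_s, offset_s = sp$onset_s + sp$duration_s,
      channel = sp$channel, label = "seizure", stringsAsFactors = FALSE))
  }
  if (nrow(ann)) ann <- ann[order(ann$onset_s), , drop = FALSE]
  rownames(ann) <- NULL
  list(recording = recording, annotations = ann)
}

empty_annotations <- function() {
  data.frame(onset_s = numeric(0), offset_s = numeric(0),
             channel = character(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic EMU dataset
#'
#' Background plus planted seizures in one deterministic step: the scaled
#' stand-in for an epilepsy-monitoring-unit admission.
#'
#' @param config a [synthetic_config()] with `seizures` set.
#' @return list with `recording` and `annotations` as in [inject_seizures()].
#' @export
generate_emu_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    bg <- background_impl(config)
    inject_impl(bg, config$seizures)
  })
}
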