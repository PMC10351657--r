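#' Morlet wavelet analysis parameters
#'
#' The wavelet family is a complex Morlet parameterized by the full width at
#' half maximum (FWHM) of its time-domain Gaussian envelope: 3 s at the 1 Hz
#' reference frequency. Under the default `scaling = "cycles"` the FWHM
#' scales inversely with frequency (constant number of cycles per wavelet,
#' the usual constant-Q reading); `scaling = "fixed"` keeps the 3-s envelope
#' at every frequency (constant spectral resolution).
#'
#' @param freqs_hz monotone increasing vector of analysis frequencies in Hz,
#'   or NULL to resolve a default grid (`f_lo` to just below Nyquist in
#'   steps of `f_step`) when the sampling rate is known.
#' @param fwhm_s time-domain envelope FWHM in seconds at `fwhm_ref_hz`
#'   (default 3).
#' @param fwhm_ref_hz reference frequency anchoring the FWHM (default 1 Hz).
#' @param scaling "cycles" (FWHM ~ 1/f, default) or "fixed".
#' @param f_lo,f_hi,f_step default grid bounds and spacing in Hz used when
#'   `freqs_hz` is NULL; `f_hi = NULL` means just below Nyquist.
#' @param time_decim integer decimation factor for the spectrogram time axis
#'   (default 1 = native resolution; long records should decimate).
#' @return an object of class `wavelet_params`.
#' @export
wavelet_params <- function(freqs_hz = NULL, fwhm_s = 3, fwhm_ref_hz = 1,
                           scaling = c("cycles", "fixed"),
                           f_lo = 1, f_hi = NULL, f_step = 0.2,
                           time_decim = 1L) {
  scaling <- match.arg(scaling)
  if (fwhm_s <= 0) stopf("`fwhm_s` must be > 0")
  if (!is.null(freqs_hz)) {
    if (is.unsorted(freqs_hz, strictly = TRUE) || any(freqs_hz <= 0))
      stopf("`freqs_hz` must be positive and strictly increasing")
  }
  if (time_decim < 1) stopf("`time_decim` must be >= 1")
  structure(
    list(freqs_hz = freqs_hz, fwhm_s = fwhm_s, fwhm_ref_hz = fwhm_ref_hz,
         scaling = scaling, f_lo = f_lo, f_hi = f_hi, f_step = f_step,
         time_decim = as.integer(time_decim)),
    class = "wavelet_params")
}

resolve_freqs <- function(params, fs_hz) {
  if (!is.null(params$freqs_hz)) return(params$freqs_hz)
  hi <- params$f_hi %||% (fs_hz / 2 - params$f_step)
  hi <- min(hi, fs_hz / 2 - params$f_step / 2)
  seq(params$f_lo, hi, by = params$f_step)
}

wavelet_fwhm <- function(params, f) {
  if (params$scaling == "cycles") params$fwhm_s * params$fwhm_ref_hz / f
  else rep(params$fwhm_s, length(f))
}

#' Morlet wavelet power spectral density of one channel
#'
#' Convolves the channel with a family of complex Morlet wavelets (computed
#' in the frequency domain: each wavelet is a Gaussian around its centre
#' frequency, restricted to positive frequencies and unit peak gain) and
#' returns squared magnitude per time and frequency. Samples within one
#' wavelet half-support (one envelope FWHM) of either record edge are set to
#' NA, per frequency, so edge artefacts never enter baseline statistics.
#'
#' @param recording an [ieeg_recording()].
#' @param channel channel label.
#' @param params a [wavelet_params()].
#' @return object of class `wavelet_spectrogram`: list with `power`
#'   (time x frequency matrix, NA at masked edges), `times_s`, `freqs_hz`,
#'   `channel`, `fs_hz`, `params`.
#' @export
morlet_psd <- function(recording, channel, params = wavelet_params()) {
  stopifnot(inherits(recording, "ieeg_recording"),
            inherits(params, "wavelet_params"))
  fs <- recording$fs_hz
  freqs <- resolve_freqs(params, fs)
  if (any(freqs >= fs / 2))
    stopf("analysis frequency %.2f Hz is not below Nyquist (%g Hz)",
          max(freqs), fs / 2)
  x <- recording$samples[channel_index(recording, channel), ]
  n <- length(x)
  tidx <- seq(1L, n, by = params$time_decim)
  times <- (tidx - 1) / fs
  X <- stats::fft(x)
  nu <- (seq_len(n) - 1) * fs / n          # fft bin frequencies, 0..fs
  pos <- nu <= fs / 2                      # analytic: keep positive half only
  fwhms <- wavelet_fwhm(params, freqs)
  power <- matrix(NA_real_, nrow = length(tidx), ncol = length(freqs))
  XH <- complex(length.out = n)
  for (j in seq_along(freqs)) {
    f <- freqs[j]; fwhm <- fwhms[j]
    a <- pi^2 * fwhm^2 / (4 * log(2))      # H(nu) = exp(-a (nu - f)^2)
    # support window: beyond ~9.2 sd the gain underflows anyway
    half <- sqrt(40 / a)
    keep <- which(pos & nu >= f - half & nu <= f + half)
    XH[] <- 0
    XH[keep] <- X[keep] * exp(-a * (nu[keep] - f)^2)
    amp <- stats::fft(XH, inverse = TRUE)[tidx] / n
    p <- Re(amp)^2 + Im(amp)^2
    mask_s <- fwhm                          # one half-support each end
    p[times < mask_s | times > (n - 1) / fs - mask_s] <- NA_real_
    power[, j] <- p
  }
  structure(
    list(power = power, times_s = times, freqs_hz = freqs, channel = channel,
         fs_hz = fs, params = params),
    class = "wavelet_spectrogram")
}

#' @export
print.wavelet_spectrogram <- function(x, ...) {
  cat(sprintf("<wavelet_spectrogram> channel %s: %d times x %d freqs (%.2f-%.2f Hz)\n",
              x$channel, nrow(x$power), ncol(x$power),
              min(x$freqs_hz), max(x$freqs_hz)))
  invisible(x)
}

#' Per-frequency baseline statistics of a spectrogram interval
#'
#' Mean and sample standard deviation (denominator n-1) of wavelet power per
#' frequency over the time samples of a pre-ictal baseline interval.
#' Edge-masked (NA) samples are excluded. If annotations are supplied the
#' interval must not overlap any annotated seizure.
#'
#' @param spec a `wavelet_spectrogram`.
#' @param interval_s numeric length-2, (start, end) seconds; half-open
#'   `[start, end)`.
#' @param annotations optional seizure annotation data.frame (onset_s,
#'   offset_s, ...) to guard against ictal contamination.
#' @param min_duration_s minimum allowed interval length (default 0; the
#'   pipeline passes its configured baseline duration, 900 s by default).
#' @return object of class `baseline_stats`: per-frequency `mean`, `sd`,
#'   plus `baseline_interval_s`, `n_samples`, `freqs_hz`.
#' @export
baseline_stats <- function(spec, interval_s, annotations = NULL,
                           min_duration_s = 0) {
  stopifnot(inherits(spec, "wavelet_spectrogram"), length(interval_s) == 2)
  start <- interval_s[1]; end <- interval_s[2]
  if (end <= start) stopf("baseline interval must have end > start")
  if (end - start < min_duration_s)
    stopf("baseline interval %.1f s is shorter than the configured minimum %.1f s",
          end - start, min_duration_s)
  dt <- if (length(spec$times_s) > 1) stats::median(diff(spec$times_s)) else 0
  if (start < min(spec$times_s) - 1e-9 || end > max(spec$times_s) + dt + 1e-9)
    stopf("baseline interval [%g, %g] s outside spectrogram times", start, end)
  if (!is.null(annotations) && nrow(annotations) > 0 &&
      any(annotations$onset_s < end & annotations$offset_s > start))
    stopf("baseline interval overlaps an annotated seizure")
  rows <- spec$times_s >= start & spec$times_s < end
  if (!any(rows)) stopf("baseline interval contains no time samples")
  p <- spec$power[rows, , drop = FALSE]
  m <- colMeans(p, na.rm = TRUE)
  s <- apply(p, 2, stats::sd, na.rm = TRUE)
  nk <- colSums(!is.na(p))
  if (any(nk < 2))
    stopf("fewer than 2 unmasked baseline samples at %.2f Hz",
          spec$freqs_hz[which(nk < 2)[1]])
  structure(
    list(mean = m, sd = s, baseline_interval_s = c(start, end),
         n_samples = sum(rows), freqs_hz = spec$freqs_hz),
    class = "baseline_stats")
}

#' z-score normalize a spectrogram against baseline statistics
#'
#' `z[t, f] = (power[t, f] - mean[f]) / sd[f]`; the normalization that turns
#' raw wavelet power into "increase over the pre-ictal baseline" units.
#'
#' @param spec a `wavelet_spectrogram`.
#' @param stats a [baseline_stats()] with an identical frequency axis.
#' @return object of class `normalized_spectrogram` with `z`, `times_s`,
#'   `freqs_hz`, `channel`, `baseline`.
#' @export
zscore_normalize <- function(spec, stats) {
  stopifnot(inherits(spec, "wavelet_spectrogram"),
            inherits(stats, "baseline_stats"))
  if (length(spec$freqs_hz) != length(stats$freqs_hz) ||
      any(abs(spec$freqs_hz - stats$freqs_hz) > 1e-9))
    stopf("spectrogram and baseline frequency axes differ")
  if (any(stats$sd == 0))
    stopf("degenerate baseline: sd = 0 at %.2f Hz",
          stats$freqs_hz[which(stats$sd == 0)[1]])
  z <- sweep(sweep(spec$power, 2, stats$mean, "-"), 2, stats$sd, "/")
  structure(
    list(z = z, times_s = spec$times_s, freqs_hz = spec$freqs_hz,
         channel = spec$channel, baseline = stats),
    class = "normalized_spectrogram")
}

#' @export
print.normalized_spectrogram <- function(x, ...) {
  cat(sprintf("<normalized_spectrogram> channel %s: %d times x %d freqs\n",
              x$channel, nrow(x$z), ncol(x$z)))
  invisible(x)
}

# Collapse the time axis of a normalized spectrogram over an interval to one
# summary z per frequency. The default (median) is robust to brief
# within-seizure artefacts.
ictal_summary <- function(norm, interval_s,
                          stat = c("median", "mean", "max")) {
  stat <- match.arg(stat)
  stopifnot(inherits(norm, "normalized_spectrogram"), length(interval_s) == 2)
  rows <- norm$times_s >= interval_s[1] & norm$times_s < interval_s[2]
  if (!any(rows)) stopf("interval [%g, %g] s contains no time samples",
                        interval_s[1], interval_s[2])
  zz <- norm$z[rows, , drop = FALSE]
  fun <- switch(stat, median = function(v) stats::median(v, na.rm = TRUE),
                mean = function(v) mean(v, na.rm = TRUE),
                max = function(v) max(v, na.rm = TRUE))
  apply(zz, 2, fun)
}
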