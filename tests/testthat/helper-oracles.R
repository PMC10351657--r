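# Independent oracles used to check the implementation. These deliberately
# avoid the package's own spectral code paths.

# Segment-averaged (Welch) periodogram, rectangular window, no overlap.
# Returns freqs (one-sided) and power density-like values adequate for
# slope fits and band comparisons.
welch_psd <- function(x, fs, seg_s = 2) {
  spw <- round(seg_s * fs)
  nseg <- floor(length(x) / spw)
  stopifnot(nseg >= 1)
  acc <- numeric(spw %/% 2 + 1)
  for (k in seq_len(nseg)) {
    seg <- x[((k - 1) * spw + 1):(k * spw)]
    X <- fft(seg)
    P <- (Mod(X)^2) / spw
    acc <- acc + P[seq_len(spw %/% 2 + 1)]
  }
  list(freq = (seq_len(spw %/% 2 + 1) - 1) * fs / spw, power = acc / nseg)
}

# log-log spectral slope of x over [f_lo, f_hi] Hz
welch_slope <- function(x, fs, f_lo = 1, f_hi = 100, seg_s = 2) {
  w <- welch_psd(x, fs, seg_s)
  sel <- w$freq >= f_lo & w$freq <= f_hi
  unname(coef(lm(log(w$power[sel]) ~ log(w$freq[sel])))[2])
}

# Exhaustive enumeration of all valid sliding bins: the oracle for
# scan_bins. zsums: list of per-seizure summary-z vectors on `freqs`.
brute_force_bins <- function(zsums, freqs, bands, width, step) {
  out <- NULL
  for (b in bands) {
    if (b$high_hz - b$low_hz < width - 1e-9) next
    lo <- b$low_hz
    while (lo + width <= b$high_hz + 1e-9) {
      sel <- freqs >= lo - 1e-9 & freqs < lo + width - 1e-9
      if (any(sel)) {
        ps <- sapply(zsums, function(z) mean(z[sel], na.rm = TRUE))
        out <- rbind(out, c(low_hz = lo, center_hz = lo + width / 2,
                            score = mean(ps)))
      }
      lo <- lo + step
    }
  }
  df <- as.data.frame(out)
  df[order(df$center_hz), , drop = FALSE]
}

# hand-built spectrogram objects for unit tests of the normalization layer
fake_spectrogram <- function(power, times, freqs, channel = "LEFT", fs = 250) {
  structure(list(power = power, times_s = times, freqs_hz = freqs,
                 channel = channel, fs_hz = fs, params = NULL),
            class = "wavelet_spectrogram")
}

fake_norm <- function(z, times, freqs, channel = "LEFT") {
  structure(list(z = z, times_s = times, freqs_hz = freqs, channel = channel,
                 baseline = NULL),
            class = "normalized_spectrogram")
}

fake_timeline <- function(values, window_s = 10, band = frequency_band(12.15, 17.15),
                          channel = "LEFT", t0 = 0, mode = "FIR", fs = 250) {
  structure(list(values = values, window_s = window_s, band = band,
                 channel = channel, t0_s = t0, mode = mode, fs_hz = fs),
            class = "band_power_timeline")
}

# scratch file path inside tempdir for IO tests
withr_local_file <- function(name) file.path(tempdir(), name)
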