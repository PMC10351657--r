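make_rec <- function(x, fs = 250, labels = "LEFT") {
  ieeg_recording(matrix(x, nrow = 1), fs, labels)
}

test_that("zero signal gives zero interior power and masked edges", {
  rec <- make_rec(numeric(30 * 250))
  wp <- wavelet_params(freqs_hz = c(5, 10, 20), fwhm_s = 3, scaling = "cycles")
  spec <- morlet_psd(rec, "LEFT", wp)
  expect_true(all(spec$power == 0, na.rm = TRUE))
  # at 5 Hz the envelope FWHM is 0.6 s: the first samples must be masked
  expect_true(all(is.na(spec$power[spec$times_s < 0.6, 1])))
  expect_false(anyNA(spec$power[spec$times_s > 1 & spec$times_s < 29, ]))
})

test_that("a pure sinusoid peaks at the nearest grid frequency at every interior time", {
  fs <- 250
  tt <- (0:(30 * fs - 1)) / fs
  rec <- make_rec(sin(2 * pi * 20 * tt), fs)
  wp <- wavelet_params(freqs_hz = seq(10, 30, 0.5))
  spec <- morlet_psd(rec, "LEFT", wp)
  interior <- spec$times_s > 2 & spec$times_s < 28
  peak <- apply(spec$power[interior, ], 1, which.max)
  expect_true(all(spec$freqs_hz[peak] == 20))
})

test_that("wavelet power is quadratic in amplitude and separates two tones", {
  fs <- 250
  tt <- (0:(40 * fs - 1)) / fs
  x <- 1.0 * sin(2 * pi * 10 * tt) + 0.5 * sin(2 * pi * 80 * tt)
  rec <- make_rec(x, fs)
  wp <- wavelet_params(freqs_hz = seq(5, 100, 0.5))
  spec <- morlet_psd(rec, "LEFT", wp)
  mid <- which.min(abs(spec$times_s - 20))
  p <- spec$power[mid, ]
  i10 <- which.min(abs(spec$freqs_hz - 10))
  i80 <- which.min(abs(spec$freqs_hz - 80))
  # closed form: response power at the matching frequency scales with A^2,
  # so the peak ratio equals (1 / 0.5)^2 = 4
  expect_equal(p[i10] / p[i80], 4, tolerance = 0.1)
  # linearity across amplitudes: doubling the signal quadruples power
  spec2 <- morlet_psd(make_rec(2 * x, fs), "LEFT", wp)
  expect_equal(spec2$power[mid, i10] / p[i10], 4, tolerance = 1e-6)
})

test_that("interior spectrogram columns shift with the input", {
  fs <- 250
  set.seed(42)
  n <- 20 * fs
  x <- rnorm(n)
  k <- 50                                  # shift by 50 samples
  xs <- c(x[(k + 1):n], x[1:k])            # circular shift, matches fft conv
  wp <- wavelet_params(freqs_hz = c(10, 25), time_decim = 1)
  a <- morlet_psd(make_rec(x, fs), "LEFT", wp)
  b <- morlet_psd(make_rec(xs, fs), "LEFT", wp)
  interior <- which(a$times_s > 2 & a$times_s < 18 - k / fs)
  expect_equal(b$power[interior, ], a$power[interior + k, ], tolerance = 1e-9)
})

test_that("baseline statistics use the sample SD and honour masks", {
  freqs <- c(10, 20)
  times <- seq(0, 9.9, 0.1)
  p <- matrix(3, nrow = length(times), ncol = 2)
  spec <- fake_spectrogram(p, times, freqs)
  bl <- baseline_stats(spec, c(0, 10))
  expect_equal(unname(bl$mean), c(3, 3))
  expect_equal(unname(bl$sd), c(0, 0))

  # two-sample toy column {1, 3}: mean 2, sample sd (ddof = 1) sqrt(2)
  spec2 <- fake_spectrogram(matrix(c(1, 3, 1, 3), nrow = 2), c(0, 1), freqs)
  bl2 <- baseline_stats(spec2, c(0, 2))
  expect_equal(unname(bl2$mean), c(2, 2))
  expect_equal(unname(bl2$sd), c(sqrt(2), sqrt(2)))
})

test_that("baseline intervals are validated", {
  spec <- fake_spectrogram(matrix(1, 100, 2), seq(0, 99), c(10, 20))
  expect_error(baseline_stats(spec, c(0, 50), min_duration_s = 900), "minimum")
  expect_error(baseline_stats(spec, c(50, 200)), "outside")
  ann <- data.frame(onset_s = 30, offset_s = 40, channel = "LEFT",
                    label = "seizure")
  expect_error(baseline_stats(spec, c(0, 50), annotations = ann), "overlaps")
  expect_silent(baseline_stats(spec, c(41, 99), annotations = ann))
})

test_that("z-normalization matches its definition and flags degenerate baselines", {
  freqs <- c(10, 20)
  times <- 0:9
  p <- matrix(rep(c(2, 4), each = 10), ncol = 2)   # mean per freq: 2 and 4
  p[3, 1] <- 2 + 3.3 * 1                           # one cell at the threshold
  spec <- fake_spectrogram(p, times, freqs)
  bl <- structure(list(mean = c(2, 4), sd = c(1, 2),
                       baseline_interval_s = c(0, 10), n_samples = 10,
                       freqs_hz = freqs), class = "baseline_stats")
  z <- zscore_normalize(spec, bl)
  expect_equal(z$z[1, ], c(0, 0))
  expect_equal(z$z[3, 1], 3.3)

  bl$sd <- c(1, 0)
  expect_error(zscore_normalize(spec, bl), "20.00 Hz")
})

test_that("1/f background yields a baseline mean that decreases with frequency", {
  cfg <- synthetic_config(duration_s = 240, seed = 6)
  rec <- generate_background(cfg)
  # fixed-FWHM scaling keeps the analysis bandwidth constant across
  # frequency (a Welch-consistent estimate), so mean power tracks the 1/f
  # input spectrum; the constant-cycles mode whitens 1/f by construction
  spec <- morlet_psd(rec, "LEFT",
                     wavelet_params(f_lo = 2, f_hi = 60, f_step = 1,
                                    scaling = "fixed", time_decim = 10))
  bl <- baseline_stats(spec, c(10, 230))
  expect_lt(cor(bl$mean, spec$freqs_hz, method = "spearman"), -0.9)
})

test_that("z-scores are invariant to a global amplitude rescaling", {
  cfg <- synthetic_config(duration_s = 60, seed = 9)
  rec <- generate_background(cfg)
  wp <- wavelet_params(freqs_hz = seq(5, 30, 1), time_decim = 5)
  norm1 <- zscore_normalize(s1 <- morlet_psd(rec, "LEFT", wp),
                            baseline_stats(s1, c(5, 55)))
  rec2 <- rec; rec2$samples <- rec$samples * 3
  norm2 <- zscore_normalize(s2 <- morlet_psd(rec2, "LEFT", wp),
                            baseline_stats(s2, c(5, 55)))
  expect_equal(s2$power, 9 * s1$power, tolerance = 1e-9)
  expect_equal(norm2$z, norm1$z, tolerance = 1e-6)
})

test_that("planted seizures exceed the 3.3-z significance threshold at their centre", {
  fp <- run_small_fingerprint(seed = 21)
  # median ictal z at the planted centre frequency is far above threshold
  expect_gt(fp$score, 3.3)
  expect_true(length(fp$significant_bands) >= 1)
})

test_that("unknown channels and super-Nyquist frequencies are rejected", {
  rec <- make_rec(rnorm(2500))
  expect_error(morlet_psd(rec, "MID", wavelet_params(freqs_hz = 10)), "unknown channel")
  expect_error(morlet_psd(rec, "LEFT", wavelet_params(freqs_hz = c(10, 130))),
               "Nyquist")
})
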