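sine_rec <- function(freq, fs = 250, dur = 60, amp = 1, labels = "LEFT") {
  tt <- (0:(dur * fs - 1)) / fs
  ieeg_recording(matrix(amp * sin(2 * pi * freq * tt), nrow = 1), fs, labels)
}

fingerprint_band <- frequency_band(12.15, 17.15)

test_that("FIR band power matches the analytic mean square of a sinusoid", {
  zero <- ieeg_recording(matrix(0, 1, 250 * 60), 250, "LEFT")
  tl0 <- fir_band_power(zero, "LEFT", fingerprint_band, window_s = 10)
  expect_true(all(tl0$values == 0))
  expect_length(tl0$values, 6)

  # unit sinusoid at the band centre: mean square = A^2 / 2 = 0.5
  tl <- fir_band_power(sine_rec(14.65), "LEFT", fingerprint_band,
                       window_s = 10)
  inner <- tl$values[2:5]                  # windows clear of filter ramps
  expect_true(all(abs(inner - 0.5) < 0.025))

  # 30 Hz lies in the stopband: residual power < 0.005
  tl30 <- fir_band_power(sine_rec(30), "LEFT", fingerprint_band, window_s = 10)
  expect_true(all(tl30$values[2:5] < 0.005))

  expect_error(fir_band_power(sine_rec(14.65, dur = 5), "LEFT",
                              fingerprint_band, window_s = 10), "shorter")
})

test_that("Percept FFT mode allocates white-noise power proportional to band width", {
  set.seed(31)
  fs <- 250; dur <- 200
  rec <- ieeg_recording(matrix(rnorm(fs * dur), 1), fs, "LEFT")
  band <- frequency_band(40, 45)
  tl <- percept_timeline(rec, "LEFT", band, window_s = 10)
  total <- mean(rec$samples[1, ]^2)
  expect_length(tl$values, 20)
  expect_equal(mean(tl$values) / total, 5 / 125, tolerance = 0.1)
})

test_that("FIR and FFT band-power timelines agree on synthetic seizures", {
  for (s in 1:3) {
    cfg <- small_emu_config(seed = 400 + s)
    ds <- generate_emu_dataset(cfg)
    tf <- fir_band_power(ds$recording, "LEFT", fingerprint_band, window_s = 20)
    tp <- percept_timeline(ds$recording, "LEFT", fingerprint_band,
                           window_s = 20)
    expect_equal(which.max(tf$values), which.max(tp$values))
    expect_gt(cor(tf$values, tp$values, method = "spearman"), 0.95)
    ef <- detect_events(tf)$window_index
    ep <- detect_events(tp)$window_index
    expect_equal(length(ef), length(ep))
    expect_true(all(abs(ef - ep) <= 1))
  }
})

test_that("event detection z-scores, thresholds and merges correctly", {
  flat <- fake_timeline(rep(2, 50))
  expect_equal(nrow(detect_events(flat)), 0)

  # explicit baseline with mean 1 and sample sd 0.1; one window at 1.6
  base <- 1 + 0.1 * scale(rnorm(20, 0, 1))[, 1]
  v <- c(base, 1.6)
  tl <- fake_timeline(v)
  ev <- detect_events(tl, detection_params(baseline = 1:20))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$window_index, 21)
  expect_equal(ev$z, 6, tolerance = 1e-9)
  expect_equal(ev$time_s, 200)
  expect_equal(ev$channel, "LEFT")

  # consecutive supra-threshold windows merge; a gap splits unless allowed
  v2 <- c(base, 1.6, 1.7, 1.0, 1.6)
  ev2 <- detect_events(fake_timeline(v2), detection_params(baseline = 1:20))
  expect_equal(ev2$window_index, c(21, 24))
  ev3 <- detect_events(fake_timeline(v2),
                       detection_params(baseline = 1:20,
                                        merge_gap_windows = 1))
  expect_equal(ev3$window_index, 21)

  expect_error(detect_events(fake_timeline(c(rep(1, 20), 2)),
                             detection_params(baseline = 1:20)),
               "degenerate")
  expect_error(detect_events(fake_timeline(rep(1, 5))), "at least 10")
})

test_that("ratio thresholding implements the x-times-baseline reading", {
  base <- 1 + 0.001 * scale(rnorm(20))[, 1]
  v <- c(base, 3)
  ev <- detect_events(fake_timeline(v),
                      detection_params(z_threshold = 5, baseline = 1:20,
                                       threshold_mode = "ratio"))
  expect_equal(nrow(ev), 0)                # 3 < 5 * 1
  ev2 <- detect_events(fake_timeline(c(base, 6)),
                       detection_params(z_threshold = 5, baseline = 1:20,
                                        threshold_mode = "ratio"))
  expect_equal(ev2$window_index, 21)
})

test_that("raising the threshold never increases the event count", {
  set.seed(77)
  v <- abs(rnorm(200, 1, 0.3)) + 5 * (runif(200) < 0.05)
  counts <- vapply(c(2, 3, 5, 8), function(th)
    nrow(detect_events(fake_timeline(v), detection_params(z_threshold = th))),
    0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("left-planted seizures never fire on the right channel", {
  violations <- 0L
  for (s in 1:10) {
    cfg <- synthetic_config(
      duration_s = 400, seed = 500 + s,
      seizures = list(seizure_spec(onset_s = 150, duration_s = 40,
                                   ictal_amplitude = 5),
                      seizure_spec(onset_s = 300, duration_s = 40,
                                   ictal_amplitude = 5)))
    ds <- generate_emu_dataset(cfg)
    evr <- detect_events(percept_timeline(ds$recording, "RIGHT",
                                          fingerprint_band, window_s = 10))
    if (nrow(evr) > 0) violations <- violations + 1L
    evl <- detect_events(percept_timeline(ds$recording, "LEFT",
                                          fingerprint_band, window_s = 10))
    expect_gte(nrow(evl), 1)
  }
  expect_lte(violations, 1)
})

test_that("seizure-free records stay below the z > 5 threshold", {
  clean <- logical(10)
  for (s in 1:10) {
    rec <- generate_background(synthetic_config(duration_s = 2000,
                                                channel_labels = "LEFT",
                                                seed = 600 + s))
    tl <- percept_timeline(rec, "LEFT", fingerprint_band, window_s = 10)
    expect_gte(length(tl$values), 200)
    clean[s] <- nrow(detect_events(tl)) == 0
  }
  expect_gte(mean(clean), 0.95)
})

test_that("diary evaluation matches greedily, one-to-one, channel-aware", {
  tl <- fake_timeline(rep(1, 100), window_s = 10)
  no_ev <- detect_events(fake_timeline(rep(1, 100)))
  r0 <- evaluate_against_diary(no_ev, empty_ann <- data.frame(
    onset_s = numeric(0), offset_s = numeric(0), channel = character(0),
    label = character(0)), tl)
  expect_equal(r0$n_true, 0); expect_equal(r0$n_detected, 0)
  expect_equal(r0$n_false_positive, 0)

  ann <- data.frame(onset_s = c(105, 255, 405, 555, 705),
                    offset_s = c(125, 275, 425, 575, 725),
                    channel = "LEFT", label = "seizure")
  ev <- data.frame(window_index = c(11, 26, 41, 56, 71),
                   time_s = (c(11, 26, 41, 56, 71) - 1) * 10,
                   z = rep(8, 5), channel = "LEFT")
  r <- evaluate_against_diary(ev, ann, tl, tolerance_windows = 1)
  expect_equal(r$n_true, 5)
  expect_equal(r$n_detected, 5)
  expect_equal(r$n_false_positive, 0)

  # an event far from any annotation, or on the wrong channel, is a false positive
  ev2 <- rbind(ev, data.frame(window_index = 90, time_s = 890, z = 9,
                              channel = "LEFT"))
  expect_equal(evaluate_against_diary(ev2, ann, tl)$n_false_positive, 1)
  ev3 <- ev; ev3$channel <- "RIGHT"
  r3 <- evaluate_against_diary(ev3, ann, tl)
  expect_equal(r3$n_detected, 0)
  expect_equal(r3$n_false_positive, 5)
})
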