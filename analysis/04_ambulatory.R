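#!/usr/bin/env Rscript
# Ambulatory emulation — chronic sensing after discharge. A longer (2-h)
# synthetic record carries five left-channel seizures; both channels are
# sensed in Percept BrainSense Timeline mode (per-window FFT power in the
# fingerprint band, scaled 60-s windows) and detections at z > 5 against a
# robust (median/MAD) baseline are compared with the diary, including
# laterality. Expect all five on the LEFT channel and none on the RIGHT.
# Run 02 first (the fingerprint band is read from its output).

suppressPackageStartupMessages(library(pulvfp))

fpj <- jsonlite::read_json("results/emu/fingerprint.json",
                           simplifyVector = TRUE)
band <- frequency_band(fpj$selected$low_hz, fpj$selected$high_hz)

out_dir <- "results/ambulatory"
onsets <- c(1200, 2400, 3600, 4800, 6300)
cfg <- pipeline_config(
  window_s = 60, detection_mode = "fft", band = band,
  synthetic = synthetic_config(
    duration_s = 7200, fs_hz = 250, seed = 202,
    seizures = lapply(onsets, function(o)
      seizure_spec(onset_s = o, duration_s = 90))))

run_pipeline(cfg, "simulate", out_dir)
res <- run_pipeline(cfg, "detect", out_dir)
rep <- run_pipeline(cfg, "evaluate", out_dir)$evaluate

ev <- res$detect$events
message(sprintf("Sensing band %.2f-%.2f Hz, 60-s FFT windows: %d event(s), %d on LEFT, %d on RIGHT",
                band$low_hz, band$high_hz, nrow(ev),
                sum(ev$channel == "LEFT"), sum(ev$channel == "RIGHT")))
message(sprintf("Diary concordance: %d/%d detected, %d false positive(s)",
                rep$n_detected, rep$n_true, rep$n_false_positive))
message("Artifacts under ", out_dir)
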