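#!/usr/bin/env Rscript
# Build the synthetic EMU admission used by the downstream analyses: a 1-h,
# 250 Hz, two-channel (bilateral pulvinar) record with three 90-s seizures
# planted on the LEFT channel. Each seizure carries a narrowband low-beta
# rhythm centred at 14.65 Hz at 3x the background RMS over a 1/f background.
# Artifacts (EDF recording, annotation CSV, config YAML) go to results/emu/.

suppressPackageStartupMessages(library(pulvfp))

out_dir <- "results/emu"
onsets <- c(1000, 1900, 2800)

cfg <- pipeline_config(
  wavelet = wavelet_params(time_decim = 25L),
  window_s = 30,                       # scaled-down analysis window
  detection_mode = "fir",
  synthetic = synthetic_config(
    duration_s = 3600, fs_hz = 250, seed = 101,
    seizures = lapply(onsets, function(o)
      seizure_spec(onset_s = o, duration_s = 90, ictal_center_hz = 14.65,
                   ictal_amplitude = 3))))

run_pipeline(cfg, "simulate", out_dir)
write_config(cfg, file.path(out_dir, "config.yaml"))

message("Wrote ", out_dir, "/recording.edf (1 h, 2 channels, 250 Hz), ",
        "annotations.csv (", length(onsets), " seizures) and config.yaml")
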