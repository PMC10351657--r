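#!/usr/bin/env Rscript
# Stage 2 — deploy the fingerprint on the EMU record. The band-power time
# series (zero-phase FIR bandpass, squared, averaged over non-overlapping
# 30-s windows) is z-scored against a robust timeline baseline and
# thresholded at z > 5; detections are matched against the seizure diary.
# A control band (58.15-63.15 Hz) is rerun identically and should detect
# nothing. Run 01 and 02 first.

suppressPackageStartupMessages(library(pulvfp))

out_dir <- "results/emu"
cfg <- read_config(file.path(out_dir, "config.yaml"))

res <- run_pipeline(cfg, "detect", out_dir)
run_pipeline(cfg, "evaluate", out_dir)

# control band: same record, same detector, a band away from the fingerprint
ctl_dir <- "results/emu_control"
dir.create(ctl_dir, showWarnings = FALSE, recursive = TRUE)
file.copy(file.path(out_dir, c("recording.edf", "annotations.csv")), ctl_dir,
          overwrite = TRUE)
cfg_ctl <- cfg
cfg_ctl$band <- frequency_band(58.15, 63.15)
ctl <- run_pipeline(cfg_ctl, "detect", ctl_dir)

message(sprintf("Fingerprint band: %d event(s) [%s]",
                nrow(res$detect$events),
                paste(res$detect$events$channel, collapse = ", ")))
message(sprintf("Control band 58.15-63.15 Hz: %d event(s)",
                nrow(ctl$detect$events)))
message("Events and per-channel timelines under ", out_dir,
        "; evaluation in report.json")
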