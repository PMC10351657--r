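# Small shared builders for scaled synthetic experiments.

# 600-s two-channel record with two 60-s left-channel seizures; leaves
# 300 s of clean pre-ictal baseline.
small_emu_config <- function(seed = 1, amp = 3, center = 14.65, bw = 2,
                             hfo_amplitude = 0) {
  synthetic_config(
    duration_s = 600, seed = seed,
    seizures = list(
      seizure_spec(onset_s = 330, duration_s = 60, ictal_center_hz = center,
                   ictal_bandwidth_hz = bw, ictal_amplitude = amp,
                   hfo_amplitude = hfo_amplitude),
      seizure_spec(onset_s = 480, duration_s = 60, ictal_center_hz = center,
                   ictal_bandwidth_hz = bw, ictal_amplitude = amp,
                   hfo_amplitude = hfo_amplitude)))
}

small_wavelet <- function(decim = 10)
  wavelet_params(f_lo = 5, f_hi = 40, f_step = 0.25, time_decim = decim)

# full small-scale stage-1 run: returns the fingerprint result
run_small_fingerprint <- function(seed, amp = 3, center = 14.65) {
  cfg <- small_emu_config(seed = seed, amp = amp, center = center)
  ds <- generate_emu_dataset(cfg)
  spec <- morlet_psd(ds$recording, "LEFT", small_wavelet())
  bl <- baseline_stats(spec, c(30, 330), annotations = ds$annotations)
  norm <- zscore_normalize(spec, bl)
  fingerprint_seizures(norm, list(c(330, 390), c(480, 540)))
}
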