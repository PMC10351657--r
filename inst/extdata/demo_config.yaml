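wavelet:
  freqs_hz: ~
  fwhm_s: 3.0
  fwhm_ref_hz: 1.0
  scaling: cycles
  f_lo: 5.0
  f_hi: 40.0
  f_step: 0.25
  time_decim: 10
fingerprint:
  z_threshold: 3.3
  bin_width_hz: 5.0
  bin_step_hz: 0.05
  min_band_width_hz: 1.0
  summary_stat: median
detection:
  z_threshold: 5.0
  baseline: ~
  min_baseline_windows: 10
  merge_gap_windows: 0
  threshold_mode: zscore
baseline_duration_s: 120.0
window_s: 10.0
detection_mode: fir
band: ~
tolerance_windows: 1
synthetic:
  duration_s: 300.0
  fs_hz: 250.0
  channel_labels:
  - LEFT
  - RIGHT
  seizures:
  - onset_s: 150.0
    duration_s: 30.0
    channel: LEFT
    ictal_center_hz: 14.65
    ictal_bandwidth_hz: 2.0
    ictal_amplitude: 3.0
    hfo_band_hz:
    - 61.8
    - 150.0
    hfo_amplitude: 0.0
    chirp_hz_per_s: 0.0
    ramp_s: 2.0
  - onset_s: 230.0
    duration_s: 30.0
    channel: LEFT
    ictal_center_hz: 14.65
    ictal_bandwidth_hz: 2.0
    ictal_amplitude: 3.0
    hfo_band_hz:
    - 61.8
    - 150.0
    hfo_amplitude: 0.0
    chirp_hz_per_s: 0.0
    ramp_s: 2.0
  background_exponent: 1.0
  background_rms: 50.0
  background_flatten_hz: 0.5
  seed: 2024
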