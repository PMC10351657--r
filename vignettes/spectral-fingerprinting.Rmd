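---
title: "Spectral fingerprinting of seizures: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral fingerprinting of seizures: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pulvfp)
```

## The problem

Implanted neurostimulators with chronic sensing (the Medtronic Percept
family) cannot stream raw intracranial EEG. In their Timeline mode they
sample the local field potential at 250 Hz, Fourier-transform each
10-minute window, and store a single number: the power in one 5-Hz
frequency band. An ambulatory seizure diary from such a device therefore
stands or falls with the choice of that band. `pulvfp` implements the
two-stage procedure for choosing it from a monitored-unit (EMU) admission
with annotated seizures, and the detector that then runs on the stored
power-in-band (PIB) timeline.

## Stage 1: the fingerprint model

Let $x(t)$ be one SEEG channel sampled at $f_s$ Hz. For each analysis
frequency $f$ the package computes the complex Morlet wavelet transform

$$W(t, f) = (x * w_f)(t), \qquad
  w_f(t) = e^{2\pi i f t}\, e^{-4\ln 2\, t^2 / h(f)^2},$$

implemented in the frequency domain as a Gaussian of unit peak gain around
$f$, restricted to positive frequencies (an analytic wavelet). Power is
$P(t,f) = |W(t,f)|^2$. Given a pre-ictal baseline interval, per-frequency
mean $\mu_f$ and sample standard deviation $\sigma_f$ (denominator $n-1$)
define the normalized map $z(t,f) = (P(t,f) - \mu_f)/\sigma_f$.

Per seizure, the time axis is collapsed to a per-frequency summary
(median ictal $z$ by default); maximal contiguous runs with summary
$z > 3.3$ are the *significant bands*. A 5-Hz bin then slides across them
in 0.05-Hz steps; the bin's score is its mean summary $z$ over in-bin
frequencies, averaged (unweighted) across seizures, and the argmax —
ties broken toward the lower centre — is the spectral fingerprint.

### The wavelet parameterization

The envelope FWHM is anchored at $h_0 = 3$ s for a 1-Hz reference. Two
readings are plausible and both are supported:

* `scaling = "cycles"` (default): $h(f) = h_0/f$, i.e. a constant number of
  cycles per wavelet (constant-Q). Spectral resolution scales with $f$
  (about 4.3 Hz FWHM at 14.65 Hz).
* `scaling = "fixed"`: $h(f) = h_0$ at every frequency, i.e. constant
  0.29-Hz spectral resolution, the behaviour of a Welch/STFT analysis.

A consequence worth knowing: on a $1/f$ background the constant-Q mode
yields an approximately *flat* mean power across frequency (output variance
$\propto S(f) \times \text{bandwidth}(f) \approx$ const), while the fixed
mode tracks $S(f)$ itself. The z-normalization removes this difference, so
the fingerprint is insensitive to the choice on synthetic data; the
constant-cycles default follows common practice for broadband
time-frequency maps of ictal dynamics.

Samples within one envelope FWHM of either record edge are masked (NA) per
frequency rather than silently zero-padded, and masked samples are excluded
from baseline statistics. Degenerate baselines ($\sigma_f = 0$) raise an
error naming the frequency rather than producing infinities.

### Why the bins must slide

Disjoint 5-Hz partitions of a significant band cannot represent a bin such
as 12.15–17.15 Hz; only a sliding placement (0.05-Hz steps, bins fully
inside the band) can. Bin edges are half-open $[low, high)$ and snap to the
analysis grid when frequencies are selected, so reported edges are grid
values. The default grid is 1 Hz to just below Nyquist in 0.2-Hz steps —
fine enough to represent band edges such as 9.4, 39.8 or 61.8 Hz — with the
0.05-Hz bin step giving the bin centres their resolution.

## Stage 2: the detector

The band-power timeline is computed in two interchangeable modes:

* **FIR** (SEEG analysis): Hamming-windowed linear-phase bandpass, order
  from the $3.3 f_s/\Delta f$ rule with a 2-Hz transition band, applied
  forward–backward (zero phase); the filtered signal is squared and
  averaged over non-overlapping windows, trailing partial window dropped.
* **FFT** (device emulation): per-window periodogram normalized so the sum
  over all bins equals the window's mean square (Parseval); the stored
  value is the sum over bins in $[low, high)$. Inputs not at 250 Hz are
  resampled first.

The two modes are required by tests to agree in rank order and, after
thresholding, in detected windows to within one window index.

Detection z-scores each window against a baseline. In the EMU, seizure-free
windows can be designated explicitly (mean/SD). For ambulatory timelines no
ground truth exists, so the default is a robust estimate — median and
$1.4826 \cdot \mathrm{MAD}$ over all windows — which tolerates the rare
seizure windows without contaminating the baseline. Windows with $z > 5$
(a >99.99th-percentile increase) become events; consecutive supra-threshold
windows (with a configurable merge gap, default 0) merge into one event
reported at its first window. The alternative "$x$ times baseline power"
reading of the threshold is available as `threshold_mode = "ratio"`; the
z-score reading is the default. Events carry their channel, so detection is
lateralized, and diary concordance is scored by greedy one-to-one matching
within a window tolerance (default ±1), unmatched events counting as false
positives.

## The synthetic generator

The generator emulates what the analysis needs from bilateral pulvinar
iEEG, not seizure morphology:

* **Background**: $1/f$ Gaussian noise (exponent configurable), RMS 50 μV,
  spectrum flattened below 0.5 Hz to mimic the acquisition highpass —
  without it, pure $1/f$ noise down to $1/T$ Hz puts nearly all variance
  into slow drift, unlike clinical recordings.
* **Ictal rhythm**: band-limited Gaussian noise — lowpass-filtered white
  noise heterodyned onto a carrier at the centre frequency (default
  14.65 Hz, low-beta), bandwidth 2 Hz, 2-s cosine on/off ramps, optional
  linear chirp. The 2-Hz default encodes that a rhythmic ictal discharge is
  narrowband; its amplitude default (3× background RMS) makes the planted
  rhythm unambiguous, as in the recordings that motivated the method.
* **Broadband high-frequency component**: FIR-bandpassed white noise over
  61.8–150 Hz (clipped below Nyquist), available for experiments on the
  two-band significance structure but **off by default**: the
  acceptance-facing experiments plant only the dominant narrowband rhythm.
  At scaled-down window lengths seizures fully occupy their windows, a
  regime in which even modest broadband power overlapping a control band
  would register — unlike at full scale, where a seizure occupies a small
  fraction of a 10-minute window.
* Seizure durations default to 90 s (clinically plausible for focal
  seizures); all randomness flows from one integer seed and identical
  configurations give bit-identical signals; injection modifies only the
  annotated channel and interval.

What passing on these data does **not** show: robustness to artifacts,
electrode drift, state-dependent (sleep/wake) baseline shifts, morphological
seizure variety, or volume conduction — none of which the generator models.

## Problem sizes used by the tests and scripts

The reference-scale experiments use a 1-h, 250 Hz, two-channel record with
three 90-s seizures (fingerprint stage: 620 frequencies, spectrogram time
axis decimated to 10 Hz; detection stage: 30-s windows, ≥100 seizure-free)
and a 2-h ambulatory record with five seizures sensed in 60-s FFT windows.
Monte-Carlo property tests (seed-swept recovery, null specificity,
laterality) use 600-s records with a reduced 5–40 Hz grid: the pipeline is
rate- and threshold-based, so these scales preserve its behaviour while
keeping the suite fast. All paper-facing defaults (3.3 and 5 z-thresholds,
5-Hz bins, 600-s windows, 900-s baseline, 250 Hz) are unchanged by scaling.

## Other design choices

* **Per-frequency ictal summary**: median over ictal time samples (robust
  to brief artifacts); mean and max are config options.
* **Bands across seizures**: significant bands are computed per seizure and
  merged (union) before the bin scan, so a band recruited in only some
  seizures still competes; the cross-seizure averaging then happens at the
  bin-score level.
* **Baseline guard**: `baseline_stats()` refuses intervals overlapping any
  annotated seizure and intervals shorter than the configured minimum.
* **Degenerate timelines**: a perfectly constant timeline yields no events
  (nothing can exceed a positive threshold); any other zero-spread baseline
  is an error.
* **EDF I/O**: a minimal reader/writer for uniform-rate continuous EDF
  (16-bit, symmetric physical range per channel) keeps the round-trip error
  within one quantization step; it does not parse EDF+ annotation streams.

## Known limitations

Single-channel fingerprinting (the recruited channel) only; no multiple
testing correction beyond the stated z thresholds; the Percept emulation
covers the Timeline mode's arithmetic, not device quirks (telemetry gaps,
artifact rejection, firmware rounding); the robust ambulatory baseline
assumes seizures are rare among windows — a patient in status epilepticus
would violate it.
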