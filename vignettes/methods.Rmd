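---
title: "Methods: chrominance rPPG, camera SpO2, and quality-gated streaming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chrominance rPPG, camera SpO2, and quality-gated streaming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirrorvitals)
```

# The model

Remote photoplethysmography (rPPG) recovers the cardiac pulse from the tiny
colour oscillations of facial skin in ordinary video. `mirrorvitals`
implements the classical chrominance route:

1. **Spatial averaging.** Per frame, the R, G and B intensities are averaged
   over the face ROI, giving one triple $(V_R, V_G, V_B)$ per frame — a
   $3 \times N$ trace at the camera frame rate.
2. **Chrominance projection.** The trace is projected onto two axes,
   $X_s = 3V_R - 2V_G$ and $Y_s = 1.5V_R + V_G - 1.5V_B$, chosen so that
   achromatic intensity changes (illumination, shading) appear almost
   identically on both axes while blood-volume pulsatility does not.
3. **Bandpass filtering.** Both series are mean-removed and filtered to the
   cardiac band, 0.6–4.0 Hz by default (36–240 bpm). A 0.7–3.5 Hz deployment
   preset is available (`bandpass_preset("tight")`).
4. **Skin-tone normalisation.** The pulse is
   $S = X_f - \alpha Y_f$ with $\alpha = \sigma(X_f)/\sigma(Y_f)$
   (population standard deviations). Any component shared proportionally by
   the two filtered axes — the residual illumination/motion signal the
   projection was designed to equalise — is cancelled *exactly*; this is
   asserted as a property test. The degenerate rule $\sigma(Y_f) = 0 \Rightarrow
   \alpha = 0,\ S = X_f$ is fixed for reproducibility.
5. **Heart rate.** $f_h$ is the in-band argmax of the Hann-tapered,
   zero-padded magnitude spectrum of $S$ (bin spacing $\le$ 0.02 Hz),
   refined by quadratic interpolation over the three bins around the peak;
   $\mathrm{HR} = 60 f_h$ bpm. Native resolution of a 2-s window is 0.5 Hz
   (30 bpm), so interpolation on a padded spectrum is not optional — it is
   the minimal fix that makes bpm-level output meaningful.
6. **SpO2.** Per window, DC is the mean and AC the population standard
   deviation of the *raw* red and blue channels;
   $\mathrm{SpO_2} = A - B\,\frac{AC_R/DC_R}{AC_B/DC_B}$ with the published
   camera-oximetry constants $A = 125$, $B = 26$. The linear form is
   unbounded, so output is clamped to $[0, 100]$ with a flag (never an
   error). An alternative path computing AC on the filtered channels exists
   (`use_filtered = TRUE`) but raw is the default: the decomposition is
   defined on the channel trace itself.

# Signal quality and the streaming engine

The SNR of a window is a fundamental-plus-harmonic mask ratio: power within
±0.1 Hz of $f_h$ and $2f_h$ (intersected with the band) over the remaining
in-band power. The source system states only the gate (SNR > 0.7), not a
formula, so this de Haan-style definition is the package's own and is
documented as such. Two consequences worth knowing:

* On long windows (10 s) a clean tone scores SNR > 10; on the short
  streaming analysis span (~3.3 s) spectral leakage outside the narrow mask
  caps even a noiseless tone near ~0.76. The 0.7 gate therefore behaves as
  a genuinely strict quality gate in streaming use.
* White-noise-only windows score well below 0.7 (median ≈ 0.26 in the
  seeded Monte-Carlo test), so the gate separates the two regimes.

The streaming engine (`rppg_session()` / `push_frame()`) buffers frame
samples, infers the frame rate from the first 30 timestamps (interval jitter
beyond 5% is a stream error — no silent resampling), masks frames whose
face-detection confidence is below 0.70, and:

* emits no estimate during the 26-s stabilization phase (deployments use
  26–30 s; configurable);
* afterwards emits one estimate per 1-s stride over the trailing 2-s
  window. The stride is a package choice — the source system fixes the
  2-s rolling window but not the hop; 1 s balances responsiveness against
  estimate correlation;
* accrues `stride_s` of *valid seconds* for every window whose estimate is
  valid and whose SNR exceeds the gate ("8 s of valid rPPG frames" is
  interpreted as seconds of valid windows — the frames-vs-seconds ambiguity
  is resolved toward seconds);
* allows the chatbot trigger only when ≥ 8 valid seconds have accrued, the
  latest window's mean face confidence exceeds 0.70, and at least one
  affect label with > 50% confidence has been observed.

**Window geometry.** A spectral estimate needs at least two cardiac cycles
at the band's lower edge (3.33 s at 0.6 Hz), which a 2-s window cannot
provide. The engine therefore extracts the pulse over an analysis span of
$\max(\text{window}, 2/f_{low})$ seconds ending at the window boundary,
while SpO2, the validity mask and the reported window span use the strict
2-s window. The zero-phase filter additionally needs a lookback one filter
length deeper; the 26-s stabilization phase comfortably covers both.

**Gaps.** Samples masked invalid (lost face, low confidence) are linearly
interpolated *only* so the filter keeps running across them; any window
whose analysis span touches an invalid sample is itself marked invalid and
accrues nothing. After a gap, validity resumes once the analysis span has
cleared it.

**Streaming ≡ batch.** `run_batch()` drives a recorded trace through the
identical per-sample streaming code, so offline and live runs produce
bit-identical estimate sequences by construction; the test suite still
performs the dual run and compares.

# The FIR filter

Windowed-sinc (Hamming) linear-phase design, built as the difference of two
unit-DC lowpass kernels so the DC gain is *exactly* zero. Default order:
the next even integer ≥ $3 f_s / f_{low}$ (151 taps at 30 Hz), capped at
10 s of taps. Measured at 30 Hz: 0.2 Hz drift attenuated ≈ 51 dB, DC
numerically annihilated, 1.5 Hz passband gain 1.001. Batch application is
zero-phase (centred symmetric kernel on a reflect-padded, mean-removed
series); streaming application is causal with a group delay of order/2
samples, attached to the output for timestamp compensation.

# The synthetic scene

The generator emulates a webcam watching a seated subject: channel $c$ is
$\text{base}_c + \text{ac}_c \sin(2\pi f_{hr} t) + \text{drift} +
\mathcal{N}(0, \sigma^2)$, with an optional two-harmonic waveform for SNR
tests. Default parameters and why:

| parameter | default | rationale |
|---|---|---|
| `fs` | 30 Hz | consumer webcam frame rate |
| `hr_hz` | 1.3 Hz (78 bpm) | resting adult heart rate |
| `base_rgb` | (150, 110, 90) | skin tone on the 0–255 scale |
| `ac_rgb` | (1.73, 3.2, 1.0) | 1–3% AC/DC; see below |
| `noise_sd` | 0.3 | sub-amplitude sensor noise (free choice; the source setting states only 300–350 lux office light) |
| `drift_amp`, `drift_hz` | 2, 0.1 Hz | slow illumination drift the bandpass must remove |
| `frame_shape` | 16×16 | a downsampled ROI patch; spatial averaging is resolution-independent |

Two structural points:

* **Green dominance is load-bearing.** With a single shared waveform, the
  chrominance axes carry the pulse with amplitudes $3a_R - 2a_G$ and
  $1.5a_R + a_G - 1.5a_B$. If these have the same sign the $\alpha$ rule
  cancels the scene's own pulse identically — the generator would build a
  signal its own pipeline provably annihilates. Making green the strongest
  channel (physiologically correct: haemoglobin absorption peaks in green)
  puts the pulse on the two axes with opposite polarity, which the
  combination then reinforces.
* **SpO2 encoding.** Since all channels share one waveform, the implied
  ratio-of-ratios is $(a_R/\text{base}_R)/(a_B/\text{base}_B)$;
  `scene_config_for_spo2()` inverts the calibration to hit a target
  saturation. The red/blue defaults encode 98%.

What the generator does **not** emulate: head motion, non-uniform skin,
specular highlights, sensor rolling shutter, compression artefacts, or
realistic noise spectra. A green test therefore establishes algorithmic
correctness on the stated signal model, not field robustness.

Frames are written as plain-text ASCII PPM (P3) with a JSON ROI sidecar:
portable, dependency-free, but integer-quantised — round trips are exact
only at integer intensities, and the frame-pipeline tests assert agreement
within quantisation.

# Affect geometry, prompts, agreement

* `alignment_angle()` is the printed cosine-rule angle at the reference
  vertex, in degrees; note the source text describes it as the eye-baseline
  roll angle, which is a different quantity — the formula as printed is
  implemented, and landmarks are caller-supplied.
* Prototype classification (cosine / Euclidean) operates on caller-supplied
  embeddings; the CNN that produces them is a pluggable contract (a
  deterministic toy embedder ships for tests). Ties: first prototype in
  declared order.
* The age vote is the mode of the last 30 labels, with the most recent
  occurrence breaking ties; fewer than 30 labels is `pending`, not an error.
* The English chatbot template is reproduced verbatim with the four slots
  interpolated in fixed order; the Korean template is a documented
  translation, not claimed verbatim.
* Agreement: MAE, Pearson r (flagged undefined on constant input),
  Bland–Altman bias with 95% limits `bias ± 1.96 · sd` using the sample
  (n−1) standard deviation; differences are estimate − reference so a
  negative bias means the camera under-reads.

# Numerical conventions

* Population (÷N) standard deviation throughout the signal path (α, AC);
  sample (÷(n−1)) only in the agreement statistics.
* ROI boxes are 0-based, half-open, clipped against the frame; an empty
  intersection is a signal-quality condition, not a crash.
* Seconds are the only time unit; windows are half-open `[start, end)`;
  seeds are recorded in every output for reproducibility.
* The spectral peak is clamped into the search band after interpolation;
  an all-constant pulse yields an invalid estimate with reason
  `flat_spectrum` rather than an arbitrary frequency.

# Known limitations

* No neural motion-transfer model, face detector, or CNN embedder ships
  with the package; these enter via the ROI/landmark/embedding contracts.
* Video containers are not decoded; the frame-source contract accepts
  directories of numbered PPM frames (decode externally first).
* The single-subject agreement figures reported for the original mirror
  hardware derive from unpublished sensor recordings and are not
  reproducible at desk scale; the agreement module reproduces the
  *machinery*, and all quantitative claims here are about synthetic scenes.
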