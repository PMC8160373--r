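---
title: "Methods: contact-free autonomic screening from facial video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact-free autonomic screening from facial video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rppgscreen)
```

## The problem

Task-evoked autonomic responses distinguish people with major depressive
disorder (MDD) from healthy controls more reliably than resting heart-rate
variability (HRV) alone: healthy subjects show a marked parasympathetic
withdrawal — a drop in high-frequency (HF, 0.15–0.4 Hz) HRV power — during
a demanding mental task, while depressed subjects show a blunted, flat HF
response. `rppgscreen` implements a contact-free measurement of this
phenotype: the cardiac pulse is read off a webcam video of the face
(remote photoplethysmography, rPPG), converted to interbeat intervals
(IBIs), summarized as LF/HF spectral powers per protocol period, and
classified with a logistic screening model.

The measurement protocol has three contiguous periods, half-open in time:
pre-task rest (Pre-R, 140 s), a random-number-generation mental task
(MT, 100 s), and post-task rest (Post-R, 120 s) — 360 s in total
(`protocol_config()`).

## Signal path and its assumptions

1. **Face → green trace** (`frames_to_trace()`). A face detector provides a
   bounding box; a translation tracker follows it; three landmarks — left
   cheek (A), right cheek (B) and a chin-top/philtrum point (C) — define a
   rectangle over the facial-artery territory, inset 5% per side, and the
   arithmetic mean of the green channel over that ROI is taken per frame.
   Landmark tracks are smoothed with a centered 0.3 s moving average
   (9 taps at 30 frames/s; even tap counts are rounded up to stay
   centered). Detection and landmarks are pluggable backends: the bundled
   backend operates on synthetic rendered frames; production detectors
   (Haar cascades, neural landmark models) satisfy the same contract but
   are not shipped — no detector is trained here. Frames with no detection
   are linearly interpolated if the gap is at most 1 s; longer gaps reject
   the session, because interpolation over multiple cardiac cycles
   fabricates spectral power. We use the all-pixel ROI mean (no skin-pixel
   masking): on the cheeks-and-nose rectangle nearly all pixels are skin,
   and the mean is what the downstream filter assumes.

2. **Green trace → blood-volume pulse** (`extract_bvp()`). The green
   channel is sign-inverted (hemoglobin absorbs green: systole is a
   luminance dip), mean-removed, decomposed by a maximal-overlap discrete
   wavelet transform multiresolution analysis (MODWT-MRA, symlet-4,
   level 4, reflection boundary), and the components whose octave bands
   intersect the 0.6–2.0 Hz cardiac band (at 30 Hz: D3, D4 and the smooth)
   are summed and band-pass filtered at 0.6–2.0 Hz.

   Two numerical choices matter here. First, the MRA is computed in the
   frequency domain using the identity that each MODWT-MRA component is
   zero-phase filtering by a squared-magnitude quadrature-mirror response;
   this is exact (components sum to the input at machine precision), fast,
   and free of phase distortion that would bias peak times. Second, the
   band-pass is applied as the *magnitude* response of a 4th-order
   Butterworth band-pass, again zero-phase in the frequency domain on the
   reflection-padded series. A conventional forward–backward (`filtfilt`)
   pass of a 4th-order design would square the response and attenuate
   1.9 Hz by about 4.5 dB, violating the composite pass-band contract we
   hold ourselves to (within −3 dB across 0.7–1.9 Hz, ≥ 20 dB down at
   0.2 Hz and 4 Hz); the zero-phase magnitude implementation meets it with
   margin (measured: −1.1 dB at 0.7 Hz, −2.4 dB at 1.9 Hz, −25 dB at
   0.2 and 4 Hz).

3. **Pulse → beats** (`detect_pulse_peaks()`). An adaptive-threshold
   detector: a 0.75 s moving-average baseline raised by an elevation
   chosen from {5, …, 50}% of the signal range; each supra-threshold
   region yields one peak; the elevation minimizing the IBI standard
   deviation wins, subject to a mean heart rate in 40–180 beats/min, an
   IBI coefficient of variation ≤ 0.35, and corroboration — at least two
   elevations must imply the same mean heart rate within 5%. The last two
   gates are what reject narrowband noise: band-passed sensor noise
   oscillates near 1.3 Hz and would otherwise masquerade as a plausible
   heart rate, but its "intervals" are far more dispersed than any
   physiological rhythm and its apparent rate drifts strongly with the
   threshold, whereas a genuine pulse yields the same beat set across
   elevations.
   Peaks are refined to sub-frame precision by parabolic interpolation
   over three samples: at 30 frames/s the raw grid quantizes IBIs to 33 ms
   steps, which alone would cap camera-vs-ECG agreement well below what
   the hardware can deliver.

4. **Beats → cleaned IBIs** (`clean_ibi()`). Intervals outside 300–2000 ms
   are rejected outright; then any interval deviating more than 30% from
   the median of its 11 nearest accepted neighbours is rejected,
   *iterated to a fixed point* so the operation is idempotent. Rejected
   intervals are excluded, never interpolated. More than 20% rejections
   warns; more than 50% rejects the session. These thresholds are common
   HRV artifact practice and are exposed as arguments.

5. **IBIs → features** (`compute_hrv_periods()`, `compute_features()`).
   Intervals are assigned to the period containing their *ending* beat
   (half-open boundaries, so an interval ending exactly at 140 s belongs
   to MT). Per period, accepted (time, IBI) pairs are cubic-spline
   resampled to a uniform 4 Hz grid, mean-removed, and analysed with a
   Welch estimator (Hann window, segments of `min(n, 240)` samples = up to
   60 s, 50% overlap), giving density in ms²/Hz; LF (0.04–0.15 Hz) and HF
   (0.15–0.4 Hz) powers are trapezoidal band integrals with edges
   interpolated, so adjacent bands tile additively. Welch on a resampled
   series was chosen over Lomb–Scargle because it matches the toolkit
   convention the screening coefficients assume (powers in raw ms²) and is
   well conditioned for 100–140 s segments; the estimator sits behind
   `compute_psd()` so it can be swapped. The candidate set has exactly 15
   features: {LF, HF, LF/HF} × {Pre-R, MT, Post-R} plus six percent
   changes `100 (X_B − X_A) / X_A` for Pre-R⇒MT and MT⇒Post-R — percent,
   not absolute, changes, with the earlier period as denominator; a zero
   denominator is an explicit error rather than an Inf feature.

6. **Features → screening** (`published_model()`, `score()`). The shipped
   screening equation is the fixed four-variable logistic model
   `logit = −1.2895 + 0.0013·HF_MT + 0.0051·%ΔLF(Pre-R⇒MT) −
   0.0001·%ΔHF(Pre-R⇒MT) − 0.0004·%ΔHF(MT⇒Post-R)`, with HF_MT in ms²
   (inferred from the coefficient magnitude) and the decision rule
   `logit ≥ 0 ⇒ suspected MDD` taken literally, equality included.
   `fit_lra()` refits models by unpenalized maximum likelihood (IRLS via
   `glm`), with complete separation raised as an explicit error.

## Feature selection and evaluation

`mrmr_rank()` implements greedy minimum-redundancy maximum-relevance with
the *quotient* (MIQ) scheme: mutual information after equal-frequency
quartile discretization, first pick by relevance, later picks by
relevance / (mean redundancy + 1e−12), ties broken by higher relevance
then input order — fully deterministic. The quotient scheme mirrors the
common MATLAB feature-selection behaviour; the difference scheme would be
a one-line change. `select_model_size()` scans k = 1…max_k on the ranking
and picks the smallest k maximizing cross-validated accuracy, defined as
the mean of sensitivity, specificity, PPV and NPV.

`evaluate_cv()` uses stratified folds with a fixed seed and pools
out-of-fold logits into a *single* confusion matrix at cutoff 0 (pooled,
not per-fold averaged, matching a single reported confusion matrix).
`roc_analysis()` computes AUC as the rank (Mann–Whitney) statistic with
ties counted 1/2 — identical to the trapezoidal ROC area — and the
Youden-optimal cutoff, lowest threshold on ties.

`agreement_stats()` reports Pearson r, RMSE, bias and Bland–Altman limits
`bias ± 1.96 s` with `s` the n−1 sample standard deviation of the
camera-minus-reference differences. ECG R-peaks come from a
Pan–Tompkins-style detector (5–15 Hz band-pass, squared derivative,
150 ms integration, running-maximum adaptive threshold — hence amplitude
scale invariance — 250 ms refractory period, parabolic refinement). Beats
are paired by nearest-neighbour matching within 500 ms, wide enough to
cover the ~120 ms pulse transit time plus jitter; a constant transit time
cancels when intervals are differenced.

## The synthetic-session simulator

No clinical recordings ship with the package; the simulator defines the
study conditions every test and the cohort evaluation run under.

* **Beats.** Integral pulse frequency modulation (IPFM): a beat is emitted
  each time the integral of `r(t) = (HR/60)(1 + m(t))` crosses an integer,
  with `m(t)` the sum of an LF sinusoid (0.10 Hz), an HF sinusoid
  (0.25 Hz) with period-specific amplitudes, and band-limited Gaussian
  noise (white noise smoothed over 1 s, sd 0.01 — calibrated so the
  healthy-vs-flat HF contrast the phenotypes encode is realized in at
  least 9 of 10 seeds, the design contract of the simulator). IPFM is the
  standard
  HRV-simulation mechanism whose spectral content is analytically
  controllable: with zero modulation it yields exactly constant IBIs of
  60000/HR ms, and a modulation of amplitude *a* produces an IBI sinusoid
  of amplitude ≈ a·IBI₀, so band powers are checkable in closed form.
* **Phenotypes.** Healthy HF amplitudes (0.08, 0.02, 0.08) across
  (Pre-R, MT, Post-R) — strong task suppression; depressed (0.05, 0.05,
  0.05) — flat; LF (0.05, 0.07, 0.05) for both. These defaults reproduce
  the qualitative group contrast while keeping |m| < 1 (violations are a
  hard error, since the rate would otherwise go non-positive).
* **ECG and camera trace.** A 100 Hz reference ECG places a 20 ms Gaussian
  QRS at each beat (morphology is irrelevant downstream; only R-times are
  consumed). The 30 Hz green channel subtracts a smooth systolic bump
  (Gaussian, 70 ms sd) delayed by a 120 ms pulse transit time, on a
  baseline with 0.05 Hz drift and white sensor noise (defaults: pulse
  2 tones, drift 2 tones, noise 0.2 tones). Red/blue carry baseline and
  noise only.
* **Frames.** `render_frames()` paints the trace into a face ellipse on
  320×180 frames (desk-scale stand-in for 1920×1080; fps stays 30), tones
  quantized by rounding, with optional sinusoidal head motion and blank
  dropout frames — a fully known geometry for the ROI chain.
* **Cohorts.** SDS scores: healthy ~ N(33, 5²) truncated below 48,
  depressed ~ N(53, 5²) truncated at or above 48, rounded — group means
  land near the clinical demographics (~32–34 vs ~53). Profiles get
  per-subject lognormal jitter (sdlog 0.45) on every modulation amplitude
  and N(70, 7²) mean heart rate clamped to [50, 100]. The jitter scale was
  chosen once, before evaluation, as a realistic between-subject
  heterogeneity: it makes the groups overlap (some healthy
  non-suppressors, some depressed with incidental HF drops) instead of
  being linearly separable, which is both what clinical cohorts look like
  and what keeps maximum-likelihood logistic fits well defined.

What the simulator does *not* emulate: skin optics (melanin, specular
reflection), respiration-driven amplitude modulation of the pulse
waveform, arrhythmias, illumination changes, and large non-rigid head
motion. Passing tests therefore demonstrate that the pipeline correctly
recovers autonomic structure from an idealized rPPG signal with sensor
noise, drift and rigid motion — not that it survives every real-world
artifact.

## Problem sizes and determinism

All randomness flows through explicit integer seeds (IPFM grid noise,
trace noise, cohort draws, fold assignment); every generator is
bitwise-reproducible. The test suite runs sessions of the full 360 s
protocol at 30 frames/s (10 800 frames at trace level), cohorts of
26 + 27 subjects, and a 20-seed replication of the cohort evaluation;
frame-level (rendered-video) tests use shorter streams and 160×120
frames, which exercise the identical code path at desk scale. The
cohort evaluation scans model sizes up to k = 6, keeping roughly ten
subjects per explanatory variable at the 53-subject design size.

## Known limitations

* The screening coefficients are shipped as published; the clinical
  recordings behind them are not available, so the cohort evaluation here
  is a simulator-calibrated analogue of the clinical operating point, not
  a reproduction.
* The HF_MT unit (ms²) is inferred from coefficient magnitudes and
  documented as such.
* The bundled face backend is synthetic-only; plugging a production
  detector is the integration point for real video.
* Printed Bland–Altman limits in the source clinical report are narrower
  than bias ± 1.96 s for the stated s; the standard definition is
  implemented here.
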