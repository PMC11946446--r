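---
title: "Methods: the SSVEP-gated EOG trajectory cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the SSVEP-gated EOG trajectory cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it implements: the
two-stage classification cascade, the synthetic cohort that stands in for
the unavailable recordings, the numerical choices behind the spectral
estimator, and what the passing test suite does and does not establish.

## The system being modelled

A user watches a screen on which a white ball moves along one of four
trajectories, completing one cycle per second: up–down (vertical gaze
swing of ±8.1°), right–left (horizontal ±14.2°), right-cross (both axes in
phase), and left-cross (horizontal axis inverted). The gaze angles derive
from the setup geometry — a 61 × 34 cm screen viewed at 120 cm subtends
2·atan(30.5/120) ≈ 28.5° horizontally and ≈ 16.1° vertically
(`gaze_angles()`). Eye rotation moves the corneoretinal dipole (cornea
positive, retina negative), leaving EOG artifacts in the frontal EEG
channels; those artifacts are the classification signal, not noise to be
removed.

A 7 Hz LED above the screen is the safety valve: it evokes an SSVEP while
the user is looking at the screen. The decoder therefore runs as a
cascade. **Stage 1** decides illuminated vs non-illuminated from the
normalized trapezoidal band-power ratio

z′ = trapz(PSD, 6–8 Hz) / trapz(PSD, 1–10 Hz)

of each frontal channel (AF3, F7, F8, AF4), computed on a 1–15 Hz
causally band-passed segment. **Stage 2** runs only on segments the gate
passed, classifying the four trajectories from a spectral feature bank on
the 1–45 Hz zero-phase-filtered signal. Segments the gate rejects produce
no output at all — `predict()` returns `NA` trajectories for them.

On z′: because the 6–8 Hz band is contained in 1–10 Hz, z′ ≤ 1 for any
non-negative spectrum (a property test asserts this on random spectra).
The absolute level of z′ is irrelevant — the classifier learns the
illuminated/non-illuminated boundary from the four per-channel ratios —
but the containment bound makes descriptions of the ratio exceeding 1
impossible under this definition; we implement the ratio literally and let
the classifier do the thresholding. The two z′ bands are treated as closed
integration intervals ([6, 8] and [1, 10]), so on a grid aligned with the
band edges a flat spectrum gives exactly the bandwidth ratio 2/9; the
five-band feature bank below instead uses half-open bins `[lo, hi)` (gamma
closing at 45 Hz) so the bands tile the axis without double counting.

## Spectral features

Each 3 s segment (768 samples at 256 Hz) is transformed by a Welch PSD
with a Hamming window of L = 637 samples and overlap 636 — i.e. hop 1,
K = 132 averaged modified periodograms, frequency resolution
256/637 ≈ 0.402 Hz, no zero padding (`welch_config()`). Two numerical
choices matter here:

* **Window variant.** We use the DFT-even Hamming window
  w[n] = 0.54 − 0.46 cos(2πn/L). Its Fourier transform has exactly three
  nonzero coefficients, which lets the estimator run as an exact sliding
  DFT: a one-sample-shift recursion over window positions with the window
  applied in the frequency domain (three-tap convolution). The hot loop is
  a small C++ kernel. This is algebraically identical to computing all 132
  windowed periodograms explicitly — the test suite checks agreement with
  a direct `mvfft`-based computation to a relative 1e-10 — but roughly an
  order of magnitude cheaper at hop 1. The symmetric Hamming variant
  (denominator L−1) differs negligibly at L = 637.
* **Scaling.** The estimate is one-sided power per Hz. With a single
  full-length rectangular window the Δf-weighted total equals the signal's
  mean square exactly (Parseval; asserted to machine precision). Note that
  with hop-1 overlap the 132 windows are nearly identical, so Welch
  averaging barely reduces periodogram variance — whiteness-of-spectrum
  checks in the tests therefore use non-overlapping windows, where the
  averaging premise actually holds.

From each channel's PSD, five bands (delta 0–4, theta 4–8, alpha 8–13,
beta 13–30, gamma 30–45 Hz) × eight statistics give 40 features per
channel, 160 over the four active channels, indexed channel-major:
`id = 40·(channel−1) + 8·(band−1) + statistic`, with statistics ordered
kurtosis, mean, skewness, trapz, entropy, variance, mobility, complexity
(`feature_id_map()`). Conventions for quantities the bank leaves open:

* *entropy* is the Shannon entropy (natural log) of the band's PSD values
  normalized to a probability vector — scale-invariant by construction;
* *kurtosis* is excess kurtosis, *skewness* the moment estimator
  (e1071 defaults);
* *mobility* and *complexity* are the Hjorth difference-quotient
  parameters applied to the band's PSD value sequence (the feature bank is
  extracted per frequency band from PSD output; a time-domain variant
  would require band-filtering the signal again and is not what the
  extraction order implies);
* degenerate slices follow fixed conventions: zero-variance slices have
  skewness = kurtosis = 0, an all-zero slice has entropy 0, and
  zero-variance z-score input returns zeros with a warning rather than
  aborting a batch.

Doubling the signal amplitude quadruples every band's trapezoidal power
and leaves skewness, kurtosis, entropy, mobility and complexity unchanged
(property-tested), so the shape statistics carry information orthogonal to
raw amplitude.

## Preprocessing choices

Recordings are 16 s (3 s beep + 10 s task + 3 s beep); trimming leaves the
2560 × 14 task block. Segmentation produces **five** 768-sample windows
per block at equally spaced starts {0, 448, 896, 1344, 1792} — a hop of
1.75 s. Five windows with a 2 s hop (1 s overlap) would span 11 s, which a
10 s block cannot hold; the window *count* is the constraint that drives
every downstream number (5 × 40 recordings = 200 segments per condition
per subject), so the count wins and the hop follows.

Both filter paths are fifth-order Butterworth band-passes built by
`signal::butter`. The gate path (1–15 Hz) is filtered causally (single
forward pass); the trajectory path (1–45 Hz) uses zero-phase
forward–backward filtering. The zero-phase mode extends the segment by an
odd reflection of itself on both ends before `signal::filtfilt` and trims
afterwards, so start-up transients decay inside the padding; without this
the forward–backward operation is visibly asymmetric at the segment
edges. Filtering is applied per segment, not per recording, matching the
stated order of operations.

## The synthetic cohort

The study's recordings are not public, so the generator produces data with
the statistical structure the analysis assumes — it is a first-class,
tested module, and its defaults are the package's study conditions:

* **Design**: 10 subjects × 4 trajectories × 10 repetitions × 2 LED
  conditions = 800 recordings (flags `n_subjects`, `reps_per_class`).
* **Background**: 1/f^1.5 noise plus a 10% white floor at 20 µV RMS per
  channel — EEG-like band amplitudes with most power at low frequencies.
* **SSVEP** (LED-on only): 7 Hz sinusoid with a 25% second harmonic,
  16 µV at the occipital channels, 40% of that on the frontal channels,
  15% elsewhere, random phase per recording. SSVEP is physiologically
  occipital; the frontal weight exists so the frontal-channel gate the
  system actually uses is exercisable.
* **EOG**: the trajectory's gaze-angle series (sinusoidal pursuit at
  1 cycle/s) projected through a dipole model — horizontal angle with
  opposite signs on left (AF3, F7) vs right (AF4, F8) frontal channels,
  vertical angle common-mode on all four, 10% leakage elsewhere — at
  2.5 µV/°, convolved with a 50 ms boxcar. Sinusoidal pursuit is the
  simplest waveform with the right period and extrema; real pursuit
  contains catch-up saccades the generator does not model.
* **Heterogeneity**: per-subject multiplicative jitter (±20%, seeded) on
  the EOG gain, SSVEP amplitude, and noise amplitude, so per-subject
  evaluation is non-degenerate.
* **Beep padding** carries noise only; it is discarded by trimming.

The free amplitudes (the published description gives none) were fixed once
so that the two stages are separable but not trivially so — the
acceptance-level checks then ask the pipeline to *recover* that
separability: gate accuracy ≥ 0.95 at the default SSVEP amplitude, chance
([0.4, 0.6]) at zero amplitude, trajectory accuracy ≥ 0.85 with the
16-feature consensus set, and the four frontal channels on top of the
channel ranking. Passing these shows the pipeline detects structure the
generator put in, at realistic SNR; it does not show the generator matches
real EEG (no blinks, no electrode drift, no non-stationarity, no catch-up
saccades), and accuracies on real recordings will differ.

## Evaluation protocol

Per subject, both stages are evaluated by stratified 75/25 holdout
repeated 10 times (strata: LED condition × trajectory), averaging
accuracies over repeats. The stages are linked within each repeat: the
trajectory classifier trains on illuminated training segments and is
tested on the illuminated test segments the gate predicted correctly; the
overall system accuracy divides stage-2 correct decisions by *everything*
the gate flagged illuminated (false positives included), so it equals
stage-2 accuracy exactly when the gate is perfect and is bounded by it
otherwise. Scale-sensitive classifiers (SVM, LDA, k-NN) see features
z-scored with training-fold statistics; the random forest consumes raw
features; k-NN uses the odd k nearest floor(√n_train).

ANOVA feature ranking orders features by the one-way F statistic
(between- over within-group mean squares — the conventional completion of
the total sum-of-squares decomposition). The packaged consensus set is
fixed a priori — delta mean, delta skewness, theta trapz, theta entropy on
each of the four channels (ids 2/3/12/13, 42/43/52/53, 82/83/92/93,
122/123/132/133) — rather than re-selected per run, which avoids selection
leakage into test folds. `anova_rank()` and `top_k_curve()` are available
for adaptive selection when wanted.

ITR uses the Wolpaw/Shannon bits per selection with T = 3 s (one analysis
segment — the only T consistent with 40 bits/min at p = 1 for K = 4); the
p = 1 case is the analytic limit, not 0·log 0. Cohort-level ITR is
reported both as the mean of per-subject ITRs and as the ITR of the mean
accuracy; the two differ because ITR is nonlinear in p, and the
per-subject mean is the convention used in the tables this layout mirrors.

Channel ranking scores each montage channel alone — gate accuracy from its
single z′ plus trajectory accuracy from its 40 features, averaged — which
is deliberately symmetric between the two tasks: occipital channels win
the gate (that is where the SSVEP is strongest) but carry almost no
trajectory information, and frontal channels lead once both tasks count.

## Problem sizes and determinism

All randomness — cohort generation, holdout partitions, classifier
internals — descends from explicit integer seeds; identical configuration
and seed give bit-identical recordings and identical reports
(property-tested end to end). Unit tests run on a 2-subject × 3-repetition
cohort; the acceptance-level suite evaluates the full default cohort
(10 subjects, 800 recordings, 4000 segments) with 10 holdout repeats, a
zero-amplitude control cohort of the same size, and a 14-channel ranking
at 3 repeats — sizes chosen to exercise the study-scale design while
keeping a complete test run in minutes on one core.

## Known limitations

* The generator's EOG and SSVEP amplitudes are free parameters; only their
  qualitative regime (separable, non-trivial) is anchored.
* Stage-1 uses causal filtering and stage-2 zero-phase filtering because
  the two processing descriptions differ; both are exposed via
  `filter_spec(mode = )` if a uniform choice is preferred.
* No real-time operation, no hardware interfacing, no blink/impedance
  artifacts, and no alternative SSVEP decoders (CCA, filter banks): the
  scope is the offline cascade analysis.
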