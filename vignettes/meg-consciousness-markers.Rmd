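---
title: "LZsum and the theta-alpha ratio: complexity and arousal markers for resting-state MEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LZsum and the theta-alpha ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MEGmarkers)
```

## The problem

In mild cognitive impairment (MCI) — the prodromal stage of Alzheimer's
disease — both the *level of arousal* and the *informational complexity* of
ongoing brain activity appear to decline before overt dementia. Two
sensor-level markers computed from eyes-closed resting-state MEG capture
these dimensions:

* **LZsum** — the normalized Lempel–Ziv (LZ76) complexity of binarized
  sensor signals, a proxy for the diversity of activity patterns and hence
  the capacity for conscious processing. Lower values mean more predictable,
  compressible dynamics.
* **TAR** — the theta–alpha band-power ratio, `P(3–5 Hz) / P(8–12 Hz)`
  averaged over gradiometers. Eyes-closed wakefulness is alpha-dominant;
  drowsiness shifts power toward theta, so a higher TAR means lower arousal.

This package implements the full analysis path for these two markers:
synthetic cohort generation, preprocessing, per-epoch marker computation,
subject-level aggregation, and the statistical battery that compares groups
and regresses markers on cognitive scores (MMSE, 0–30 points, lower = more
impaired).

## The LZ76 statistic

A real-valued epoch is first reduced to a binary sequence. The default rule
(`binarization = "hilbert-mean"`) computes the instantaneous amplitude of
the analytic signal (Hilbert envelope) and assigns 1 where the envelope
exceeds its epoch mean; ties map to 0. The alternative
(`"signal-median"`) thresholds the raw samples at their median. Both are
invariant to positive amplitude scaling, which the tests assert
bit-for-bit — a marker that depended on sensor gain would be meaningless
across subjects.

LZ76 then counts the words of the exhaustive-history production parsing:
scanning left to right, the current phrase ends as soon as it can no longer
be copied (with overlap allowed) from the previously seen prefix; the
final, possibly uncompleted phrase counts. The compiled implementation
follows the simplified Kaspar–Schuster scan and is verified in the test
suite against a naive brute-force reference parser on *every* binary string
of length 1–12.

The word count `c` is normalized by `n / log2(n)`, the asymptotic count for
an equiprobable random binary string:

* IID coin flips at `n = 10{,}000` give values near 1 (the suite requires
  the 100-seed mean in [0.9, 1.1]);
* a periodic "01" string of the same length stays below 0.05;
* a constant signal binarizes to all zeros and scores near 0.

Per epoch, `min(25, n_channels)` gradiometers are drawn at random
(fresh draw per epoch by default, `subsetPolicy = "per-epoch"`; a fixed
per-subject draw is available for variance studies), each channel is
binarized and parsed, and the normalized values are averaged: the epoch's
LZsum. The subject's LZsum is the arithmetic mean over kept epochs. All
draws are seeded; per-subject streams are derived from one master seed by a
counter-based split, so results are bit-reproducible.

Because the binarization rule, the normalization, the epoch-to-subject
aggregation and the seeding of the 25-channel draw are conventions rather
than published facts, each is exposed in `complexityConfig()` and recorded
in the run manifest.

## The theta-alpha ratio

Per channel, power spectral densities are estimated by Welch's method:
Hann-tapered 2-s segments with 50% overlap, giving 0.5 Hz resolution — at
least five bins inside the narrow 3–5 Hz theta band within a 4-s epoch.
The estimator satisfies Parseval's identity to within 10% for broadband
inputs, and band powers are closed-interval trapezoid integrals over bin
centers. Note the theta band here is deliberately 3–5 Hz, not the
conventional 4–8 Hz; both bands are configuration fields.

TAR uses *all* channels (no subsampling) and, by default, the
ratio-of-means convention: sensor-mean theta power over sensor-mean alpha
power. The mean-of-ratios alternative is selectable
(`ratioConvention = "mean-of-ratios"`); ratio-of-means is the default
because a single alpha-silent sensor cannot then dominate the epoch.
Epochs whose mean alpha power falls below `alphaFloor` times the mean total
power are flagged invalid rather than producing an unbounded ratio. TAR is
exactly invariant to global amplitude scaling.

## Preprocessing chain

`preprocessRecording()` reproduces a conventional post-acquisition chain:

1. **Resampling** to 250 Hz by anti-aliased polyphase decimation
   (`signal::resample`); upsampling is refused, output length is
   `floor(n · target / current)`.
2. **Filtering**: channels are demeaned, then passed through a zero-phase
   (forward–backward) 4th-order Butterworth high-pass at 0.5 Hz and a
   zero-phase IIR band-stop at 50 Hz with quality factor 30. Zero-phase
   filtering preserves timing for epoching; reflection padding suppresses
   edge transients. Re-filtering already-filtered data changes band powers
   by less than 1%.
3. **Epoching** into non-overlapping 4-s windows starting at sample 1; the
   trailing partial window is discarded. Overlap conventions are not a
   published fact; non-overlapping from the start is the simplest
   reproducible choice.
4. **Muscle-artifact rejection**: per epoch, the log of the channel-mean
   Welch band power in 55–100 Hz (above the line-noise notch, below the
   125 Hz Nyquist) is z-scored across the subject's epochs and epochs with
   z > 3 are dropped. The z-score uses the robust median/MAD form: with `k`
   epochs, a single outlier's mean/SD z-score is algebraically bounded by
   `(k − 1)/√k`, which stays below 3 for `k ≤ 11`, so a mean/SD criterion
   could never flag the one contaminated epoch of a short recording. MAD
   scoring has no such ceiling and is the standard robust choice. If more
   than `maxRejectFraction` (default 50%) of epochs are rejected, a loud
   warning is emitted.

## The synthetic cohort

Access to the multi-site clinical MEG cohort this pipeline is designed for
is application-controlled, so the package ships a generator whose defaults
emulate the published study conditions: two groups of 83 subjects, two
sites (CBU, CTB) balanced within group, ages 54–83 (truncated normal around
70.8), 56% male, MMSE 28.88 (range 25–30) in controls and 26.07 (range
17–30) in patients.

Each channel of a subject's recording is the sum of:

* an alpha sinusoid (frequency uniform in 8–12 Hz, random phase per
  channel) with amplitude `alphaGain`;
* a theta sinusoid (3–5 Hz) with amplitude `thetaGain`;
* a 1/f-shaped noise background passed through an AR(1) filter with
  coefficient `arCoefficient`, scaled to `noiseSd`;
* white sensor noise at `0.2 · noiseSd`;
* optional 0.5-s muscle bursts (band-limited 55–100 Hz noise at 10× the
  channel SD), Poisson-placed at `artifactRate` per minute.

There is deliberately no source-space forward model: the markers are
sensor-level, so per-channel independent oscillators suffice, and the AR(1)
stage provides a single scalar knob that changes temporal predictability
(and hence LZ) without moving band powers much. The generator does *not*
emulate sensor covariance, alpha peak individuality, non-stationarity, eye
movements or cardiac artifacts — passing tests therefore demonstrate
correctness of the pipeline's computations and calibration of its
statistics, not fidelity to real MEG physiology.

**Group effects and MMSE coupling.** Each subject carries a latent severity
`s ~ N(0, 1)` that scales theta gain (`exp(0.18 s)`), shifts the AR
coefficient (`+0.05 s`) and lowers MMSE (`−1.6 s` points plus unit noise,
rounded and clipped to the group range). Patients additionally get theta
gain × 1.35 and AR + 0.12. Hence, by construction: patients have lower
LZsum and higher TAR, and within and across groups lower MMSE goes with
higher TAR and lower LZsum — a linear-Gaussian coupling that makes
regression-recovery tests analytic. The published study reports marker
effects only on the real recordings, not in signal units, so these effect
sizes were calibrated once so that the pipeline detects the group
difference at the study's 83-per-group size; they are a property of the
generator, not a claim about patient physiology.

**Baseline values** (`signalParams()` defaults: alpha 1.0, theta 0.9,
1/f exponent 1, AR 0.35, noise SD 0.5) were likewise fixed once so that
control subjects land at LZsum ≈ 0.46 and TAR ≈ 0.8 — the same order of
magnitude as published resting-state values (≈ 0.59 and ≈ 1.0) — while
keeping a strong eyes-closed alpha peak over a 1/f background.

## The statistical battery

`runBattery()` reproduces the analysis structure: descriptives; a Welch
(unequal-variance, Satterthwaite df) t test on LZsum; Shapiro–Wilk
normality checks at α = 0.05 on both markers (TAR is typically right-skewed
— it is a ratio — which is what motivates the additional rank test); a
Wilcoxon rank-sum test on TAR; and the OLS set `lzsum ~ group + age`,
`lzsum ~ group + site`, `lzsum ~ group + sex`, `lzsum ~ group + tar`,
`tar ~ group + age`, `tar ~ group + site`, plus `marker ~ mmse` on all
subjects and on patients alone. Unadjusted group models are recorded
alongside for audit.

Conventions, all documented in the output: W is the rank sum of the
*control* sample (midranks for ties; exact enumeration when `n ≤ 20` and
tie-free, else the tie-corrected normal approximation); dummy coding uses
control / first-alphabetical sex / first-alphabetical site as reference
levels; missing markers are handled by complete-case analysis with counts
logged; verdicts are two-sided at α = 0.05 with no multiplicity correction
(matching the emulated report), though a Benjamini–Hochberg column is
emitted for transparency.

All three test statistics are verified against independent closed-form or
enumeration oracles to 1e-10, and the battery's calibration is checked by
simulation: on null cohorts (no group effect, 30 per group, 200 seeds) the
group tests must reject in 2–9% of runs at nominal 5%; on effect cohorts at
83 per group (100 seeds) the group directions and the MMSE coefficient
signs must reproduce in ≥ 90% of runs and the LZsum t test must reject in
≥ 80%.

## Problem sizes used by the checks

Simulation-based checks run the full pipeline per subject, so the suite
uses reduced recordings — 4 channels and 8 s (two 4-s epochs) per subject
for the repeated-cohort calibration runs, with the LZ subset size lowered
to the available channel count — while keeping subject counts at their
stated values (30 or 83 per group). The acceptance script uses 16 channels
and 32 s per subject at the full 166-subject cohort size. Marker variance
shrinks as channels × epochs grow, so calibration results at reduced sensor
counts are conservative for the full-scale configuration.

## Worked example

```{r example, eval = FALSE}
library(MEGmarkers)

spec <- cohortSpec(nPerGroup = 10, nChannels = 8, duration = 16, seed = 42)
cohort <- generateCohort(spec, keepRecordings = FALSE)
markers <- cohortMarkers(
  cohort, complexityCfg = complexityConfig(nSubsampleChannels = 8, seed = 42))
report <- runBattery(markers$subjects)
report
```

## Reproducibility and degenerate inputs

* One master seed drives everything: `runConfig(masterSeed = s)` splits it
  into the cohort stream and the channel-subset stream with a counter-based
  derivation; two runs with the same seed produce byte-identical output
  trees (asserted in the tests).
* Constant channels binarize to all zeros with a warning; subjects with no
  kept epochs, or no epoch with valid alpha power, yield `NA` markers, are
  excluded by complete-case analysis, and are logged.
* Ties at binarization thresholds map to 0 — arbitrary but fixed.
* Integer-ratio resampling takes the exact polyphase path; the
  float32 on-disk container quantizes once and round-trips bit-identically
  thereafter.

## Known limitations

* Sensor-space only: no source modelling, no magnetometers, no realistic
  channel covariance; the 25-channel subsample therefore behaves like an
  IID draw, which understates the variance reduction real (spatially
  correlated) sensors would give.
* The artifact detector targets broadband high-frequency bursts; slow
  drifts, eye blinks and cardiac artifacts are assumed removed upstream.
* The MMSE coupling is linear-Gaussian with rounding — adequate for
  recovery tests, not a cognitive model.
* FIF ingestion is not provided; the documented binary + JSON container is
  the interchange format, and external recordings must be converted to it.
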