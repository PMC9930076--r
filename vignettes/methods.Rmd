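---
title: "Methods: kinematic comparison and group statistics for upper-limb prosthesis studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinematic comparison and group statistics for upper-limb prosthesis studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ulpkin)
```

## The analysis problem

Cross-over studies of myoelectric hand prostheses compare a multi-grip hand
(MHP) against a standard single-grip hand (SHP) along two arms:

* a **within-group arm**, in which the same users perform standardized
  tasks — the refined clothespin relocation test (RCRT, upward and downward,
  5 repetitions each) and a bimanual tray task (10 repetitions) — once with
  each hand while 7 joint angles (trunk flexion/extension, trunk axial
  bending, trunk lateral bending, shoulder flexion/extension, shoulder
  internal/external rotation, shoulder abduction/adduction, elbow
  flexion/extension) are recorded at 60 Hz with an inertial motion-capture
  suit; and
* a **between-group arm**, in which MHP and SHP user cohorts answer a
  battery of patient-reported instruments (OPUS-UEFS, TAPES-upper, RAND-36,
  EQ-5D-5L, D-QUEST, PUF-ULP, visual-analogue items).

`ulpkin` implements both arms as a reproducible pipeline, together with a
synthetic-data generator that emulates the study conditions so that every
stage can be tested against known ground truth.

## Waveform analysis

### Segmentation

Raw recordings include quiescent time before and after the movement. The
original protocol segmented trials visually; this package replaces that
with a deterministic velocity rule. A trial starts at the first sample
where the angular velocity of either shoulder detection channel
(flexion/extension or abduction/adduction) exceeds a threshold (default
5°/s) for a sustained period (default 100 ms) — conventional values in
movement science. Two implementation details make the rule robust on real,
noisy angle data:

* velocities are computed on a zero-phase low-pass copy of the angles
  (Butterworth order 2, default cutoff 1.5 Hz, reflection-free constant
  padding), so sensor-level noise does not differentiate into spurious
  velocity; and
* a candidate onset is only accepted if velocity reaches 3x the threshold
  within 0.5 s (a genuine reach peaks an order of magnitude above
  threshold); otherwise the earliest sustained crossing is used. Slow noise
  ramps that merely cross the threshold are thereby rejected.

The end of the trial is the first sample after the last sustained
suprathreshold movement at which both shoulder channels have returned to
within 2° of their pre-start baseline, defined as the mean over the first
0.5 s of the recording (the protocol does not define "starting value"; a
short pre-movement average is the stable choice). When the angles never
return — the participant ends in a different posture — the stopwatch
completion time replaces the detected end, and the substitution is flagged
in the QC output.

### Artifact screening

Euler-angle traces near gimbal lock show unaccountable single-sample
peaks; such trials are excluded. The screen excludes a trial when any
joint jumps by more than 30° between consecutive samples (1800°/s at
60 Hz, far beyond voluntary movement) or leaves ±180°. Both thresholds are
configurable; every violation is enumerated with joint, sample index, and
magnitude so exclusions are auditable.

### Time-normalization, RoM, KV, KR

Each segmented trial is resampled to exactly 500 points at equally spaced
normalized times in [0, 1] by cubic-spline interpolation, with both segment
endpoints included. Range of motion (RoM) is deliberately computed on the
**raw** segment (max minus min per joint, per trial) — normalization must
not alter amplitudes — while the two waveform-similarity measures use the
normalized trials:

* **Kinematic variability (KV)**: the across-trial sample standard
  deviation (denominator M − 1, appropriate for the 5–10 trials of the
  protocol) at each normalized time point, averaged over the 500 points.
  Degrees; 0 for identical trials.
* **Kinematic repeatability (KR)**: the adjusted coefficient of multiple
  determination. With $Y_{mt}$ the angle of trial $m$ of $M$ at time $t$ of
  $T$, $\bar Y_t$ the across-trial mean and $\bar Y$ the grand mean,

  $$KR = 1 - \frac{\sum_{m,t}(Y_{mt} - \bar Y_t)^2 \,/\, (T(M-1))}
                 {\sum_{m,t}(Y_{mt} - \bar Y)^2 \,/\, (TM-1)}.$$

  KR is 1 exactly when within-time deviations vanish, near 0 when trials
  share no waveform, and can be negative in small samples; negative values
  are reported unclamped (with a warning) rather than truncated, so that
  downstream averages are not biased. A constant waveform has zero total
  variance and yields `NA` ("degenerate waveform") rather than a number.

```{r toy}
toy <- function(v) matrix(rep(v, 7), ncol = 7,
                          dimnames = list(NULL, jointNames()))
trials <- list(toy(c(0, 10, 20)), toy(c(0, 12, 20)))
round(computeKv(trials)[1], 4)   # mean of per-time SDs (0, sqrt 2, 0)
round(computeKr(trials)[1], 4)
```

### Coordination-pattern classification

Some users switch shoulder strategy between hands: external rotation with
abduction using one hand, internal rotation with adduction using the
other. The package classifies each participant from the clothespin trials
by the signed mean excursion (time-averaged deviation from the pre-start
baseline) of shoulder rotation and of abduction/adduction, per condition.
The label is `JC_DIFF` only when **both** excursion signs flip between
conditions; excursions within ±1° of zero are treated as indeterminate and
resolve to `JC_SIM`, the conservative choice for a rule replacing a
qualitative judgement. The underlying excursions are retained for audit.

## The statistics battery

All tests follow the conventions of mainstream commercial statistics
software so that results are comparable with the published literature, at
a significance level of α = 0.01 (chosen against multiple testing):

* **Routing**: Shapiro–Wilk at α = 0.05 decides parametric vs
  nonparametric per measure (a Kolmogorov–Smirnov test is reported
  alongside for audit only); Levene's test with center = mean routes
  pooled vs Welch t.
* **Mann–Whitney**: U is reported with the smaller-value convention; z
  uses the normal approximation with tie-corrected variance and **no**
  continuity correction, and the effect size is $r = z/\sqrt N$. These
  conventions jointly reproduce published U/z/r triples; with them the
  normal-approximation p sits within about 0.05 of the exact enumeration p
  at group sizes of 7–8.
* **Chi-squared**: Pearson without Yates correction by default (a `yates`
  option exists), with Cramér's V and df-specific magnitude bands
  (1 df: 0.1/0.3/0.5; 3 df: 0.06/0.17/0.29).
* **Repeated-measures ANOVA**: the 2 (hand) x 7 (joint) fully-within
  design is decomposed completely, each effect tested against its own
  subject-interaction error term. Mauchly's test (on orthonormal-contrast
  covariances) gates the Greenhouse–Geisser correction at α = 0.05; when
  too few subjects make Mauchly's W inestimable (fewer subjects than
  factor levels), the correction is applied unconditionally, the
  conservative option. The effect size is the generalized eta squared for
  fully-within designs,
  $\eta_G^2 = SS_\text{effect} / (SS_\text{effect} + SS_\text{subject} + \sum SS_\text{error})$.
* **Effect-size labels**: r bands 0.1/0.3/0.5, $\eta_G^2$ bands
  0.02/0.13/0.26; published threshold sentences use strict inequalities
  that leave boundary values undefined, so boundaries are assigned to the
  **higher** category, documented here as the package's convention.
* **Rounding**: presentation tables round statistics and effect sizes to
  1 decimal and p to 2 decimals, mirroring published tables; the
  full-precision twin is always retained.

Validation strategy: the between-group statistics are checked against
published summary tables (t from group means/SDs/sizes, χ²/V from printed
2x2 counts, r from printed t/df and z/N), and the RM-ANOVA against the
error-stratum decomposition of `stats::aov`, exact-enumeration rank tests,
and the algebraic identity $F_\text{hand} = t_\text{paired}^2$.

## Instrument scoring

Scores follow each instrument's documented structure: OPUS-UEFS as a
19-item sum (0–57), TAPES-upper as five subscale sums (9–45, 3–15, 4–20,
5–25, 2–10), RAND-36 by item recoding then min–max transform to 0–100 per
subscale, D-QUEST as means of device/service/all items (1–5), EQ-5D-5L by
tariff valuation of the five-level profile, and PUF-ULP as the sum of
estimated answer-level weights plus 12 (range 0–12.1 under the study's
weight table, whose worst/best level sums are −12.0 and 0.1; the two worst
levels of the user-friendliness and reliability items share one weight).
Two principles apply throughout:

* **No imputation.** Missing items raise an explicit error naming them;
  the study design (phone follow-up of incomplete questionnaires) implies
  complete data, so no imputation rule exists to copy.
* **External tables are pluggable, never invented.** National EQ-5D-5L
  tariffs and the PUF-ULP weight estimates are licensed/unpublished
  externals, supplied as CSV tables; the package ships only synthetic
  example tables (marked `_synthetic` in the filename) whose endpoint sums
  reproduce the documented score ranges. The RAND-36 recoding key ships as
  an editable CSV rather than hard-coded constants.

## The synthetic-data generator

The generator emulates the study conditions, not any particular recording:

* **Protocol**: 14 participants, both conditions, 5 + 5 + 10 trials,
  60 Hz; per-condition task durations use the study's completion-time
  summaries (e.g. clothespin-up 23.8 ± 6.8 s with the MHP vs 16.3 ± 5.6 s
  with the SHP), with each participant's duration offset shared across
  conditions to reflect the paired design.
* **Waveforms**: no raw waveform statistics are published, so trials use a
  smooth reach–hold–return profile per joint (raised-cosine rise over 1 s,
  plateau, mirrored return; amplitudes 40° shoulder flexion, 20°
  abduction, −15° rotation, 30° elbow, 6–10° trunk). The quick rise makes
  velocity-threshold onset detection well-posed at 20 s task durations;
  pin-level sub-movements within a task are deliberately not modelled, so
  passing tests validate the estimators, not the biomechanics of
  clothespin transfer.
* **Noise**: trial-to-trial amplitude scatter (10%), duration scatter
  (10%), and smooth additive noise — white noise low-passed at 6 Hz
  (zero-phase Butterworth) and rescaled by the filter's stationary gain so
  its marginal SD is exactly the configured value (default 0.5°). The
  rescaling is what lets KV recover the configured SD to within a few
  percent at 50 trials. Spike artifacts (default: 5% of trials,
  single-sample, 90°) emulate gimbal-lock discontinuities.
* **Coordination modes**: `JC_DIFF` flips the signs of the shoulder
  rotation and abduction excursions in the MHP condition only.
* **Determinism**: per-participant RNG substreams are derived
  arithmetically from the master seed, so adding participants never
  perturbs earlier ones, and identical configurations yield byte-identical
  datasets.

KV-recovery checks use the generator's ground-truth segment bounds
(carried in trial metadata) rather than detected bounds: that isolates the
estimator property being tested from onset-detection jitter, which is
assessed separately against the same ground truth (detected starts land
within ±0.1 s under default noise).

## Numerical choices and problem sizes

* Cubic-spline interpolation uses the classical piecewise-cubic
  (Forsythe–Malcolm–Moler) end conditions of `stats::spline`; both segment
  endpoints are knots, so bound values are preserved exactly.
* Completion-time SD across trials and all sample SDs use denominator
  n − 1.
* Mauchly's p uses the standard chi-squared approximation on the
  log-determinant statistic; ε is clamped to its theoretical range
  [1/(k−1), 1].
* Simulation sizes in the test suite: 50 trials for noise recovery, 20
  participants for coordination recovery, and one full-protocol study
  (14 x 2 x 20 trials) for the end-to-end run — sizes at which the
  Monte-Carlo checks are decisive while the whole suite runs in well under
  a minute.

## Known limitations

* The segmentation rule is a declared, reproducible substitute for the
  original visual segmentation; agreement with human raters has not been
  assessed.
* The artifact screen catches gimbal-lock-like discontinuities, not subtler
  sensor-fusion drift.
* The generator's single reach–hold–return shape under-represents the
  multi-phasic structure of real clothespin transfers; KV/KR estimates on
  real data will sit in different absolute ranges than on synthetic data.
* Whether the original analysis used the population- or sample-SD form of
  KV is unstated in the protocol; this package uses the sample form
  (M − 1) throughout.
* EQ-5D-5L utilities and PUF-ULP totals are only as good as the supplied
  tariff/weight tables; the shipped synthetic tables exercise the code
  paths but carry no clinical meaning.
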