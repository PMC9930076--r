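# ulpkin

Kinematic and patient-reported outcome comparison for upper-limb
prosthesis studies.

## What it is for

Clinical movement scientists comparing a multi-grip myoelectric hand
prosthesis (MHP) with a standard single-grip hand (SHP) face two analysis
arms: a within-group arm, where the same users perform standardized tasks
(the refined clothespin relocation test up/down and a bimanual tray task)
with each hand while seven joint angles are recorded at 60 Hz, and a
between-group arm, where MHP and SHP user cohorts answer patient-reported
instruments (OPUS-UEFS, TAPES-upper, RAND-36, EQ-5D-5L, D-QUEST, PUF-ULP,
VAS items). `ulpkin` turns both arms into a tested, deterministic
pipeline:

* **Trial processing** — velocity-threshold segmentation with
  stopwatch-time fallback, gimbal-lock artifact screening, cubic-spline
  time-normalization to 500 steps;
* **Waveform metrics** — per-trial range of motion (raw max − min),
  kinematic variability (KV: time-averaged across-trial SD of the
  normalized waveform) and kinematic repeatability (KR: the adjusted
  coefficient of multiple determination),

  KR = 1 − [Σ (Y_mt − Ȳ_t)² / (T(M−1))] / [Σ (Y_mt − Ȳ)² / (TM−1)],

  plus classification of each participant's shoulder coordination pattern
  (`JC_SIM` / `JC_DIFF`) from the signed rotation and abduction
  excursions;
* **Group statistics** — SPSS-convention battery: Shapiro–Wilk routing,
  paired t, Levene-routed pooled/Welch t, Mann–Whitney with tie-corrected
  z (no continuity correction) and r = z/√N, Pearson chi-squared with
  Cramér's V, and the 2 (hand) × 7 (joint) fully-within repeated-measures
  ANOVA with Mauchly's test, Greenhouse–Geisser correction and
  generalized eta squared, all at α = 0.01 with magnitude labels;
* **Instrument scoring** — the six questionnaire instruments with their
  documented ranges and transforms, pluggable tariff/weight tables, and
  strict no-imputation handling of missing items;
* **Synthetic data** — a generator emulating the study protocol
  (14 participants × 2 conditions × 5 + 5 + 10 trials, amplitude/duration
  scatter, smooth 6 Hz-band additive noise, spike artifacts, coordination
  modes) with full ground truth, so every stage is testable without the
  original recordings.

## Worked example

Simulate a small cross-over study and run the within-group arm:

```r
library(ulpkin)
cfg <- syntheticConfig(n_participants = 4, seed = 7)
trials <- generateKinematicDataset(cfg)
report <- runWithinComparison(trials)
print(report)
#> Within-group comparison report: 4 participants, 0 excluded
#> Coordination labels:
#>
#> JC_SIM
#>      4
#> RCRT_up completion time: t = 16.07, df = 3, p = 0.001, r = 0.99
#> RCRT_down completion time: t = 6.15, df = 3, p = 0.009, r = 0.96
#> TRAY completion time: t = 1.22, df = 3, p = 0.310, r = 0.58
```

All four synthetic participants keep the same shoulder strategy with both
hands (`JC_SIM`, the generator's default), and the paired t tests pick up
the generator's built-in completion-time gap between the MHP and SHP
conditions on the clothespin tasks (large effect sizes r), but not on the
tray task, whose configured durations are nearly equal. `report` also
carries the full kinematic summary table (RoM/KV/KR per participant ×
condition × task × joint), per-trial QC rows and the RM-ANOVA tables.

Summary statistics published for two cohorts can be tested directly:

```r
age <- tFromSummary(48.6, 12.4, 14, 58.1, 15.7, 19, method = "pooled")
age
#> pooled_t: statistic = -1.872, df = 31, p = 0.07068
#>   effect (pearson_r) = -0.3187 [medium]
#>   not significant at alpha = 0.01
```

i.e. a 9.5-year age difference between cohorts of 14 and 19 users is a
medium-sized but non-significant effect at this sample size.

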