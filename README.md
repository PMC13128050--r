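# rampgait

Analysis pipeline for studies of lower-limb gait on level ground and ramps,
built for the question: *do age groups differ more in their sagittal joint
kinematics when walking up or down a ramp than on level ground, once walking
velocity is accounted for?* It is aimed at movement scientists who have
per-frame joint-angle and landmark time series (e.g. exported from a
markerless motion-capture workflow) and want a reproducible path from raw
trials to velocity-adjusted group comparisons.

## What it computes

**Per trial** (sampling rate 60 Hz by default):

1. Zero-lag low-pass filtering (2nd-order Butterworth applied
   forward-backward with dual-pass cutoff correction; nominal cutoff 6 Hz).
2. Coordinate-based gait events: per side, initial contact (IC) at the
   local maxima of the heel-minus-pelvis anterior-posterior displacement,
   toe-off (TO) at the minima of the toe-minus-pelvis displacement, with a
   prominence floor and a minimum inter-event interval. The walking
   direction is estimated per trial as the first principal axis of pelvis
   displacement, so on a 7° ramp all projections are along-slope.
3. Foot-strike classification (heel vs forefoot) from relative heel/toe
   height along the walkway normal at each IC.
4. Trial trimming: steps (ICs of either foot, in temporal order) 3..N-3
   are analyzed on level ground, 2..N-1 on ramps.
5. Cycle segmentation (ipsilateral IC to IC, exactly one TO inside),
   time normalization to a 101-point 0-100% gait-cycle grid, and
   cadence / velocity / step length over the kept window.

**Per participant and condition**: cycles are averaged within trial and
side, then across limbs, then across trials, giving one representative
waveform per joint; from it the twelve representative sagittal parameters
are extracted — per joint (hip, knee, ankle): range of motion over the full
cycle plus window-specific extrema (peak flexion in stance / stance phase 1
/ swing, peak extension in stance, peak dorsiflexion in stance phase 2,
peak plantarflexion within ±10% cycle of toe-off, and the ankle angle at
IC). Stance phase 1/2 split at mid-stance (toe-off percent / 2).

**Group comparisons**, two tiers:

- *Spatiotemporal* (cadence, velocity, step length): independent
  two-tailed pooled-variance t tests per condition,
  Benjamini-Hochberg FDR within each parameter, and pooled-SD Cohen's
  `d = (m_y - m_o) / s_p`, labelled negligible / small / medium / large at
  |d| cut points 0.2 / 0.5 / 0.8.
- *Joint angles* (12 parameters): one linear mixed model per parameter,
  `angle ~ velocity + group * condition + (1 | participant)` (REML,
  sum-to-zero contrasts), type-III F tests with Satterthwaite degrees of
  freedom, estimated marginal means at the grand-mean velocity,
  young-minus-older contrasts per condition gated on a significant
  group×condition interaction, BH correction pooled over all evaluated
  contrasts, and effect sizes `d = (EMM_y - EMM_o) / residual SD`.

A synthetic cohort generator (`cohort_spec()` / `generate_cohort()`)
produces two-group cohorts with known ground truth — waveform templates
calibrated so their extrema equal published group values, participant-level
random offsets, frame-level noise, and exact event times — so every stage
of the pipeline is testable without access to raw motion-capture data.

## Worked example

```r
library(rampgait)

spec   <- cohort_spec(n_young = 6, n_old = 6, trials_per_condition = 3,
                      participant_sd = 3, noise_sd = 2, seed = 42)
cohort <- generate_cohort(spec)
res    <- run_pipeline(cohort, run_config())

res$ttests[res$ttests$parameter == "velocity",
           c("condition","mean_young","mean_older","p","p_fdr","d","magnitude")]
#>   condition mean_young mean_older      p  p_fdr     d magnitude
#> 4     level       1.39       1.28 0.2528 0.2528 0.701    medium
#> 5    ascent       1.24       1.08 0.0197 0.0592 1.600     large
#> 6   descent      1.27       1.11 0.1042 0.1564 1.032     large

cc <- res$lmm$contrasts
cc[cc$parameter == "knee_MaxFlex_ST1",
   c("condition","emm_young","emm_old","estimate","p_fdr","d","magnitude")]
#>    condition emm_young emm_old estimate  p_fdr     d magnitude
#> 16    ascent      25.1    33.3    -8.20 0.0038 -23.9     large
#> 17   descent      23.1    28.3    -5.12 0.0545 -14.9     large
#> 18     level      13.5    17.1    -3.58 0.1705 -10.4     large
```

The generator is calibrated so group means equal their configured targets;
with 6 participants per group the velocity t tests recover the configured
group difference (older slower, `d = 1.6` on the ascent), and the
early-stance knee flexion contrast recovers the configured -8.4°
ascent difference (the large |d| values reflect the generator's small
residual variance, not a realistic cohort). All 447 analyzed contacts are
classified as heel strikes. `write_cohort()` / `read_cohort()` round-trip
cohorts through tab-separated trial files, and `run_pipeline(..., out_dir =)`
writes features, both statistical tiers and a provenance JSON embedding the
full configuration.

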