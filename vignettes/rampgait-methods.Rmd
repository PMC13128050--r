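---
title: "rampgait: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rampgait: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rampgait)
```

This vignette documents the scientific choices behind the package: the
processing model and its assumptions, the tunable parameters and their
defaults, what the synthetic cohort generator does and does not emulate,
and the numerical decisions a maintainer would want spelled out.

## Processing model

The pipeline assumes per-trial time series at a fixed sampling rate
(default 60 Hz) of sagittal joint angles (hip, knee, ankle; flexion and
dorsiflexion positive) for both limbs, and anterior-posterior plus vertical
positions of the heel, toe and pelvis landmarks. Stages run strictly in
order: filtering, event detection, trimming, segmentation, time
normalization, hierarchical averaging, feature extraction, group
statistics. Every stage is a plain function that can be run and tested in
isolation.

**Walking direction.** Rather than trusting the file's axis conventions,
each trial's walking direction is the first principal axis of pelvis
displacement in the sagittal plane, signed so the projected pelvis position
increases. On a ramp this axis is the slope direction, so projected
("AP") positions, step lengths and velocities are along-slope quantities.
The orthogonal axis (walkway normal) is used for foot-strike
classification, making the heel-vs-toe height comparison slope-aware. A
trial must displace the pelvis by at least 0.5 m; rigid rotations or
translations of all landmarks do not change any downstream result (this is
a tested invariant).

**Event detection.** Initial contact is detected at local maxima of
heel-minus-pelvis AP displacement and toe-off at minima of toe-minus-pelvis
displacement — the standard coordinate-based approach for level and ramp
walking. Two acceptance rules reject jitter peaks: a minimum topographic
prominence of 20% of the signal's interquartile range, and a minimum
0.3 s interval between like events (admitting cadences up to 200
steps/min). Both are configurable (`min_prominence_frac`,
`min_interval_s`); the source study does not report the thresholds it used
with this algorithm, so these defaults are declared rather than inferred.
Plateau maxima resolve deterministically to their first frame. Toe-offs
before the first or after the last ipsilateral IC are dropped so each
side's series alternates IC, TO, ..., IC.

**Trimming.** Steps are ICs of either foot in temporal order, indexed
1..N — the everyday meaning of counting steps. Level trials keep steps
3..N-3 (analysis starts with the third step after standing start and ends
three steps before stopping); ramp trials keep 2..N-1. A cycle is
analyzable if both of its bounding ipsilateral ICs are kept. In place of
manual event correction (used in lab practice with 3D animation), a QC
screen flags cycles whose duration deviates from the trial median by more
than 3 SD; flagged cycles are excluded from averaging.

**Filtering.** The study's processing chain names a generalized
cross-validatory quintic spline at a 6 Hz cutoff; its smoothing parameter
is not recoverable from a cutoff alone, so the package uses the gait-lab
standard equivalent: a 2nd-order Butterworth applied forward and backward
(4th-order, zero phase lag) with the dual-pass cutoff correction
1/0.802, giving -3.25 dB at the nominal 6 Hz cutoff, <0.1% attenuation at
1 Hz, and >97% attenuation at 15 Hz. Series are extended by
endpoint-reflected padding before filtering so constants pass through
unchanged and edge transients are suppressed. `filter_cutoff = NULL`
disables the stage: noiseless synthetic cohorts are band-limited by
construction, and for them the filter's genuine (and expected) ~0.2°
attenuation of higher gait harmonics is a property of filtering, not an
error of recovery — the calibration round-trip checks therefore run the
noiseless arm unfiltered and the noisy arm with the default 6 Hz filter.

**Normalization and averaging.** Cycles are resampled to 101 points
(0-100% in 1% steps, the field convention) by cubic interpolation on the
cycle's own time base with endpoints preserved exactly; toe-off is carried
as a percent of cycle duration. Averaging mirrors the study hierarchy:
cycles within a trial and side, then left/right limbs, then trials. The SD
band of a representative waveform is computed across trial-level
(limb-averaged) waveforms — the export labels this, since a between-trial
and a between-participant band answer different questions. If a trial has
cycles on one side only, the single-side mean is used with a warning.

**Features.** Twelve parameters per participant-condition (so 36 when all
three conditions are present): per joint the full-cycle range of motion
plus window extrema. Mid-stance is not defined by the study; the package
uses the temporal midpoint of stance (toe-off percent / 2), the only
definition computable from events alone, overridable via
`mid_stance_percent`. Peak plantarflexion "at the stance-to-swing
transition" is taken in a ±10% cycle window around toe-off (configurable
width), which captures the push-off peak that straddles TO. Sign
conventions follow the published tables: hip extension and ankle
plantarflexion peaks are positive magnitudes; knee extension and the ankle
IC angle are signed, negative meaning hyperextension/plantarflexion.
Step length is the heel-to-heel distance projected on the walking direction
at each kept contact (heel-marker based, along-slope on ramps); velocity is
pelvis displacement along the walking direction over the kept window
divided by its duration; cadence counts kept ICs only. Velocity is
pelvis-based rather than walkway-distance-based; both choices are common
and the difference is negligible on straight walkways.

## Statistical tiers

Spatiotemporal parameters are compared with independent two-tailed
pooled-variance t tests (Welch available via `var_equal = FALSE`);
pooled variance is consistent with pooled-SD Cohen's d, which the package
reports with half-open magnitude bands (negligible <0.2, small <0.5,
medium <0.8, large >=0.8, boundary inclusive at 0.8). The default FDR
family is the three conditions within each parameter; a global family is a
config switch, since the family definition for this tier is ambiguous in
the source description. Both raw and adjusted p-values are always reported.

Each joint-angle parameter gets its own linear mixed model:
`angle ~ velocity + group * condition + (1 | participant)`, REML,
sum-to-zero factor contrasts so type-III F tests are meaningful,
Satterthwaite denominator degrees of freedom (via numerical differentiation
of the variance of estimable functions with respect to the variance
parameters, as implemented in lmerTest). Estimated marginal means evaluate
the velocity covariate at its grand mean over all observations — the
standard covariate-adjustment convention; whether the original analysis
used the grand or per-condition mean is unstated. Young-minus-older
contrasts within each condition are only *evaluated* when the
group×condition interaction is significant (unadjusted p < 0.05 — FDR is
applied to the simple effects, not the gate), and BH correction pools all
evaluated contrast p-values across parameters and conditions. The
standardized effect size divides the EMM difference by the model's
residual SD. Singular fits (participant variance estimated at zero) are
retained and flagged, not refitted. When every participant contributes a
single observation the random intercept is unidentifiable; the package
then fits the fixed-effects model and reports exact type-III F tests with
residual degrees of freedom, which reduces to the two-sample t test in the
one-condition two-group case.

One distributional caveat worth recording: the Benjamini-Hochberg step-up
adjustment is monotone and order-preserving, and its largest adjusted value
equals the largest raw value, but it is *not* a fixed point of itself —
p = (0.1, 0.9) adjusts to (0.2, 0.9), which would re-adjust to (0.4, 0.9).
The test suite asserts the properties that actually hold.

## The synthetic cohort generator

The generator exists so that every pipeline stage has inputs with known
ground truth. Joint waveforms are periodic monotone-cubic (Fritsch-Carlson)
interpolants through a small keypoint schedule per joint; because
shape-preserving interpolation cannot overshoot its knots, requested
extrema are placed exactly at keypoints and `build_template()` verifies by
re-extraction that a noiseless 101-sample cycle reproduces every requested
target to 0.05°, rejecting infeasible sets (e.g. a swing peak placed inside
stance). Default targets are the published group-level values for the three
conditions. Range of motion is deliberately *not* a calibration target: the
published group values are adjusted model means fitted per parameter and
are not mutually constrained by waveform algebra (for the ascent knee they
are jointly infeasible for any single waveform), so RoM is emergent from
the calibrated extrema.

Landmark trajectories follow a single-support timing model: the stance foot
is stationary on the walking surface while the pelvis advances uniformly
along it, so heel-minus-pelvis displacement peaks exactly at IC and
toe-minus-pelvis troughs exactly at toe-off — the generator realizes the
detection model's assumptions by construction. Stance keypoints are
collinear around mid-cycle so that the interpolant is exactly linear where
the trailing foot sits at a contralateral IC; heel separation at any IC
then equals the configured step length identically. Ramp trials rotate the
along-slope/normal frame by ±7°, so the vertical coordinate follows
slope × horizontal progress and the pelvis advances monotonically along
the incline. Stance fractions (level 0.60, ramps 0.61) are
literature-typical assumptions — the study reports no stance percentages —
and are configurable.

Cohort structure: per participant, spatiotemporal targets are group target
plus a normal offset per condition (velocity and step length drawn with the
published SDs; cadence derived as 60·velocity/step length, which reproduces
the published cadences to within a steps-per-minute or so), and each
joint's waveform is shifted by a participant-level normal offset
(`participant_sd`, default 3°) constant across conditions — exactly the
random-intercept structure the mixed model assumes. Frame-level angle noise
(`noise_sd`, default 2°) and proportional landmark jitter model measurement
error. The calibration contract: participant draws are standardized to
exact mean 0 and exact target SD within group (`standardize = TRUE`), so a
cohort "calibrated to" a published mean realizes that mean exactly rather
than up to sampling error; raw draws are available for simulation studies,
and the mixed-model validity simulations in the test suite use raw normal
draws at the feature level. Draw order is fixed (velocity offsets, step
length offsets, joint offsets, then per-trial frame noise) and one seed
drives everything, so identical specs give bit-identical cohorts.

What the generator does **not** emulate: within-stride velocity
fluctuation, double-support timing details, left/right asymmetry, stride-
to-stride variability beyond white noise, soft-tissue or pose-estimation
artifacts, non-sagittal motion, and kinetics. Passing round-trips on
synthetic cohorts therefore demonstrate the pipeline's correctness under
its own assumptions — events at displacement extrema, stationary stance
foot, additive noise — not its accuracy on real markerless captures, where
event-detection bias and marker-model differences dominate.

## Numerical choices and problem sizes

- Peak ties resolve to the first frame of a plateau; minimum-distance
  enforcement keeps the more prominent peak, ties to the earlier one.
- Cubic (not monotone) interpolation is used for time normalization:
  at 101 samples per ~60-frame cycle the overshoot risk is negligible and
  cubic preserves extrema amplitude better; normalization of an
  already-uniform 101-sample cycle is an identity to 1e-9.
- Default trial sizes: 9 steps on the 7 m level path, 6 on the 3.25 m ramp
  with 1.5 m level approach/exit allowances on either side (a 3.25 m ramp
  cannot physically hold the six steps the trimming rule needs, so real
  trials necessarily start and stop on adjoining level ground).
- Validation problem sizes, chosen to make the checks sharp while keeping
  the full suite around two minutes of compute: calibration round-trips use
  20+20 participants × 3 conditions × 5 trials; mixed-model validity uses
  500 null simulations (type-I error of the type-III group test) and 200
  effect simulations (bias and 95% CI coverage of the group×condition
  contrast) at 20 participants per group, participant SD 3°, residual SD 2°.
- The trial file format is tab-separated text with `#`-prefixed metadata —
  human-diffable and fixture-friendly. Readers validate column presence
  (order-insensitive), 1/fs time spacing, and finite angles, and report
  malformed rows by line number.

## Known limitations

- The LMM tier offers random intercepts only — no random slopes,
  Kenward-Roger df, or longitudinal structure.
- No gap-filling: missing frames must be handled upstream.
- No force-plate or pressure-based event detection; the coordinate-based
  detector assumes steady forward progression and will mis-fire on turns
  or stops inside the analyzed window.
- Foot-strike classification uses relative heel/toe height with a 0 cm
  threshold — the simplest kinematic proxy; studies with marker offsets may
  need the configurable threshold.
- C3D ingestion is not implemented; recordings arrive via the TSV dialect
  or are constructed in R.
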