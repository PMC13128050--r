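Package: rampgait
Title: Gait Event Detection, Sagittal Kinematic Features, and Velocity-Adjusted Group Comparisons for Level and Ramp Walking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for lower-limb gait studies comparing age
    groups across level walking and ramp ascent/descent. Provides
    coordinate-based detection of initial-contact and toe-off events from
    heel, toe, and pelvis trajectories, foot-strike classification,
    condition-specific trial trimming, zero-lag low-pass filtering, gait
    cycle time normalization to a 101-point grid, hierarchical averaging
    into representative waveforms, extraction of twelve sagittal hip/knee/
    ankle parameters plus cadence, velocity and step length, and a two-tier
    statistical layer: pooled-variance t tests with Benjamini-Hochberg
    correction and Cohen's d for spatiotemporal parameters, and
    velocity-adjusted linear mixed models with type-III tests, estimated
    marginal means, FDR-corrected simple effects and residual-SD effect
    sizes for joint-angle parameters. A calibrated synthetic gait cohort
    generator with known ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    lme4,
    lmerTest,
    emmeans,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
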