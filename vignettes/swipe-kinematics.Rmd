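---
title: "Movement-unit kinematics of goal-directed touchscreen swipes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-unit kinematics of goal-directed touchscreen swipes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swipekin)
```

## Overview

`swipekin` analyses goal-directed finger swipes recorded on a touchscreen
during gameplay in which food pieces are moved from a central *food area*
onto one of four *plates*. The pipeline takes raw touch events (timestamp,
pixel position, touch phase) and produces swipe-level kinematic outcomes,
a filtered analysis cohort, and mixed-effects model fits that relate the
outcomes to target distance, age, and group membership.

This vignette documents the model, the numerical procedures, every
parameter with its unit, default and rationale, and the open design
decisions the implementation had to settle.

## Touch-event model

Events follow the UITouch phase convention: `0` = touch began, `1` =
moved, `3` = ended. A well-formed gesture starts with phase 0 and ends
with phase 3; gestures lacking either are flagged `missing_structure` and
never receive kinematics. When the log has no gesture identifiers, gestures
are reconstructed per participant from the phase stream. Duplicate
`(gesture, t, phase)` events keep their first occurrence with a warning.

Two gestures of one participant whose time intervals strictly overlap are
both flagged `multiple_touch`: a unique swipe path cannot be attributed to
either. Sharing a single endpoint is not an overlap.

A swipe is *goal-directed* when its raw start point lies in the food area
and its raw end point in any plate area. Only the endpoints are tested;
the finger may wander in between. Rectangles are half-open (`[x0, x1)`,
`[y0, y1)`) so adjacent regions cannot double-claim a boundary point. The
default layout (`default_layout()`) is a 2048 x 1536 px screen at 326 ppi
with a centred 528-px food square and four plates whose shortest
food-to-plate gap is 173 px = 13.48 mm; layouts round-trip through JSON
(`read_layout()` / `write_layout()`).

## Preprocessing

*Units.* Pixels convert to millimetres as `mm = px * 25.4 / 326`
(`px_to_mm()`); all kinematics are in mm and seconds.

*Resampling* (`regularise_sampling()`). Device timestamps jitter, so each
swipe is linearly interpolated onto a uniform grid at `fs = 60` Hz (the
device sampling rate) spanning its recorded duration. Input already on a
uniform grid (jitter below 10% of one sample period) passes through
unchanged, so clean data is never altered. Swipes spanning fewer than five
grid points cannot support the derivative stencil and raise a typed error.

*Smoothing* (`lowpass_zero_phase()`). A 4th-order low-pass Butterworth
filter with an 8-Hz cut-off is applied forward and backward, giving zero
phase lag and a squared magnitude response `1 / (1 + (f / 8)^8)`; the
effective gain at the cut-off is 0.5. Each pass is initialised at the
filter's steady state for the first sample value, and the series is
padded with `3 * order` samples of odd reflection at both ends, so
constant signals are reproduced exactly and edge transients do not
corrupt the window. Series too short to pad are passed through unfiltered
with a warning rather than dropped. 8 Hz preserves voluntary movement
(below ~6 Hz in young children) while suppressing sensor noise; 60 Hz
sampling leaves a comfortable margin to the 30-Hz Nyquist limit.

*Differentiation* (`derivative_five_point()`). Velocities come from a
five-point central stencil, `(-f[i+2] + 8 f[i+1] - 8 f[i-1] + f[i-2]) /
(12 dt)`, which is 4th-order accurate in the interior; one-sided and
central 2nd-order formulas cover the two samples at each edge. Speed is
the Euclidean norm of the velocity components.

## Movement-unit segmentation

A *movement unit* (MU) is a velocity maximum together with its
acceleration phase (from the preceding velocity minimum, or from touch
onset) and deceleration phase (to the following minimum, or to touch
end). `segment_units()` retains a candidate peak when

1. its summed rise and fall is at least `min_cumulative_change = 8` mm/s, and
2. the peak speed exceeds `min_peak_fraction = 0.05` of the swipe's
   global peak velocity (computed once, before any merging).

Candidates failing either criterion are merged, weakest first (smallest
rise + fall, then lowest peak, then earliest), by deleting the *higher*
of the two flanking minima so that the deepest troughs survive as unit
boundaries; ties delete the left minimum, and the merged region keeps the
higher of the two peaks. The first (last) peak always merges rightward
(leftward). This iterative, deterministic rule makes the result
independent of bookkeeping order, and is verified in the test suite
against an independent reference implementation on a thousand random
multi-bell profiles. Plateaus collapse to their midpoint sample;
profiles that are flat or monotone yield a single spanning unit flagged
degenerate. The `criterion = "separate"` option instead requires rise
*and* fall to each reach the threshold, for auditing the stricter
reading of the cumulative-change rule.

## Swipe-level outcomes

From the trajectory, velocity profile and units, `compute_features()`
derives: movement time MT (s); peak velocity PV (mm/s) and time to it
TTPV (s, first sample attaining the maximum); the deceleration phase
`%Dec = 100 (MT - TTPV) / MT`; the first unit's peak PV1 and the binary
PV1-b (is the global peak in the first unit?); the MU count and MU-APV
(units whose peak lies strictly after the PV sample, never counting the
unit containing PV); target distance (straight-line displacement between
the *raw* recorded endpoints, so smoothing cannot shrink it);
path length along the filtered track; and straightness = path / distance.
Distances bin into six 10-mm categories, `[10,20) ... [60,70]`, half-open
with a closed top. Sensitivity margins record the distance covered before
the first velocity minimum and after the last one.

## Cohort filtering

The swipe-level exclusion cascade (`apply_swipe_exclusions()`) fires in a
fixed order, each swipe keeping the first reason: `multiple_touch`,
`too_few_samples` (< 5), `short_distance` (< 13.5 mm, the shortest
food-plate gap — anything shorter cannot be a genuine food-to-plate
movement), `mt_outlier` (> 2.0 s), `dist_outlier` (> 70 mm), and
`straightness` (> 1.5). Movements failing these bounds are unlikely to be
efficient single-goal movements. The full per-swipe trail is kept so
alternative orderings can be audited.

The participant rule retains a participant when their goal-directed
swipes are at least 10% of all swipes they made — evidence of engaged,
task-directed play. A boundary ratio of exactly 10% is retained. This is
a deliberate design decision: the alternative literal reading (excluding
participants *above* 10%) would discard the most task-engaged children
and empty the analysis sample, but it remains available behind
`filter_params(literal_participant_rule = TRUE)` for auditing.

The sensitivity subset (`sensitivity_subset()`) further requires both
boundary margins to be strictly below 5 mm, removing movements that
decelerate over a sizeable share of the target distance before the swipe
proper, or creep to the goal and accelerate only while lifting off.

## Mixed models

`prepare_covariates()` centres the distance category at the median
(30–40 mm, so `dist_c` runs −2..3) and age at 4.7 years. The final
per-outcome specifications (`final_model_specs()`) pair each outcome with
its family and the fixed effects retained by model building; every model
carries a by-subject random intercept and distance slope,
`(1 + dist_c | subject)`:

| outcome | family / transform | fixed effects |
|---|---|---|
| MT, PV, TTPV | gaussian, log | Dist + age + ASD + ASD:age |
| PV1-b | binomial (logit) | Dist + age + ASD |
| MU-APV | Poisson (log) | Dist + age + ASD + ASD:age + ASD:Dist |
| MU | zero-truncated Poisson | Dist + age + ASD |
| PV1 | gaussian | Dist + age + ASD + Dist:age |
| %Dec | gaussian | Dist + age + ASD |

Gaussian models are fitted by REML with `lmerTest` (Satterthwaite degrees
of freedom for tests and intervals). The generalised families are fitted
with `glmmTMB` (ML, Laplace approximation, Wald z inference); `glmmTMB`
was chosen over `lme4::glmer` because it fits the same models several
times faster with indistinguishable estimates, which matters for the
200-replicate recovery study. MU is at least 1 by construction, hence the
zero-truncated Poisson; the exact truncated likelihood is exposed as
`ztp_loglik()` and the test suite verifies `glmmTMB`'s fits against it.
Singular random-effects fits are flagged, not raised.

Variance partitioning follows Nakagawa & Schielzeth: the random-effect
variance averages `tau00 + 2 rho sqrt(tau00 tau11) d + tau11 d^2` over
the observed distance indices; the residual variance is `sigma^2`
(gaussian), `pi^2 / 3` (logistic latent scale), or the log-normal
approximation `ln(1 + 1/lambda)` with `lambda = exp(b0 + var_re / 2)`
(Poisson families). `dispersion_ratio()` (Pearson chi-square over
residual df) diagnoses overdispersion in the count models.
`cohort_tests()` adds the descriptive battery (chi-squared with Yates
correction for 2x2 tables, pooled-variance t, variance-ratio F,
Mann–Whitney), degrading to Fisher's exact test on empty cells and to
`NA` with a note on degenerate data.

## Synthetic data

Two simulators provide ground truth.

*Trajectories* (`simulate_trajectory()`): sums of minimum-jerk
submovements — speed `(A/T)(30 tau^2 - 60 tau^3 + 30 tau^4)`, peak
`1.875 A / T` at the midpoint — composed in velocity space, plus Gaussian
positional noise (default SD 0.3 mm, a touchscreen sensor-noise
calibration choice), emitted as a 60-Hz touch-event log in device pixels.
Because the closed forms are known, the whole pipeline can be validated
end to end: the test suite requires PV within 1%, TTPV within one sample,
and %Dec within 2 points of 50 across a grid of amplitudes and durations.

*Cohorts* (`simulate_cohort_outcomes()`): subjects (default 35 + 35, ages
uniform on 2.8–6.6 years, 55 swipes each) carry correlated random
intercepts and distance slopes from a bivariate normal; distance
categories follow the pooled observed proportions; each outcome is drawn
from its model family. The generative defaults
(`default_generative_params()`) are the estimated fixed effects and
variance components of the final models for this cohort. Two caveats are
built in rather than hidden: the published slope variances for the
gaussian outcomes round to 0.00 while their intercept–slope correlations
are nonzero, so a small positive `tau11 = 0.003` is used; and the MU, PV1
and %Dec parameter sets are this package's own plausible choices (the
corresponding fits were not tabulated), flagged `synthetic = TRUE`.

`parameter_recovery_study()` refits the final models over replicate
cohorts and reports per-term bias, Monte-Carlo SE, RMSE and coverage;
`zero_group_effects()` supports type-I-error calibration;
`mu_recovery_calibration()` quantifies segmentation robustness to
positional noise. The generator does *not* emulate game mechanics,
fatigue or learning over the session, non-uniform age distributions, or
within-swipe autocorrelated sensor noise.

## What the acceptance checks cover

The test suite ends with acceptance tests at fixed tolerances: the
minimum-jerk grid; exact agreement of the segmentation with an
independent oracle on 1000 random profiles; the filter's measured gains
at 1, 8 and 25 Hz against the analytic squared-Butterworth magnitude; an
engineered 500-swipe exclusion fixture with known per-rule counts and
idempotence of the cascade; a 200-replicate parameter-recovery study
(per-term |bias| <= 3 Monte-Carlo SEs, coverage in [0.90, 0.99], no fit
failures); and the type-I error of the group effect under a
zero-group-effect null within 2.5 binomial SEs of 0.05.
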