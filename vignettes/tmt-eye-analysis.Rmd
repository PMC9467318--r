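---
title: "From gaze samples to dominance verdicts: the trailgaze methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From gaze samples to dominance verdicts: the trailgaze methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trailgaze)
```

## The task and its measures

trailgaze analyzes a computerized Trail-Making Test (TMT) in which
participants click 25 targets in a prescribed order -- numbers 1 to 25 in
part A, alternating numbers and letters (1, A, 2, B, ...) in part B --
while their gaze is recorded, under instructions emphasizing either speed
or central (accurate) clicking. Eight scores summarize each trial: trial
duration (s), mean fixation duration (ms), mean saccade amplitude
(degrees of visual angle), number of fixations, numbers of guiding and
searching fixations, mean eye-hand span (s) and scanpath length
(degrees). The statistical question the package answers, per score and
test half, is whether the score is dominated by the experimental
speed/accuracy manipulation or by stable differences between individuals.

## Geometry and event detection

Gaze positions arrive in screen pixels; everything downstream works in
degrees of visual angle. The conversion is a per-axis arctangent about
the screen center, `theta = atan((p - center) * pitch / distance)`, where
pitch is the physical pixel size. We deliberately avoid the small-angle
linearization: the arctangent is exact at all on-screen eccentricities,
trivially invertible (`deg_to_px()` reverses `px_to_deg()` to below
1e-9 px), and costs nothing. Distances, amplitudes and scanpaths are
Euclidean in `(theta_x, theta_y)` space. Default geometry: 1024 x 768 px,
36 x 27 cm, viewed from 71 cm, sampled at 1000 Hz.

Saccade/fixation parsing mirrors a standard video-oculography online
parser: a sample is saccadic while angular speed exceeds 30 deg/s *or*
absolute acceleration exceeds 8000 deg/s^2. Speed is estimated by central
differences over a 3-sample window (configurable; wider windows smooth
noisier recordings at the cost of temporal resolution) and acceleration
as the central difference of the speed signal. Runs of saccadic samples
become saccades; the intervening runs become fixations, whose centroid
is the mean sample position. Proprietary online parsers do not document
their internal smoothing, so our detector is threshold-faithful rather
than guaranteed sample-identical to any tracker's output; the test suite
pins it instead to a brute-force per-sample scanner.

Numerical conventions worth stating: event boundaries tile the recording
(an event's offset is the next event's onset within a continuous valid
segment), so durations partition the valid span exactly; single-sample
fixation candidates (duration 0) are discarded; runs of two or more
invalid samples become blinks that terminate any open event -- we never
interpolate across blinks, which avoids fabricating fixations at the
price of occasionally splitting one -- while isolated one-sample dropouts
are skipped without splitting. Consecutive fixations closer than 1 degree
are merged iteratively left to right, the merged fixation taking the
duration-weighted centroid and absorbing the saccade between them; a
merged fixation is immediately re-checked against its successor using the
merged centroid. There is no minimum fixation duration by default
(`min_fix_dur = 0`), configurable.

## Classification and scoring

A fixation is *guiding* if its centroid falls within the 3.25-degree
classification circle (radius 1.625 deg) of the target that is currently
to be clicked, *searching* if it falls within that circle of any other
(past or future) target, and *unassigned* otherwise. Three decisions the
task description leaves open:

* **The current target is the one pending at the fixation's onset.** A
  fixation cannot be guided by a target that only becomes current after
  it ends; anticipatory fixations on the upcoming target therefore count
  as searching, consistent with the "present target" definition of
  guiding.
* **Unassigned fixations count in `n_fixations` but in neither
  subtype**, so the subtype counts need not sum to the total (a flag,
  `include_unassigned = FALSE`, excludes them from the total for
  sensitivity analyses).
* **Overlapping classification circles resolve to the nearest center**,
  with exact ties going to the current target.

The eye-hand span of a target is the time from the onset of the *first*
guiding fixation on it -- after it became current and before its hit
click -- to that click, in seconds; the eyes lead the hand, so spans are
strictly positive. Targets never fixated while current contribute
*missing* spans, never zero: a zero would be a real (and impossible)
observation, and means over spans must not be dragged toward it. Scanpath
length is the summed centroid-to-centroid distance over merged fixations
rather than the raw sample path (robust to sample noise) or the summed
saccade amplitudes (which would drop merged segments). Misclicks make a
low-pitched sound and do not advance the sequence; all time until the
final hit belongs to the trial.

## What the synthetic data emulate

The generator exists so that every downstream stage is testable without
human recordings. It emulates the statistical structure the analysis
assumes, not oculomotor physiology:

* **Layouts**: targets occupy distinct fields of a 5 x 5 grid spanning
  the screen, jittered uniformly (default 0.8 deg) and rejection-sampled
  to a minimum pairwise separation. The default separation of 2.6 deg,
  combined with fixation scatter that is radially truncated at 2.5 SDs,
  guarantees that a fixation generated on a target is always nearest to
  that target and inside its classification circle whenever the scatter
  SD is at most 0.5 deg -- so ground-truth roles and the classifier must
  agree exactly, a property the tests exploit. Stimulus arrangements are
  shared by all subjects within a version and are *not* matched across
  test halves.
* **Trials**: per target, a Poisson number of searching fixations on
  other targets (the simplest count model with the required monotone
  condition structure), then one guiding fixation, then a click after a
  log-normal eye-hand-span delay. Speed instructions scale the searching
  rate down (x0.65) and the span down (x0.60) but widen click scatter
  (0.45 vs 0.20 deg SD), so misses and corrective re-clicks increase:
  the speed-accuracy trade-off emerges mechanically. TMT-B scales the
  searching rate up (x1.4). Per-subject log-normal intercepts on
  fixation duration, searching rate and span produce the interindividual
  variability the mixed models target.
* **Raw streams**: `render_gaze()` holds each centroid for the fixation's
  duration and moves between centroids along linear ramps at 300 deg/s --
  comfortably supra-threshold, with no pretense of realistic saccade
  dynamics -- so detection recovers the generated event sequence
  (pipeline round trip).
* **Score tables**: `simulate_scores()` draws directly from the model the
  inference assumes, `y = X beta + u_subject + e`, dummy-coded with
  reference levels TMT-A and accuracy. The per-score defaults in
  `tmt_reference_params()` are on realistic scales for healthy adults
  (e.g. trial duration: intercept 72.55 s, instruction effect -28.18 s,
  subject SD 17.22 s, residual SD 20.9 s). Four right-skewed scores
  (fixation count, searching count, eye-hand span, scanpath length) are
  generated and modelled on the natural-log scale; their slopes and SDs
  are unit-free, and their intercepts are set on the package's units
  (seconds for the span, fixation-centroid degrees for the scanpath --
  about 1.8 s and 125 deg at the accuracy/TMT-A baseline).

What the generator does *not* emulate -- main-sequence saccade dynamics,
saliency-driven search, pupil dynamics, drift and calibration error,
heavy-tailed response times -- bounds what green tests mean: they certify
the estimators and the pipeline plumbing on data satisfying the model's
assumptions, not robustness to real recordings' violations of them.

All randomness descends from one integer seed. Multi-unit generators
derive one sub-seed per unit (`seed + 1000003 * i`, modulo a 31-bit
prime), so any single layout, subject or trial can be regenerated in
isolation and whole fixtures are byte-reproducible.

## The mixed models

Every score is analyzed with a random-intercept linear mixed model,
`y_ij = X_ij beta + u_j + e_ij`, `u_j ~ N(0, sd_intercept^2)`, fitted
from scratch. With a single grouping factor the covariance
`V = I + lambda Z Z'` (with `lambda = sd_intercept^2 / sd_resid^2`) is
block-diagonal by subject, so each likelihood evaluation reduces to
per-group Woodbury identities and the whole fit is a one-dimensional
profiled (RE)ML optimization over `log(lambda)` (bounded search on
[-15, 15], with the `lambda = 0` boundary evaluated explicitly so
zero-variance fits are exact, not merely approached). REML is the
default; ML is available for likelihood comparisons. The test suite pins
the optimizer to a dense grid search (step 1e-4 on the log scale), to
ordinary least squares when the subject variance is zero, and to lme4 on
shared datasets.

Inference: standard errors from the generalized-least-squares covariance
at the optimum, `t = b/SE`, and Wald 95% intervals `b +/- 1.96 SE` -- an
approximation to profile intervals with small expected discrepancies.
P-values in mixed models are approximations however computed, and
intervals are the primary output; `wald_pvalues()` offers a residual-df
method (`n - p - (J - 1)`, the classical within-subject residual df) and
a Satterthwaite method whose per-coefficient df come from the numerical
REML Hessian of the variance components. Responses are complete-case
filtered per score, with the fitted group and observation counts always
reported. Log transforms use the natural log.

## The dominance analysis

The package's second stage asks, per score and per test half, whether
the data are better predicted by the experimental manipulation or by
subject identity. Within one half the design leaves instruction as the
only fixed factor, which resolves any ambiguity about the per-half
model. Two Bayes factors are computed against the intercept-only model
under Zellner-Siow mixture-of-g priors: the *fixed-effects-only* model
(instruction, Cauchy scale 0.5 on the sum-to-zero standardized effects)
and the *random-effects-only* model (subject, scale 1.0, independent
level effects) -- the conventional medium/nuisance defaults, recorded in
every output. Integrating the intercept exactly projects the problem
onto the complement of the constant vector, after which the marginal
likelihood ratio at each g costs O(k) via an eigendecomposition of the
centered Gram matrix, and the scalar g is integrated out by adaptive
quadrature on the log-g scale (deterministic to the configured
tolerance, default 1e-6; no Monte Carlo). The resulting Bayes factors
are exactly location/scale invariant. The dominance quotient is
BF(fixed) / BF(random); above 1 the manipulation dominates, below 1
interindividual variability does.

Alongside, the variance decomposition of the per-half mixed model gives
marginal R^2 (fixed effects only) and conditional R^2 (fixed plus random)
with `R2m = s2_f / (s2_f + s2_u + s2_e)` and
`R2c = (s2_f + s2_u) / (...)`, where `s2_f` is the population variance of
the fixed-effect predictions. Their 95% intervals come from a cluster
bootstrap: subjects -- the exchangeable unit, preserving within-subject
dependence -- are resampled with replacement, relabelled so a subject
drawn twice forms two clusters, and the model is refitted per replicate;
intervals are percentile-based, and failed refits are dropped and
counted.

## Validation scale and numerical choices

The package validates itself at deliberately chosen problem sizes: 500
simulated 58-subject studies for standard-error calibration of the
instruction coefficient (the balanced-design analytic value is
`sd_resid * sqrt(2/58)`); 1000 replicates for REML variance
unbiasedness; 200 replicates per regime for the direction of the
dominance quotient; and 200 outer replications with 400 bootstrap
replicates each for interval coverage of the marginal R^2 against its
construction truth. Oracle comparisons run on small instances where
brute force is exact company: 6-8 subjects for the profiled-likelihood
grid search, 12-16 rows for dense trapezoid g-integration (1e5 nodes)
behind the Bayes factors.

Degenerate inputs are handled explicitly rather than by accident:
zero-variance responses refuse a Bayes factor; singular designs (an
empty design cell) raise a rank error naming the cause; noise-free data
profile to the `lambda = 0` boundary and reproduce least squares
exactly; a bootstrap with one replicate returns that replicate's values
as both interval ends.

## Known limitations

* The detector is threshold-faithful to the stated velocity and
  acceleration criteria but not sample-identical to proprietary online
  parsers, whose smoothing is undocumented.
* Wald intervals and either df method are approximations; profile or
  parametric-bootstrap intervals for fixed effects are out of scope.
* Percentile cluster-bootstrap intervals for R^2 carry the usual modest
  undercoverage for bounded statistics at moderate subject counts.
* The Bayes factors cover the fixed-only, random-only and intercept-only
  models the dominance quotient needs -- not a model-averaged ANOVA over
  all sub-models.
* The score-level generator assumes Gaussian (or log-Gaussian) scores
  with a single variance component; real recordings contain structure
  (drift, blinked-out targets, learning across trials) it does not
  attempt.
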