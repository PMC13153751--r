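---
title: "Grip strength from smartphone sensing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grip strength from smartphone sensing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gripsense)
```

## The problem

Maximal isometric grip strength, measured in kilograms with a handgrip
dynamometer, is a widely used clinical biomarker: diagnostic cutoffs for
sarcopenia sit near 28 kg (men) and 18 kg (women), and the minimal
clinically important difference is about 5.0–6.5 kg. `gripsense` estimates
grip strength from touchscreen interaction instead. A user holds the phone
in one hand, performs three short tasks with the thumb — tapping 10 targets,
flicking a ball into a goal 10 times, tracing a spiral once — and the
logged touch events and 60 Hz inertial streams are regressed on dynamometer
readings collected alongside.

The premise is that grip strength expresses itself in fine-motor control:
weaker grip goes with slower, less accurate, less steady interaction. The
package does not test that physiological premise; it implements the
estimation machinery and validates it on synthetic cohorts whose
grip-to-behavior link is generated by construction.

## Data model

One **session set** is a participant-day-set unit: two dynamometer readings
(their mean is the regression target; it is always derived at read time,
never stored, so the two can never diverge) and one execution each of the
tap, flick, and drag tasks. Each execution carries its sub-events (target
appearances and the input events that resolved them), a touch stream
(`t`, `x`, `y`, `phase`, `contact_area`), and a sensor stream (`t` plus
nine channels: accelerometer, gyroscope, orientation, in m/s², rad/s, and
degrees).

Coordinates are millimeters from the screen's top-left corner, y downward;
the default screen is the 72.9 × 152.0 mm device used in the reference
design. Contact area stays in the device's normalized units — no attempt is
made to convert it to mm² because touch controllers do not define the
scale. Timestamps are seconds since task start. Session logs are JSON
Lines with a header line declaring schema version, device, screen size, and
sample rate; feature matrices are RFC-4180 CSV with the ground-truth
`grip_kg` as the last column and the feature-schema hash in a leading
comment, which fitted models check before predicting.

## Task geometry

The drag task's reference curve is an Archimedean spiral
\(r(\theta) = p\,\theta / 2\pi\). The reference design specifies only the
stroke width (4.4 mm) and the direction (clockwise for right-handed use);
pitch and turn count are free choices, defaulting to 8 mm and 3 turns so
the outer radius (24 mm) fits the screen width with margin. `spiral_point()`
parameterizes the centerline by arc length (inverting the closed-form arc
length of the Archimedean spiral on a dense monotone table), and
`distance_to_spiral()` returns the distance to the nearest centerline
point. It is computed by a vectorized dense-grid search (1536 angular
samples) followed by parabolic refinement of the squared distance around
the grid minimum; tests hold it to within 0.01 mm of a brute-force
100 000-sample oracle, and the observed deviation is below 1e-3 mm. The
per-arc bounded 1-D minimization that was considered first gives the same
accuracy but costs one optimizer call per touch sample, which dominates
drag feature extraction; the grid-plus-parabola form is exact enough and
two orders of magnitude cheaper.

Tap targets (14.6 mm diameter) are placed uniformly with a one-radius
margin from every edge; consecutive targets must be at least one diameter
apart center-to-center — the design says only that each new target appears
"at a different location", and one diameter is the weakest reading that
guarantees non-overlap. The flick goal sits at a fixed 25 mm from the
7.3 mm ball in a uniformly random direction; the true ball-goal distance is
unspecified in the reference design, and fixing it keeps flick kinematics
comparable across sub-events.

Left-handed use mirrors the horizontal axis: `mirror_for_left_hand()` maps
every touch and target x to `width - x` and flips the chirality of the
attached spiral. The transform is an involution and leaves timestamps and
sensor streams untouched.

## Preprocessing

Sensor streams are first rebuilt on a uniform 1/60 s grid
(`interpolate_missing()`): interior gaps are filled by per-channel linear
interpolation, boundary gaps by nearest-value extension, and a channel with
fewer than two valid frames is a hard error. The operation is idempotent.

Low-pass filtering (`lowpass()`) uses a 4th-order Butterworth design at a
20 Hz cutoff, applied forward and backward for zero phase. Order and type
are choices — the reference design states only "low-pass, 20 Hz" — and a
4th-order Butterworth is the conventional IMU smoother. At 60 Hz sampling
the cutoff sits at 2/3 of Nyquist, where a naive zero-padded
forward-backward pass leaks edge transients; the implementation therefore
pads by odd reflection (3 filter lengths) and warms the filter state on a
constant run of the first sample, which makes a constant signal pass
through bit-exactly and matches an independent frequency-response
evaluation at 25 Hz to three significant figures. Filtering is applied to
the full stream before window extraction; the alternative order (window
first, filter later) would distort the 10-frame windows with filter edges.

Around each input event, `extract_windows()` cuts three windows: the 10
frames strictly before the anchor, the frame average over a one-frame-wide
interval centered on it ("during input"), and the 10 frames strictly
after. Events closer than 10 frames to a stream edge are padded by
repeating the terminal frame rather than dropped, so every sub-event
yields a complete feature set; the padding counts are returned for logging.

## Features

Per tap sub-event: spatial error (distance from the touch-down point to the
target center, mm), elimination time (target shown → input, s), touch
duration (down → up, s), and mean contact area over the stroke. Per flick
sub-event: the flick direction as the unit vector from the first to the
last touch sample of the stroke (a regression fit of the path would be
less literal a reading of "direction of the flick input"), elimination
time, stroke duration, and mean contact area; zero-length strokes have no
direction and are excluded with a logged count. The drag execution yields
the tracing error (mean distance of touch samples to the spiral
centerline), speed and acceleration magnitude (mean and max) from central
finite differences of the raw touch path — the touch path is deliberately
not low-pass filtered, since the 20 Hz filter is specified for sensor
data — mean contact area, and total duration.

Every input anchor also contributes 99 sensor statistics: for each of the
9 channels and each of the pre/post windows, the maximum, minimum, range,
mean, and mean absolute consecutive-frame difference (5 × 9 × 2), plus the
9 during-input values. Tap and flick average the per-sub-event quantities
and the per-anchor sensor statistics over their 10 sub-events — the row
unit is one task execution mapped to one grip value, and the mean is the
natural within-execution aggregator when none is prescribed. Drag anchors
its single window set at the trace midpoint. The unified scope concatenates
the three task vectors with task-prefixed names (107 + 104 + 106 = 317
columns). Feature names are hashed (FNV-1a) into the matrix header, and
models refuse matrices whose schema hash differs from their training set.

## Synthetic cohorts

The generator emulates the reference study design — 21 participants ×
5 days × 10 consecutive sets, 1050 rows per task — with the latent grip
model

\[ G_{ids} = \mu + u_i + v_{id} - \beta\,(s - 1), \qquad
   u_i \sim N(0, \sigma_u^2),\; v_{id} \sim N(0, \sigma_d^2), \]

truncated at 1 kg, where \(\beta\) is the within-day fatigue slope across
the 10 consecutive sets (each set follows a maximal dynamometer squeeze,
so grip genuinely declines across a day's sets). The two dynamometer
readings add independent \(N(0, \sigma_m^2)\) noise. Defaults: \(\mu = 30\)
kg (collected values concentrated between 25 and 35 kg), \(\sigma_u = 5\),
\(\sigma_d = 1\), \(\beta = 0.3\) kg/set (the design induces variability
across sets but reports no magnitude; 0.3 kg/set yields a 2.7 kg within-day
range, comfortably inside day-to-day physiology), \(\sigma_m = 0.5\) kg.

Behavior is driven by a latent per-event variable
\(b = c\,(z + 0.35\,\delta_i) + (1 - c)\,(0.6\,\eta + 0.8\,\varepsilon)\),
where \(z\) is standardized latent grip, \(\delta_i\) a stable user-style
offset, \(\eta\) an execution-level noise component shared by a task run's
sub-events and independent across the three tasks, \(\varepsilon\)
per-event scatter, and \(c\) the `coupling` parameter. Touch durations,
elimination times, spatial and tracing error, and device-motion jitter
amplitude decrease linearly in \(b\) (steadier, faster, more accurate
interaction with stronger grip); contact area increases. Two structural
choices matter and were made on first principles when calibrating the
generator's null and orderings:

- **Everything user-stable scales with `coupling`** — the style offsets
  \(\delta_i\), the behavioral baselines, and the per-user postural sensor
  baselines. A coupling-0 cohort is therefore pure independent noise. Were
  stable offsets present at coupling 0, a pooled model could fingerprint
  each participant from style alone and predict that participant's mean
  grip, yielding strongly positive held-out R² in a cohort that is
  supposed to contain no signal. With the scaling, the no-signal null
  behaves as a null (held-out R² is negative on every algorithm).
- **The execution-level noise component \(\eta\)** prevents single-task
  models from becoming arbitrarily good by averaging per-event noise over
  10 sub-events: some noise is shared within a task run but independent
  across tasks, which is precisely the part a unified multi-task model can
  average away. This reproduces the qualitative superiority of the unified
  scope without tuning either model.

Per-participant random substreams are derived from the master seed by a
counter scheme, so enlarging a cohort never perturbs existing
participants, and the same seed yields a bit-identical cohort.

What the generator does *not* emulate: real hand biomechanics, device
heterogeneity, screen traction, attention lapses, or the error magnitudes
of the human study. A model that performs well here demonstrates that the
pipeline recovers a grip-coupled signal of the assumed monotone form —
nothing more. In particular the human study's headline numbers (MAE
2.62 kg, MAPE 8.91 %, R² 0.802 under a random split) are properties of 21
specific humans whose data are not public; the synthetic numbers are not
comparable to them, and the package makes no attempt to match them.

## Models

`grip_fit()` z-scores every feature column with statistics from the
training rows only (constant columns get scale 1 and a warning), then fits
one of four regressors with the reference configurations: random forest
(ranger; 200 trees, depth 20, ⌊√p⌋ candidate features per split, seeded),
RBF support vector regression (e1071; C = 100, kernel width by the "scale"
rule γ = 1/(p·Var(X)) computed on the standardized training matrix,
ε = 0.1), gradient boosting (xgboost; 100 rounds, learning rate 0.1, depth
5, exact tree construction, single thread), and distance-weighted k-NN
(k = 9, Manhattan metric, weight 1/d, exact matches resolved by the plain
mean of zero-distance neighbors — the 1/d rule is undefined at d = 0). The
k-NN regressor is implemented in the package because no installed R
implementation offers distance weighting with the Manhattan metric; its
test oracle is an independent brute-force recomputation. `random_state`
defaults to 42 and fixes all three stochastic learners; a degenerate
constant training target short-circuits every algorithm to the constant.
`grid_search()` minimizes mean cross-validated MAPE over an explicit
parameter grid, enumerating candidates in grid order so ties resolve
deterministically; the grids are caller-supplied since only the selected
values, not the searched spaces, are documented in the reference design.

## Validation protocols

`eval_random_kfold()` shuffles rows with a seed into 5 near-equal folds;
rows are shuffled freely rather than stratified by participant (the less
structured reading of "5-fold cross-validation"; participant-grouped
validation is what leave-one-user-out is for).
`eval_leave_one_user_out()` holds out every row of one participant per
fold. `eval_few_day_calibration()` trains on all other participants plus
the target's chronologically first `d` days — an onboarding scenario; which
days the human study used is unstated — and tests the target's remaining
days; `d = 0` reduces exactly to leave-one-user-out. Metrics are MAE,
MAPE (denominator the true grip, which the data model keeps ≥ 1 kg), and
R² computed per fold and averaged, matching mean-(SD)-across-folds
reporting; per-participant R² in leave-one-user-out can be far below zero
when a participant's own grip barely varies, which is expected behavior of
per-fold R², not a defect. Every report carries a mean-predictor baseline
evaluated on the same splits: with no public data to compare against,
improvement relative to that baseline is the meaningful scale.

## Problem sizes and runtime choices

The test suite and the acceptance script exercise the full 21 × 5 × 10
design where only counts and determinism are measured, and scaled-down
cohorts where models are repeatedly fitted: 10 × 5 × 4 (200 rows) for the
headline evaluations, 8 × 5 × 3 across 10 seeds for the scheme-ordering
experiment, and 6 × 2 × 5 across 10 seeds for the no-signal null. These
sizes keep multi-seed experiments fast while leaving every compared effect
(baseline gap, leave-one-user-out degradation, calibration trend) far
larger than its seed-to-seed scatter.

## Known limitations

- The generator's grip-behavior link is linear-monotone by construction;
  the pipeline's performance on it says nothing about effect sizes in
  humans.
- Contact area semantics vary by device and are treated as opaque
  normalized units.
- The left-hand transform mirrors geometry but not the asymmetries of real
  left-hand motor control.
- MAPE is undefined at zero grip; the data model excludes readings below
  1 kg upstream, which also means the generator cannot represent complete
  grip failure.
- The spiral's pitch and turn count are configuration, not inferred values;
  tracing-error magnitudes depend on them.
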