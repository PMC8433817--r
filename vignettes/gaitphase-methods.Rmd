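---
title: "Methods: IMU gait-phase estimation with magnitude features and recurrent models"
author: "gaitphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IMU gait-phase estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Two inertial sensors worn above the ankles record, per leg and at 100 Hz,
tri-axial angular velocity (deg/s), tri-axial free acceleration (gravity
removed, m/s^2) and the `Mat[1][1]` element of the orientation rotation
matrix (direction cosine matrix). From these streams we want the discrete
timepoints of three gait phases per step of each leg:

* **FO (foot-off)** — the foot leaves the ground,
* **MidS (mid-swing)** — the swing-phase peak of leg angular speed,
* **FC (foot-contact)** — the foot touches down again.

Classical peak-picking on a single gyroscope axis works when walking is
steady and the sensor mounting is known, but breaks down around gait
initiation and termination, during turning, and under arbitrary sensor
orientation. The pipeline here combines an orientation-invariant feature
representation, a deterministic peak-based labeler (to produce training
labels at scale), one recurrent sequence model per phase, and a two-stage
event caller.

## Features

For each leg the three model inputs are per-frame magnitudes, each smoothed
with a Gaussian kernel:

* `AngVelMag = sqrt(Gyr_X^2 + Gyr_Y^2 + Gyr_Z^2)`
* `FreeAccMag = sqrt(FreeAcc_X^2 + FreeAcc_Y^2 + FreeAcc_Z^2)`
* `RotMatMag = sqrt(r11_left^2 + r11_right^2)` (bilateral, shared by both
  legs)

The Euclidean norm makes the first two invariant under any fixed rotation of
the sensor axes — the property that frees the method from mounting
conventions. `RotMatMag` is nearly constant while the person walks straight
and deviates while the heading changes, which is what the turning detector
uses. Because each `r11` is a direction cosine in `[-1, 1]`, `RotMatMag` is
bounded by `sqrt(2)`.

Smoothing is applied to the magnitude signals, not the raw axes: the labeler
and every downstream decision operate on "smoothed AngVelMag", and smoothing
before or after the norm are not equivalent operations (a config switch,
`smooth_raw_channels`, additionally smooths the raw axes for fidelity
experiments). Model inputs are min–max scaled to `[0, 1]` per recording;
how (or whether) the inputs should be normalized is not standardized
anywhere, so the choice is recorded in every run's metadata.

## Cleaning and smoothing

Channels are cleaned by (1) "pad" imputation — each missing sample takes the
nearest preceding value, leading gaps take the first observed value — and
(2) physical-range outlier removal at ±160 m/s² (accelerometer) and
±2000 deg/s (gyroscope), the measurement limits of this sensor class;
out-of-range samples become missing and are then pad-imputed, i.e. removed
rather than clipped.

The Gaussian smoothing kernel is specified by its full width at half
maximum, FWHM = 9 frames (90 ms at 100 Hz), converted by
`sigma = FWHM / (2 sqrt(2 ln 2)) ≈ 3.822` frames. The kernel is truncated at
4σ per side and renormalized to sum to one (so constants pass through
unchanged); edges are handled by reflection, which avoids the droop a
zero-padded convolution shows on short trials. FWHM is interpreted in
frames: at 100 Hz this gives a ~90 ms kernel, consistent with the visible
smoothing scale of gait signals.

## The peak-based labeler

On smoothed `AngVelMag` each step appears as a triple peak: a short foot-off
peak, the large mid-swing peak, and a short foot-contact peak. Labeling
proceeds:

1. **Mid-swing**: local maxima above `mids_min_prominence` (default 0.1) of
   the signal range, with closer-than-`mids_min_separation_s` (0.4 s) peaks
   suppressed in favor of the higher one. The separation rule is what rejects
   the flank peaks: within a step the flanks sit ~0.30–0.35 s from mid-swing
   (swing time is nearly speed-invariant), while successive mid-swing peaks
   of one leg are at least a full gait cycle (~0.9 s) apart.
2. **Foot-off / foot-contact**: for each mid-swing frame, the highest local
   maximum in `(mids − 0.8 s, mids)` and `(mids, mids + 0.8 s)`. Each window
   is additionally clipped at the midpoint toward the adjacent mid-swing
   peak. The clip matters: at ordinary cadence the next step's foot-off peak
   (usually the tallest flank) falls inside the raw 0.8 s window of this
   step's foot-contact, and an unclipped "most prominent" rule would label
   the wrong peak. Attributing each flank to the nearer swing resolves this
   deterministically; ties between equal maxima break toward the mid-swing
   frame. A mid-swing without both flanks (e.g. at a recording edge) is
   dropped with a message.
3. **Step types**: a step is *initial* when no step ends within `rest_gap_s`
   (2.0 s, the protocol's inter-task pause) before its foot-off, *terminal*
   when no step starts within the gap after its foot-contact, *steady*
   otherwise; a lone step is labeled terminal. The types matter because the
   morphology differs: an initial step's foot-off peak is reduced, a
   terminal step's foot-contact peak is small and is the hardest event in
   the data.
4. **Turning invalidation**: deviations of smoothed `RotMatMag` from its
   straight-walking baseline (two-pass median estimate) exceeding
   `turning_threshold` (0.25) for at least 0.5 s form turning cores; cores
   grow outward while the deviation stays above half the threshold
   (hysteresis) and are padded by 0.5 s. Both additions are needed because a
   heading sweep's deviation starts at zero: a plain threshold crossing
   covers only ~70% of a turn and lets steps at the sweep edges leak into
   the labeled set. Any step with an event frame inside a turning interval
   is invalid: it keeps its events for inspection but is excluded from the
   binary label channels. In-place stepping is not separately detected; the
   simulator can generate it, and such steps are expected to be rejected by
   the model having never seen them as positives.

All thresholds are package defaults — none is standardized — and every run
writes them into its metadata file.

The label channels are one 0/1 vector per phase with 1 exactly at the event
frames of valid steps, which by construction carry equal numbers of FO, MidS
and FC labels.

## Windows and class imbalance

Training examples are all length-251 sliding windows (2.51 s) of the three
scaled features; the target is the phase's label at the window's center
frame (0-based offset 125, the exact center). Windows never cross recording
boundaries, and events within 125 frames of a series edge cannot become
positives.

At realistic event density (roughly one labeled frame per 500), an
all-negative predictor already achieves ~0.998 frame accuracy, so training
on the raw stream (strategy `"none"`, available as the fidelity condition)
mostly rewards the all-negative answer, and frame accuracy is reported only
alongside its all-negative baseline. The desk-scale default instead
rebalances: targets are first dilated to ±2 frames of each event (an event
"occurs" at the window center up to the labeling jitter), every positive
window is kept, and negatives are undersampled at 6 per positive. Of the
kept negatives, 60% are drawn from within 170 frames of *any* truth event of
any phase — including invalid turning steps — and the rest uniformly.
These hard negatives are essential, and their band must span the adjacent
gait cycle: uniform negatives almost never include windows centered on
another phase's peak, and a model trained without them learns "some step
peak near the center" instead of "this phase's peak at the center", firing
at all three peaks of every step and at one-cycle-shifted ghost positions.
A generous negative budget also matters at activity boundaries — with too
few negatives after a terminal step, the probability trace saturates into a
plateau that drifts into the rest period and the called event lands tens of
frames late.

## The per-phase sequence models

One recurrent binary classifier per phase (FO, MidS, FC), all with the same
architecture: LSTM(30) → three LSTM(60) → LSTM(30) → Dense(1, sigmoid),
with batch normalization (momentum 0.99, epsilon 0.001) and dropout (0.2)
after every recurrent layer. All recurrent layers except the last return
per-step sequences; the last returns its final state (the standard stacking
contract — the alternative does not type-check). Training uses Adam
(learning rate 1e-4) on binary cross-entropy for up to 100 epochs; batch
size is not standardized and defaults to 64.

The recurrent stack, its backpropagation-through-time gradients, batch-norm
and dropout are implemented in compiled code inside the package (RcppArmadillo),
with correctness pinned by a finite-difference gradient check in the test
suite. Dropout masks and shuffling draw from R's RNG, so a run is
bit-reproducible from its seed. Batch normalization uses biased batch
variance and running statistics at inference; dropout is inverted (scaled at
train time, identity at inference), so the forward pass at inference is
deterministic.

The **desk_scale profile** — units 8/16/16/16/8, 10 epochs, learning rate
1e-3, batch 32, the balanced window scheme above (~8,400 windows per
phase) — trains one phase in about three minutes on one CPU core. It exists
because the full profile is a multi-hour GPU-scale run, and all
property-based validation in this package runs at desk scale. The problem
sizes used by the tests and the acceptance script are 5 training
simulations (240 valid straight-walking steps over 10 leg-recordings) and
one held-out simulation per evaluation. Initialization uses uniform Glorot
kernels with the forget-gate bias set to 2: the window center lies 125
steps before the final state that feeds the classifier, and a model whose
memory decays too fast falls back on recency patterns that alias across
gait cycles.

## Event calling and scoring

A trained model slid over a recording yields a probability trace (one value
per possible center frame). Events are called in two stages: find the
probable region, then localize on the raw signal.

* **Calling**: each local maximum of the trace at or above
  `probability_threshold` (0.5) becomes a candidate; candidates closer than
  `min_separation_s` (0.4 s) merge, keeping the higher probability. Working
  with trace peaks rather than supra-threshold regions makes the caller
  exactly monotone in the threshold (a region can split in two as the
  threshold rises; a peak set cannot grow).
* **Refinement**: each called event moves to the *nearest* local maximum of
  the raw (unsmoothed) `AngVelMag` within ±0.3 s whose height reaches 35% of
  the window maximum. Nearest, not highest: the mid-swing peak is within
  0.3 s of both flank peaks and would otherwise capture every foot-off and
  foot-contact call. The 35% floor sits above the noise floor but below the
  smallest genuine flank-to-window-maximum ratio the step morphology
  produces (an initial step's reduced foot-off against its own mid-swing,
  ~44%).

Event agreement is scored by greedy nearest-first one-to-one matching at a
±5-frame (50 ms) tolerance, yielding precision, recall, F1 and the mean
absolute timing error over matched pairs. Greedy matching equals optimal
assignment whenever reference events are separated by more than twice the
tolerance; the caller's separation merge and gait periodicity guarantee
this, and the equivalence is property-tested against an exhaustive matcher
on small instances. Event-level scores are the primary metric throughout
because frame accuracy at this event density is uninformative (see above).

## The synthetic gait simulator

No public recording accompanies the protocol this pipeline targets, so the
package ships a simulator that reproduces the protocol's structure with
exact ground truth: straight bouts at three self-selected speeds
(defaults 0.9 / 0.65 / 1.15 per-leg steps/s), 180° turns taken with small
steps between bouts, optional in-place stepping, 2.5 s rests and 3 s
standing pads. Per step, the sagittal gyroscope carries two negative
pulses — toe-off and heel-strike surrogates, sd 0.04 s — flanking a positive
swing pulse (sd 0.08 s), so `AngVelMag` shows the triple-peak shape; the
foot-off→mid-swing and mid-swing→foot-contact latencies are fixed at
0.30/0.35 s across speeds (swing time varies little with walking speed —
cadence acts on stance). Steady amplitudes are 250/400/230 deg/s
(FO/MidS/FC); an initial step's FO is 70% of steady and a terminal step's
FC is 30% of steady, reproducing the step-type morphology. Free-acceleration
bursts (3 m/s², sd 0.03 s) coincide with foot-off and foot-contact, a
smaller one with mid-swing; where these bursts should sit is not described
anywhere authoritative and is a modeling choice. `r11 = cos(heading)` on
both legs, constant in bouts and sweeping during turns. Gaussian noise is
added per channel (defaults: 10 deg/s gyroscope, 0.3 m/s² acceleration,
0.005 on the direction cosine) — scaled to the soft-tissue and sensor noise
seen in ankle-worn recordings rather than to the much smaller instrument
noise floor.

What the simulator does **not** emulate: real pulse shapes (bumps are
Gaussian, not recorded gait waveforms), inter-step and inter-subject
variability of amplitude and timing, cross-axis gyroscope content, drift, or
pathological gaits. Passing tests on simulated data therefore demonstrate
that every mechanism of the pipeline is implemented correctly and the
models can learn phase-specific temporal structure — not that the trained
weights transfer to recorded human data, which requires retraining on real
labeled recordings.

## Numerical and design notes

* Frames are 0-based throughout the public interfaces; seconds appear only
  in exported tables (`time_s = frame / rate`).
* Legs of a pair may differ in length (wireless dropouts); both are
  truncated to the shorter series with a warning rather than erroring.
* The free-acceleration magnitude norm treats a printed formula ambiguity as
  the obvious Euclidean norm of all three components.
* Equal flank maxima break toward the mid-swing frame; equal trace peaks
  break toward the earlier frame — all tie-breaks are deterministic.
* `balance_windows` with a fixed seed, the simulator with a fixed config,
  training with a fixed `train_config` and the labeler throughout are
  bit-reproducible; every pipeline run writes its resolved parameters to
  `run_metadata.json` first.
* Known limitations: no jerk-based invalidation (the "excessive jerky moves"
  criterion is not quantified anywhere), no refinement against raw `Gyr_Z`
  (only `AngVelMag`), no temporal gait parameters beyond event timestamps,
  and no in-place-stepping detector (excluded by training instead).
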