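---
title: "Methods: analysing gaze while tracking an occluded target on a circular trajectory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing gaze while tracking an occluded target on a circular trajectory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occlutrack)
```

## The task and its geometry

`occlutrack` analyses eye-tracking recordings from a visual tracking task in
which a small target moves clockwise on a circle (radius $R = 13.5^\circ$ of
visual angle, angular rate $f = 0.25$ turns/s, i.e. one cycle in 4 s and a
tangential speed $2\pi R f \approx 21^\circ$/s). On each trial the target is
visible for 1--2 s, occluded for 0--3 s (both uniform), then reappears
carrying a Landolt-C probe for 0.05 s; a 1 s feedback display follows, and
the circular motion is never interrupted.

Tracking error is decomposed in polar coordinates about the circle center:
the **radius difference** (gaze radius minus target radius, degrees) indexes
spatial error relative to the path, and the **phase difference** (gaze phase
minus target phase, in turns along the direction of motion, wrapped to
$(-0.5, 0.5]$; positive = ahead) indexes timing error. Screen pixels are
converted to degrees with the flat factor $80/1920$ (an 80-degree horizontal
field of view over 1920 pixels). This is deliberately a linear
approximation, not a true angular projection; all analyses inherit it. The
phase origin is fixed at the positive x axis -- the choice is arbitrary and
cancels in every reported quantity, which are all differences.

Three hypothetical "null strategy" trajectories provide baselines for the
positional-error time series after target disappearance: continuing along
the tangent, staying at the disappearance point (error = chord
$2R\sin(\pi f t)$), and jumping to the circle center (error $\equiv R$).

## Head-pose estimation

With a head-mounted tracker, head movement decouples eye-in-head from
gaze-on-screen coordinates. The scene camera's pose (position in screen
heights relative to the screen center; yaw, pitch, roll) is estimated from
detections of four fiducial markers taped to the screen corners, using an
unscented Kalman smoother: a random-walk transition scaled by the frame
interval, and an observation model that projects the known marker corners
through a pinhole camera. The stated noise magnitudes (position 0.01 screen
heights/s per axis, rotation 1 rad/s per axis, observation 0.05 screen
heights) are interpreted as standard deviations (per $\sqrt{s}$ for the
transition); a `interpret = "var"` switch reads them as variances instead.
At these magnitudes the results are insensitive to the reading. Observation
noise is applied in focal-normalised image coordinates after dividing by the
nominal viewing distance (`z_ref`, default 1.25 screen heights, matching
85 cm from a 55-inch screen).

Two numerical caveats are documented rather than hidden. First, with the
very permissive default rotation transition (1 rad/s), the unscented
transform's curvature correction biases the estimated depth by a few
hundredths of a screen height on static scenes; this is inherent to
sigma-point filters with large process noise, and disappears with a
transition prior matched to the actual head dynamics. Second, the default
synthetic camera uses a 100-degree field of view: at the task geometry a FOV
below about 72 degrees could never image the corner markers at all.

Gaze points recorded in scene-camera image coordinates are mapped to the
screen by back-projecting to a ray and intersecting the plane $z = 0$
(ray-intersection rather than homography; both are geometrically equivalent
for an exact pose, and the ray form degrades gracefully for oblique poses).
A per-frame nonlinear least-squares fit (`fit_pose_per_frame`) mimics the
homography-per-frame alternative; it is the baseline the smoother is
validated against, and it degrades badly when markers drop out -- the
motivation for smoothing.

## Denoising and event segmentation

The degree-scale gaze signal is partitioned into piecewise-linear segments
("naive segmented linear regression"). The implementation searches for
breakpoints by **exact dynamic programming** over shared piece boundaries,
minimising squared reconstruction error plus a per-piece penalty, with piece
lengths bounded (3--96 samples). During the search each candidate piece is
scored by the residual around the straight line through its endpoint
samples: pieces share endpoints, so the implied curve is continuous and a
saccade cannot hide inside a step discontinuity -- it must be modelled by a
short steep piece. (An earlier greedy top-down splitter with independent
per-side fits was abandoned: it routinely absorbed 2-degree catch-up
saccades into neighbouring pursuit because a discontinuous two-line fit
models a step with a single break.) Given the chosen knots, the final
continuous piecewise-linear fit is solved as a sparse hat-basis least
squares; the fitted curve is the denoised signal, and all downstream
statistics use fitted endpoints, not raw samples.

The per-piece penalty is expressed in units of the noise variance,
estimated robustly from median absolute second differences. The default
(5) was calibrated once on synthetic sessions at the default noise level
(0.3 degrees per axis) and frozen; at that setting the detected saccade
rates are within a few percent of ground truth and recovery of true
saccades (one-to-one matching on launch time, 25 ms tolerance) exceeds
90%. Runs separated by confidence gaps (pupil confidence < 0.8) or
dropped frames longer than 50 ms are segmented independently; no segment
spans a gap.

Segments are classified by Viterbi decoding of a hidden Markov model with
four internal states (fixation, pursuit, saccade, post-saccadic
oscillation) and diagonal-Gaussian emissions on log mean speed and log
duration, collapsed on output to `saccade` versus `pursuit_fixation`. The
emission and transition parameters are not specified by any external
source; they were fit once on synthetic sessions and frozen in
`hmm_config()`. Consecutive saccade-class segments merge into one saccade
*event* (absorbing post-saccadic oscillations), and events are the unit for
saccade rates and launch/landing statistics. Segments fully inside a
visible window are `visible`, fully inside an occlusion `occluded`, and
segments straddling the onset are a third `crossing` category (segments are
never split at the boundary); windows are closed-open, so a segment ending
exactly at occlusion onset is visible.

## Metrics

* **Positional error over time**: the denoised gaze is interpolated onto a
  60 samples/s grid aligned to occlusion onset; Euclidean, phase, and
  radius errors are summarised by per-time-point medians, with the three
  hypothetical baselines for reference. No extrapolation beyond observed
  data.
* **Anticipation**: phase difference at saccade launch and landing, medians
  of signed and absolute values by visibility. The per-participant
  indicator "absolute landing median exceeds absolute launch median during
  occlusion" feeds an exact two-sided binomial test (enumeration of all
  outcomes with probability not exceeding the observed one).
* **Cumulative phase coverage**: per trial and period, signed segment phase
  deltas (assumed under half a turn per segment, true at these speeds) are
  summed by class; the pursuit share at 1.5 s into the period uses
  linearly pro-rated partial segments. The class sums equal the total by
  construction, and that bookkeeping identity is asserted exactly in the
  tests.
* **Pursuit gain**: per pursuit/fixation segment, gaze phase change divided
  by target phase change ($f \times$ duration).
* **Discrimination**: success rates stratified by gaze error at reappearance
  (1.5 degrees) and occlusion duration (1 s); empty strata are missing, not
  zero.
* **Uncertainty accumulation**: occluded saccade launch points are treated
  as samples of the internal position estimate. Per participant, each
  trial's launch sequence is interpolated onto a 500-point grid; the SD
  across trials is kept where at least five traces overlap; SD is regressed
  on time for $t > 0.5$ s with a random participant intercept (lme4),
  reporting the fixed slope and marginal $R^2$ (fixed-effect variance over
  total variance), with an OLS fit alongside and a configurable participant
  exclusion list. Random slopes are not fitted by default (the reference
  analysis reports a marginal $R^2$, implying random intercepts; a random
  slope would absorb exactly the quantity being estimated on small
  cohorts).

## The synthetic observer

The generator is a stated world, not a tuning dial: its defaults encode the
behavioral regimes the analysis is designed to measure, and tests then
verify the pipeline recovers them.

* **Visible tracking**: smooth pursuit at gain 0.87 plus catch-up saccades.
  A saccade is triggered when the accrued phase lag reaches a threshold and
  lands slightly ahead of the target; threshold and overshoot derive from
  the configured rate (1.5/s) and amplitude (1.83 degrees). The triple
  (gain, rate, amplitude) is mutually constrained -- saccades must cancel
  exactly the lag accrued through sub-unity gain, $\text{rate} \times
  \text{amplitude} = (1-\text{gain}) \times 2\pi R f$ -- and 0.87 is the
  gain that makes the reported rate and amplitude consistent. Launches fall
  slightly behind and landings slightly ahead, as observed.
* **Occluded tracking**: after a first-saccade latency (uniform 0.2--0.5 s)
  during which pursuit gain decays, tracking becomes a sequence of
  anticipatory saccades landing 0.05 turns ahead of the *internal estimate*
  of target phase, separated by low-gain pursuit (gain 0.3 -- a value near
  zero would contradict the observed one-third of occluded phase covered by
  pursuit). The next saccade launches, after a 50--100 ms motor latency,
  when the internal estimate approaches the current gaze position within a
  small margin ("gaze waits for the target"); the resulting inter-saccade
  intervals give about 2.8 saccades/s. A Poisson-interval option is kept
  (`isi_mode = "poisson"`), since inter-saccade interval distributions
  during occlusion are not reported anywhere -- the trigger model is this
  package's design choice because it reproduces rate, launch and landing
  statistics simultaneously.
* **Internal-estimate noise**: the phase estimate accrues error at
  0.025 turns/s. In the default `linear` mode each trial draws a random
  clock-rate error (SD across trials then grows linearly in time, matching
  a linear regression of SD on time); a random-walk mode (SD growing with
  $\sqrt{t}$) is provided. The radius estimate is re-anchored at every
  fixation with SD 1.8 degrees -- the allocentric mechanism that makes
  radius uncertainty plateau while phase uncertainty accumulates. This
  dissociation is exactly what the uncertainty-accumulation metric must
  recover.
* **Measurement layer**: additive Gaussian noise (0.3 degrees per axis,
  a conservative figure for a head-mounted tracker's precision), pupil
  confidence with 0.5% of samples below the 0.8 threshold, 120 Hz gaze
  and 60 Hz camera sampling. Saccade kinematics are linear ramps with a
  main-sequence duration rule (21 ms + 2.2 ms/deg); real saccades have
  sigmoidal profiles, which the piecewise-linear segmenter would only see
  as slightly blurred breakpoints.
* **Discrimination**: correctness is Bernoulli with probability 0.92 when
  the reappearance error is at most 1.5 degrees and 0.51 otherwise; wrong
  responses are uniform over the other three directions (confusion
  structure is unreported).
* **Camera**: head pose follows a slow random walk; the four corner markers
  project through the pinhole model with pixel noise and per-marker
  dropout (default 20%), emulating markers leaving the field of view.

What a green test does *not* establish: the generator contains no blinks,
no eyelid dynamics, no saccadic curvature or dynamic overshoot, no
participant heterogeneity in gains or rates, and its noise is Gaussian and
stationary. Agreement on synthetic sessions validates the pipeline's
internal consistency and parameter recovery, not its behavior on any real
recording.

## Numerical choices and degenerate inputs

* Gaze exactly at the circle center has undefined phase; it is propagated
  as missing and skipped by summaries rather than raising.
* Phase wrapping maps differences to $(-0.5, 0.5]$, with the boundary tie
  assigned to $+0.5$.
* The hat-basis refit adds a $10^{-10}$ ridge for numerical safety.
* Runs shorter than two samples become degenerate single-sample pieces,
  flagged and excluded from statistics.
* Trials whose occlusion is shorter than the first-saccade latency produce
  no occluded saccades and simply contribute no launch trace.
* The unscented transform uses the conventional $\alpha = 10^{-3}$,
  $\beta = 2$, $\kappa = 0$; the transition being linear, the prediction
  step is exact and only the observation update uses sigma points, and the
  backward pass is a standard Rauch-Tung-Striebel sweep.

## Known limitations

* The flat pixel-to-degree approximation overestimates eccentric angles;
  it is kept deliberately for comparability.
* The exact settings of the original third-party segmenter and classifier
  are unpublished; equivalence is targeted at the statistics level, not
  per-segment.
* No real recordings are redistributed here, and the exact on-disk layout
  of archived recordings from this paradigm varies by acquisition stack;
  `read_session()` defines a native schema and the loader rejects
  mismatches with row-level diagnostics rather than guessing.
* With fewer than two launches in a trial no trace can be interpolated, so
  very short occlusions are underrepresented in the SD curves -- as in any
  launch-based analysis.
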