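# occlutrack

Analysis of gaze behavior while tracking a target that moves on a circular
trajectory and is intermittently occluded.

## The problem

When people visually track a moving object that disappears behind an
occluder, smooth pursuit — the slow eye movement that normally matches gaze
velocity to target velocity — largely stops, and tracking continues as a
sequence of *anticipatory saccades* that land ahead of the (invisible)
target and wait for it. Quantifying this regime change requires a full
processing chain: estimating head pose from fiducial markers so gaze can be
expressed in screen coordinates, denoising and segmenting the gaze signal
into saccades versus pursuit/fixation, and decomposing tracking error into
components that separate *where the path is* from *where on the path the
target is*.

`occlutrack` implements that chain for the circular-tracking paradigm:
a target on a circle of radius R = 13.5° moving at f = 0.25 turns/s
(tangential speed 2πRf ≈ 21°/s), visible 1–2 s, occluded 0–3 s, followed by
a brief Landolt-C discrimination probe. Gaze is decomposed about the circle
center into the **phase difference** Δφ (turns along the motion; positive =
gaze ahead; timing error) and the **radius difference** Δr (degrees;
spatial error relative to the path). Key statistics:

* saccade rates and amplitudes by visibility; launch/landing phase
  differences (anticipation) with an exact two-sided binomial test across
  participants;
* cumulative phase covered by pursuit versus saccades, and the pursuit
  share after 1.5 s of tracking;
* pursuit gain g = Δφ_gaze / Δφ_target per segment;
* positional error over occlusion time against three hypothetical
  baselines (tangent, stay, center);
* accumulation of uncertainty: SD of Δφ and Δr across trials at saccade
  launches, interpolated onto a 500-point grid, regressed on time
  (t > 0.5 s) with random participant intercepts — the signature finding
  being that phase SD grows (~0.025 turns/s) while radius SD plateaus,
  consistent with an allocentrically anchored internal estimate.

Because the deposited recordings are not bundled, a first-class
synthetic-data module generates complete sessions (schedules, oculomotor
gaze traces, discrimination responses, head-pose drift and marker
detections) with exactly these statistical regimes, so the entire pipeline
is testable offline. See the methods vignette
(`vignettes/occluded-tracking-methods.Rmd`) for models, assumptions and
design decisions.

## Worked example

```r
library(occlutrack)

dir <- tempfile("session")
simulate_session(dir, n_trials = 30, seed = 42)   # write a synthetic bundle
res <- run_pipeline(dir)                          # full analysis
str(res$summary[c("saccade_rate_visible", "saccade_rate_occluded",
                  "mean_error_at_reappear", "pursuit_share")])
```

```
List of 4
 $ saccade_rate_visible  : num 1.41
 $ saccade_rate_occluded : num 2.83
 $ mean_error_at_reappear: num 2.96
 $ pursuit_share         :List of 2
  ..$ occluded: num 0.267
  ..$ visible : num 0.809
```

Reading: while the target is visible the synthetic observer makes ~1.4
catch-up saccades/s and pursuit covers ~81% of the phase angle; during
occlusion the saccade rate doubles (~2.8/s) while the pursuit share drops
below 30%, and gaze is still only ~3° from the target when it reappears —
tracking survives occlusion, but its oculomotor basis changes from pursuit
to anticipatory saccades.

The cohort-level uncertainty analysis:

```r
cfg <- task_config()
cohort <- simulate_cohort(10, 30, seed = 7)
launches <- data.table::rbindlist(lapply(cohort, function(s)
  launch_table(s$saccades, s$trials, cfg, s$participant_id)))
ua <- uncertainty_accumulation(launches)
ua$regression$phase$slope    # 0.0269 turns/s  (generator configured 0.025)
ua$regression$radius$slope   # -0.065 deg/s    (radius SD plateaus)
```

A command-line interface wraps the same stages
(`simulate`, `headpose`, `segment`, `analyze`, `report`); see
`?occlutrack_cli`.

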