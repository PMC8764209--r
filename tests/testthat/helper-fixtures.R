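# Shared small fixtures; everything is generated in code.

default_cfg <- function() task_config()

# Point on the default circle at a given phase (turns) and radius (deg).
polar_to_xy_pub <- function(phase, radius) {
  a <- 2 * pi * phase
  data.frame(x = radius * cos(a), y = -radius * sin(a))
}

# One-to-one greedy matching of detected saccade events to ground truth by
# launch-time proximity; returns a logical hit vector over the truth rows.
match_saccades <- function(events, truth, tol = 0.025) {
  used <- rep(FALSE, nrow(events))
  hit <- logical(nrow(truth))
  for (i in order(truth$t_launch)) {
    d <- abs(events$t_launch - truth$t_launch[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol) { hit[i] <- TRUE; used[j] <- TRUE }
  }
  hit
}

# A compact session used by several test files: enough trials for stable
# statistics but small enough to keep the suite fast.
small_session <- function(n_trials = 12, seed = 42, params = oculomotor_params()) {
  cfg <- default_cfg()
  sched <- generate_schedule(n_trials, cfg, seed = seed)
  gaze <- simulate_gaze(sched, params, cfg, seed = seed + 1)
  list(cfg = cfg, schedule = sched, gaze = gaze, params = params)
}
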