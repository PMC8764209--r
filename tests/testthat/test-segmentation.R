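cfg <- task_config()

test_that("confidence filter drops exactly the sub-threshold samples", {
  s <- data.table::data.table(t = seq(0, 9.99, by = 0.01),
                              x = 0, y = 0, confidence = 1)
  expect_equal(nrow(confidence_filter(s)), 1000)   # all confident: identity
  set.seed(31)
  low <- sample(1000, 5)
  s$confidence[low] <- runif(5, 0, 0.79)
  f <- confidence_filter(s)
  expect_equal(nrow(f), 995)
  expect_equal(attr(f, "n_dropped"), 5L)
  expect_equal(nrow(confidence_filter(s, threshold = 0)), 1000)
  s$confidence <- 0.1
  expect_error(confidence_filter(s), "confidence threshold")
})

test_that("segmentation finds exact breakpoints on constructed inputs", {
  # noise-free two-slope trace: exactly 2 segments, breakpoint within a sample
  t <- seq(0, 1, by = 1 / 120)
  x <- ifelse(t < 0.5, 2 * t, 1 + 30 * (t - 0.5))
  r <- segment_nslr(data.table::data.table(t = t, x = x, y = 0))
  expect_equal(nrow(r$segments), 2)
  expect_lt(abs(r$segments$t_end[1] - 0.5), 1 / 120 + 1e-9)
  # constant position with small noise: a single segment
  set.seed(32)
  r2 <- segment_nslr(data.table::data.table(
    t = t, x = rnorm(length(t), 0, 0.1), y = rnorm(length(t), 0, 0.1)))
  expect_equal(nrow(r2$segments), 1)
})

test_that("runs are split at gaps and degenerate runs flagged", {
  t <- c(seq(0, 0.5, by = 1 / 120), 1, seq(2, 2.5, by = 1 / 120))
  n <- length(t)
  r <- segment_nslr(data.table::data.table(t = t, x = rep(0, n), y = 0))
  expect_true(any(r$segments$degenerate))       # the isolated sample at t = 1
  expect_false(any(r$segments$t_start < 1 & r$segments$t_end > 1 &
                     !r$segments$degenerate))   # no segment spans the gap
  # partition property: non-degenerate segments tile each run
  seg <- r$segments[!r$segments$degenerate]
  for (run_start in c(0, 2)) {
    ss <- seg[seg$t_start >= run_start - 1e-9 & seg$t_end <= run_start + 0.5 + 1e-9]
    expect_equal(ss$t_start[-1], ss$t_end[-nrow(ss)])
  }
})

test_that("increasing the penalty never increases the segment count", {
  s <- small_session(n_trials = 3, seed = 33)
  g <- confidence_filter(s$gaze$samples)
  counts <- vapply(c(2, 5, 10, 20, 40), function(pen)
    nrow(segment_nslr(g[, c("t", "x", "y")], penalty = pen)$segments), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("classification separates unambiguous feature regions", {
  seg <- data.table::data.table(
    segment_id = 1:3,
    t_start = c(0, 0.5, 0.54), t_end = c(0.5, 0.54, 1.1),
    x0 = 0, y0 = 0, x1 = 1, y1 = 0,
    amplitude_deg = c(0.3, 12, 0.4),
    mean_speed_dps = c(0.5, 300, 0.6),
    duration = c(0.5, 0.04, 0.56),
    n_samples = c(60, 5, 67), degenerate = FALSE)
  cl <- classify_segments(seg)
  expect_equal(cl$class, c("pursuit_fixation", "saccade", "pursuit_fixation"))
  # an all-fixation trace yields zero saccades
  slow <- data.table::data.table(
    segment_id = 1:10, t_start = (0:9) / 2, t_end = (1:10) / 2,
    x0 = 0, y0 = 0, x1 = 0.1, y1 = 0, amplitude_deg = 0.25,
    mean_speed_dps = 0.5, duration = 0.5, n_samples = 60, degenerate = FALSE)
  expect_true(all(classify_segments(slow)$class == "pursuit_fixation"))
})

test_that("saccade recovery, reconstruction and rates on default sessions", {
  s <- small_session(n_trials = 25, seed = 34)
  g <- confidence_filter(s$gaze$samples)
  segres <- segment_nslr(g[, c("t", "x", "y")])
  # reconstruction: fitted curve close to the noise-free path
  mer <- merge(segres$fitted, s$gaze$samples[, c("t", "x_true", "y_true")],
               by = "t")
  rms <- sqrt(mean((mer$x - mer$x_true)^2 + (mer$y - mer$y_true)^2))
  expect_lt(rms, 1.5 * s$params$measurement_noise_sd)

  seg <- assign_visibility(classify_segments(segres$segments), s$gaze$trials)
  ev <- saccade_events(seg)
  truth <- s$gaze$saccades
  hit <- match_saccades(ev, truth, tol = 0.025)
  expect_gte(mean(hit), 0.9)
  # detected rates within 20% of the generator's realized rates
  vt <- sum(s$schedule$visible_duration); ot <- sum(s$schedule$occl_duration)
  for (vv in c("visible", "occluded")) {
    det <- sum(ev$visibility == vv) / (if (vv == "visible") vt else ot)
    tru <- sum(truth$visibility == vv) / (if (vv == "visible") vt else ot)
    expect_lt(abs(det - tru) / tru, 0.2)
  }
})

test_that("visibility assignment follows the closed-open window rules", {
  tr <- data.table::data.table(trial_id = 1L, t_visible_on = 0,
                               t_occl_on = 1.5, t_reappear = 2.5)
  seg <- data.table::data.table(
    segment_id = 1:5,
    t_start = c(0.1, 1.4, 1.6, 1.0, 2.6),
    t_end = c(0.4, 1.7, 2.0, 1.5, 2.9),
    x0 = 0, y0 = 0, x1 = 1, y1 = 1, amplitude_deg = 1, mean_speed_dps = 1,
    duration = 0.3, n_samples = 30, degenerate = FALSE, class = "saccade")
  av <- assign_visibility(seg, tr)
  expect_equal(av$visibility,
               c("visible",   # fully inside the visible window
                 "crossing",  # spans occlusion onset
                 "occluded",  # fully inside the occlusion
                 "visible",   # ends exactly at occlusion onset
                 "other"))    # outside any trial window (feedback)
})
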