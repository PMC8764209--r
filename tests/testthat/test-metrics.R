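cfg <- task_config()

test_that("binom_test_exact matches enumeration and stats::binom.test", {
  expect_equal(binom_test_exact(9, 10, 0.5), 22 / 1024, tolerance = 1e-12)
  expect_equal(binom_test_exact(10, 10, 0.5), 2 / 1024, tolerance = 1e-12)
  expect_equal(binom_test_exact(5, 10, 0.5), 1)
  expect_error(binom_test_exact(0, 0))
  # oracle loop: all (k, n, p0) up to n = 25 against stats::binom.test
  for (n in c(1, 2, 5, 10, 17, 25)) for (p0 in c(0.3, 0.5, 0.62))
    for (k in 0:n)
      expect_equal(binom_test_exact(k, n, p0),
                   stats::binom.test(k, n, p0)$p.value, tolerance = 1e-9)
})

test_that("error_timeseries reproduces closed-form baselines", {
  # gaze frozen at the disappearance point equals the 'stay' curve
  tr <- data.table::data.table(trial_id = 1L, t_visible_on = 0, t_occl_on = 2,
                               t_reappear = 5, occl_duration = 3)
  p0 <- object_position(2, cfg)
  tt <- seq(0, 5, by = 1 / 120)
  frozen <- data.table::data.table(
    t = tt, x = ifelse(tt < 2, object_position(tt, cfg)$x, p0$x),
    y = ifelse(tt < 2, object_position(tt, cfg)$y, p0$y))
  et <- error_timeseries(frozen, tr, cfg)
  occl <- et$traces[et$traces$t_rel >= 0]
  stay <- hypothetical_trajectory("stay", occl$t_rel, cfg, phase_occl = p0$phase)
  expect_equal(occl$euclidean, stay$error_deg, tolerance = 1e-6)
  # perfect tracking: zero error everywhere
  perfect <- data.table::data.table(t = tt, x = object_position(tt, cfg)$x,
                                    y = object_position(tt, cfg)$y)
  ep <- error_timeseries(perfect, tr, cfg)
  expect_lt(max(ep$traces$euclidean), 1e-9)
  # no extrapolation: grid limited to the observed range
  expect_lte(max(et$traces$t_rel), 3)
  expect_gte(min(et$traces$t_rel), -1)
})

test_that("saccade anticipation medians and binomial test", {
  s <- small_session(n_trials = 20, seed = 41)
  sac <- data.table::as.data.table(s$gaze$saccades)
  sac[, `:=`(participant_id = 1L)]
  ant <- saccade_anticipation(sac, cfg)
  med <- ant$medians
  occ <- med[med$visibility == "occluded", ]
  vis <- med[med$visibility == "visible", ]
  expect_gt(occ$land_abs_med, occ$launch_abs_med)  # landings lead more
  expect_lt(abs(occ$land_med - 0.05), 0.02)
  expect_lt(abs(vis$land_med), 0.02)
  # p-values for the per-participant indicator counts
  expect_equal(round(binom_test_exact(9, 10, 0.5), 3), 0.021)
  expect_equal(round(binom_test_exact(10, 10, 0.5), 3), 0.002)
})

test_that("phase coverage conserves bookkeeping and separates regimes", {
  s <- small_session(n_trials = 15, seed = 42)
  g <- confidence_filter(s$gaze$samples)
  segres <- segment_nslr(g[, c("t", "x", "y")])
  seg <- assign_visibility(classify_segments(segres$segments), s$gaze$trials)
  cov <- cumulative_phase_coverage(seg, s$gaze$trials, cfg)
  # conservation: per-trial class sums equal the total (exact bookkeeping)
  pt <- cov$per_trial
  expect_equal(pt$pursuit_phase + pt$saccade_phase, pt$total_phase,
               tolerance = 1e-9)
  # the headline dissociation: pursuit covers the majority when visible,
  # a minority when occluded
  sh <- cov$shares
  expect_gt(sh$median_share[sh$period == "visible"], 0.5)
  expect_lt(sh$median_share[sh$period == "occluded"], 0.5)
})

test_that("pursuit gain recovers configured gains per regime", {
  s <- small_session(n_trials = 15, seed = 43)
  g <- confidence_filter(s$gaze$samples)
  segres <- segment_nslr(g[, c("t", "x", "y")])
  seg <- assign_visibility(classify_segments(segres$segments), s$gaze$trials)
  gn <- pursuit_gain(seg, cfg)
  visible_gain <- median(gn$gain[gn$visibility == "visible"])
  occl_gain <- median(gn$gain[gn$visibility == "occluded"])
  expect_lt(abs(visible_gain - s$params$visible_gain), 0.1)
  expect_lt(abs(occl_gain - s$params$occl_pursuit_gain), 0.12)
  expect_gt(visible_gain, occl_gain)
  # trivial cases on constructed segments
  mk_seg <- function(gain) {
    t0 <- 1; dur <- 0.4
    ph0 <- object_position(t0, cfg)$phase
    p0 <- polar_to_xy_pub(ph0, 13.5)
    p1 <- polar_to_xy_pub((ph0 + gain * cfg$rate_tps * dur) %% 1, 13.5)
    data.table::data.table(segment_id = 1L, trial_id = 1L, t_start = t0,
                           t_end = t0 + dur, x0 = p0$x, y0 = p0$y, x1 = p1$x,
                           y1 = p1$y, amplitude_deg = 1, mean_speed_dps = 10,
                           duration = dur, n_samples = 48, degenerate = FALSE,
                           class = "pursuit_fixation", visibility = "visible")
  }
  expect_equal(pursuit_gain(mk_seg(1), cfg)$gain, 1, tolerance = 1e-9)
  expect_equal(pursuit_gain(mk_seg(0), cfg)$gain, 0, tolerance = 1e-9)
})

test_that("discrimination summary stratifies correctly", {
  tr <- data.table::data.table(
    trial_id = 1:8, correct = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    error_at_reappear = c(0.5, 1.0, 2.0, 5.0, 1.2, 8.0, 0.3, 3.0),
    occl_duration = c(0.5, 0.8, 1.5, 2.0, 0.2, 2.5, 0.9, 1.2))
  ds <- discrimination_summary(tr)
  expect_equal(ds$overall, 6 / 8)
  expect_equal(ds$near, 1)          # errors <= 1.5: all correct
  expect_equal(ds$far, 2 / 4)
  expect_equal(ds$short_occl, 4 / 4)
  expect_equal(ds$long_occl, 2 / 4)
  expect_equal(ds$mean_error_correct, mean(c(0.5, 1, 2, 1.2, 0.3, 3)))
  # all-correct and empty-stratum behavior
  tr2 <- data.table::copy(tr); tr2$correct <- TRUE
  tr2$error_at_reappear <- 0.5
  ds2 <- discrimination_summary(tr2)
  expect_equal(ds2$overall, 1)
  expect_true(is.na(ds2$far))       # empty stratum reported missing
})

test_that("uncertainty accumulation recovers drift and the dissociation", {
  # zero drift: phase slope near zero
  p0 <- oculomotor_params(phase_drift_sd_rate = 0)
  coh0 <- simulate_cohort(4, 12, params = p0, seed = 44)
  la0 <- data.table::rbindlist(lapply(coh0, function(s)
    launch_table(s$saccades, s$trials, cfg, s$participant_id)))
  ua0 <- uncertainty_accumulation(la0, min_trials = 3)
  expect_lt(abs(ua0$regression$phase$slope), 0.01)
  # configured drift recovered on a scaled-down cohort (wider band than the
  # full 10 x 30 acceptance criterion, reflecting the smaller n)
  coh <- simulate_cohort(5, 25, seed = 45)
  la <- data.table::rbindlist(lapply(coh, function(s)
    launch_table(s$saccades, s$trials, cfg, s$participant_id)))
  ua <- uncertainty_accumulation(la)
  expect_lt(abs(ua$regression$phase$slope - 0.025) / 0.025, 0.4)
  # radius re-anchoring: radius SD slope much smaller than phase SD slope
  # (slopes are on different scales; compare normalised by typical SD)
  expect_gt(ua$regression$phase$slope / mean(ua$curves$sd_phase),
            ua$regression$radius$slope / mean(ua$curves$sd_radius))
  # interpolation never extrapolates: no curve point beyond the longest launch
  expect_lte(max(ua$curves$t), max(la$t_since_occl) + 1e-9)
  # below the trace minimum: skipped with a warning
  expect_warning(
    uncertainty_accumulation(la[la$participant_id == 1 & la$trial_id <= 3]),
    "skipped")
})
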