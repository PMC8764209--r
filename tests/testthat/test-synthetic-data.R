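cfg <- task_config()

test_that("generate_schedule draws a well-ordered continuous timeline", {
  sch <- generate_schedule(30, cfg, seed = 1)
  expect_equal(nrow(sch), 30)
  expect_true(all(sch$visible_duration >= 1 & sch$visible_duration <= 2))
  expect_true(all(sch$occl_duration >= 0 & sch$occl_duration <= 3))
  expect_true(all(sch$t_visible_on < sch$t_occl_on))
  expect_true(all(sch$t_occl_on <= sch$t_reappear))
  # timeline conservation: next trial starts right after probe + feedback
  expect_equal(sch$t_visible_on[-1],
               sch$t_reappear[-30] + cfg$probe_duration + cfg$feedback_duration,
               tolerance = 1e-12)
  expect_equal(nrow(generate_schedule(1, cfg, seed = 2)), 1)
  # uniform-distribution moments at large n (3 SE band)
  big <- generate_schedule(10000, cfg, seed = 3)
  se <- (3 / sqrt(12)) / sqrt(10000)
  expect_lt(abs(mean(big$occl_duration) - 1.5), 3 * se)
})

test_that("noise-free unity-gain observer reproduces the target exactly", {
  cfg0 <- task_config(occlusion_range = c(0, 0))
  p0 <- oculomotor_params(visible_gain = 1, visible_saccade_rate = 0,
                          occl_pursuit_gain = 1, phase_drift_sd_rate = 0,
                          measurement_noise_sd = 0, low_conf_fraction = 0,
                          visible_radius_sd = 0)
  sch <- generate_schedule(4, cfg0, seed = 4)
  ses <- simulate_gaze(sch, p0, cfg0, seed = 5)
  # restrict to visible windows
  idx <- rep(FALSE, nrow(ses$samples))
  for (i in seq_len(nrow(sch)))
    idx <- idx | (ses$samples$t >= sch$t_visible_on[i] &
                    ses$samples$t < sch$t_occl_on[i])
  obj <- object_position(ses$samples$t[idx], cfg0)
  expect_lt(max(abs(ses$samples$x[idx] - obj$x)), 1e-9)
  expect_lt(max(abs(ses$samples$y[idx] - obj$y)), 1e-9)
})

test_that("default occluded saccade statistics match the emulated regime", {
  sch <- generate_schedule(90, cfg, seed = 6)
  ses <- simulate_gaze(sch, oculomotor_params(), cfg, seed = 7)
  sac <- ses$saccades
  occ_rate <- sum(sac$visibility == "occluded") / sum(sch$occl_duration)
  expect_lt(abs(occ_rate - 2.88) / 2.88, 0.2)
  vis_rate <- sum(sac$visibility == "visible") / sum(sch$visible_duration)
  expect_lt(abs(vis_rate - 1.5) / 1.5, 0.2)
  # anticipatory landing: occluded saccades land about 0.05 turns ahead
  o <- sac$visibility == "occluded"
  pl <- polar_decompose(sac$x1[o], sac$y1[o], cfg)
  ob <- object_position(sac$t_land[o], cfg)
  land <- wrap_phase_diff(pl$phase - ob$phase)
  expect_lt(abs(median(land) - 0.05), 0.02)
  # launches near the target position
  pl0 <- polar_decompose(sac$x0[o], sac$y0[o], cfg)
  ob0 <- object_position(sac$t_launch[o], cfg)
  expect_lt(abs(median(wrap_phase_diff(pl0$phase - ob0$phase))), 0.02)
  # first-saccade latency in the configured range
  first <- ses$saccades[ses$saccades$visibility == "occluded", ]
  lat <- vapply(seq_len(nrow(sch)), function(i) {
    ts <- first$t_launch[first$t_launch >= sch$t_occl_on[i] &
                           first$t_launch < sch$t_reappear[i]]
    if (length(ts)) min(ts) - sch$t_occl_on[i] else NA_real_
  }, 0)
  lat <- lat[!is.na(lat)]
  expect_true(all(lat >= 0.19 & lat <= 0.52))
})

test_that("ground-truth events partition the session; confidence as configured", {
  s <- small_session(n_trials = 8, seed = 8)
  ev <- s$gaze$events
  expect_true(all(abs(ev$t_start[-1] - ev$t_end[-nrow(ev)]) < 1e-9))
  expect_gte(min(s$gaze$samples$t), 0)
  expect_lte(max(s$gaze$samples$t), max(ev$t_end))
  # every sample is inside exactly one event (partition + coverage)
  counts <- findInterval(s$gaze$samples$t, ev$t_start)
  expect_true(all(counts >= 1 & counts <= nrow(ev)))
  expect_lt(abs(mean(s$gaze$samples$confidence < 0.8) - 0.005), 0.01)
})

test_that("generators are reproducible under a fixed seed", {
  a <- simulate_gaze(generate_schedule(5, cfg, seed = 9),
                     oculomotor_params(), cfg, seed = 10)
  b <- simulate_gaze(generate_schedule(5, cfg, seed = 9),
                     oculomotor_params(), cfg, seed = 10)
  expect_identical(a$samples, b$samples)
  expect_identical(a$saccades, b$saccades)
  cam_a <- simulate_camera(1, seed = 11)
  cam_b <- simulate_camera(1, seed = 11)
  expect_identical(cam_a$markers, cam_b$markers)
})

test_that("simulate_response follows the two-rate correctness model", {
  tr <- generate_schedule(10000, cfg, seed = 12)
  # error 0 with p_near = 1: always correct
  r0 <- simulate_response(tr[1:50], error = rep(0, 50),
                          model = list(p_near = 1, p_far = 0.51, threshold = 1.5),
                          seed = 13)
  expect_true(all(r0$correct))
  expect_true(all(r0$response == r0$probe_direction))
  # error 1 deg at defaults: 92% within 3 binomial SE
  r1 <- simulate_response(tr, error = rep(1, nrow(tr)), seed = 14)
  expect_lt(abs(mean(r1$correct) - 0.92), 3 * sqrt(0.92 * 0.08 / nrow(tr)))
  # error 10 deg: about 51%
  r2 <- simulate_response(tr, error = rep(10, nrow(tr)), seed = 15)
  expect_lt(abs(mean(r2$correct) - 0.51), 3 * sqrt(0.51 * 0.49 / nrow(tr)))
  # wrong responses never equal the probe direction
  expect_true(all(r2$response[!r2$correct] != r2$probe_direction[!r2$correct]))
})

test_that("simulate_camera produces the configured dropout and noise", {
  lay <- marker_layout(); cam <- camera_model()
  sim <- simulate_camera(20, list(drop_frac = 0.1, obs_noise_px = 1.5,
                                  walk_pos_sd = 0, walk_rot_sd = 0), seed = 16)
  # about 10% of marker slots dropped (binomial band)
  n_slots <- nrow(sim$pose) * 4
  n_obs <- nrow(unique(sim$markers[, c("t", "marker_id")]))
  p_drop <- 1 - n_obs / n_slots
  expect_lt(abs(p_drop - 0.1), 3 * sqrt(0.1 * 0.9 / n_slots) + 0.01)
  # reprojection residuals have the configured SD within 10%
  tru <- project_markers(as.numeric(sim$pose[1, 2:7]), cam, lay)
  mk <- merge(sim$markers, cbind(lay, tru), by = c("marker_id", "corner_id"))
  resid <- c(mk$u.x - mk$u.y, mk$v.x - mk$v.y)
  expect_lt(abs(sd(resid) - 1.5) / 1.5, 0.1)
})
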