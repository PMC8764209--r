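cam <- camera_model()
lay <- marker_layout()

test_that("pinhole projection matches an independently coded oracle", {
  # camera square-on over a corner: that corner projects to the principal point
  crn <- data.frame(x = -8 / 9, y = -0.5)
  pr <- project_markers(c(-8 / 9, -0.5, 1.25, 0, 0, 0), cam, crn)
  expect_equal(c(pr$u, pr$v), cam$principal_point, tolerance = 1e-9)

  # doubling the focal doubles offsets from the principal point
  cam2 <- cam; cam2$focal <- 2 * cam$focal
  p <- c(0.05, -0.1, 1.3, 0.08, -0.05, 0.1)
  a <- project_markers(p, cam, lay); b <- project_markers(p, cam2, lay)
  expect_equal(b$u - cam$principal_point[1],
               2 * (a$u - cam$principal_point[1]), tolerance = 1e-9)

  # brute-force oracle: explicit rotation matrices and perspective divide
  oracle <- function(pose, pts) {
    cy <- cos(pose[4]); sy <- sin(pose[4])
    cp <- cos(pose[5]); sp <- sin(pose[5])
    cr <- cos(pose[6]); sr <- sin(pose[6])
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
    Rx <- matrix(c(1, 0, 0, 0, cp, sp, 0, -sp, cp), 3)
    Rz <- matrix(c(cr, sr, 0, -sr, cr, 0, 0, 0, 1), 3)
    R <- Ry %*% Rx %*% Rz
    t(apply(pts, 1, function(w) {
      cc <- diag(c(1, -1, -1)) %*% t(R) %*% (w - pose[1:3])
      c(cam$focal * cc[1] / cc[3], cam$focal * cc[2] / cc[3]) +
        cam$principal_point
    }))
  }
  set.seed(21)
  for (rep in 1:5) {
    pose <- c(runif(2, -0.3, 0.3), runif(1, 1, 1.6), runif(3, -0.3, 0.3))
    pts <- cbind(runif(6, -0.9, 0.9), runif(6, -0.5, 0.5), 0)
    pr <- project_markers(pose, cam, data.frame(x = pts[, 1], y = pts[, 2]))
    ora <- oracle(pose, pts)
    expect_equal(cbind(pr$u, pr$v), ora, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  # corner behind the projection plane is flagged invalid
  behind <- project_markers(c(0, 0, -1, 0, 0, 0), cam, data.frame(x = 0, y = 0))
  expect_false(behind$valid)
})

test_that("gaze mapping inverts projection and shifts with translation", {
  # gaze at principal point, camera facing screen center square-on
  ctr <- map_gaze_to_screen(cam$principal_point[1], cam$principal_point[2],
                            c(0, 0, 1.25, 0, 0, 0), cam)
  expect_equal(c(ctr$x_sh, ctr$y_sh), c(0, 0), tolerance = 1e-12)
  # round trip: project a screen point, map it back
  set.seed(22)
  for (rep in 1:5) {
    pose <- c(runif(2, -0.2, 0.2), runif(1, 1.1, 1.5), runif(3, -0.2, 0.2))
    pt <- c(runif(1, -0.8, 0.8), runif(1, -0.45, 0.45))
    pr <- project_markers(pose, cam, data.frame(x = pt[1], y = pt[2]))
    back <- map_gaze_to_screen(pr$u, pr$v, pose, cam)
    expect_equal(c(back$x_sh, back$y_sh), pt, tolerance = 1e-9)
  }
  # frontoparallel translation shifts the intersection the opposite way:
  # the same image point then corresponds to a translated screen point
  g0 <- map_gaze_to_screen(700, 400, c(0, 0, 1.25, 0, 0, 0), cam)
  g1 <- map_gaze_to_screen(700, 400, c(0.1, -0.05, 1.25, 0, 0, 0), cam)
  expect_equal(g1$x_sh - g0$x_sh, 0.1, tolerance = 1e-9)
  expect_equal(g1$y_sh - g0$y_sh, -0.05, tolerance = 1e-9)
  # ray away from the screen is invalid
  away <- map_gaze_to_screen(cam$principal_point[1], cam$principal_point[2],
                             c(0, 0, 1.25, 0, pi, 0), cam)
  expect_false(away$valid)
})

test_that("smoother recovers a static scene and stays constant", {
  sim <- simulate_camera(2, list(walk_pos_sd = 0, walk_rot_sd = 0,
                                 obs_noise_px = 0, drop_frac = 0), seed = 23)
  nm <- noise_config(pos_rate = 1e-3, rot_rate = 1e-3, obs_sd = 1e-3)
  sm <- uks_smooth(sim$markers, lay, cam, noise = nm)
  err <- as.matrix(sm[, 2:7]) - as.matrix(sim$pose[, 2:7])
  expect_lt(max(abs(err)), 1e-4)
  # constant: frame-to-frame variation negligible (far below any physical
  # head motion; the Bayes filter retains a slow sub-1e-4 convergence drift)
  expect_lt(max(abs(apply(as.matrix(sm[, 2:7]), 2, diff))), 1e-4)
})

test_that("smoothing beats filtering beats per-frame fits on dropout streams", {
  sim <- simulate_camera(8, list(), seed = 24)
  nm <- noise_config(pos_rate = 0.02, rot_rate = 0.03,
                     obs_sd = 2 / cam$focal * 1.25)
  sm <- uks_smooth(sim$markers, lay, cam, noise = nm, times = sim$pose$t,
                   return_filter = TRUE)
  pf <- fit_pose_per_frame(sim$markers, lay, cam)
  idx <- match(round(pf$t, 9), round(sim$pose$t, 9))
  tru <- as.matrix(sim$pose[, 2:7])
  rmse <- function(m, rows, cols) sqrt(mean(rowSums(
    (m[rows, cols, drop = FALSE] - tru[rows, cols, drop = FALSE])^2)))
  sm_m <- as.matrix(sm[, 2:7]); fl_m <- as.matrix(sm[, 8:13])
  pf_m <- matrix(NA_real_, nrow(tru), 6); pf_m[idx, ] <- as.matrix(pf[, 2:7])
  rows <- which(rowSums(is.na(pf_m)) == 0)
  expect_lt(rmse(sm_m, rows, 1:3), rmse(fl_m, rows, 1:3))
  expect_lt(rmse(fl_m, rows, 1:3), rmse(pf_m, rows, 1:3))
  expect_lt(rmse(sm_m, rows, 4:6), rmse(fl_m, rows, 4:6))
  expect_lt(rmse(fl_m, rows, 4:6), rmse(pf_m, rows, 4:6))

  # no high-frequency noise: variance of frame-to-frame steps far below the
  # per-frame fit's
  step_var <- function(m) mean(apply(m[rows, ], 2, function(v) var(diff(v))))
  expect_lt(step_var(sm_m), 0.01 * step_var(pf_m))

  # smoother consistency: joint log-density of the smoothed trajectory under
  # the generative model is at least the filter's
  joint_ld <- function(m) {
    dt <- diff(sim$pose$t)
    q <- c(rep(nm$q_pos, 3), rep(nm$q_rot, 3))
    ld <- 0
    for (k in 2:nrow(m))
      ld <- ld + sum(stats::dnorm(m[k, ], m[k - 1, ], sqrt(q * dt[k - 1]),
                                  log = TRUE))
    fo <- occlutrack:::frame_observations(sim$markers, lay)
    for (k in seq_along(fo$times)) {
      fr <- fo$frames[[k]]
      i <- match(round(fo$times[k], 9), round(sim$pose$t, 9))
      pr <- project_markers(m[i, ], cam, fr)
      ld <- ld + sum(stats::dnorm(c(fr$u, fr$v), c(pr$u, pr$v),
                                  sqrt(nm$r_var) * cam$focal, log = TRUE))
    }
    ld
  }
  expect_gte(joint_ld(sm_m), joint_ld(fl_m))
})

test_that("smoother is deterministic and robust to bad input", {
  sim <- simulate_camera(1, list(), seed = 25)
  a <- uks_smooth(sim$markers, lay, cam)
  b <- uks_smooth(sim$markers, lay, cam)
  expect_identical(a, b)
  expect_error(uks_smooth(sim$markers[0], lay, cam), "no usable")
  bad <- data.table::copy(sim$markers)
  bad$u[3] <- NaN
  expect_warning(uks_smooth(bad, lay, cam), "non-finite")
})

test_that("marker dropout mid-sequence is bridged without jumps", {
  sim <- simulate_camera(4, list(obs_noise_px = 1, drop_frac = 0), seed = 26)
  mk <- sim$markers[sim$markers$t < 1.5 | sim$markers$t > 2.5, ]
  nm <- noise_config(pos_rate = 0.02, rot_rate = 0.03,
                     obs_sd = 1 / cam$focal * 1.25)
  sm <- uks_smooth(mk, lay, cam, noise = nm, times = sim$pose$t)
  m <- as.matrix(sm[, 2:7])
  dtf <- 1 / 60
  # inside the gap the pose interpolates smoothly: tiny per-frame steps
  gap <- which(sm$t > 1.5 & sm$t < 2.5)
  gap_steps <- apply(m[gap, ], 2, function(v) max(abs(diff(v))))
  expect_true(all(gap_steps < c(rep(0.02, 3), rep(0.03, 3)) * sqrt(dtf)))
  # and no re-acquisition jump: global steps stay within a few transition SDs
  steps <- apply(m, 2, function(v) max(abs(diff(v))))
  expect_true(all(steps < 6 * c(rep(0.02, 3), rep(0.03, 3)) * sqrt(dtf)))
})
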