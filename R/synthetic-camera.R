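#' Simulate a scene-camera marker stream
#'
#' Generates a slow random-walk head-pose trajectory and the corresponding
#' fiducial-marker corner detections: the four screen-corner markers are
#' projected through the pinhole camera at each frame, pixel noise is added,
#' and a configurable fraction of markers drop out (emulating markers
#' leaving the camera's field of view or failed detections).
#'
#' @param duration Session duration, seconds.
#' @param pose_params List of generator settings: `pos0` (initial position,
#'   screen heights; default `c(0, 0, 1.25)`), `rot0` (initial Euler angles,
#'   radians), `walk_pos_sd` / `walk_rot_sd` (random-walk SD per
#'   sqrt-second), `obs_noise_px` (detection noise SD, pixels),
#'   `drop_frac` (per-frame per-marker dropout probability), `frame_rate`
#'   (Hz, default 60).
#' @param cam A [camera_model()].
#' @param layout A [marker_layout()].
#' @param seed Optional RNG seed.
#' @return A list with `markers` (long-format detection `data.table`:
#'   `t, marker_id, corner_id, u, v`) and `pose` (ground-truth pose
#'   `data.table`: `t, x, y, z, yaw, pitch, roll`).
#' @export
simulate_camera <- function(duration,
                            pose_params = list(),
                            cam = camera_model(),
                            layout = marker_layout(),
                            seed = NULL) {
  pp <- modifyList(list(pos0 = c(0, 0, 1.25), rot0 = c(0, 0, 0),
                        walk_pos_sd = 0.02, walk_rot_sd = 0.03,
                        obs_noise_px = 2, drop_frac = 0.2,
                        frame_rate = 60), pose_params)
  stopifnot(cam$focal > 0, duration > 0)
  with_seed(seed, {
    tt <- seq(0, duration, by = 1 / pp$frame_rate)
    N <- length(tt)
    dt <- 1 / pp$frame_rate
    walk <- function(x0, s) x0 + cumsum(c(0, rnorm(N - 1, 0, s * sqrt(dt))))
    pose <- cbind(
      walk(pp$pos0[1], pp$walk_pos_sd), walk(pp$pos0[2], pp$walk_pos_sd),
      walk(pp$pos0[3], pp$walk_pos_sd), walk(pp$rot0[1], pp$walk_rot_sd),
      walk(pp$rot0[2], pp$walk_rot_sd), walk(pp$rot0[3], pp$walk_rot_sd))
    res <- vector("list", N)
    for (k in seq_len(N)) {
      pr <- project_markers(pose[k, ], cam, layout)
      keep_marker <- runif(4) >= pp$drop_frac
      keep <- keep_marker[layout$marker_id + 1L] & pr$valid &
        pr$u >= 0 & pr$u <= cam$resolution[1] &
        pr$v >= 0 & pr$v <= cam$resolution[2]
      if (!any(keep)) next
      res[[k]] <- data.table::data.table(
        t = tt[k], marker_id = layout$marker_id[keep],
        corner_id = layout$corner_id[keep],
        u = pr$u[keep] + rnorm(sum(keep), 0, pp$obs_noise_px),
        v = pr$v[keep] + rnorm(sum(keep), 0, pp$obs_noise_px))
    }
    markers <- data.table::rbindlist(res)
    truth <- data.table::data.table(t = tt, x = pose[, 1], y = pose[, 2],
                                    z = pose[, 3], yaw = pose[, 4],
                                    pitch = pose[, 5], roll = pose[, 6])
    list(markers = markers, pose = truth)
  })
}
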