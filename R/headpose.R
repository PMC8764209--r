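#' Scene-camera model and noise configuration
#'
#' `camera_model()` builds pinhole intrinsics for the forward-facing scene
#' camera from a horizontal field of view and a pixel resolution (defaults:
#' 100 degree FOV at 1280x720, a typical wide-angle head-mounted scene
#' camera; note that at the nominal viewing distance of 1.25 screen heights
#' a FOV under about 72 degrees could never image the screen-corner
#' markers).
#' `noise_config()` holds the pose-estimation noise model: a random-walk
#' transition whose position term grows by 0.01 screen heights and rotation
#' term by 1 radian per second per axis, and a spherical marker-observation
#' error of 0.05 screen heights. The printed magnitudes are interpreted as
#' standard deviations (per sqrt-second for the transition); set
#' `interpret = "var"` to read them as variances instead.
#'
#' All head-pose computations use screen heights as the length unit with the
#' origin at the screen center, x rightward, y upward and z out of the
#' screen towards the viewer. Marker observations are normalised by the
#' focal length inside the smoother, and `z_ref` (nominal viewing distance
#' in screen heights) converts the screen-height observation error to that
#' normalised scale.
#'
#' @param fov_deg Horizontal field of view in degrees.
#' @param resolution Camera resolution in pixels, `c(width, height)`.
#' @param pos_rate Transition noise for position, screen heights.
#' @param rot_rate Transition noise for rotation, radians.
#' @param obs_sd Marker-corner observation error, screen heights.
#' @param interpret `"sd"` (default) or `"var"`: how the printed magnitudes
#'   are read.
#' @param z_ref Nominal camera-to-screen distance, screen heights.
#' @return A list of class `camera_model` or `noise_config`.
#' @export
camera_model <- function(fov_deg = 100, resolution = c(1280, 720)) {
  stopifnot(fov_deg > 0, fov_deg < 180, length(resolution) == 2)
  focal <- (resolution[1] / 2) / tan(fov_deg * pi / 360)
  structure(list(focal = focal, principal_point = resolution / 2,
                 resolution = as.numeric(resolution)),
            class = "camera_model")
}

#' @rdname camera_model
#' @export
noise_config <- function(pos_rate = 0.01, rot_rate = 1, obs_sd = 0.05,
                         interpret = c("sd", "var"), z_ref = 1.25) {
  interpret <- match.arg(interpret)
  stopifnot(pos_rate > 0, rot_rate > 0, obs_sd > 0, z_ref > 0)
  q <- if (interpret == "sd") c(pos_rate, rot_rate)^2 else c(pos_rate, rot_rate)
  r <- if (interpret == "sd") (obs_sd / z_ref)^2 else obs_sd / z_ref^2
  structure(list(pos_rate = pos_rate, rot_rate = rot_rate, obs_sd = obs_sd,
                 interpret = interpret, z_ref = z_ref,
                 q_pos = q[1], q_rot = q[2], r_var = r),
            class = "noise_config")
}

#' Fiducial-marker layout on the screen plane
#'
#' Places one square marker at each screen corner (the physical setup this
#' models tapes optical markers to the four corners of the display). Corner
#' coordinates are in screen heights on the screen plane z = 0, origin at
#' the screen center.
#'
#' @param aspect Screen width/height ratio.
#' @param marker_size Marker edge length in screen heights.
#' @return A `data.table` with columns `marker_id, corner_id, x, y`.
#' @export
marker_layout <- function(aspect = 16 / 9, marker_size = 0.05) {
  h <- marker_size / 2
  centers <- expand.grid(cx = c(-aspect / 2, aspect / 2), cy = c(-0.5, 0.5))
  off <- expand.grid(dx = c(-h, h), dy = c(-h, h))
  out <- do.call(rbind, lapply(seq_len(4), function(m)
    data.frame(marker_id = m - 1L, corner_id = seq_len(4) - 1L,
               x = centers$cx[m] + off$dx, y = centers$cy[m] + off$dy)))
  data.table::as.data.table(out)
}

# Elementary rotations and the yaw-pitch-roll Euler matrix (camera body
# orientation in world coordinates).
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
euler_matrix <- function(yaw, pitch, roll) rot_y(yaw) %*% rot_x(pitch) %*% rot_z(roll)

# Base orientation: a camera with zero Euler angles sits facing the screen,
# so its optical axis is -z (world) and its image y axis points down.
CAM_BASE <- diag(c(1, -1, -1))

# World -> camera coordinates for an Nx3 matrix of points.
world_to_cam <- function(pts, pose) {
  R <- euler_matrix(pose[4], pose[5], pose[6])
  M <- CAM_BASE %*% t(R)
  sweep(pts, 2, pose[1:3]) %*% t(M)
}

#' Project marker corners through the pinhole camera
#'
#' Applies the rigid transform defined by the pose (position `[x, y, z]` in
#' screen heights relative to the screen center, rotation
#' `[yaw, pitch, roll]` in radians) followed by the standard pinhole
#' projection. Corners at or behind the projection plane are flagged
#' invalid.
#'
#' @param pose Numeric length-6 vector `c(x, y, z, yaw, pitch, roll)`.
#' @param cam A [camera_model()].
#' @param corners Data frame with columns `x, y` (screen-plane points,
#'   screen heights; z = 0).
#' @return A `data.table` with columns `u, v` (pixels) and `valid`.
#' @export
project_markers <- function(pose, cam, corners) {
  pts <- cbind(corners$x, corners$y, 0)
  cc <- world_to_cam(pts, pose)
  depth <- cc[, 3]
  valid <- depth > 1e-9
  u <- cam$focal * cc[, 1] / depth + cam$principal_point[1]
  v <- cam$focal * cc[, 2] / depth + cam$principal_point[2]
  u[!valid] <- NA_real_; v[!valid] <- NA_real_
  data.table::data.table(u = u, v = v, valid = valid)
}

#' Map eye-camera gaze points to screen coordinates
#'
#' Back-projects a gaze point on the scene-camera image to a ray, transforms
#' it to world coordinates with the (smoothed) camera pose, intersects the
#' ray with the screen plane z = 0 and returns the intersection both in
#' screen heights and in screen pixels. Rays parallel to or pointing away
#' from the screen are marked invalid.
#'
#' @param u,v Gaze position on the scene-camera image, pixels.
#' @param pose Length-6 pose vector, or a matrix/data.frame with one pose
#'   per gaze sample (columns x, y, z, yaw, pitch, roll).
#' @param cam A [camera_model()].
#' @param cfg Optional [task_config()] for the pixel conversion; if
#'   supplied, screen-pixel coordinates `u_px, v_px` are included.
#' @return A `data.table` with `x_sh, y_sh` (screen heights), `valid`, and
#'   optionally `u_px, v_px`.
#' @export
map_gaze_to_screen <- function(u, v, pose, cam, cfg = NULL) {
  n <- length(u)
  if (is.null(dim(pose))) pose <- matrix(pose, nrow = n, ncol = 6, byrow = TRUE)
  pose <- as.matrix(pose)
  stopifnot(nrow(pose) == n)
  d_cam <- cbind((u - cam$principal_point[1]) / cam$focal,
                 (v - cam$principal_point[2]) / cam$focal, 1)
  x <- numeric(n); y <- numeric(n); ok <- logical(n)
  for (i in seq_len(n)) {
    R <- euler_matrix(pose[i, 4], pose[i, 5], pose[i, 6])
    D <- R %*% CAM_BASE %*% d_cam[i, ]
    s <- -pose[i, 3] / D[3]
    if (!is.finite(s) || s <= 0) { ok[i] <- FALSE; next }
    x[i] <- pose[i, 1] + s * D[1]
    y[i] <- pose[i, 2] + s * D[2]
    ok[i] <- TRUE
  }
  x[!ok] <- NA_real_; y[!ok] <- NA_real_
  out <- data.table::data.table(x_sh = x, y_sh = y, valid = ok)
  if (!is.null(cfg)) {
    h <- cfg$screen_px[2]
    out[, `:=`(u_px = x_sh * h + cfg$screen_px[1] / 2,
               v_px = cfg$screen_px[2] / 2 - y_sh * h)]
  }
  out[]
}

#' Single-frame pose fit by nonlinear least squares
#'
#' Estimates the camera pose from one frame's marker-corner observations by
#' minimising the pixel reprojection error. This is the per-frame
#' (homography-style) alternative to the smoother, used for initialisation
#' and as a comparison baseline; it is noisy when markers drop out.
#'
#' @param obs `data.table` with columns `u, v` (pixels) and the matching
#'   world corners `x, y` (screen heights).
#' @param cam A [camera_model()].
#' @param start Length-6 starting pose.
#' @return List with `pose` (length-6) and `rmse` (pixel reprojection RMSE).
#' @export
fit_pose_frame <- function(obs, cam, start = c(0, 0, 1.25, 0, 0, 0)) {
  stopifnot(nrow(obs) >= 3)
  corners <- obs[, c("x", "y")]
  target <- cbind(obs$u, obs$v)
  sse <- function(p) {
    pr <- project_markers(p, cam, corners)
    if (anyNA(pr$u)) return(1e12)
    sum((pr$u - target[, 1])^2 + (pr$v - target[, 2])^2)
  }
  o <- optim(start, sse, method = "Nelder-Mead",
             control = list(maxit = 2000, reltol = 1e-12))
  o <- optim(o$par, sse, method = "BFGS",
             control = list(maxit = 500, reltol = 1e-14))
  list(pose = o$par, rmse = sqrt(o$value / (2 * nrow(obs))))
}

# Split a long-format marker stream into per-frame observation tables
# (u, v, x, y) joined against the layout. Returns list(times, frames).
frame_observations <- function(markers, layout) {
  stopifnot(all(c("t", "marker_id", "corner_id", "u", "v") %in% names(markers)))
  mk <- data.table::as.data.table(markers)
  mk <- mk[is.finite(u) & is.finite(v)]
  mk <- merge(mk, layout, by = c("marker_id", "corner_id"), sort = FALSE)
  data.table::setorder(mk, t)
  sp <- split(mk, by = "t", sorted = TRUE)
  list(times = as.numeric(names(sp)), frames = sp)
}
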