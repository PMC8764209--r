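#' Unscented Kalman smoother for head pose
#'
#' Estimates the scene-camera pose over time from fiducial-marker corner
#' observations. The state is the 6-dof pose (position in screen heights,
#' yaw/pitch/roll in radians) with a random-walk transition scaled by the
#' inter-frame interval; the observation model projects the known marker
#' corners through the pinhole camera and compares them with the detections
#' in focal-normalised image coordinates. The forward pass is an unscented
#' Kalman filter (sigma points through the projection; the transition is
#' linear so the prediction is exact); the backward pass is a
#' Rauch-Tung-Striebel smoothing sweep. Frames without usable detections are
#' carried by prediction alone. The returned poses are the posterior means.
#'
#' @param markers Long-format detections: `data.table(t, marker_id,
#'   corner_id, u, v)` in pixels; missing rows are dropped corners.
#'   Non-finite detections are skipped with a warning.
#' @param layout Marker-corner world coordinates, see [marker_layout()].
#' @param cam A [camera_model()].
#' @param noise A [noise_config()].
#' @param times Optional full frame-time schedule (seconds, strictly
#'   increasing); defaults to the observation times. Frames in `times`
#'   without observations are interpolated by the model.
#' @param init Optional length-6 initial pose; defaults to a single-frame
#'   fit of the first frame with at least 6 corners.
#' @param ut Unscented-transform parameters `list(alpha, beta, kappa)`.
#' @param return_filter If `TRUE`, also return the causal filter means.
#' @return A `data.table` with columns `t, x, y, z, yaw, pitch, roll` (and
#'   `x_f, ..., roll_f` when `return_filter = TRUE`).
#' @export
uks_smooth <- function(markers, layout = marker_layout(), cam = camera_model(),
                       noise = noise_config(), times = NULL, init = NULL,
                       ut = list(alpha = 1e-3, beta = 2, kappa = 0),
                       return_filter = FALSE) {
  mk <- data.table::as.data.table(markers)
  bad <- !is.finite(mk$u) | !is.finite(mk$v)
  if (any(bad)) {
    warning(sprintf("skipping %d non-finite marker detections", sum(bad)))
    mk <- mk[!bad]
  }
  if (nrow(mk) == 0) stop("no usable marker observations", call. = FALSE)
  fo <- frame_observations(mk, layout)
  tt <- if (is.null(times)) fo$times else sort(unique(as.numeric(times)))
  if (any(diff(tt) <= 0)) stop("frame times must be strictly increasing", call. = FALSE)
  # index observations onto the frame schedule
  obs_idx <- match(round(fo$times, 9), round(tt, 9))
  if (anyNA(obs_idx)) stop("observation times missing from `times`", call. = FALSE)
  frames <- vector("list", length(tt))
  frames[obs_idx] <- fo$frames

  nlx <- 6L
  q_diag <- c(rep(noise$q_pos, 3), rep(noise$q_rot, 3))
  r_var <- noise$r_var
  pp <- cam$principal_point; f <- cam$focal

  if (is.null(init)) {
    k1 <- which(vapply(frames, function(x) !is.null(x) && nrow(x) >= 6, TRUE))[1]
    if (is.na(k1)) stop("no frame with enough corners to initialise", call. = FALSE)
    init <- fit_pose_frame(frames[[k1]], cam,
                           start = c(0, 0, noise$z_ref, 0, 0, 0))$pose
  }
  P0 <- diag(c(rep(0.05^2, 3), rep(0.1^2, 3)))

  lambda <- ut$alpha^2 * (nlx + ut$kappa) - nlx
  wm <- c(lambda / (nlx + lambda), rep(1 / (2 * (nlx + lambda)), 2 * nlx))
  wc <- wm; wc[1] <- wc[1] + (1 - ut$alpha^2 + ut$beta)

  # normalised projection of a corner set for one pose
  h_fun <- function(pose, corners) {
    cc <- world_to_cam(cbind(corners$x, corners$y, 0), pose)
    depth <- pmax(cc[, 3], 1e-6)
    c(rbind(cc[, 1] / depth, cc[, 2] / depth))
  }

  N <- length(tt)
  m_f <- matrix(NA_real_, N, nlx); P_f <- vector("list", N)
  m_p <- matrix(NA_real_, N, nlx); P_p <- vector("list", N)
  m <- init; P <- P0
  for (k in seq_len(N)) {
    dt <- if (k == 1) 0 else tt[k] - tt[k - 1]
    m_pred <- m
    P_pred <- P + diag(q_diag * dt, nlx)
    m_p[k, ] <- m_pred; P_p[[k]] <- P_pred
    fr <- frames[[k]]
    if (!is.null(fr) && nrow(fr) >= 1) {
      z <- c(rbind((fr$u - pp[1]) / f, (fr$v - pp[2]) / f))
      nz <- length(z)
      S_chol <- t(chol((nlx + lambda) * P_pred))
      X <- cbind(m_pred, m_pred + S_chol, m_pred - S_chol)  # 6 x 13
      Z <- vapply(seq_len(ncol(X)), function(j) h_fun(X[, j], fr),
                  numeric(nz))                               # nz x 13
      z_bar <- drop(Z %*% wm)
      Zc <- Z - z_bar
      Xc <- X - m_pred
      S <- Zc %*% (wc * t(Zc)) + diag(r_var, nz)
      C <- Xc %*% (wc * t(Zc))
      K <- C %*% solve(S)
      m <- m_pred + drop(K %*% (z - z_bar))
      P <- P_pred - K %*% S %*% t(K)
      P <- (P + t(P)) / 2
    } else {
      m <- m_pred; P <- P_pred
    }
    m_f[k, ] <- m; P_f[[k]] <- P
  }

  # backward RTS sweep (transition is the identity)
  m_s <- m_f
  for (k in (N - 1):1) {
    if (N < 2) break
    G <- P_f[[k]] %*% solve(P_p[[k + 1]])
    m_s[k, ] <- m_f[k, ] + drop(G %*% (m_s[k + 1, ] - m_p[k + 1, ]))
  }
  m_s[, 4:6] <- wrap_angle(m_s[, 4:6])
  out <- data.table::data.table(t = tt, x = m_s[, 1], y = m_s[, 2],
                                z = m_s[, 3], yaw = m_s[, 4], pitch = m_s[, 5],
                                roll = m_s[, 6])
  if (return_filter) {
    mf <- wrap_angle_cols(m_f)
    out[, `:=`(x_f = mf[, 1], y_f = mf[, 2], z_f = mf[, 3],
               yaw_f = mf[, 4], pitch_f = mf[, 5], roll_f = mf[, 6])]
  }
  out[]
}

wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[!is.na(w) & w == -pi] <- pi
  w
}

wrap_angle_cols <- function(m) { m[, 4:6] <- wrap_angle(m[, 4:6]); m }

#' Per-frame pose trajectory by independent least-squares fits
#'
#' Fits each frame's pose independently (warm-started from the previous
#' frame). This mimics the per-frame homography approach and serves as the
#' noisy baseline the smoother is compared against.
#'
#' @inheritParams uks_smooth
#' @param min_corners Frames with fewer matched corners are carried over
#'   from the previous estimate.
#' @return A `data.table` with columns `t, x, y, z, yaw, pitch, roll`.
#' @export
fit_pose_per_frame <- function(markers, layout = marker_layout(),
                               cam = camera_model(),
                               init = c(0, 0, 1.25, 0, 0, 0),
                               min_corners = 3) {
  fo <- frame_observations(markers, layout)
  N <- length(fo$times)
  out <- matrix(NA_real_, N, 6)
  cur <- init
  for (k in seq_len(N)) {
    fr <- fo$frames[[k]]
    if (nrow(fr) >= min_corners) {
      ft <- fit_pose_frame(fr, cam, start = cur)
      cur <- ft$pose
    }
    out[k, ] <- cur
  }
  data.table::data.table(t = fo$times, x = out[, 1], y = out[, 2], z = out[, 3],
                         yaw = out[, 4], pitch = out[, 5], roll = out[, 6])
}
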