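#' Task configuration: trajectory geometry and trial schedule parameters
#'
#' Describes the circular-tracking task: a small target moving clockwise on a
#' circle of fixed radius at a constant angular rate, intermittently occluded
#' for a random duration, followed by a brief discrimination probe (a Landolt
#' C) and a feedback period. The defaults reproduce the standard task:
#' radius 13.5 degrees, 0.25 turns per second (one cycle in 4 s, tangential
#' speed about 21 deg/s), visibility 1--2 s, occlusion 0--3 s, probe 0.05 s,
#' feedback 1 s, and a flat pixel-to-degree conversion of 80/1920 degrees per
#' pixel for a 1920-pixel-wide screen spanning an 80 degree field of view.
#'
#' Coordinate conventions: screen positions are expressed in degrees with the
#' origin at the circle/screen center, x rightward and y upward. Phase is
#' measured in turns along the direction of motion (clockwise), with phase 0
#' at the positive x axis, so the target sits at
#' `(R cos(2*pi*phase), -R sin(2*pi*phase))`.
#'
#' @param radius_deg Circle radius in visual degrees.
#' @param rate_tps Angular rate in turns per second (along the motion).
#' @param center_deg Circle center on screen, degrees, `c(x, y)`.
#' @param px_to_deg Degrees per pixel (flat linear approximation).
#' @param screen_px Screen resolution in pixels, `c(width, height)`.
#' @param visible_range Visible-duration interval in seconds.
#' @param occlusion_range Occlusion-duration interval in seconds.
#' @param probe_duration Discrimination-probe duration in seconds.
#' @param feedback_duration Feedback-period duration in seconds.
#' @param phase0 Target phase (turns) at t = 0.
#' @return An object of class `task_config` (a named list).
#' @export
#' @examples
#' cfg <- task_config()
#' tangential_speed(cfg)  # about 21 deg/s
task_config <- function(radius_deg = 13.5,
                        rate_tps = 0.25,
                        center_deg = c(0, 0),
                        px_to_deg = 80 / 1920,
                        screen_px = c(1920, 1080),
                        visible_range = c(1, 2),
                        occlusion_range = c(0, 3),
                        probe_duration = 0.05,
                        feedback_duration = 1,
                        phase0 = 0) {
  stopifnot(radius_deg > 0, rate_tps > 0, px_to_deg > 0,
            length(center_deg) == 2, length(screen_px) == 2,
            occlusion_range[1] >= 0, visible_range[1] > 0,
            diff(visible_range) >= 0, diff(occlusion_range) >= 0)
  structure(list(
    radius_deg = radius_deg, rate_tps = rate_tps,
    center_deg = as.numeric(center_deg), px_to_deg = px_to_deg,
    screen_px = as.numeric(screen_px),
    visible_range = as.numeric(visible_range),
    occlusion_range = as.numeric(occlusion_range),
    probe_duration = probe_duration, feedback_duration = feedback_duration,
    phase0 = phase0
  ), class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Circular-tracking task configuration\n")
  cat(sprintf("  radius %.2f deg, rate %.3f turns/s (tangential %.1f deg/s)\n",
              x$radius_deg, x$rate_tps, tangential_speed(x)))
  cat(sprintf("  visible %g-%g s, occlusion %g-%g s, probe %g s, feedback %g s\n",
              x$visible_range[1], x$visible_range[2],
              x$occlusion_range[1], x$occlusion_range[2],
              x$probe_duration, x$feedback_duration))
  cat(sprintf("  screen %dx%d px, %.5f deg/px\n",
              x$screen_px[1], x$screen_px[2], x$px_to_deg))
  invisible(x)
}

#' Target position at given times
#'
#' Position of the target on the circular trajectory, both in screen degrees
#' and as polar coordinates (phase in turns along the direction of motion,
#' radius in degrees).
#'
#' @param t Time(s) in seconds; must be finite.
#' @param cfg A [task_config()].
#' @return A `data.frame` with columns `t, x, y, phase, radius`.
#' @export
object_position <- function(t, cfg) {
  stopifnot(all(is.finite(t)))
  phase <- (cfg$phase0 + cfg$rate_tps * t) %% 1
  a <- 2 * pi * phase
  data.frame(
    t = t,
    x = cfg$center_deg[1] + cfg$radius_deg * cos(a),
    y = cfg$center_deg[2] - cfg$radius_deg * sin(a),
    phase = phase,
    radius = cfg$radius_deg
  )
}

# Instantaneous target velocity (deg/s) at time(s) t.
object_velocity <- function(t, cfg) {
  phase <- (cfg$phase0 + cfg$rate_tps * t) %% 1
  a <- 2 * pi * phase
  w <- 2 * pi * cfg$rate_tps * cfg$radius_deg
  cbind(vx = -w * sin(a), vy = -w * cos(a))
}

#' Tangential speed of the target
#'
#' `2 * pi * radius * rate`: the vectorial speed of the target along its
#' circular path, in degrees per second.
#'
#' @param cfg A [task_config()].
#' @return Speed in deg/s.
#' @export
tangential_speed <- function(cfg) {
  2 * pi * cfg$radius_deg * cfg$rate_tps
}

#' Convert screen pixel coordinates to degrees (and back)
#'
#' Applies the flat linear pixel-to-degree approximation about the screen
#' center: `x = (u - W/2) * k`, `y = (H/2 - v) * k` where `k` is the
#' configured degrees-per-pixel factor. Pixel coordinates follow the image
#' convention (origin top-left, v downward); degree coordinates have the
#' origin at the screen center with y upward.
#'
#' @param u,v Pixel coordinates (vectors).
#' @param cfg A [task_config()].
#' @return A `data.frame` with columns `x, y` in degrees.
#' @export
px_to_degrees <- function(u, v, cfg) {
  data.frame(x = (u - cfg$screen_px[1] / 2) * cfg$px_to_deg,
             y = (cfg$screen_px[2] / 2 - v) * cfg$px_to_deg)
}

#' @rdname px_to_degrees
#' @param x,y Degree coordinates (vectors).
#' @export
degrees_to_px <- function(x, y, cfg) {
  data.frame(u = x / cfg$px_to_deg + cfg$screen_px[1] / 2,
             v = cfg$screen_px[2] / 2 - y / cfg$px_to_deg)
}

#' Polar decomposition of screen positions relative to the trajectory
#'
#' Decomposes gaze (or any screen position, in degrees) into radius (distance
#' from the circle center, degrees) and phase (position along the trajectory
#' in turns, increasing along the direction of motion). A point exactly at
#' the center has undefined phase, propagated as `NA`.
#'
#' @param x,y Screen position(s) in degrees.
#' @param cfg A [task_config()].
#' @return A `data.frame` with columns `phase, radius`.
#' @export
polar_decompose <- function(x, y, cfg) {
  dx <- x - cfg$center_deg[1]
  dy <- y - cfg$center_deg[2]
  r <- sqrt(dx^2 + dy^2)
  ph <- (-atan2(dy, dx) / (2 * pi)) %% 1
  ph[r == 0] <- NA_real_
  data.frame(phase = ph, radius = r)
}

# Inverse of polar_decompose.
polar_to_xy <- function(phase, radius, cfg) {
  a <- 2 * pi * phase
  data.frame(x = cfg$center_deg[1] + radius * cos(a),
             y = cfg$center_deg[2] - radius * sin(a))
}

#' Wrap phase differences into (-0.5, 0.5]
#'
#' @param d Phase difference(s) in turns.
#' @return Wrapped difference(s); positive values mean ahead of the target
#'   along the direction of motion.
#' @export
wrap_phase_diff <- function(d) {
  w <- ((d + 0.5) %% 1) - 0.5
  w[!is.na(w) & w == -0.5] <- 0.5
  w
}

#' Polar difference between gaze and target
#'
#' Computes the phase difference (gaze phase minus target phase, wrapped to
#' (-0.5, 0.5], positive = gaze ahead of the target), the radius difference
#' (gaze radius minus target radius, positive = outside the circle), and the
#' Euclidean gaze-to-target displacement in degrees. The Euclidean distance
#' is computed from the Cartesian positions, not from the polar residuals,
#' and is therefore defined even when the phase is not (gaze at the center).
#'
#' @param gaze A data frame with columns `phase, radius` (see
#'   [polar_decompose()]).
#' @param obj Same structure, for the target.
#' @param cfg A [task_config()].
#' @return A `data.frame` with columns `phase_diff, radius_diff, euclidean`.
#' @export
polar_difference <- function(gaze, obj, cfg) {
  pd <- wrap_phase_diff(gaze$phase - obj$phase)
  rd <- gaze$radius - obj$radius
  g <- polar_to_xy(ifelse(is.na(gaze$phase), 0, gaze$phase), gaze$radius, cfg)
  o <- polar_to_xy(obj$phase, obj$radius, cfg)
  # With undefined gaze phase the gaze point is the center regardless of the
  # phase placeholder (radius 0), so the Euclidean term stays exact.
  eu <- sqrt((g$x - o$x)^2 + (g$y - o$y)^2)
  data.frame(phase_diff = pd, radius_diff = rd, euclidean = eu)
}

#' Hypothetical gaze trajectories during occlusion
#'
#' Reference trajectories for what gaze-to-target error would look like under
#' three alternative non-tracking strategies after the target disappears:
#' continuing straight along the tangent at disappearance (`"tangent"`),
#' staying at the disappearance point (`"stay"`), or shifting to the circle
#' center (`"center"`). Useful as baselines for the positional-error time
#' series.
#'
#' Closed forms: the center error is constant at the radius; the stay error
#' is the chord `2 R sin(pi * rate * t)`; the tangent error is the distance
#' between the point `p0 + v0 t` and the target.
#'
#' @param kind One of `"tangent"`, `"stay"`, `"center"`.
#' @param times Times since occlusion onset, seconds, all >= 0.
#' @param cfg A [task_config()].
#' @param phase_occl Target phase (turns) at occlusion onset.
#' @return A `data.frame` with columns `t, x, y, error_deg`.
#' @export
hypothetical_trajectory <- function(kind = c("tangent", "stay", "center"),
                                    times, cfg, phase_occl = 0) {
  kind <- match.arg(kind)
  stopifnot(all(times >= 0))
  p0 <- polar_to_xy(phase_occl, cfg$radius_deg, cfg)
  pos <- switch(kind,
    stay = data.frame(x = rep(p0$x, length(times)), y = rep(p0$y, length(times))),
    center = data.frame(x = rep(cfg$center_deg[1], length(times)),
                        y = rep(cfg$center_deg[2], length(times))),
    tangent = {
      a <- 2 * pi * phase_occl
      w <- 2 * pi * cfg$rate_tps * cfg$radius_deg
      data.frame(x = p0$x - w * sin(a) * times,
                 y = p0$y - w * cos(a) * times)
    })
  obj <- object_position(times, within_cfg_phase(cfg, phase_occl))
  data.frame(t = times, x = pos$x, y = pos$y,
             error_deg = sqrt((pos$x - obj$x)^2 + (pos$y - obj$y)^2))
}

# cfg with phase0 replaced, so object_position(t) starts at the given phase.
within_cfg_phase <- function(cfg, phase0) {
  cfg$phase0 <- phase0
  cfg
}
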