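#' Write and read session bundles
#'
#' A session bundle is a directory holding one recording session in the
#' package's native plain-text formats, all times in float seconds on a
#' single session clock:
#' \itemize{
#'   \item `gaze.csv`: `t, u_px, v_px, confidence` -- gaze on screen in
#'     pixels (image convention, origin top-left), or in scene-camera image
#'     pixels when `gaze_frame: camera` is set in the config;
#'   \item `markers.csv` (optional): `t, marker_id, corner_id, u_px, v_px`
#'     -- fiducial-marker corner detections; missing rows are dropped
#'     corners;
#'   \item `events.json`: the trial schedule (visibility/occlusion windows,
#'     probe direction, response, correctness);
#'   \item `config.yaml`: the serialized [task_config()] plus bundle
#'     options (`participant_id`, `gaze_frame`).
#' }
#' `write_session()` serialises a simulated session; `read_session()`
#' validates and loads a bundle into typed in-memory streams.
#'
#' @param session A session as returned by [simulate_gaze()] (optionally
#'   with `markers` from [simulate_camera()] attached).
#' @param dir Bundle directory.
#' @param cfg A [task_config()].
#' @param participant_id Stored in the config.
#' @return `write_session()` returns `dir` invisibly; `read_session()`
#'   returns a list with `gaze`, `markers` (or `NULL`), `trials`, `cfg`,
#'   `participant_id`, `gaze_frame`.
#' @export
write_session <- function(session, dir, cfg, participant_id = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  px <- degrees_to_px(session$samples$x, session$samples$y, cfg)
  gz <- data.table::data.table(t = session$samples$t, u_px = px$u, v_px = px$v,
                               confidence = session$samples$confidence)
  data.table::fwrite(gz, file.path(dir, "gaze.csv"))
  if (!is.null(session$markers))
    data.table::fwrite(
      data.table::setnames(data.table::copy(session$markers),
                           c("u", "v"), c("u_px", "v_px")),
      file.path(dir, "markers.csv"))
  trials <- as.data.frame(session$trials)
  jsonlite::write_json(trials, file.path(dir, "events.json"),
                       auto_unbox = FALSE, digits = NA, na = "null")
  conf <- c(unclass(cfg), list(participant_id = participant_id,
                               gaze_frame = "screen"))
  yaml::write_yaml(conf, file.path(dir, "config.yaml"))
  # ground truth (synthetic sessions only) for tests and validation
  if (!is.null(session$events)) {
    data.table::fwrite(session$events, file.path(dir, "truth_events.csv"))
    data.table::fwrite(session$saccades, file.path(dir, "truth_saccades.csv"))
  }
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  need <- file.path(dir, c("gaze.csv", "events.json", "config.yaml"))
  miss <- need[!file.exists(need)]
  if (length(miss))
    stop("session bundle is missing: ", paste(basename(miss), collapse = ", "),
         call. = FALSE)
  conf <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- task_config(
    radius_deg = conf$radius_deg, rate_tps = conf$rate_tps,
    center_deg = unlist(conf$center_deg), px_to_deg = conf$px_to_deg,
    screen_px = unlist(conf$screen_px),
    visible_range = unlist(conf$visible_range),
    occlusion_range = unlist(conf$occlusion_range),
    probe_duration = conf$probe_duration,
    feedback_duration = conf$feedback_duration,
    phase0 = conf$phase0 %||% 0)
  gaze <- data.table::fread(file.path(dir, "gaze.csv"))
  check_stream(gaze, c("t", "u_px", "v_px", "confidence"), "gaze.csv")
  trials <- data.table::as.data.table(
    jsonlite::read_json(file.path(dir, "events.json"), simplifyVector = TRUE))
  check_stream(trials, c("trial_id", "t_visible_on", "t_occl_on", "t_reappear"),
               "events.json", time_col = "t_visible_on")
  markers <- NULL
  mpath <- file.path(dir, "markers.csv")
  if (file.exists(mpath)) {
    markers <- data.table::fread(mpath)
    check_stream(markers, c("t", "marker_id", "corner_id", "u_px", "v_px"),
                 "markers.csv", monotone = FALSE)
    data.table::setnames(markers, c("u_px", "v_px"), c("u", "v"))
  }
  list(gaze = gaze, markers = markers, trials = trials, cfg = cfg,
       participant_id = conf$participant_id %||% 1L,
       gaze_frame = conf$gaze_frame %||% "screen")
}

check_stream <- function(x, cols, file, time_col = "t", monotone = TRUE) {
  miss <- setdiff(cols, names(x))
  if (length(miss))
    stop(sprintf("%s: missing columns %s", file, paste(miss, collapse = ", ")),
         call. = FALSE)
  if (nrow(x) == 0) stop(file, ": empty stream", call. = FALSE)
  for (cc in intersect(cols, names(x))) {
    bad <- which(!is.finite(x[[cc]]) & !is.character(x[[cc]]) & !is.logical(x[[cc]]))
    if (cc %in% c("t", time_col) && length(bad))
      stop(sprintf("%s: non-finite value in column '%s' at row %d", file, cc,
                   bad[1]), call. = FALSE)
  }
  tv <- x[[time_col]]
  if (monotone && any(diff(tv) < 0))
    stop(sprintf("%s: time not monotone at row %d", file,
                 which(diff(tv) < 0)[1] + 1), call. = FALSE)
  invisible(TRUE)
}

#' Run the full analysis pipeline on a session
#'
#' Executes the processing chain: (optional) head-pose smoothing and
#' gaze-to-screen mapping, pixel-to-degree conversion, confidence
#' filtering, piecewise-linear segmentation, saccade classification,
#' visibility assignment, and all summary metrics. Deterministic given
#' inputs and configuration.
#'
#' @param bundle A bundle from [read_session()], or a bundle directory.
#' @param params Optional list overriding analysis settings:
#'   `conf_threshold`, `penalty`, `hmm`, `probe_time`, `cam`, `layout`,
#'   `noise` (head-pose), `error_rate` (error-trace grid rate).
#' @param out_dir Optional directory to persist stage outputs (segment
#'   table, error traces, summary JSON).
#' @return A list with `segments`, `saccade_events`, `fitted`, `errors`,
#'   `coverage`, `gain`, `anticipation`, `trials`, `summary` (headline
#'   statistics), and `log` (per-stage counts).
#' @export
run_pipeline <- function(bundle, params = list(), out_dir = NULL) {
  if (is.character(bundle)) bundle <- read_session(bundle)
  p <- modifyList(list(conf_threshold = 0.8, penalty = 5, hmm = hmm_config(),
                       probe_time = 1.5, cam = camera_model(),
                       layout = marker_layout(), noise = noise_config(),
                       error_rate = 60), params)
  cfg <- bundle$cfg
  log <- list(n_samples = nrow(bundle$gaze))
  gaze <- data.table::copy(bundle$gaze)

  if (identical(bundle$gaze_frame, "camera")) {
    if (is.null(bundle$markers))
      stop("pipeline stage 'headpose': gaze is in camera frame but the bundle has no marker stream",
           call. = FALSE)
    pose <- uks_smooth(bundle$markers, p$layout, p$cam, p$noise)
    pose_at <- vapply(c("x", "y", "z", "yaw", "pitch", "roll"), function(cc)
      approx(pose$t, pose[[cc]], xout = gaze$t, rule = 2)$y,
      numeric(nrow(gaze)))
    mp <- map_gaze_to_screen(gaze$u_px, gaze$v_px, pose_at, p$cam, cfg)
    gaze[, `:=`(u_px = mp$u_px, v_px = mp$v_px)]
    gaze <- gaze[mp$valid]
    log$n_invalid_rays <- sum(!mp$valid)
    log$pose_frames <- nrow(pose)
  }

  dg <- px_to_degrees(gaze$u_px, gaze$v_px, cfg)
  gaze[, `:=`(x = dg$x, y = dg$y)]
  gaze <- confidence_filter(gaze, p$conf_threshold)
  log$n_low_confidence <- attr(gaze, "n_dropped")
  log$frac_low_confidence <- attr(gaze, "frac_dropped")

  segres <- segment_nslr(gaze[, c("t", "x", "y")], penalty = p$penalty)
  seg <- classify_segments(segres$segments, p$hmm)
  seg <- assign_visibility(seg, bundle$trials)
  log$n_segments <- nrow(seg)
  log$n_saccade_segments <- sum(seg$class == "saccade")

  ev <- saccade_events(seg)
  if (nrow(ev) && !is.null(bundle$participant_id))
    ev[, participant_id := bundle$participant_id]
  ant <- if (nrow(ev)) saccade_anticipation(ev, cfg) else NULL
  cov <- cumulative_phase_coverage(seg, bundle$trials, cfg,
                                   probe_time = p$probe_time)
  gn <- pursuit_gain(seg, cfg)
  err <- error_timeseries(segres$fitted, bundle$trials, cfg,
                          rate = p$error_rate)

  trials <- data.table::as.data.table(bundle$trials)
  # gaze error at reappearance from the denoised signal (interpolated)
  fx <- approxfun(segres$fitted$t, segres$fitted$x, rule = 1)
  fy <- approxfun(segres$fitted$t, segres$fitted$y, rule = 1)
  ob <- object_position(trials$t_reappear, cfg)
  trials[, error_at_reappear := sqrt((fx(t_reappear) - ob$x)^2 +
                                       (fy(t_reappear) - ob$y)^2)]
  pr <- polar_decompose(fx(trials$t_reappear), fy(trials$t_reappear), cfg)
  trials[, `:=`(phase_diff_at_reappear = wrap_phase_diff(pr$phase - ob$phase),
                radius_diff_at_reappear = pr$radius - ob$radius)]

  vis_t <- sum(trials$t_occl_on - trials$t_visible_on)
  occ_t <- sum(trials$t_reappear - trials$t_occl_on)
  occl_err <- err$traces[t_rel >= 0]
  summary <- list(
    n_trials = nrow(trials),
    saccade_rate_visible = if (nrow(ev)) sum(ev$visibility == "visible") / vis_t else 0,
    saccade_rate_occluded = if (nrow(ev)) sum(ev$visibility == "occluded") / occ_t else NA_real_,
    saccade_amp_median_visible = if (nrow(ev)) median(ev$amplitude_deg[ev$visibility == "visible"]) else NA_real_,
    saccade_amp_median_occluded = if (nrow(ev)) median(ev$amplitude_deg[ev$visibility == "occluded"]) else NA_real_,
    mean_error_at_reappear = mean(trials$error_at_reappear[trials$t_reappear > trials$t_occl_on], na.rm = TRUE),
    mean_abs_phase_diff_occl = mean(abs(occl_err$phase_diff), na.rm = TRUE),
    mean_abs_radius_diff_occl = mean(abs(occl_err$radius_diff), na.rm = TRUE),
    pursuit_share = if (nrow(cov$shares)) as.list(setNames(cov$shares$median_share, cov$shares$period)) else NULL,
    launch_land = if (!is.null(ant)) as.data.frame(ant$medians) else NULL,
    frac_low_confidence = log$frac_low_confidence)
  if (!is.null(trials$correct) && any(!is.na(trials$correct)))
    summary$discrimination <- discrimination_summary(trials)[
      c("overall", "near", "far", "short_occl", "long_occl")]

  out <- list(segments = seg, saccade_events = ev, fitted = segres$fitted,
              errors = err, coverage = cov, gain = gn, anticipation = ant,
              trials = trials, summary = summary, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(seg, file.path(out_dir, "segments.csv"))
    if (nrow(ev)) data.table::fwrite(ev, file.path(out_dir, "saccade_events.csv"))
    data.table::fwrite(err$median_curve, file.path(out_dir, "error_median.csv"))
    data.table::fwrite(trials, file.path(out_dir, "trials.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
  }
  out
}

#' Simulate and write a complete session bundle
#'
#' Convenience wrapper: draws a schedule, simulates gaze and responses
#' (and optionally the scene-camera marker stream), and writes the bundle.
#'
#' @param dir Output directory.
#' @param n_trials Number of trials.
#' @param cfg A [task_config()].
#' @param params An [oculomotor_params()].
#' @param seed RNG seed (all stages derive child seeds from it).
#' @param with_camera Also simulate and store a marker stream.
#' @param participant_id Stored in the config.
#' @return The bundle directory, invisibly.
#' @export
simulate_session <- function(dir, n_trials = 30, cfg = task_config(),
                             params = oculomotor_params(), seed = 1,
                             with_camera = FALSE, participant_id = 1L) {
  sched <- generate_schedule(n_trials, cfg, seed = child_seed(seed, 1))
  ses <- simulate_gaze(sched, params, cfg, seed = child_seed(seed, 2))
  ses$trials <- simulate_response(ses$trials, seed = child_seed(seed, 3))
  if (with_camera) {
    dur <- max(ses$samples$t)
    ses$markers <- simulate_camera(dur, seed = child_seed(seed, 4))$markers
  }
  write_session(ses, dir, cfg, participant_id = participant_id)
}
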