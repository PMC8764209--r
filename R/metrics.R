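#' Positional-error time series around occlusion onset
#'
#' Interpolates the denoised gaze signal onto a uniform grid (default 60
#' samples/s) aligned to each trial's occlusion onset (t = 0), computes the
#' Euclidean gaze-to-target displacement and its polar decomposition (phase
#' and radius differences), and summarises across trials with per-time-point
#' medians. Grid points outside a trial's observed data range are missing
#' (no extrapolation).
#'
#' @param fitted Denoised gaze `data.table(t, x, y)` (degrees), e.g. the
#'   `fitted` element of [segment_nslr()].
#' @param trials Trial table.
#' @param cfg A [task_config()].
#' @param rate Grid rate, samples per second.
#' @param t_before Seconds before occlusion onset to include.
#' @return A list with `traces` (per-trial `data.table`: `trial_id, t_rel,
#'   euclidean, phase_diff, radius_diff`) and `median_curve`
#'   (`data.table(t_rel, euclidean, phase_diff, radius_diff, n_trials)`, the
#'   across-trial median of magnitudes).
#' @export
error_timeseries <- function(fitted, trials, cfg, rate = 60, t_before = 1) {
  tr <- data.table::as.data.table(trials)
  fx <- approxfun(fitted$t, fitted$x, rule = 1)
  fy <- approxfun(fitted$t, fitted$y, rule = 1)
  tmin <- min(fitted$t); tmax <- max(fitted$t)
  res <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    occ0 <- tr$t_occl_on[i]
    grid <- seq(-t_before, tr$t_reappear[i] - occ0, by = 1 / rate)
    ta <- occ0 + grid
    ok <- ta >= max(tmin, tr$t_visible_on[i]) & ta <= tmax
    if (!any(ok)) next
    ta <- ta[ok]; grid <- grid[ok]
    gx <- fx(ta); gy <- fy(ta)
    obj <- object_position(ta, cfg)
    gp <- polar_decompose(gx, gy, cfg)
    pd <- polar_difference(gp, data.frame(phase = obj$phase, radius = obj$radius), cfg)
    res[[i]] <- data.table::data.table(
      trial_id = tr$trial_id[i], t_rel = round(grid * rate) / rate,
      euclidean = pd$euclidean, phase_diff = pd$phase_diff,
      radius_diff = pd$radius_diff)
  }
  traces <- data.table::rbindlist(res)
  med <- traces[, .(euclidean = median(euclidean, na.rm = TRUE),
                    phase_diff = median(abs(phase_diff), na.rm = TRUE),
                    radius_diff = median(abs(radius_diff), na.rm = TRUE),
                    n_trials = .N), keyby = t_rel]
  list(traces = traces, median_curve = med)
}

#' Saccade launch/landing anticipation statistics
#'
#' For each saccade the phase difference (gaze minus target, turns) at
#' launch and at landing is computed from the segment endpoints; medians of
#' the signed and absolute values are reported by visibility category.
#' Positive values indicate gaze ahead of the target: anticipatory saccades
#' land ahead. With per-participant data the indicator "absolute landing
#' median exceeds absolute launch median during occlusion" is tested with
#' the exact two-sided binomial test against p = 0.5.
#'
#' @param saccades `data.table` of saccade events with columns `t_launch,
#'   t_land, x0, y0, x1, y1, visibility` and optionally `participant_id`.
#' @param cfg A [task_config()].
#' @return A list with `events` (the table plus launch/land polar
#'   differences), `medians` (by visibility), and, when participants are
#'   present, `binomial` (successes, n, p-value).
#' @export
saccade_anticipation <- function(saccades, cfg) {
  sc <- data.table::as.data.table(saccades)
  stopifnot(nrow(sc) >= 1)
  lg <- polar_decompose(sc$x0, sc$y0, cfg)
  ob_l <- object_position(sc$t_launch, cfg)
  ld <- polar_decompose(sc$x1, sc$y1, cfg)
  ob_n <- object_position(sc$t_land, cfg)
  sc[, `:=`(launch_phase_diff = wrap_phase_diff(lg$phase - ob_l$phase),
            land_phase_diff = wrap_phase_diff(ld$phase - ob_n$phase),
            launch_radius_diff = lg$radius - ob_l$radius,
            land_radius_diff = ld$radius - ob_n$radius)]
  med <- sc[visibility %in% c("visible", "occluded"),
            .(launch_med = median(launch_phase_diff, na.rm = TRUE),
              land_med = median(land_phase_diff, na.rm = TRUE),
              launch_abs_med = median(abs(launch_phase_diff), na.rm = TRUE),
              land_abs_med = median(abs(land_phase_diff), na.rm = TRUE),
              n = .N), keyby = visibility]
  out <- list(events = sc[], medians = med)
  if ("participant_id" %in% names(sc)) {
    by_p <- sc[visibility == "occluded",
               .(gt = median(abs(land_phase_diff), na.rm = TRUE) >
                   median(abs(launch_phase_diff), na.rm = TRUE)),
               keyby = participant_id]
    k <- sum(by_p$gt); n <- nrow(by_p)
    out$binomial <- list(successes = k, n = n,
                         p_value = if (n > 0) binom_test_exact(k, n, 0.5)
                         else NA_real_,
                         per_participant = by_p)
  }
  out
}

#' Exact two-sided binomial test
#'
#' Two-sided p-value by enumeration: the probabilities of all outcomes not
#' exceeding that of the observed count (up to a relative tolerance) are
#' summed under Binomial(n, p0).
#'
#' @param k Observed successes.
#' @param n Number of trials (> 0).
#' @param p0 Null success probability.
#' @return The p-value.
#' @export
#' @examples
#' binom_test_exact(9, 10, 0.5)   # 0.021
#' binom_test_exact(10, 10, 0.5)  # 0.002
binom_test_exact <- function(k, n, p0 = 0.5) {
  stopifnot(n > 0, k >= 0, k <= n, p0 >= 0, p0 <= 1)
  probs <- dbinom(0:n, n, p0)
  min(1, sum(probs[probs <= probs[k + 1] * (1 + 1e-7)]))
}

#' Cumulative phase coverage by segment class
#'
#' Accumulates, within each trial's visible and occluded period, the signed
#' phase angle (turns, along the direction of motion) covered by
#' pursuit/fixation and by saccade segments, and computes the proportion of
#' total gaze phase covered by pursuit after `probe_time` seconds of
#' tracking in that period. Segment phase deltas come from the fitted
#' endpoints, wrapped under the assumption that no segment covers more than
#' half a turn; crossing segments are excluded from the per-period shares
#' (they belong to neither period).
#'
#' @param segments Classified segment table (needs `class`, `visibility`,
#'   `trial_id`, endpoints).
#' @param trials Trial table.
#' @param cfg A [task_config()].
#' @param probe_time Evaluation time (s) into the period.
#' @return A list with `per_segment` (segment phase deltas), `per_trial`
#'   (`trial_id, period, pursuit_phase, saccade_phase, total_phase,
#'   pursuit_share` evaluated at `probe_time`) and `shares` (pursuit share
#'   medians by period).
#' @export
cumulative_phase_coverage <- function(segments, trials, cfg,
                                      probe_time = 1.5) {
  seg <- data.table::as.data.table(segments)
  seg <- seg[degenerate == FALSE]
  p0 <- polar_decompose(seg$x0, seg$y0, cfg)
  p1 <- polar_decompose(seg$x1, seg$y1, cfg)
  seg[, dphase := wrap_phase_diff(p1$phase - p0$phase)]
  tr <- data.table::as.data.table(trials)
  res <- list()
  for (i in seq_len(nrow(tr))) {
    for (period in c("visible", "occluded")) {
      w0 <- if (period == "visible") tr$t_visible_on[i] else tr$t_occl_on[i]
      w1 <- if (period == "visible") tr$t_occl_on[i] else tr$t_reappear[i]
      if (w1 - w0 < probe_time) next
      ss <- seg[visibility == period & trial_id == tr$trial_id[i]]
      if (!nrow(ss)) next
      tcut <- w0 + probe_time
      frac <- pmax(0, pmin(1, (tcut - ss$t_start) / (ss$t_end - ss$t_start)))
      d <- ss$dphase * frac
      pur <- sum(d[ss$class == "pursuit_fixation"])
      sac <- sum(d[ss$class == "saccade"])
      tot <- pur + sac
      res[[length(res) + 1L]] <- data.table::data.table(
        trial_id = tr$trial_id[i], period = period, pursuit_phase = pur,
        saccade_phase = sac, total_phase = tot,
        pursuit_share = if (abs(tot) > 1e-9) pur / tot else NA_real_)
    }
  }
  per_trial <- data.table::rbindlist(res)
  shares <- if (nrow(per_trial))
    per_trial[, .(median_share = median(pursuit_share, na.rm = TRUE), n = .N),
              keyby = period]
  else data.table::data.table()
  list(per_segment = seg[], per_trial = per_trial, shares = shares)
}

#' Pursuit gain from the phase component
#'
#' For every pursuit/fixation segment, the ratio of the change in gaze
#' phase over the segment to the change in target phase over the same
#' interval (which is `rate * duration`, always positive). Segments are
#' tagged by their timing relative to occlusion onset: `"visible"` (before
#' onset), `"crossing"` (spanning onset) or `"occluded"` ("blind" pursuit).
#'
#' @param segments Classified segment table with visibility assigned.
#' @param cfg A [task_config()].
#' @param min_duration Minimum segment duration (s) to include.
#' @return A `data.table` with `segment_id, trial_id, t_start, t_end,
#'   t_mid_rel, visibility, gain`.
#' @export
pursuit_gain <- function(segments, cfg, min_duration = 0.02) {
  seg <- data.table::as.data.table(segments)
  seg <- seg[class == "pursuit_fixation" & degenerate == FALSE &
               duration >= min_duration &
               visibility %in% c("visible", "occluded", "crossing")]
  if (!nrow(seg)) return(data.table::data.table())
  p0 <- polar_decompose(seg$x0, seg$y0, cfg)
  p1 <- polar_decompose(seg$x1, seg$y1, cfg)
  seg[, gain := wrap_phase_diff(p1$phase - p0$phase) / (cfg$rate_tps * duration)]
  seg[, .(segment_id, trial_id, t_start, t_end, visibility, gain, duration)]
}

#' Discrimination-task summary
#'
#' Success rates overall, stratified by gaze error at reappearance
#' (threshold 1.5 degrees) and by occlusion duration (threshold 1 s), plus
#' mean error by correctness. Empty strata are reported as `NA`, not zero.
#'
#' @param trials Trial table with `correct`, `error_at_reappear`,
#'   `occl_duration` and optionally `participant_id`.
#' @param error_threshold Degrees.
#' @param occl_threshold Seconds.
#' @return A list of summary statistics.
#' @export
discrimination_summary <- function(trials, error_threshold = 1.5,
                                   occl_threshold = 1) {
  tr <- data.table::as.data.table(trials)
  tr <- tr[!is.na(correct)]
  stopifnot(nrow(tr) > 0)
  rate <- function(x) if (length(x)) mean(x) else NA_real_
  out <- list(
    overall = rate(tr$correct),
    n_trials = nrow(tr),
    near = rate(tr$correct[tr$error_at_reappear <= error_threshold]),
    far = rate(tr$correct[tr$error_at_reappear > error_threshold]),
    short_occl = rate(tr$correct[tr$occl_duration <= occl_threshold]),
    long_occl = rate(tr$correct[tr$occl_duration > occl_threshold]),
    mean_error_correct = if (any(tr$correct)) mean(tr$error_at_reappear[tr$correct]) else NA_real_,
    mean_error_false = if (any(!tr$correct)) mean(tr$error_at_reappear[!tr$correct]) else NA_real_)
  if ("participant_id" %in% names(tr))
    out$by_participant <- tr[, .(rate = mean(correct), n = .N),
                             keyby = participant_id]
  out
}

#' Accumulation of prediction uncertainty from saccade launch points
#'
#' Treats occluded saccade launch points as samples of the internal target
#' estimate. Per participant, each trial's launch sequence (phase and
#' radius difference versus time since occlusion onset) is linearly
#' interpolated onto a common grid (default 500 points spanning the
#' occlusion range); the SD across trials is computed at every grid point
#' where at least `min_traces` traces overlap (never extrapolating beyond a
#' trial's observed launches). The growth rate is then estimated by
#' regressing SD on time for t > `t_min`, pooling participants with a
#' random participant intercept (lme4), reporting the fixed-effect slope
#' and marginal R-squared; an OLS fit is reported alongside.
#'
#' @param launches `data.table` with `participant_id, trial_id,
#'   t_since_occl, phase_diff, radius_diff` for occluded saccade launches.
#' @param n_grid Grid points per participant.
#' @param min_traces Minimum overlapping traces per retained grid point.
#' @param min_trials Minimum usable traces per participant (participants
#'   below this are skipped with a warning).
#' @param t_min Regression restricted to times beyond this, seconds.
#' @param exclude_participants Participant ids dropped from the regression
#'   (but kept in the curves).
#' @param t_max Upper end of the interpolation grid; defaults to the
#'   longest observed launch time.
#' @return A list with `curves` (`participant_id, t, sd_phase, sd_radius,
#'   n_traces`) and `regression` (slopes, marginal R2, per measure, for the
#'   mixed and OLS fits).
#' @export
uncertainty_accumulation <- function(launches, n_grid = 500, min_traces = 5,
                                     min_trials = 5, t_min = 0.5,
                                     exclude_participants = NULL,
                                     t_max = NULL) {
  la <- data.table::as.data.table(launches)
  stopifnot(all(c("participant_id", "trial_id", "t_since_occl",
                  "phase_diff", "radius_diff") %in% names(la)))
  t_hi <- t_max %||% max(la$t_since_occl)
  curves <- list()
  for (p in unique(la$participant_id)) {
    lp <- la[participant_id == p]
    grid <- seq(0, t_hi, length.out = n_grid)
    tr_ids <- unique(lp$trial_id)
    mats_p <- matrix(NA_real_, length(tr_ids), n_grid)
    mats_r <- matrix(NA_real_, length(tr_ids), n_grid)
    nuse <- 0L
    for (j in seq_along(tr_ids)) {
      lt <- lp[trial_id == tr_ids[j]][order(t_since_occl)]
      if (nrow(lt) < 2) next  # a single launch cannot be interpolated
      nuse <- nuse + 1L
      mats_p[j, ] <- approx(lt$t_since_occl, lt$phase_diff, xout = grid,
                            rule = 1)$y
      mats_r[j, ] <- approx(lt$t_since_occl, lt$radius_diff, xout = grid,
                            rule = 1)$y
    }
    if (nuse < min_trials) {
      warning(sprintf("participant %s has %d usable traces (<%d); skipped",
                      p, nuse, min_trials))
      next
    }
    nt <- colSums(!is.na(mats_p))
    sd_p <- apply(mats_p, 2, sd, na.rm = TRUE)
    sd_r <- apply(mats_r, 2, sd, na.rm = TRUE)
    keep <- nt >= min_traces
    curves[[length(curves) + 1L]] <- data.table::data.table(
      participant_id = p, t = grid[keep], sd_phase = sd_p[keep],
      sd_radius = sd_r[keep], n_traces = nt[keep])
  }
  curves <- data.table::rbindlist(curves)
  if (!nrow(curves))
    return(list(curves = curves,
                regression = list(phase = NULL, radius = NULL, n_points = 0L)))
  reg_data <- curves[t > t_min &
                       !(participant_id %in% (exclude_participants %||% integer()))]
  fit_one <- function(col) {
    d <- data.frame(y = reg_data[[col]], time = reg_data$t,
                    pid = factor(reg_data$participant_id))
    ols <- lm(y ~ time, data = d)
    out <- list(slope_ols = unname(coef(ols)[2]),
                r2_ols = summary(ols)$r.squared)
    if (nlevels(d$pid) > 1) {
      mm <- tryCatch(
        lme4::lmer(y ~ time + (1 | pid), data = d, REML = TRUE),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(mm)) {
        fe <- lme4::fixef(mm)
        var_f <- var(as.numeric(model_matrix_fe(mm) %*% fe))
        vc <- as.data.frame(lme4::VarCorr(mm))
        var_r <- sum(vc$vcov[vc$grp != "Residual"])
        var_e <- vc$vcov[vc$grp == "Residual"]
        out$slope <- unname(fe[2])
        out$r2_marginal <- var_f / (var_f + var_r + var_e)
      }
    }
    if (is.null(out$slope)) { out$slope <- out$slope_ols; out$r2_marginal <- NA_real_ }
    out
  }
  list(curves = curves,
       regression = list(phase = fit_one("sd_phase"),
                         radius = fit_one("sd_radius"),
                         n_points = nrow(reg_data)))
}

model_matrix_fe <- function(mm) lme4::getME(mm, "X")

#' Occluded saccade launch table from ground truth or detections
#'
#' Convenience constructor for the input of [uncertainty_accumulation()]:
#' converts a saccade table (with launch positions and times) into launch
#' phase/radius differences relative to the target, tagged with the time
#' since the containing trial's occlusion onset.
#'
#' @param saccades Saccade table (`t_launch, x0, y0, visibility`,
#'   optionally `participant_id`).
#' @param trials Trial table (matched by containment of `t_launch` in the
#'   occlusion window).
#' @param cfg A [task_config()].
#' @param participant_id Used if the saccade table has no such column.
#' @return `data.table(participant_id, trial_id, t_since_occl, phase_diff,
#'   radius_diff)`.
#' @export
launch_table <- function(saccades, trials, cfg, participant_id = 1L) {
  sc <- data.table::as.data.table(saccades)
  sc <- sc[visibility == "occluded"]
  tr <- data.table::as.data.table(trials)
  idx <- findInterval(sc$t_launch, tr$t_occl_on)
  ok <- idx >= 1 & sc$t_launch <= tr$t_reappear[pmax(idx, 1)]
  sc <- sc[ok]; idx <- idx[ok]
  gp <- polar_decompose(sc$x0, sc$y0, cfg)
  ob <- object_position(sc$t_launch, cfg)
  pid <- if ("participant_id" %in% names(sc)) sc$participant_id else participant_id
  data.table::data.table(
    participant_id = pid,
    trial_id = tr$trial_id[idx],
    t_since_occl = sc$t_launch - tr$t_occl_on[idx],
    phase_diff = wrap_phase_diff(gp$phase - ob$phase),
    radius_diff = gp$radius - ob$radius)
}
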