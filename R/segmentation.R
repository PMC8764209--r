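#' Filter gaze samples by pupil-detection confidence
#'
#' Removes samples whose confidence falls below the threshold (default 0.8,
#' the conventional cutoff for pupil-detection confidence). The resulting
#' gaps are recorded as missing intervals; no interpolation is performed
#' here -- downstream segmentation treats each contiguous run independently.
#'
#' @param samples `data.table` with columns `t` and `confidence` (in
#'   `[0, 1]`).
#' @param threshold Confidence cutoff.
#' @return The filtered `data.table`, with attributes `n_dropped`,
#'   `frac_dropped` and `gaps` (a `data.table` of removed intervals).
#' @export
confidence_filter <- function(samples, threshold = 0.8) {
  stopifnot(all(samples$confidence >= 0 & samples$confidence <= 1))
  keep <- samples$confidence >= threshold
  if (!any(keep)) stop("all samples fall below the confidence threshold", call. = FALSE)
  out <- data.table::as.data.table(samples)[keep]
  dropped <- samples$t[!keep]
  gaps <- if (length(dropped)) {
    brk <- c(0, which(diff(dropped) > 1.5 * median(diff(samples$t))), length(dropped))
    data.table::data.table(t_start = dropped[head(brk, -1) + 1],
                           t_end = dropped[brk[-1]])
  } else data.table::data.table(t_start = numeric(), t_end = numeric())
  data.table::setattr(out, "n_dropped", sum(!keep))
  data.table::setattr(out, "frac_dropped", mean(!keep))
  data.table::setattr(out, "gaps", gaps)
  out[]
}

# ---- naive segmented linear regression --------------------------------------

# Robust noise SD from median absolute second differences (second
# differences of iid noise have variance 6 sigma^2; slow signal cancels).
robust_noise_sd <- function(x) {
  d2 <- diff(x, differences = 2)
  if (!length(d2)) return(0)
  stats::median(abs(d2)) / (0.6745 * sqrt(6))
}

# Piece SSE for the continuity-respecting search: residual sum of squares
# around the straight line through the piece's endpoints (pieces share
# their boundary samples, so the implied piecewise-linear curve is
# continuous and a saccade cannot hide in a discontinuity). The anchor
# values are taken from a 3-point running mean, so cutting at a noise
# outlier does not spuriously zero its residual. Computed in O(1) per
# query via prefix sums; `i` may be a vector.
make_sse_fun <- function(t, x, y, smooth_anchors = TRUE) {
  smooth3 <- function(v) {
    n <- length(v)
    if (n < 3 || !smooth_anchors) return(v)
    c(v[1], (v[-c(1, 2)] + v[-c(1, n)] + v[-c(n - 1, n)]) / 3, v[n])
  }
  xs <- smooth3(x); ys <- smooth3(y)
  cs <- function(v) c(0, cumsum(v))
  S1 <- cs(rep(1, length(t))); St <- cs(t); Stt <- cs(t * t)
  Sx <- cs(x); Stx <- cs(t * x); Sxx <- cs(x * x)
  Sy <- cs(y); Sty <- cs(t * y); Syy <- cs(y * y)
  function(i, j) {
    m <- S1[j + 1] - S1[i]
    st <- St[j + 1] - St[i]; stt <- Stt[j + 1] - Stt[i]
    sse_dim <- function(vs, Sv, Stv, Svv) {
      b <- (vs[j] - vs[i]) / pmax(t[j] - t[i], 1e-12)
      a <- vs[i] - b * t[i]
      sv <- Sv[j + 1] - Sv[i]; stv <- Stv[j + 1] - Stv[i]
      svv <- Svv[j + 1] - Svv[i]
      svv - 2 * (a * sv + b * stv) + m * a^2 + 2 * a * b * st + b^2 * stt
    }
    pmax(sse_dim(xs, Sx, Stx, Sxx), 0) + pmax(sse_dim(ys, Sy, Sty, Syy), 0)
  }
}

# Exact split search by dynamic programming over shared piece boundaries
# (knots at samples), minimising total SSE plus `penalty` per piece, with
# piece lengths bounded in [min_len, max_len] samples (the cap keeps the
# search near-linear; pieces longer than the cap simply get split, which
# the trajectory's curvature forces anyway). Returns the interior knots.
dp_splits <- function(sse, n, penalty, min_len, max_len) {
  cost <- c(0, rep(Inf, n - 1))  # cost[i] = optimal cost of samples 1..i
  back <- integer(n)
  for (j in 2:n) {
    lo_i <- max(1L, j - max_len + 1L)
    hi_i <- j - min_len + 1L
    if (hi_i < lo_i) hi_i <- lo_i  # short head/tail pieces are allowed
    cand <- lo_i:hi_i
    val <- cost[cand] + sse(cand, j) + penalty
    b <- which.min(val)
    cost[j] <- val[b]
    back[j] <- cand[b]
  }
  cuts <- integer(); j <- n
  while (j > 1) { i <- back[j]; if (i > 1) cuts <- c(i, cuts); j <- i }
  cuts
}

# Free-line (ordinary least squares) piece SSE, used by the merge pass:
# unlike the endpoint-anchored score it cannot be gamed by noise outliers
# at piece boundaries. `i` may be a vector.
make_ols_sse_fun <- function(t, x, y) {
  cs <- function(v) c(0, cumsum(v))
  S1 <- cs(rep(1, length(t))); St <- cs(t); Stt <- cs(t * t)
  Sx <- cs(x); Stx <- cs(t * x); Sxx <- cs(x * x)
  Sy <- cs(y); Sty <- cs(t * y); Syy <- cs(y * y)
  function(i, j) {
    m <- S1[j + 1] - S1[i]
    st <- St[j + 1] - St[i]; stt <- Stt[j + 1] - Stt[i]
    vt <- stt - st^2 / m
    sse_dim <- function(Sv, Svv, Stv) {
      sv <- Sv[j + 1] - Sv[i]; svv <- Svv[j + 1] - Svv[i]
      stv <- Stv[j + 1] - Stv[i]
      ctv <- stv - st * sv / m
      vv <- svv - sv^2 / m
      ifelse(vt > 1e-12, vv - ctv^2 / vt, vv)
    }
    pmax(sse_dim(Sx, Sxx, Stx), 0) + pmax(sse_dim(Sy, Syy, Sty), 0)
  }
}

# Merge pass: remove interior knots whose removal raises the (free-line)
# SSE by less than the merge threshold, considering only pairs whose
# combined span exceeds the DP's maximum piece length. This undoes the
# splits the length cap forces on long quiet stretches without touching
# saccade knots (short spans are never candidates, and knots kept by a
# real movement raise the SSE by orders of magnitude more anyway).
merge_splits <- function(sse, cuts, n, penalty, max_len) {
  repeat {
    if (!length(cuts)) return(cuts)
    kn <- c(1L, cuts, n)
    span <- kn[seq_along(cuts) + 2] - kn[seq_along(cuts)] + 1L
    gain <- rep(Inf, length(cuts))
    el <- which(span > max_len)
    if (!length(el)) return(cuts)
    gain[el] <- vapply(el, function(ii)
      sse(kn[ii], kn[ii + 2]) -
        (sse(kn[ii], kn[ii + 1]) + sse(kn[ii + 1], kn[ii + 2])), 0)
    b <- which.min(gain)
    if (gain[b] >= penalty) return(cuts)
    cuts <- cuts[-b]
  }
}

# Continuous piecewise-linear least squares with fixed knots (hat basis).
# Returns fitted values at all samples and the knot values.
fit_continuous_pwl <- function(t, v, knot_idx) {
  kt <- t[knot_idx]
  n <- length(t); k <- length(knot_idx)
  if (k == 1) return(list(fitted = rep(mean(v), n), knots = mean(v)))
  seg <- findInterval(t, kt, rightmost.closed = TRUE)
  seg[seg < 1] <- 1; seg[seg > k - 1] <- k - 1
  dt <- kt[seg + 1] - kt[seg]
  w2 <- (t - kt[seg]) / dt
  w1 <- 1 - w2
  A <- Matrix::sparseMatrix(i = c(seq_len(n), seq_len(n)),
                            j = c(seg, seg + 1),
                            x = c(w1, w2), dims = c(n, k))
  AtA <- Matrix::crossprod(A)
  Atv <- Matrix::crossprod(A, v)
  beta <- as.numeric(Matrix::solve(AtA + Matrix::Diagonal(k, 1e-10), Atv))
  list(fitted = as.numeric(A %*% beta), knots = beta)
}

#' Piecewise-linear gaze segmentation (naive segmented linear regression)
#'
#' Partitions each contiguous run of gaze samples into linear pieces by a
#' greedy top-down split search minimising squared reconstruction error with
#' a per-split penalty, followed by local breakpoint refinement and a
#' continuous piecewise-linear refit (the pieces share values at
#' breakpoints). The fitted curve is the denoised gaze signal; all segment
#' statistics downstream use the fitted endpoints.
#'
#' Runs are separated wherever the sample stream has a gap longer than
#' `gap_max` seconds (e.g. after confidence filtering); no segment spans a
#' gap. Runs shorter than two samples are emitted as degenerate pieces
#' flagged `degenerate = TRUE` and are excluded from statistics.
#'
#' @param samples `data.table` with columns `t, x, y` (degrees).
#' @param penalty Per-piece penalty in units of the (robustly estimated)
#'   noise variance. The default was calibrated once on synthetic sessions
#'   at the default noise level and frozen.
#' @param min_len Minimum samples per piece.
#' @param max_len Maximum samples per piece (bounds the split search).
#' @param merge_factor Hysteresis for the merge pass: adjacent pieces whose
#'   joint fit raises the SSE by less than `merge_factor * penalty` noise
#'   variances are merged. Splits kept by a real saccade are orders of
#'   magnitude above this; marginal noise-driven splits are not.
#' @param gap_max Maximum tolerated inter-sample gap within a run, seconds.
#' @return A list with `segments` (a `data.table`: `segment_id, t_start,
#'   t_end, x0, y0, x1, y1, amplitude_deg, mean_speed_dps, duration,
#'   n_samples, degenerate`) and `fitted` (`data.table(t, x, y)` of the
#'   denoised signal).
#' @export
segment_nslr <- function(samples, penalty = 5, min_len = 3, max_len = 96,
                         merge_factor = 3, gap_max = 0.05) {
  s <- data.table::as.data.table(samples)
  stopifnot(all(c("t", "x", "y") %in% names(s)))
  data.table::setorder(s, t)
  run_id <- cumsum(c(1, diff(s$t) > gap_max))
  seg_list <- list(); fit_list <- list()
  sid <- 0L
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    tr <- s$t[idx]; xr <- s$x[idx]; yr <- s$y[idx]
    n <- length(idx)
    if (n < 2) {
      sid <- sid + 1L
      seg_list[[length(seg_list) + 1L]] <- data.table::data.table(
        segment_id = sid, t_start = tr[1], t_end = tr[1], x0 = xr[1], y0 = yr[1],
        x1 = xr[1], y1 = yr[1], amplitude_deg = 0, mean_speed_dps = 0,
        duration = 0, n_samples = 1L, degenerate = TRUE)
      fit_list[[length(fit_list) + 1L]] <- data.table::data.table(t = tr, x = xr, y = yr)
      next
    }
    sig2 <- robust_noise_sd(xr)^2 + robust_noise_sd(yr)^2
    # anchor smoothing guards against noise outliers at piece boundaries;
    # on (near) noise-free input it would itself bias the anchors
    sse <- make_sse_fun(tr, xr, yr, smooth_anchors = sig2 > 1e-3)
    sig2 <- max(sig2, 8e-4)  # floor at 0.02 deg per axis
    splits <- dp_splits(sse, n, penalty * sig2, min_len, max_len)
    ols_sse <- make_ols_sse_fun(tr, xr, yr)
    splits <- merge_splits(ols_sse, splits, n, merge_factor * penalty * sig2,
                           max_len)
    knot_idx <- unique(c(1L, splits, n))
    # knots mark piece boundaries: piece i spans knot i .. knot i+1
    fx <- fit_continuous_pwl(tr, xr, knot_idx)
    fy <- fit_continuous_pwl(tr, yr, knot_idx)
    kx <- fx$knots; ky <- fy$knots; kt <- tr[knot_idx]
    np <- length(knot_idx) - 1
    for (p in seq_len(np)) {
      sid <- sid + 1L
      amp <- sqrt((kx[p + 1] - kx[p])^2 + (ky[p + 1] - ky[p])^2)
      dur <- kt[p + 1] - kt[p]
      seg_list[[length(seg_list) + 1L]] <- data.table::data.table(
        segment_id = sid, t_start = kt[p], t_end = kt[p + 1],
        x0 = kx[p], y0 = ky[p], x1 = kx[p + 1], y1 = ky[p + 1],
        amplitude_deg = amp, mean_speed_dps = amp / dur, duration = dur,
        n_samples = knot_idx[p + 1] - knot_idx[p] + 1L, degenerate = FALSE)
    }
    fit_list[[length(fit_list) + 1L]] <-
      data.table::data.table(t = tr, x = fx$fitted, y = fy$fitted)
  }
  list(segments = data.table::rbindlist(seg_list),
       fitted = data.table::rbindlist(fit_list))
}

# ---- segment classification -------------------------------------------------

#' Default hidden-Markov classifier parameters
#'
#' Four internal states (fixation, pursuit, saccade, post-saccadic
#' oscillation) with diagonal-Gaussian emissions on log mean speed (deg/s)
#' and log duration (s). The parameters were fit once on synthetic sessions
#' and frozen; the output collapses saccade and PSO into `"saccade"` and
#' fixation and pursuit into `"pursuit_fixation"`.
#'
#' @return A list with `states`, emission `means`/`sds` (2 columns:
#'   log-speed, log-duration), transition matrix `trans` and initial
#'   distribution `init`.
#' @export
hmm_config <- function() {
  states <- c("fixation", "pursuit", "saccade", "pso")
  means <- rbind(fixation = c(log(2), log(0.3)),
                 pursuit = c(log(19), log(0.25)),
                 saccade = c(log(100), log(0.03)),
                 pso = c(log(30), log(0.02)))
  sds <- rbind(fixation = c(1.3, 1.4),
               pursuit = c(0.45, 1.4),
               saccade = c(0.6, 0.9),
               pso = c(0.5, 0.6))
  trans <- rbind(fixation = c(0.40, 0.30, 0.299, 0.001),
                 pursuit = c(0.30, 0.40, 0.299, 0.001),
                 saccade = c(0.46, 0.46, 0.01, 0.07),
                 pso = c(0.50, 0.49, 0.009, 0.001))
  trans <- trans / rowSums(trans)
  dimnames(trans) <- list(states, states)
  list(states = states, means = means, sds = sds, trans = trans,
       init = c(0.4, 0.4, 0.199, 0.001))
}

#' Classify segments as saccade or pursuit/fixation
#'
#' Viterbi decoding over the segment sequence with the hidden-Markov model
#' of [hmm_config()], then collapsing to two output classes: `"saccade"`
#' (saccade + post-saccadic oscillation) and `"pursuit_fixation"`
#' (pursuit + fixation). Degenerate single-sample segments are labelled
#' `"pursuit_fixation"` but keep their `degenerate` flag.
#'
#' @param segments Segment table from [segment_nslr()].
#' @param config HMM parameters, see [hmm_config()].
#' @return The segment table with a `class` column added.
#' @export
classify_segments <- function(segments, config = hmm_config()) {
  seg <- data.table::as.data.table(segments)
  if (!nrow(seg)) { seg[, class := character()]; return(seg[]) }
  feats <- cbind(log(pmax(seg$mean_speed_dps, 0.05)),
                 log(pmax(seg$duration, 1e-3)))
  K <- length(config$states)
  n <- nrow(seg)
  logem <- sapply(seq_len(K), function(k)
    rowSums(dnorm2_log(feats, config$means[k, ], config$sds[k, ])))
  logem <- matrix(logem, nrow = n)
  ltr <- log(config$trans)
  delta <- matrix(-Inf, n, K); psi <- matrix(0L, n, K)
  delta[1, ] <- log(config$init) + logem[1, ]
  if (n > 1) for (i in 2:n) for (k in seq_len(K)) {
    v <- delta[i - 1, ] + ltr[, k]
    psi[i, k] <- which.max(v)
    delta[i, k] <- max(v) + logem[i, k]
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (i in (n - 1):1) path[i] <- psi[i + 1, path[i + 1]]
  lab <- config$states[path]
  seg[, class := ifelse(lab %in% c("saccade", "pso"), "saccade", "pursuit_fixation")]
  seg[degenerate == TRUE, class := "pursuit_fixation"]
  seg[]
}

dnorm2_log <- function(x, mu, sd) {
  cbind(stats::dnorm(x[, 1], mu[1], sd[1], log = TRUE),
        stats::dnorm(x[, 2], mu[2], sd[2], log = TRUE))
}

#' Merge consecutive saccade segments into saccade events
#'
#' A detected saccade event is a maximal run of temporally contiguous
#' segments classified `"saccade"` (this absorbs post-saccadic-oscillation
#' pieces into the saccade that produced them). The event launches at the
#' first segment's start point and lands at the last segment's end point.
#' Saccade rates and launch/landing statistics operate on events, not raw
#' segments.
#'
#' @param segments Classified segment table (from [classify_segments()]),
#'   optionally with visibility assigned.
#' @return A `data.table` with `t_launch, t_land, x0, y0, x1, y1,
#'   amplitude_deg` plus `visibility`/`trial_id` when present (taken from
#'   the first segment of the run; an event mixing visible and occluded
#'   member segments is `"crossing"`).
#' @export
saccade_events <- function(segments) {
  seg <- data.table::as.data.table(segments)[class == "saccade" &
                                               degenerate == FALSE]
  if (!nrow(seg)) return(data.table::data.table())
  data.table::setorder(seg, t_start)
  new_run <- c(TRUE, seg$t_start[-1] > seg$t_end[-nrow(seg)] + 1e-9)
  seg[, run := cumsum(new_run)]
  has_vis <- "visibility" %in% names(seg)
  ev <- seg[, {
    out <- list(t_launch = t_start[1], t_land = t_end[.N],
                x0 = x0[1], y0 = y0[1], x1 = x1[.N], y1 = y1[.N])
    if (has_vis) {
      vv <- unique(visibility)
      out$visibility <- if (length(vv) == 1) vv
      else if (all(c("visible", "occluded") %in% vv) ||
               "crossing" %in% vv) "crossing" else vv[1]
      out$trial_id <- trial_id[1]
    }
    out
  }, by = run]
  ev[, run := NULL]
  ev[, amplitude_deg := sqrt((x1 - x0)^2 + (y1 - y0)^2)]
  ev[]
}

#' Assign visibility categories to segments
#'
#' Labels each segment by the task period it falls in: fully inside a
#' visible window (`[t_visible_on, t_occl_on)`) is `"visible"`, fully
#' inside an occlusion (`[t_occl_on, t_reappear)`) is `"occluded"`, and a
#' segment overlapping both periods of a trial is `"crossing"` (segments
#' are never split across the boundary). Segments outside any trial window
#' -- e.g. during probe or feedback -- are labelled `"other"`. Windows are
#' closed-open, so a segment ending exactly at occlusion onset is visible.
#'
#' @param segments Segment table (needs `t_start`, `t_end`).
#' @param trials Trial table from [generate_schedule()].
#' @return The segment table with `visibility` and `trial_id` columns.
#' @export
assign_visibility <- function(segments, trials) {
  seg <- data.table::as.data.table(segments)
  tr <- data.table::as.data.table(trials)
  n <- nrow(seg)
  vis <- rep("other", n); tid <- rep(NA_integer_, n)
  for (i in seq_len(nrow(tr))) {
    v0 <- tr$t_visible_on[i]; o0 <- tr$t_occl_on[i]; r0 <- tr$t_reappear[i]
    in_vis <- seg$t_start >= v0 & seg$t_end <= o0
    in_occ <- seg$t_start >= o0 & seg$t_end <= r0 & r0 > o0
    cross <- seg$t_start >= v0 & seg$t_start < o0 & seg$t_end > o0 &
      seg$t_end <= r0 & r0 > o0
    vis[in_vis] <- "visible"; vis[in_occ] <- "occluded"; vis[cross] <- "crossing"
    tid[in_vis | in_occ | cross] <- tr$trial_id[i]
  }
  seg[, visibility := vis]
  seg[, trial_id := tid]
  seg[]
}
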