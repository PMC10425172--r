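#' Wrap angles into (-180, 180] degrees
#'
#' @param a angles in degrees.
#' @return wrapped angles.
#' @export
wrap_angle <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

# circular mean in degrees
circ_mean <- function(a) {
  (atan2(mean(sin(a * pi / 180)), mean(cos(a * pi / 180)))) * 180 / pi
}

#' Animal trajectory
#'
#' Time-stamped 2-D positions of one tracked animal (or synthetic agent) in
#' the arena frame, mm, nominally sampled at 14 Hz. Gaps longer than 1 s
#' should be split into separate tracks before construction (see
#' [as_trajectories()]).
#'
#' @param track_id identifier.
#' @param times sample times, s, strictly increasing with no gap > 1 s.
#' @param x,y positions in mm.
#' @return A `trajectory` object with derived per-sample `heading` (deg,
#'   CCW-positive, from forward differences) and `speed` (mm/s).
#' @export
trajectory <- function(track_id, times, x, y) {
  times <- as.numeric(times); x <- as.numeric(x); y <- as.numeric(y)
  if (length(times) < 2L) stop("a trajectory needs at least 2 samples")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(diff(times) > 1 + 1e-9))
    stop("gap > 1 s: split the track first (see as_trajectories)")
  dt <- diff(times)
  dx <- diff(x); dy <- diff(y)
  heading <- c(atan2(dy, dx) * 180 / pi, NA)
  heading[length(heading)] <- heading[length(heading) - 1L]
  speed <- c(sqrt(dx^2 + dy^2) / dt, NA)
  speed[length(speed)] <- speed[length(speed) - 1L]
  structure(list(track_id = track_id, times = times, x = x, y = y,
                 heading = heading, speed = speed),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> '%s': %d samples, %.1f s, net displacement %.2f mm\n",
              x$track_id, length(x$times), diff(range(x$times)),
              sqrt((x$x[length(x$x)] - x$x[1])^2 +
                   (x$y[length(x$y)] - x$y[1])^2)))
  invisible(x)
}

track_duration <- function(tr) diff(range(tr$times))
track_displacement <- function(tr)
  sqrt((tr$x[length(tr$x)] - tr$x[1])^2 + (tr$y[length(tr$y)] - tr$y[1])^2)

#' Split a tidy tracking table into trajectory objects
#'
#' @param df data.frame with columns `track_id,time_s,x_mm,y_mm`.
#' @param max_gap_s gaps longer than this split a track into pieces.
#' @return list of [trajectory()] objects.
#' @export
as_trajectories <- function(df, max_gap_s = 1) {
  need <- c("track_id", "time_s", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stop("need columns track_id,time_s,x_mm,y_mm")
  out <- list()
  for (d in split(df, df$track_id)) {
    d <- d[order(d$time_s), ]
    piece <- cumsum(c(0, diff(d$time_s) > max_gap_s))
    split_needed <- max(piece) > 0
    for (p in split(d, piece)) {
      if (nrow(p) < 2L) next
      id <- if (split_needed)
        sprintf("%s.%d", p$track_id[1], piece[match(p$time_s[1], d$time_s)] + 1)
      else as.character(p$track_id[1])
      out[[length(out) + 1L]] <- trajectory(id, p$time_s, p$x_mm, p$y_mm)
    }
  }
  out
}

#' Smooth a trajectory with a local cubic polynomial
#'
#' Savitzky-Golay smoothing of each coordinate: a third-order polynomial
#' over a centered 0.5 s window (7 samples at 14 Hz), the standard filter
#' for removing centroid tracking noise while preserving turns. Endpoints
#' use the filter's one-sided startup fits. Timestamps are unchanged;
#' heading and speed are rederived from the smoothed positions.
#'
#' @param track a [trajectory()].
#' @param window_s smoothing window, s.
#' @return smoothed [trajectory()]; tracks shorter than the window are
#'   returned unchanged with attribute `unsmoothed = TRUE`.
#' @export
smooth_track <- function(track, window_s = 0.5) {
  stopifnot(inherits(track, "trajectory"))
  dt <- stats::median(diff(track$times))
  n <- max(3L, round(window_s / dt))
  if (n %% 2L == 0L) n <- n + 1L
  if (length(track$times) < n + 1L || track_duration(track) < window_s) {
    attr(track, "unsmoothed") <- TRUE
    return(track)
  }
  xs <- signal::sgolayfilt(track$x, p = 3, n = n)
  ys <- signal::sgolayfilt(track$y, p = 3, n = n)
  trajectory(track$track_id, track$times, xs, ys)
}

#' Filter tracks by duration, displacement and start concentration
#'
#' Keeps tracks observed for more than 60 s with net displacement larger
#' than 3 mm, and drops tracks starting where the odor concentration is
#' higher than 70% of the field maximum (animals that had likely completed
#' chemotaxis before tracking began). All three thresholds are strict
#' inequalities.
#'
#' @param tracks list of [trajectory()] objects.
#' @param context a [gradient_context()].
#' @param min_duration_s,min_displacement_mm,max_start_frac thresholds.
#' @return the surviving tracks (possibly empty list).
#' @export
filter_tracks <- function(tracks, context, min_duration_s = 60,
                          min_displacement_mm = 3, max_start_frac = 0.7) {
  stopifnot(inherits(context, "gradient_context"))
  keep <- vapply(tracks, function(tr) {
    if (!(track_duration(tr) > min_duration_s)) return(FALSE)
    if (!(track_displacement(tr) > min_displacement_mm)) return(FALSE)
    c0 <- field_eval(context$field, tr$x[1] / context$mm_per_unit,
                     tr$y[1] / context$mm_per_unit)
    c0 <= max_start_frac * context$max_ppm
  }, logical(1))
  tracks[keep]
}

#' Bearing of a track relative to the local odor gradient
#'
#' The bearing is the signed angle from the local gradient direction to the
#' instantaneous velocity direction, CCW-positive, in (-180, 180]: 0 deg is
#' straight up-gradient, +/-180 deg straight down-gradient. Samples where
#' the gradient magnitude is below the context floor (1% of the field's
#' maximum gradient) are returned as `NA` and excluded from
#' bearing-conditioned statistics.
#'
#' @param track a [trajectory()] (positions in mm).
#' @param context a [gradient_context()].
#' @return numeric vector of bearings (deg) per sample.
#' @export
bearing_series <- function(track, context) {
  stopifnot(inherits(track, "trajectory"), inherits(context, "gradient_context"))
  g <- gradient_eval(context$grad, track$x / context$mm_per_unit,
                     track$y / context$mm_per_unit)
  gmag <- sqrt(g$gx^2 + g$gy^2)
  gdir <- atan2(g$gy, g$gx) * 180 / pi
  b <- wrap_angle(track$heading - gdir)
  b[gmag <= context$grad_floor] <- NA
  b
}

# gradient direction (deg) at arbitrary mm positions, NA below floor
gradient_dir_at <- function(context, px_mm, py_mm) {
  g <- gradient_eval(context$grad, px_mm / context$mm_per_unit,
                     py_mm / context$mm_per_unit)
  gmag <- sqrt(g$gx^2 + g$gy^2)
  out <- atan2(g$gy, g$gx) * 180 / pi
  out[gmag <= context$grad_floor] <- NA
  out
}

#' Detect sharp turns in a trajectory
#'
#' A turn (pirouette) is an angle change larger than `threshold_deg`
#' between the displacement vectors spanning consecutive 1 s windows:
#' at sample time t the angle between p(t) - p(t - w) and p(t + w) - p(t).
#' Candidate instants above threshold are merged within a refractory window
#' equal to the detection window, keeping the instant of maximum angle
#' change, so a slow continuous turn is not double counted. Samples where
#' either window's mean speed is below `speed_floor` are skipped (angle
#' undefined at standstill).
#'
#' @param track a smoothed [trajectory()].
#' @param threshold_deg turn threshold (default 60 deg).
#' @param window_s detection and refractory window (default 1 s).
#' @param speed_floor_mm_s minimum mean speed for a valid angle.
#' @return data.frame of turn events: `track_id`, `time`, `angle_change`
#'   (signed deg), `heading_before`, `heading_after`, `x`, `y` (mm).
#'   Empty for tracks shorter than two windows.
#' @export
detect_turns <- function(track, threshold_deg = 60, window_s = 1.0,
                         speed_floor_mm_s = 0.01) {
  stopifnot(inherits(track, "trajectory"))
  empty <- data.frame(track_id = character(), time = numeric(),
                      angle_change = numeric(), heading_before = numeric(),
                      heading_after = numeric(), x = numeric(), y = numeric())
  tt <- track$times
  if (diff(range(tt)) < 2 * window_s) return(empty)
  dt <- stats::median(diff(tt))
  k <- max(1L, round(window_s / dt))
  n <- length(tt)
  idx <- (k + 1L):(n - k)
  if (!length(idx)) return(empty)
  bx <- track$x[idx] - track$x[idx - k]; by <- track$y[idx] - track$y[idx - k]
  fx <- track$x[idx + k] - track$x[idx]; fy <- track$y[idx + k] - track$y[idx]
  hb <- atan2(by, bx) * 180 / pi
  hf <- atan2(fy, fx) * 180 / pi
  ang <- wrap_angle(hf - hb)
  sp_b <- sqrt(bx^2 + by^2) / (k * dt)
  sp_f <- sqrt(fx^2 + fy^2) / (k * dt)
  valid <- sp_b >= speed_floor_mm_s & sp_f >= speed_floor_mm_s
  cand <- which(abs(ang) > threshold_deg & valid)
  if (!length(cand)) return(empty)
  # merge candidates within the refractory window, keep max |angle|
  keep <- integer()
  i <- 1L
  while (i <= length(cand)) {
    j <- i
    while (j < length(cand) &&
           tt[idx[cand[j + 1L]]] - tt[idx[cand[j]]] <= window_s) j <- j + 1L
    grp <- cand[i:j]
    keep <- c(keep, grp[which.max(abs(ang[grp]))])
    i <- j + 1L
  }
  data.frame(track_id = track$track_id, time = tt[idx[keep]],
             angle_change = ang[keep], heading_before = hb[keep],
             heading_after = hf[keep],
             x = track$x[idx[keep]], y = track$y[idx[keep]])
}

# TRUE for positions within margin_mm of the arena (field) boundary; wall
# contacts produce sharp heading changes that are locomotor artifacts, not
# navigation decisions, so bearing-conditioned statistics exclude them
near_edge <- function(context, x_mm, y_mm, margin_mm) {
  if (margin_mm <= 0) return(rep(FALSE, length(x_mm)))
  xl <- range(context$field$x) * context$mm_per_unit
  yl <- range(context$field$y) * context$mm_per_unit
  x_mm < xl[1] + margin_mm | x_mm > xl[2] - margin_mm |
    y_mm < yl[1] + margin_mm | y_mm > yl[2] - margin_mm
}

# per-sample occupancy table across tracks: bearing, dt, speed, position
occupancy_samples <- function(tracks, context, edge_margin_mm = 0) {
  pieces <- lapply(tracks, function(tr) {
    b <- bearing_series(tr, context)
    dt <- c(diff(tr$times), 0)
    data.frame(bearing = b, dt = dt, speed = tr$speed,
               x = tr$x, y = tr$y)
  })
  occ <- do.call(rbind, pieces)
  occ[!near_edge(context, occ$x, occ$y, edge_margin_mm), , drop = FALSE]
}

# turn events across tracks with pre-turn bearing attached
turn_events <- function(tracks, context, threshold_deg = 60, window_s = 1.0,
                        edge_margin_mm = 0) {
  evs <- lapply(tracks, function(tr)
    detect_turns(tr, threshold_deg, window_s))
  ev <- do.call(rbind, evs)
  if (is.null(ev) || !nrow(ev)) return(ev)
  ev <- ev[!near_edge(context, ev$x, ev$y, edge_margin_mm), , drop = FALSE]
  if (!nrow(ev)) return(ev)
  gdir <- gradient_dir_at(context, ev$x, ev$y)
  ev$bearing_before <- wrap_angle(ev$heading_before - gdir)
  ev$bearing_after <- wrap_angle(ev$heading_after - gdir)
  ev
}

#' Turn rate as a function of bearing to the gradient
#'
#' Probability per unit time of observing a sharp turn, binned by the
#' absolute bearing to the local gradient: turns with |pre-turn bearing| in
#' a bin divided by the total track time spent at |bearing| in that bin.
#' Uncertainty from counting statistics (`sqrt(N) / T` per bin). A dip at
#' 0 deg and peak at 180 deg is the biased-random-walk signature.
#'
#' @param tracks list of (smoothed, filtered) [trajectory()] objects.
#' @param context a [gradient_context()].
#' @param bin_width_deg bin width on |bearing| in [0, 180].
#' @param threshold_deg,window_s passed to [detect_turns()].
#' @param edge_margin_mm occupancy and events this close to the arena wall
#'   are excluded: wall reflections produce heading changes that are not
#'   navigation decisions.
#' @return data.frame per bin: `bearing_lo`, `bearing_hi`, `bearing_mid`,
#'   `n_turns`, `occupancy_s`, `rate` (1/s; `NA` for empty bins), `se`.
#' @export
turn_rate_by_bearing <- function(tracks, context, bin_width_deg = 30,
                                 threshold_deg = 60, window_s = 1.0,
                                 edge_margin_mm = 5) {
  occ <- occupancy_samples(tracks, context, edge_margin_mm)
  ev <- turn_events(tracks, context, threshold_deg, window_s, edge_margin_mm)
  breaks <- seq(0, 180, by = bin_width_deg)
  occ_bin <- findInterval(abs(occ$bearing), breaks, rightmost.closed = TRUE)
  T_bin <- vapply(seq_len(length(breaks) - 1L), function(i)
    sum(occ$dt[occ_bin == i], na.rm = TRUE), numeric(1))
  n_bin <- if (is.null(ev) || !nrow(ev)) rep(0, length(breaks) - 1L) else {
    eb <- findInterval(abs(ev$bearing_before), breaks, rightmost.closed = TRUE)
    vapply(seq_len(length(breaks) - 1L), function(i)
      sum(eb == i, na.rm = TRUE), numeric(1))
  }
  rate <- ifelse(T_bin > 0, n_bin / T_bin, NA_real_)
  se <- ifelse(T_bin > 0, sqrt(pmax(n_bin, 1)) / T_bin, NA_real_)
  data.frame(bearing_lo = breaks[-length(breaks)], bearing_hi = breaks[-1],
             bearing_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
             n_turns = n_bin, occupancy_s = T_bin, rate = rate, se = se)
}

#' Path curvature sampled at fixed arc length
#'
#' Resamples the path at 1 mm arc-length steps and returns the signed angle
#' between successive 1 mm displacement vectors, CCW-positive, in deg/mm.
#' Stationary segments contribute no samples. Each sample carries the
#' segment midpoint position and direction for bearing conditioning.
#'
#' @param track a [trajectory()] (positions mm).
#' @param step_mm arc-length step.
#' @return data.frame: `s` (arc length), `curvature` (deg/mm), `x`, `y`
#'   (mm, at the vertex), `heading` (deg, direction of the incoming
#'   segment). Empty if the path is shorter than 2 steps.
#' @export
curvature_series <- function(track, step_mm = 1.0) {
  stopifnot(inherits(track, "trajectory"))
  seg <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  s <- c(0, cumsum(seg))
  empty <- data.frame(s = numeric(), curvature = numeric(), x = numeric(),
                      y = numeric(), heading = numeric())
  if (s[length(s)] < 2 * step_mm) return(empty)
  # drop zero-length (stationary) segments for a strictly increasing map
  keep <- c(TRUE, diff(s) > 1e-12)
  su <- s[keep]
  sv <- seq(0, su[length(su)], by = step_mm)
  xr <- stats::approx(su, track$x[keep], sv)$y
  yr <- stats::approx(su, track$y[keep], sv)$y
  dx <- diff(xr); dy <- diff(yr)
  hd <- atan2(dy, dx) * 180 / pi
  curv <- wrap_angle(diff(hd)) / step_mm
  v <- 2:(length(sv) - 1L)
  data.frame(s = sv[v], curvature = curv, x = xr[v], y = yr[v],
             heading = hd[v - 1L])
}

# pooled curvature samples with bearings across tracks
curvature_samples <- function(tracks, context, step_mm = 1.0) {
  pieces <- lapply(tracks, function(tr) curvature_series(tr, step_mm))
  cs <- do.call(rbind, pieces)
  if (is.null(cs) || !nrow(cs)) return(cs)
  gdir <- gradient_dir_at(context, cs$x, cs$y)
  cs$bearing <- wrap_angle(cs$heading - gdir)
  cs[!is.na(cs$bearing), , drop = FALSE]
}

# bearing quadrant classes: up |b|<45, perpendicular 45<=|b|<135 (split by
# sign), down |b|>=135
bearing_class <- function(b) {
  cls <- rep(NA_character_, length(b))
  cls[abs(b) < 45] <- "up"
  cls[abs(b) >= 45 & abs(b) < 135 & b > 0] <- "perp_left"
  cls[abs(b) >= 45 & abs(b) < 135 & b <= 0] <- "perp_right"
  cls[abs(b) >= 135] <- "down"
  cls
}

#' Curvature distributions conditioned on bearing quadrant
#'
#' Distributions of path curvature in the bearing quadrants (up-gradient,
#' perpendicular, down-gradient), with the curvature sign of perpendicular
#' samples re-oriented so that positive means turning toward the gradient
#' (a positive bearing puts the gradient clockwise of the heading, so a
#' toward-gradient maneuver is a negative CCW curvature there). A positive
#' perpendicular-class mean is the weathervaning signature. Classes are
#' compared pairwise with two-sample Kolmogorov-Smirnov tests.
#'
#' @param tracks list of [trajectory()] objects.
#' @param context a [gradient_context()].
#' @param step_mm arc-length step for [curvature_series()].
#' @param min_samples classes with fewer samples are flagged low-power.
#' @return list with `samples` (data.frame curvature_toward x class),
#'   `means` (per-class mean, se, n, low_power), `ks_tests` (pairwise
#'   statistic and p-value, Bonferroni-flagged at alpha = 0.001).
#' @export
curvature_by_bearing <- function(tracks, context, step_mm = 1.0,
                                 min_samples = 50) {
  cs <- curvature_samples(tracks, context, step_mm)
  if (is.null(cs) || !nrow(cs)) stop("no curvature samples with defined bearing")
  cls3 <- bearing_class(cs$bearing)
  cls3[cls3 %in% c("perp_left", "perp_right")] <- "perpendicular"
  toward <- ifelse(cs$bearing > 0, -cs$curvature, cs$curvature)
  samples <- data.frame(class = cls3, curvature_toward = toward,
                        curvature = cs$curvature, bearing = cs$bearing)
  classes <- c("up", "perpendicular", "down")
  means <- do.call(rbind, lapply(classes, function(cl) {
    v <- samples$curvature_toward[samples$class == cl]
    data.frame(class = cl, n = length(v), mean = mean(v),
               se = stats::sd(v) / sqrt(max(length(v), 1)),
               low_power = length(v) < min_samples)
  }))
  pairs <- utils::combn(classes, 2)
  ks <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- samples$curvature_toward[samples$class == pairs[1, j]]
    b <- samples$curvature_toward[samples$class == pairs[2, j]]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(class_a = pairs[1, j], class_b = pairs[2, j],
                        statistic = NA, p_value = NA, significant = NA))
    kt <- suppressWarnings(stats::ks.test(a, b))
    data.frame(class_a = pairs[1, j], class_b = pairs[2, j],
               statistic = unname(kt$statistic), p_value = kt$p.value,
               significant = kt$p.value < 0.001 / ncol(pairs))
  }))
  list(samples = samples, means = means, ks_tests = ks)
}

#' Mean curvature as a function of signed bearing
#'
#' Mean signed curvature (CCW-positive, deg/mm) per signed-bearing bin with
#' standard errors. With this package's bearing convention (angle from
#' gradient to velocity, CCW-positive) weathervaning toward the gradient
#' appears as an antisymmetric, roughly sinusoidal curve
#' `mean curvature ~ -g sin(bearing)`; null navigators give a flat curve.
#'
#' @param tracks list of [trajectory()] objects.
#' @param context a [gradient_context()].
#' @param bin_width_deg signed-bearing bin width.
#' @param step_mm arc-length step.
#' @return data.frame per bin: `bearing_mid`, `n`, `mean_curvature`, `se`.
#' @export
mean_curvature_vs_bearing <- function(tracks, context, bin_width_deg = 30,
                                      step_mm = 1.0) {
  cs <- curvature_samples(tracks, context, step_mm)
  if (is.null(cs) || !nrow(cs)) stop("no curvature samples with defined bearing")
  breaks <- seq(-180, 180, by = bin_width_deg)
  bin <- findInterval(cs$bearing, breaks, rightmost.closed = TRUE)
  do.call(rbind, lapply(seq_len(length(breaks) - 1L), function(i) {
    v <- cs$curvature[bin == i]
    data.frame(bearing_mid = (breaks[i] + breaks[i + 1]) / 2, n = length(v),
               mean_curvature = if (length(v)) mean(v) else NA_real_,
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  }))
}

#' Drift velocity versus gradient steepness
#'
#' The drift velocity `V cos(theta)` -- the component of crawling velocity
#' along the local gradient -- binned by gradient magnitude. Per bin the
#' mean, lower/upper quartiles, a one-sample t-test against zero drift, and
#' two-sample t and Kolmogorov-Smirnov tests against the lowest-gradient
#' bin. Positive drift in all but the shallowest bin is the overall
#' chemotaxis-performance signature.
#'
#' @param tracks list of [trajectory()] objects.
#' @param context a [gradient_context()].
#' @param n_bins number of gradient-magnitude bins (quantile edges).
#' @param stride_s subsampling interval, s: consecutive video-rate samples
#'   of one animal are strongly autocorrelated (bearings decorrelate on the
#'   turn timescale ~1/lambda0), so drift measurements enter the tests at
#'   this stride to keep them approximately independent.
#' @return data.frame per bin: `grad_lo/hi/mid` (ppm/mm), `n`, `mean_drift`
#'   (mm/s), `q25`, `q75`, `p_zero` (t-test vs 0), `p_t_vs_first`,
#'   `p_ks_vs_first`.
#' @export
drift_velocity_curve <- function(tracks, context, n_bins = 5, stride_s = 30) {
  pieces <- lapply(tracks, function(tr) {
    b <- bearing_series(tr, context)
    g <- gradient_eval(context$grad, tr$x / context$mm_per_unit,
                       tr$y / context$mm_per_unit)
    gmag_mm <- sqrt(g$gx^2 + g$gy^2) / context$mm_per_unit  # ppm/mm
    dt <- stats::median(diff(tr$times))
    k <- max(1L, round(stride_s / dt))
    i <- seq(1L, length(tr$times), by = k)
    data.frame(drift = (tr$speed * cos(b * pi / 180))[i], gmag = gmag_mm[i])
  })
  d <- do.call(rbind, pieces)
  d <- d[is.finite(d$drift) & is.finite(d$gmag), ]
  if (!nrow(d)) stop("no samples with defined drift velocity")
  edges <- unique(stats::quantile(d$gmag, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(edges) < 3) stop("gradient magnitudes too concentrated to bin")
  bin <- findInterval(d$gmag, edges, rightmost.closed = TRUE)
  first <- d$drift[bin == 1L]
  do.call(rbind, lapply(seq_len(length(edges) - 1L), function(i) {
    v <- d$drift[bin == i]
    if (length(v) < 2)
      return(data.frame(grad_lo = edges[i], grad_hi = edges[i + 1],
                        grad_mid = mean(edges[i:(i + 1)]), n = length(v),
                        mean_drift = if (length(v)) mean(v) else NA,
                        q25 = NA, q75 = NA, p_zero = NA,
                        p_t_vs_first = NA, p_ks_vs_first = NA))
    tz <- stats::t.test(v)
    tv <- if (i == 1L) NA_real_ else stats::t.test(v, first)$p.value
    kv <- if (i == 1L) NA_real_ else
      suppressWarnings(stats::ks.test(v, first)$p.value)
    data.frame(grad_lo = edges[i], grad_hi = edges[i + 1],
               grad_mid = mean(edges[i:(i + 1)]), n = length(v),
               mean_drift = mean(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)),
               p_zero = tz$p.value, p_t_vs_first = tv, p_ks_vs_first = kv)
  }))
}

#' Larva turn statistics: rate and corrective heading change by bearing
#'
#' Turn rate per bearing quadrant (counting-statistics errors) and the mean
#' signed bearing change across turns (bearing after minus bearing before,
#' wrapped, circular mean) per pre-turn bearing quadrant. Turns are
#' centroid-heading-change events from [detect_turns()] (posture-based
#' head-cast detection is out of scope). The chemotaxis signatures: a
#' higher rate headed down-gradient than up-gradient, and corrective
#' reorientation -- negative mean change from +90 deg bearing, positive
#' from -90 deg.
#'
#' @param tracks list of [trajectory()] objects (larva speed ~3 mm/s).
#' @param context a [gradient_context()].
#' @param threshold_deg,window_s turn detection parameters.
#' @param min_turns fewer total turns flags the output low-power.
#' @param edge_margin_mm wall-exclusion margin as in
#'   [turn_rate_by_bearing()]; larvae hit the walls often at ~3 mm/s and
#'   the specular heading flips would otherwise contaminate the
#'   down-gradient classes.
#' @return list with `rates` (per quadrant: n, occupancy, rate, se),
#'   `heading_changes` (per pre-turn quadrant: n, circular mean change,
#'   se), `n_turns`, `low_power`.
#' @export
larva_turn_statistics <- function(tracks, context, threshold_deg = 60,
                                  window_s = 1.0, min_turns = 20,
                                  edge_margin_mm = 5) {
  occ <- occupancy_samples(tracks, context, edge_margin_mm)
  ev <- turn_events(tracks, context, threshold_deg, window_s, edge_margin_mm)
  classes <- c("up", "perp_left", "perp_right", "down")
  occ_cls <- bearing_class(occ$bearing)
  T_cls <- vapply(classes, function(cl)
    sum(occ$dt[occ_cls == cl], na.rm = TRUE), numeric(1))
  n_total <- if (is.null(ev)) 0L else nrow(ev)
  if (n_total) {
    ev <- ev[!is.na(ev$bearing_before), , drop = FALSE]
    ev_cls <- bearing_class(ev$bearing_before)
    dchg <- wrap_angle(ev$bearing_after - ev$bearing_before)
  } else {
    ev_cls <- character()
    dchg <- numeric()
  }
  rates <- do.call(rbind, lapply(classes, function(cl) {
    n <- sum(ev_cls == cl)
    data.frame(class = cl, n_turns = n, occupancy_s = T_cls[[cl]],
               rate = if (T_cls[[cl]] > 0) n / T_cls[[cl]] else NA_real_,
               se = if (T_cls[[cl]] > 0) sqrt(max(n, 1)) / T_cls[[cl]] else NA_real_)
  }))
  heading_changes <- do.call(rbind, lapply(classes, function(cl) {
    v <- dchg[ev_cls == cl]
    data.frame(class = cl, n = length(v),
               mean_change = if (length(v)) circ_mean(v) else NA_real_,
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  }))
  list(rates = rates, heading_changes = heading_changes,
       n_turns = n_total, low_power = n_total < min_turns)
}
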