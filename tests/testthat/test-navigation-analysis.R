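test_that("angle wrapping and circular means behave", {
  expect_equal(wrap_angle(c(190, -190, 360, 180, -180)),
               c(-170, 170, 0, 180, 180))
  # circular mean of {+179, -179} is +/-180, not 0
  expect_equal(abs(odorscape:::circ_mean(c(179, -179))), 180)
})

test_that("track smoothing removes noise but preserves clean paths", {
  tt <- seq(0, 10, by = 1 / 14)
  # straight line unchanged
  straight <- trajectory("s", tt, 0.5 * tt, -0.2 * tt)
  sm <- smooth_track(straight)
  expect_lt(max(abs(sm$x - straight$x)), 1e-9)
  expect_lt(max(abs(sm$y - straight$y)), 1e-9)
  # constant position unchanged
  const <- trajectory("c", tt, rep(1, length(tt)), rep(2, length(tt)))
  smc <- smooth_track(const)
  expect_equal(smc$x, const$x)
  # sine path + one-pixel white noise: RMS error halved at least
  set.seed(21)
  cx <- tt; cy <- sin(tt)
  noisy <- trajectory("n", tt, cx + rnorm(length(tt), 0, 0.032),
                      cy + rnorm(length(tt), 0, 0.032))
  smn <- smooth_track(noisy)
  rms_before <- sqrt(mean((noisy$x - cx)^2 + (noisy$y - cy)^2))
  rms_after <- sqrt(mean((smn$x - cx)^2 + (smn$y - cy)^2))
  # a cubic/7-point filter passes 1/3 of white-noise variance at its
  # center (sum of squared coefficients), so the achievable RMS reduction
  # is ~40-50%
  expect_lt(rms_after, 0.6 * rms_before)
  # too-short track returned flagged
  short <- trajectory("sh", c(0, 0.1), c(0, 1), c(0, 1))
  expect_true(isTRUE(attr(smooth_track(short), "unsmoothed")))
})

test_that("track filter applies the three rules with strict inequalities", {
  ctx <- ramp_context()  # max at y = 60 mm band, linear in y
  mk <- function(id, dur, disp, y0) {
    tt <- seq(0, dur, by = 1 / 14)
    trajectory(id, tt, seq(0, disp, length.out = length(tt)),
               rep(y0, length(tt)))
  }
  max_ppm <- ctx$max_ppm
  # concentration at height y (mm): 1 + slope * y/10 (grid in cm)
  y_at_frac <- function(f) (f * max_ppm - 1) / 1 * 10
  tracks <- list(
    mk("keep1", 90, 5, y_at_frac(0.2)),
    mk("drop_short", 30, 5, y_at_frac(0.2)),
    mk("drop_still", 90, 1, y_at_frac(0.2)),
    mk("drop_high", 90, 5, y_at_frac(0.8)),
    mk("keep2", 61, 3.1, y_at_frac(0.69)))
  kept <- filter_tracks(tracks, ctx)
  expect_equal(vapply(kept, `[[`, character(1), "track_id"),
               c("keep1", "keep2"))
  # boundary cases at exactly 60 s / 3 mm are dropped (strict >)
  boundary <- list(mk("at60", 60, 5, y_at_frac(0.2)),
                   mk("at3mm", 90, 3, y_at_frac(0.2)),
                   mk("at70pc", 90, 5, y_at_frac(0.7)))
  kept_b <- filter_tracks(boundary, ctx)
  expect_equal(vapply(kept_b, `[[`, character(1), "track_id"), "at70pc")
  # all passing -> identity
  ok <- list(mk("a", 90, 5, y_at_frac(0.1)), mk("b", 70, 4, y_at_frac(0.3)))
  expect_length(filter_tracks(ok, ctx), 2)
})

test_that("turn detection matches constructed paths", {
  tt <- seq(0, 60, by = 1 / 14)
  # straight: no events
  straight <- trajectory("s", tt, 0.2 * tt, 0 * tt)
  expect_equal(nrow(detect_turns(straight)), 0)
  # single instantaneous 90-degree bend
  n <- length(tt); half <- floor(n / 2)
  bend <- trajectory("b", tt,
                     c(0.2 * tt[1:half], rep(0.2 * tt[half], n - half)),
                     c(rep(0, half), 0.2 * (tt[(half + 1):n] - tt[half])))
  ev <- detect_turns(bend)
  expect_equal(nrow(ev), 1)
  expect_equal(abs(ev$angle_change), 90, tolerance = 2)
  # slow 30 deg/s arc: windowed angle stays < 60 deg -> no events
  arc30 <- trajectory("a30", tt, cumsum(0.01 * cospi(30 * tt / 180)),
                      cumsum(0.01 * sinpi(30 * tt / 180)))
  expect_equal(nrow(detect_turns(arc30)), 0)
  # 90 deg/s arc: continuous turning, deduplicated within refractory bouts
  arc90 <- trajectory("a90", tt[tt <= 3],
                      cumsum(0.01 * cospi(90 * tt[tt <= 3] / 180)),
                      cumsum(0.01 * sinpi(90 * tt[tt <= 3] / 180)))
  ev90 <- detect_turns(arc90)
  expect_gte(nrow(ev90), 1)
  # refractory: events separated by > 1 s
  if (nrow(ev90) > 1) expect_true(all(diff(ev90$time) > 1))
  # too-short track: empty
  expect_equal(nrow(detect_turns(trajectory("t", tt[1:14], tt[1:14], tt[1:14]))), 0)
})

test_that("turn detection agrees with the brute-force oracle", {
  set.seed(31)
  agree <- 0
  for (i in 1:100) {
    tt <- seq(0, 30, by = 1 / 14)
    # random run-and-turn path
    heading <- cumsum(c(runif(1, -180, 180),
                        rnorm(length(tt) - 1, 0, 4) +
                          sample(c(0, 120, -120), length(tt) - 1, TRUE,
                                 c(0.992, 0.004, 0.004))))
    x <- cumsum(0.05 * cospi(heading / 180))
    y <- cumsum(0.05 * sinpi(heading / 180))
    tr <- trajectory(sprintf("r%d", i), tt, x, y)
    ev <- detect_turns(tr)
    orc <- oracle_turns(tr)
    same_n <- nrow(ev) == nrow(orc)
    same_t <- same_n && (nrow(ev) == 0 ||
                           all(abs(ev$time - orc$time) <= 1 / 14 + 1e-9))
    agree <- agree + (same_n && same_t)
  }
  expect_equal(agree, 100)
})

test_that("bearings follow the gradient-frame convention", {
  ctx <- ramp_context()  # gradient points +y everywhere
  tt <- seq(0, 10, 1 / 14)
  up <- trajectory("up", tt, rep(30, length(tt)), 20 + 0.5 * tt)
  expect_equal(median(bearing_series(up, ctx), na.rm = TRUE), 0, tolerance = 1e-6)
  down <- trajectory("dn", tt, rep(30, length(tt)), 40 - 0.5 * tt)
  expect_equal(abs(median(bearing_series(down, ctx), na.rm = TRUE)), 180,
               tolerance = 1e-6)
  # uniform field: all samples undefined
  xg <- seq(0, 6, 0.5); yg <- seq(0, 6, 0.5)
  uni <- gradient_context(scalar_field(xg, yg, matrix(2, 13, 13)))
  expect_true(all(is.na(bearing_series(up, uni))))
})

test_that("curvature sampling matches circle geometry and chirality", {
  tt <- seq(0, 100, by = 1 / 14)
  # straight path: all zeros
  straight <- trajectory("s", tt, 2 * tt, rep(0, length(tt)))
  cs <- curvature_series(straight)
  expect_lt(max(abs(cs$curvature)), 1e-6)
  # circle of radius R: |curvature| = (180/pi)/R deg/mm
  for (R in c(3, 5, 10)) {
    th <- seq(0, 4 * pi, length.out = 2000)
    circ <- trajectory("c", seq_along(th) / 14, R * cos(th), R * sin(th))
    cc <- curvature_series(circ)
    expect_equal(median(abs(cc$curvature)), (180 / pi) / R,
                 tolerance = 0.02)
    # mirrored path: negated curvature
    mir <- trajectory("m", seq_along(th) / 14, R * cos(th), -R * sin(th))
    cm <- curvature_series(mir)
    expect_equal(median(cm$curvature), -median(cc$curvature),
                 tolerance = 1e-6)
  }
})

test_that("turn-rate modulation is recovered and null agents are flat", {
  ctx <- study_context()
  # biased population
  tr <- simulate_agents(ctx, worm_params(turn_bias_b = 0.5), 200, 1200,
                        seed = 11)
  rates <- turn_rate_by_bearing(lapply(tr, smooth_track), ctx)
  lam <- function(theta) 0.03 * (1 - 0.5 * cos(theta * pi / 180))
  # per-bin agreement with the generative law, allowing the detector's
  # known downward bias (refractory merging plus sub-threshold kernel
  # mass lose a few percent of true turns)
  expect_true(all(abs(rates$rate - lam(rates$bearing_mid)) <=
                    2.5 * rates$se + 0.1 * lam(rates$bearing_mid)))
  expect_equal(which.min(rates$rate), 1)
  expect_equal(which.max(rates$rate), nrow(rates))
  # fitted modulation recovers (lambda0, b) within 20%
  fit <- nls(rate ~ l0 * (1 - b * cos(bearing_mid * pi / 180)), data = rates,
             start = list(l0 = 0.02, b = 0.3), weights = 1 / rates$se^2)
  expect_lt(abs(coef(fit)["l0"] - 0.03) / 0.03, 0.2)
  expect_lt(abs(coef(fit)["b"] - 0.5) / 0.5, 0.2)
  # null agents: flat (no bin off by > 3 SE from the pooled mean)
  tr0 <- simulate_agents(ctx, worm_params(), 150, 1200, seed = 12)
  r0 <- turn_rate_by_bearing(lapply(tr0, smooth_track), ctx)
  pooled <- sum(r0$n_turns) / sum(r0$occupancy_s)
  expect_true(all(abs(r0$rate - pooled) <= 3 * r0$se))
  # single turn, single bin: rate = 1 / occupancy
  expect_equal(r0$rate, r0$n_turns / r0$occupancy_s)
})

test_that("weathervaning appears in curvature statistics iff g > 0", {
  ctx <- study_context()
  tr <- simulate_agents(ctx, worm_params(weathervane_gain_g = 2), 200, 1200,
                        seed = 13)
  trs <- lapply(tr, smooth_track)
  cb <- curvature_by_bearing(trs, ctx)
  perp <- cb$means[cb$means$class == "perpendicular", ]
  expect_gt(perp$mean / perp$se, 3)   # skew toward the gradient
  up <- cb$means[cb$means$class == "up", ]
  expect_lt(abs(up$mean), perp$mean)  # aligned class much less skewed
  # mean curvature vs bearing ~ -g sin(theta)
  mc <- mean_curvature_vs_bearing(trs, ctx)
  expect_true(all(abs(mc$mean_curvature - (-2 * sinpi(mc$bearing_mid / 180)))
                  <= 2.5 * mc$se))
  # null agents: class means near zero, KS tests mostly non-significant
  tr0 <- simulate_agents(ctx, worm_params(), 150, 1200, seed = 14)
  cb0 <- curvature_by_bearing(lapply(tr0, smooth_track), ctx)
  expect_true(all(abs(cb0$means$mean) <= 3 * cb0$means$se))
  mc0 <- mean_curvature_vs_bearing(lapply(tr0, smooth_track), ctx)
  expect_true(all(abs(mc0$mean_curvature) <= 3 * mc0$se))
})

test_that("reversing the gradient flips the mean-curvature curve", {
  ctx <- ramp_context(slope = 1)
  # the same tracks against the reversed-gradient field
  xg <- ctx$field$x; yg <- ctx$field$y
  rev_ctx <- gradient_context(scalar_field(xg, yg,
                                           max(ctx$field$values) + 1 -
                                             ctx$field$values))
  set.seed(15)
  tr <- simulate_agents(ctx, worm_params(weathervane_gain_g = 3), 60, 600,
                        seed = 15)
  mc_f <- mean_curvature_vs_bearing(tr, ctx, bin_width_deg = 45)
  mc_r <- mean_curvature_vs_bearing(tr, rev_ctx, bin_width_deg = 45)
  # bearing flips by 180: bin at theta maps to theta - 180; curve negates
  # in the sense that kappa(theta) = kappa_rev(wrap(theta - 180))
  m <- mc_f$mean_curvature
  mr <- mc_r$mean_curvature
  shifted <- c(mr[5:8], mr[1:4])
  ok <- is.finite(m) & is.finite(shifted)
  expect_gt(cor(m[ok], shifted[ok]), 0.8)
})

test_that("drift velocity is positive for chemotacting agents, null otherwise", {
  ctx <- study_context()
  tr <- simulate_agents(ctx, worm_params(turn_bias_b = 0.5,
                                         weathervane_gain_g = 2),
                        200, 1200, seed = 16)
  dv <- drift_velocity_curve(lapply(tr, smooth_track), ctx)
  expect_true(all(dv$mean_drift[-1] > 0))
  expect_true(all(dv$p_zero[-1] < 0.001))
  # bounded by the crawl speed
  expect_true(all(abs(c(dv$q25, dv$q75)) <= 0.1 + 1e-9))
  # null agents: no bin beyond 3 SE of zero
  tr0 <- simulate_agents(ctx, worm_params(), 150, 1200, seed = 17)
  dv0 <- drift_velocity_curve(lapply(tr0, smooth_track), ctx)
  se0 <- (dv0$q75 - dv0$q25) / sqrt(dv0$n)  # IQR-scale SE proxy
  expect_true(all(abs(dv0$mean_drift) <= 3.5 * se0))
})

test_that("larva statistics show both navigation signatures", {
  ctx <- study_context()
  ap <- larva_params(turn_bias_b = 0.5, turn_dir_bias = 0.7)
  tr <- simulate_agents(ctx, ap, 60, 600, seed = 18)
  st <- larva_turn_statistics(lapply(tr, smooth_track), ctx)
  expect_false(st$low_power)
  r <- st$rates
  up <- r[r$class == "up", ]; down <- r[r$class == "down", ]
  # higher rate headed down-gradient, beyond 2 SE
  expect_gt(down$rate - up$rate, 2 * sqrt(down$se^2 + up$se^2))
  h <- st$heading_changes
  left <- h[h$class == "perp_left", ]    # +90 bearing
  right <- h[h$class == "perp_right", ]  # -90 bearing
  expect_lt(left$mean_change + 2 * left$se, 0)
  expect_gt(right$mean_change - 2 * right$se, 0)
  # null agents: flat rates, centered heading changes
  tr0 <- simulate_agents(ctx, larva_params(), 60, 600, seed = 19)
  st0 <- larva_turn_statistics(lapply(tr0, smooth_track), ctx)
  pooled <- sum(st0$rates$n_turns) / sum(st0$rates$occupancy_s)
  expect_true(all(abs(st0$rates$rate - pooled) <= 3 * st0$rates$se))
  # null mean changes are small against the corrective signature (~130 deg);
  # turns cluster within tracks, so the naive SE understates the spread and
  # an absolute bound is the honest check
  expect_true(all(abs(st0$heading_changes$mean_change) <= 35))
})

test_that("a single constructed corrective turn is classified exactly", {
  ctx <- ramp_context()  # gradient +y
  tt <- seq(0, 4, 1 / 14)
  n <- length(tt); half <- floor(n / 2)
  # heading 180 deg (bearing +90), then turn to heading 90 (bearing 0)
  x <- c(40 - 3 * tt[1:half], rep(40 - 3 * tt[half], n - half))
  y <- c(rep(20, half), 20 + 3 * (tt[(half + 1):n] - tt[half]))
  tr <- trajectory("one", tt, x, y)
  st <- larva_turn_statistics(list(tr), ctx)
  expect_true(st$low_power)  # a single turn
  left <- st$heading_changes[st$heading_changes$class == "perp_left", ]
  expect_equal(left$n, 1)
  expect_equal(left$mean_change, -90, tolerance = 3)
})

test_that("bearing statistics are invariant under scene rotation", {
  ctx <- ramp_context()
  set.seed(22)
  tr <- simulate_agents(ctx, worm_params(turn_bias_b = 0.5,
                                         weathervane_gain_g = 2),
                        40, 600, seed = 22)
  rates <- turn_rate_by_bearing(tr, ctx)
  # rotate field and tracks by 90 degrees: gradient now along -x
  xg <- ctx$field$x; yg <- ctx$field$y
  rot_field <- scalar_field(xg, yg,
                            t(ctx$field$values[, rev(seq_along(yg))]))
  # rotating (x, y) -> (-y, x) about the arena center
  cx <- mean(range(xg)) * 10; cy <- mean(range(yg)) * 10
  rot_tracks <- lapply(tr, function(t1)
    trajectory(t1$track_id, t1$times,
               cx - (t1$y - cy), cy + (t1$x - cx)))
  rot_ctx <- gradient_context(rot_field)
  rates_rot <- turn_rate_by_bearing(rot_tracks, rot_ctx)
  expect_equal(rates_rot$n_turns, rates$n_turns, tolerance = 0.05)
  expect_equal(rates_rot$rate, rates$rate, tolerance = 0.05)
})

test_that("tidy tracking tables split on gaps and convert cleanly", {
  df <- data.frame(track_id = c(rep(1, 10), rep(2, 6)),
                   time_s = c(1:5, 10:14, 1:6),
                   x_mm = runif(16), y_mm = runif(16))
  trs <- as_trajectories(df)
  expect_length(trs, 3)  # track 1 split at the 5 s gap
  expect_true(all(vapply(trs, function(t1)
    all(diff(t1$times) <= 1), logical(1))))
})
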