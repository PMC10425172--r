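# shared small-chamber setup for the spatial tests
agar_setup <- function(length = 8, dx = 0.2) {
  geom <- chamber_geometry(length = length)
  xg <- seq(0, length, by = dx)
  yg <- seq(-7.5, 7.5, by = dx)
  list(geom = geom, xg = xg, yg = yg,
       mask = rect_mask(xg, yg, c(3, 6), c(-4.8, 4.8)),
       empty = matrix(FALSE, length(xg), length(yg)))
}

test_that("point model: w = 0 relaxes exponentially on the chamber timescale", {
  p <- agar_params(absorption_weight_w = 0, chamber_timescale_tau = 34)
  sim <- simulate_point_model(p, source_schedule(0, 100), duration = 300)
  expected <- 100 * (1 - exp(-sim$time / 34))
  expect_lt(max(abs(sim$C - expected)), 1)
})

test_that("point model steady state is Co for any agar parameters", {
  # the quasi-equilibrium identity: C* = Co independent of (w, ka, kd, M)
  for (pars in list(list(w = 1, ka = 0.05, kd = 0.001, M = 200),
                    list(w = 2, ka = 0.2, kd = 0.01, M = 120),
                    list(w = 0.5, ka = 0.01, kd = 0.0005, M = 500))) {
    p <- agar_params(absorption_weight_w = pars$w, assoc_rate_ka = pars$ka,
                     dissoc_rate_kd = pars$kd, capacity_M = pars$M)
    horizon <- 20 * max(p$chamber_timescale_tau, 1 / p$dissoc_rate_kd)
    sim <- simulate_point_model(p, source_schedule(0, 100), horizon)
    expect_equal(tail(sim$C, 1), 100, tolerance = 1e-3)
    ss <- point_model_steady_state(p, 100)
    expect_equal(tail(sim$A, 1), ss$A, tolerance = 1e-3)
  }
})

test_that("absorbing agar slows the approach to equilibrium", {
  t95 <- function(p) {
    sim <- simulate_point_model(p, source_schedule(0, 100), 4000)
    sim$time[min(which(sim$C >= 95))]
  }
  expect_gt(t95(agar_params()), t95(agar_params(absorption_weight_w = 0)))
})

test_that("point model enforces its stability precondition", {
  p <- agar_params(chamber_timescale_tau = 5)
  expect_error(simulate_point_model(p, source_schedule(0, 10), 100, dt = 2),
               "step-size")
})

test_that("spatial solver with w = 0 matches the marching closed form", {
  su <- agar_setup()
  p <- agar_params(absorption_weight_w = 0)
  res <- simulate_field(p, su$empty, source_schedule(0, 100), su$geom, 150,
                        dx = 0.2)
  march <- steady_plume_field(plume_params(), su$geom, nx = 40, ny = 101)
  pde <- res$state$air_field_C
  gg <- expand.grid(x = march$x, y = march$y)
  pv <- field_eval(pde, gg$x, gg$y)
  expect_lt(sqrt(mean((pv - as.vector(march$values))^2)) / max(march$values),
            0.03)
})

test_that("empty mask is bit-identical to w = 0 under the same stepping", {
  su <- agar_setup(length = 5)
  p0 <- agar_params(absorption_weight_w = 0)
  p1 <- agar_params(absorption_weight_w = 1)
  empty <- matrix(FALSE, length(seq(0, 5, 0.2)), length(su$yg))
  r0 <- simulate_field(p0, empty, source_schedule(0, 100), su$geom, 30,
                       dx = 0.2, dt = 0.05)
  r1 <- simulate_field(p1, empty, source_schedule(0, 100), su$geom, 30,
                       dx = 0.2, dt = 0.05)
  expect_identical(r0$state$air_field_C$values, r1$state$air_field_C$values)
})

test_that("agar depresses the downstream profile but not the upstream one", {
  # full-size agar slab (9.6 cm, as on the bench) shortly after flow onset
  geom <- chamber_geometry(length = 14)
  xg <- seq(0, 14, 0.2); yg <- seq(-7.5, 7.5, 0.2)
  mask <- rect_mask(xg, yg, c(2.2, 11.8), c(-4.8, 4.8))
  p <- agar_params()
  p0 <- agar_params(absorption_weight_w = 0)
  r1 <- simulate_field(p, mask, source_schedule(0, 100), geom, 90, dx = 0.2)
  r0 <- simulate_field(p0, mask, source_schedule(0, 100), geom, 90, dx = 0.2)
  b1 <- boundary_profiles(r1$state)
  b0 <- boundary_profiles(agar_state(r0$state$air_field_C,
                                     r0$state$agar_field_A, mask, 90))
  # downstream depressed
  expect_lt(max(b1$downstream$ppm), 0.8 * max(b0$downstream$ppm))
  # upstream essentially unchanged: > 95% of nodes within 2%
  up_ref <- pmax(b0$upstream$ppm, 0.01 * max(b0$upstream$ppm))
  frac_close <- mean(abs(b1$upstream$ppm - b0$upstream$ppm) / up_ref < 0.02)
  expect_gt(frac_close, 0.95)
})

test_that("solver guards: CFL, inlet mask, grid mismatch, full-length mask", {
  su <- agar_setup(length = 5)
  p <- agar_params()
  mask_inlet <- su$mask[seq_along(seq(0, 5, 0.2)), ]
  mask_inlet[1, 10] <- TRUE
  expect_error(simulate_field(p, mask_inlet, source_schedule(0, 1), su$geom,
                              10, dx = 0.2), "inlet")
  empty5 <- matrix(FALSE, length(seq(0, 5, 0.2)), length(su$yg))
  expect_error(simulate_field(p, empty5, source_schedule(0, 1), su$geom, 10,
                              dx = 0.2, dt = 10), "CFL|step-size")
  expect_error(simulate_field(p, su$empty, source_schedule(0, 1), su$geom,
                              10, dx = 0.4), "dimensions")
  full <- matrix(TRUE, length(seq(0, 5, 0.2)), length(su$yg))
  full[1, ] <- FALSE
  st <- simulate_field(p, full, source_schedule(0, 1), su$geom, 5, dx = 0.2)
  expect_error(boundary_profiles(st$state), "full")
})

test_that("mass budget closes each step", {
  su <- agar_setup(length = 6)
  p <- agar_params()
  mask <- rect_mask(seq(0, 6, 0.2), su$yg, c(2, 4), c(-4, 4))
  res <- simulate_field(p, mask, source_schedule(0, 100), su$geom, 100,
                        dx = 0.2)
  expect_lt(max(abs(res$mass_balance)), 0.005)
})

test_that("agar loading is monotone under a non-decreasing source", {
  su <- agar_setup(length = 6)
  p <- agar_params()
  mask <- rect_mask(seq(0, 6, 0.2), su$yg, c(2, 4), c(-4, 4))
  res <- simulate_field(p, mask, source_schedule(0, 100), su$geom, 120,
                        dx = 0.2, snapshot_times = c(30, 60, 90, 120))
  A_tot <- vapply(res$snapshots, function(s) sum(s$agar_field_A$values),
                  numeric(1))
  expect_true(all(diff(A_tot) > 0))
  A_nodes <- vapply(res$snapshots, function(s)
    any(diff(t(rbind(0, sapply(res$snapshots, function(z)
      z$agar_field_A$values[31, 38])))) < -1e-9), logical(1))
  # per-node monotonicity at a probe node
  a_series <- vapply(res$snapshots, function(s) s$agar_field_A$values[16, 38],
                     numeric(1))
  expect_true(all(diff(a_series) >= -1e-9))
  # A bounded by capacity, C non-negative
  expect_true(all(res$state$agar_field_A$values <= p$capacity_M + 1e-9))
  expect_true(all(res$state$air_field_C$values >= 0))
})

test_that("after shutoff the agar re-emits a downstream tail", {
  su <- agar_setup(length = 6)
  mask <- rect_mask(seq(0, 6, 0.2), su$yg, c(2, 4), c(-4, 4))
  sched <- source_schedule(c(0, 300), c(100, 0))
  p <- agar_params()
  p0 <- agar_params(absorption_weight_w = 0)
  probe <- data.frame(x = 4.4, y = 0)
  r1 <- simulate_field(p, mask, sched, su$geom, 500, dx = 0.2, probe = probe)
  r0 <- simulate_field(p0, mask, sched, su$geom, 500, dx = 0.2, probe = probe)
  after <- r1$probe_trace$time > 320
  expect_true(any(r1$probe_trace[after, 2] > r0$probe_trace[after, 2] + 0.5))
})

test_that("fractional difference has its closed-form values", {
  xg <- seq(1, 5, 0.5); yg <- seq(-2, 2, 0.5)
  b <- scalar_field(xg, yg, matrix(10, length(xg), length(yg)))
  a <- scalar_field(xg, yg, matrix(11, length(xg), length(yg)))
  expect_equal(fractional_difference(b, b), 0)
  expect_equal(fractional_difference(a, b), 0.10)
  other <- scalar_field(seq(0, 4, 0.5), yg, matrix(1, 9, 9))
  expect_error(fractional_difference(a, other), "grid")
})

test_that("boundary profiles behave on constructed fields", {
  su <- agar_setup()
  p0 <- agar_params(absorption_weight_w = 0)
  res <- simulate_field(p0, su$empty, source_schedule(0, 100), su$geom, 120,
                        dx = 0.2)
  st <- agar_state(res$state$air_field_C, res$state$agar_field_A, su$mask, 120)
  bp <- boundary_profiles(st)
  # both profiles Gaussian-like, downstream wider
  fu <- gaussian_fit_profile(bp$upstream$y, bp$upstream$ppm)
  fd <- gaussian_fit_profile(bp$downstream$y, bp$downstream$ppm)
  expect_false(fu$degenerate); expect_false(fd$degenerate)
  expect_gt(fd$width, fu$width)
  # uniform field: both profiles constant
  uni <- scalar_field(su$xg, su$yg,
                      matrix(5, length(su$xg), length(su$yg)))
  stu <- agar_state(uni, scalar_field(su$xg, su$yg,
                                      0 * uni$values), su$mask, 0)
  bpu <- boundary_profiles(stu)
  expect_equal(var(bpu$upstream$ppm), 0)
  expect_equal(var(bpu$downstream$ppm), 0)
})

test_that("pre-equilibration design meets its contract", {
  su <- agar_setup()
  p <- agar_params()
  monitor <- data.frame(x = 6.4, y = c(-1, 0, 1))
  # boost = target degenerates to a constant schedule
  pe0 <- design_preequilibration(p, su$mask, 50, 50, su$geom, monitor,
                                 max_duration = 400, settle_duration = 0,
                                 dx = 0.2)
  expect_length(pe0$schedule$times, 1)
  expect_equal(pe0$switch_time, 0)
  # boosted protocol: switch found, post-switch overshoot decays
  pe <- design_preequilibration(p, su$mask, 50, 500, su$geom, monitor,
                                settle_duration = 400, dx = 0.2)
  expect_gt(pe$switch_time, 0)
  tr <- pe$monitor_trace
  late <- tr$level[tr$time > pe$switch_time + 300]
  expect_lt(abs(tail(late, 1) - pe$target_level) / pe$target_level, 0.10)
  # switch time decreases monotonically with boost
  sw <- vapply(c(2, 5, 10), function(fac)
    design_preequilibration(p, su$mask, 50, fac * 50, su$geom, monitor,
                            settle_duration = 0, dx = 0.2)$switch_time,
    numeric(1))
  expect_true(all(diff(sw) < 0))
})

test_that("pre-equilibration strictly beats the constant-source protocol", {
  su <- agar_setup()
  p <- agar_params()
  monitor <- data.frame(x = 6.4, y = c(-1, 0, 1))
  pe <- design_preequilibration(p, su$mask, 50, 500, su$geom, monitor,
                                settle_duration = 1200, dx = 0.2)
  cc <- simulate_field(p, su$mask, source_schedule(0, 50), su$geom,
                       pe$switch_time + 1200, dx = 0.2, probe = monitor)
  tgt <- pe$target_level
  time_within <- function(tr, tol = 0.05) {
    ok <- abs(tr$level - tgt) <= tol * tgt
    bad <- which(!ok)
    if (!length(bad)) return(tr$time[1])
    if (max(bad) == length(ok)) return(Inf)
    tr$time[max(bad) + 1]
  }
  t_pe <- time_within(pe$monitor_trace)
  t_cc <- time_within(odorscape:::monitor_mean(cc))
  expect_lt(t_pe, t_cc)
})

test_that("quasi-equilibrium identity holds in the spatial model", {
  # steady state with agar equals steady state without, interior RMS < 1%
  su <- agar_setup(length = 6)
  mask <- rect_mask(seq(0, 6, 0.2), su$yg, c(2, 4), c(-4, 4))
  p <- agar_params(dissoc_rate_kd = 0.01)  # faster kd to reach steady state
  horizon <- 1500
  r1 <- simulate_field(p, mask, source_schedule(0, 100), su$geom, horizon,
                       dx = 0.2)
  p0 <- agar_params(absorption_weight_w = 0)
  r0 <- simulate_field(p0, mask, source_schedule(0, 100), su$geom, 150,
                       dx = 0.2)
  C1 <- r1$state$air_field_C$values
  C0 <- r0$state$air_field_C$values
  interior <- C0 > 0.05 * max(C0)
  expect_lt(sqrt(mean((C1[interior] - C0[interior])^2)) / max(C0), 0.01)
})
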