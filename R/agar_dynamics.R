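#' Odor-agar interaction model parameters
#'
#' Parameters of the reaction-convection-diffusion description of odor flow
#' over an absorbing agar substrate. The airborne concentration `C` relaxes
#' toward the inflow `Co` on the chamber timescale `tau` while exchanging
#' molecules with the agar reservoir `A`:
#' `dC/dt = -(C - Co)/tau - w dA/dt`,
#' `dA/dt = ka C (1 - A/M) - kd A`.
#'
#' Numerical values of `ka`, `kd`, `M` and `w` are not measurable directly;
#' the defaults put the system in the strongly absorbing regime (`ka >> kd`,
#' target `Co < M`) in which pre-equilibration matters.
#'
#' @param chamber_timescale_tau chamber flushing timescale, s
#'   (volume / flow rate; ~34 s for 255 mL at 450 mL/min).
#' @param absorption_weight_w dimensionless coupling of agar flux into the
#'   air balance; 0 means no agar.
#' @param assoc_rate_ka association rate, 1/s.
#' @param dissoc_rate_kd dissociation rate, 1/s.
#' @param capacity_M maximum absorbable concentration, ppm-equivalent.
#' @param flow_speed_v bulk speed for the spatial model, cm/s.
#' @param diffusivity_D odor diffusivity for the spatial model, cm^2/s.
#' @return An `agar_params` object.
#' @export
agar_params <- function(chamber_timescale_tau = 34, absorption_weight_w = 1,
                        assoc_rate_ka = 0.05, dissoc_rate_kd = 0.001,
                        capacity_M = 200, flow_speed_v = 0.5,
                        diffusivity_D = 0.08) {
  if (chamber_timescale_tau <= 0) stop("tau must be positive")
  if (absorption_weight_w < 0) stop("w must be non-negative")
  if (assoc_rate_ka < 0 || dissoc_rate_kd < 0) stop("rates must be non-negative")
  if (capacity_M <= 0) stop("capacity M must be positive")
  structure(list(chamber_timescale_tau = chamber_timescale_tau,
                 absorption_weight_w = absorption_weight_w,
                 assoc_rate_ka = assoc_rate_ka,
                 dissoc_rate_kd = dissoc_rate_kd,
                 capacity_M = capacity_M,
                 flow_speed_v = flow_speed_v,
                 diffusivity_D = diffusivity_D),
            class = "agar_params")
}

#' @export
print.agar_params <- function(x, ...) {
  cat(sprintf(
    "<agar_params> tau = %g s, w = %g, ka = %g /s, kd = %g /s, M = %g ppm\n",
    x$chamber_timescale_tau, x$absorption_weight_w, x$assoc_rate_ka,
    x$dissoc_rate_kd, x$capacity_M))
  invisible(x)
}

#' Piecewise-constant source schedule
#'
#' Inflow odor concentration as a step function of time, e.g. the
#' pre-equilibration protocol (boost, then switch to the target).
#'
#' @param times breakpoint onset times, s, increasing, starting at 0.
#' @param Co inflow concentrations from each breakpoint on, ppm.
#' @return A `source_schedule` object; use it as a function of time via
#'   [schedule_at()].
#' @export
source_schedule <- function(times = 0, Co = 100) {
  times <- as.numeric(times); Co <- as.numeric(Co)
  if (length(times) != length(Co)) stop("times and Co must match in length")
  if (times[1] != 0) stop("the schedule must start at t = 0")
  if (any(diff(times) <= 0)) stop("breakpoint times must be increasing")
  if (any(Co < 0)) stop("Co must be non-negative")
  structure(list(times = times, Co = Co), class = "source_schedule")
}

#' @rdname source_schedule
#' @param schedule a `source_schedule`.
#' @param t query times, s.
#' @export
schedule_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "source_schedule"))
  schedule$Co[findInterval(t, schedule$times, rightmost.closed = FALSE)]
}

#' @export
print.source_schedule <- function(x, ...) {
  cat("<source_schedule>\n")
  for (i in seq_along(x$times))
    cat(sprintf("  t >= %8.1f s : Co = %g ppm\n", x$times[i], x$Co[i]))
  invisible(x)
}

#' Integrate the non-spatial odor-agar model
#'
#' Solves the coupled ODEs of [agar_params()] with `deSolve`, segment by
#' segment over the piecewise-constant source schedule. The fixed point for
#' constant `Co` is `C* = Co` (independent of the agar parameters -- the
#' quasi-equilibrium identity) and
#' `A* = ka Co M / (ka Co + kd M)`.
#'
#' @param params [agar_params()].
#' @param schedule [source_schedule()].
#' @param duration total simulated time, s.
#' @param dt output sampling step, s; must satisfy `dt < tau/10` and
#'   `dt < 1/(10 (ka + kd))`.
#' @param C0,A0 initial conditions.
#' @return data.frame with columns `time`, `C`, `A`.
#' @export
simulate_point_model <- function(params, schedule, duration, dt = NULL,
                                 C0 = 0, A0 = 0) {
  stopifnot(inherits(params, "agar_params"), inherits(schedule, "source_schedule"))
  p <- params
  dt_max <- min(p$chamber_timescale_tau / 10,
                1 / (10 * max(p$assoc_rate_ka + p$dissoc_rate_kd, 1e-12)))
  if (is.null(dt)) dt <- 0.5 * dt_max
  if (dt > dt_max)
    stop(sprintf("step-size error: dt must be <= min(tau/10, 1/(10(ka+kd))) = %.3g s",
                 dt_max))
  deriv <- function(t, y, parms) {
    C <- y[1]; A <- y[2]
    dA <- p$assoc_rate_ka * C * (1 - A / p$capacity_M) - p$dissoc_rate_kd * A
    dC <- -(C - parms$Co) / p$chamber_timescale_tau - p$absorption_weight_w * dA
    list(c(dC, dA))
  }
  brk <- c(schedule$times[schedule$times < duration], duration)
  out <- NULL
  y <- c(C = C0, A = A0)
  for (i in seq_len(length(brk) - 1L)) {
    tt <- seq(brk[i], brk[i + 1L], by = dt)
    if (tt[length(tt)] < brk[i + 1L]) tt <- c(tt, brk[i + 1L])
    seg <- deSolve::ode(y, tt, deriv,
                        parms = list(Co = schedule_at(schedule, brk[i])),
                        method = "lsoda")
    y <- c(C = unname(seg[nrow(seg), "C"]), A = unname(seg[nrow(seg), "A"]))
    out <- rbind(out, if (is.null(out)) seg else seg[-1, , drop = FALSE])
  }
  data.frame(time = out[, "time"], C = pmax(out[, "C"], 0),
             A = pmin(pmax(out[, "A"], 0), p$capacity_M))
}

#' Analytic steady state of the point odor-agar model
#'
#' @param params [agar_params()].
#' @param Co constant inflow concentration, ppm.
#' @return list with `C` (= Co) and `A` (= ka Co M / (ka Co + kd M)).
#' @export
point_model_steady_state <- function(params, Co) {
  stopifnot(inherits(params, "agar_params"))
  A <- params$assoc_rate_ka * Co * params$capacity_M /
    (params$assoc_rate_ka * Co + params$dissoc_rate_kd * params$capacity_M)
  list(C = Co, A = A)
}

#' State of the spatial odor-agar simulation
#'
#' @param air_field_C [scalar_field()] of airborne concentration, ppm.
#' @param agar_field_A [scalar_field()] of absorbed concentration
#'   (ppm-equivalent); non-zero only on the agar mask.
#' @param agar_mask logical matrix marking agar-covered grid nodes.
#' @param time simulation time, s.
#' @return An `agar_state` object.
#' @export
agar_state <- function(air_field_C, agar_field_A, agar_mask, time) {
  stopifnot(inherits(air_field_C, "scalar_field"),
            inherits(agar_field_A, "scalar_field"))
  if (any(agar_field_A$values[!agar_mask] != 0))
    stop("agar concentration must be zero off the agar mask")
  structure(list(air_field_C = air_field_C, agar_field_A = agar_field_A,
                 agar_mask = agar_mask, time = time),
            class = "agar_state")
}

#' @export
print.agar_state <- function(x, ...) {
  cat(sprintf("<agar_state> t = %.1f s, air max %.3g ppm, agar max %.3g\n",
              x$time, max(x$air_field_C$values), max(x$agar_field_A$values)))
  invisible(x)
}

#' Rectangular agar mask
#'
#' @param xg,yg grid coordinate vectors (cm).
#' @param x_range,y_range extents of the agar slab (cm).
#' @return logical matrix over the grid.
#' @export
rect_mask <- function(xg, yg, x_range, y_range) {
  outer(xg >= x_range[1] & xg <= x_range[2],
        yg >= y_range[1] & yg <= y_range[2], `&`)
}

#' Simulate the spatial reaction-convection-diffusion odor-agar system
#'
#' Explicit operator-split integration of
#' `dC/dt = -v dC/dx + D laplacian(C) - w dA/dt` with the local agar kinetics
#' `dA/dt = ka C (1 - A/M) - kd A` restricted to the agar mask. Per step:
#' first-order upwind convection, centered explicit diffusion, then the
#' reaction substep. Boundary conditions: Dirichlet inlet profile at `x = 0`
#' from the source schedule (top-hat cone source by default), zero-gradient
#' convective outflow at `x = L`, no-flux side walls.
#'
#' @param params [agar_params()].
#' @param agar_mask logical matrix over the grid (see [rect_mask()]); must
#'   not touch the inlet column.
#' @param schedule [source_schedule()].
#' @param geom [chamber_geometry()].
#' @param duration simulated time, s.
#' @param dx grid spacing, cm (default 0.2 = 2 mm).
#' @param dt time step, s; defaults to 80% of the stability bound
#'   `min(dx/v, dx^2/(4D), 1/(10(ka+kd)))`.
#' @param source_y,source_width inlet top-hat position and width, cm.
#' @param init optional initial `agar_state` to continue from.
#' @param snapshot_times times (s) at which to store full states.
#' @param probe optional data.frame of probe positions (`x`, `y` in cm)
#'   whose concentration is recorded every step.
#' @return list with `state` (final [agar_state()]), `snapshots` (list of
#'   states), `probe_trace` (data.frame time x probe), `mass_balance`
#'   (per-step relative residual of the mass budget).
#' @export
simulate_field <- function(params, agar_mask, schedule, geom, duration,
                           dx = 0.2, dt = NULL, source_y = 0,
                           source_width = 1, init = NULL,
                           snapshot_times = numeric(), probe = NULL) {
  stopifnot(inherits(params, "agar_params"), inherits(schedule, "source_schedule"),
            inherits(geom, "chamber_geometry"))
  v <- params$flow_speed_v; D <- params$diffusivity_D
  ka <- params$assoc_rate_ka; kd <- params$dissoc_rate_kd
  M <- params$capacity_M; w <- params$absorption_weight_w
  xg <- seq(0, geom$length, by = dx)
  yg <- seq(-geom$width / 2, geom$width / 2, by = dx)
  nx <- length(xg); ny <- length(yg)
  if (!all(dim(agar_mask) == c(nx, ny)))
    stop("agar_mask dimensions must match the grid")
  if (any(agar_mask[1, ]))
    stop("configuration error: agar mask touches the inlet boundary")
  dt_max <- min(dx / v, dx^2 / (4 * D), 1 / (10 * max(ka + kd, 1e-12)))
  if (is.null(dt)) dt <- 0.8 * dt_max
  if (dt > dt_max)
    stop(sprintf("step-size error: dt must be <= %.3g s (CFL)", dt_max))
  # inlet profile (unit amplitude), partial-cell top-hat
  inlet <- pmax(0, pmin(1, (source_width / 2 - abs(yg - source_y)) / dx + 0.5))
  if (!is.null(init)) {
    C <- init$air_field_C$values
    A <- init$agar_field_A$values
    t0 <- init$time
  } else {
    C <- matrix(0, nx, ny)
    A <- matrix(0, nx, ny)
    t0 <- 0
  }
  nsteps <- ceiling(duration / dt)
  snap_steps <- unique(pmin(nsteps, pmax(1L, round(snapshot_times / dt))))
  snapshots <- list()
  probe_trace <- NULL
  if (!is.null(probe))
    probe_trace <- matrix(NA_real_, nsteps, nrow(probe))
  mass_resid <- numeric(nsteps)
  cdx <- v * dt / dx
  ddx <- D * dt / dx^2
  for (s in seq_len(nsteps)) {
    t_now <- t0 + (s - 1) * dt
    Co <- schedule_at(schedule, t_now)
    C[1, ] <- Co * inlet  # Dirichlet boundary row, fixed within the step
    mass_before <- sum(C[2:nx, ]) + w * sum(A)
    # upwind convection in x (v > 0); interior rows only
    influx <- sum(C[1, ]) * cdx
    outflux <- sum(C[nx, ]) * cdx
    C[2:nx, ] <- C[2:nx, ] - cdx * (C[2:nx, ] - C[1:(nx - 1), ])
    # centered diffusion on interior rows: boundary row fixed, zero-gradient
    # ghost at the outlet, no-flux side walls
    influx <- influx + ddx * sum(C[1, ] - C[2, ])
    Ci <- C[2:nx, , drop = FALSE]
    ni <- nx - 1L
    Cxp <- Ci[c(2:ni, ni), , drop = FALSE]
    Cxm <- rbind(C[1, ], Ci[1:(ni - 1L), , drop = FALSE])
    Cyp <- Ci[, c(2:ny, ny), drop = FALSE]
    Cym <- Ci[, c(1, 1:(ny - 1L)), drop = FALSE]
    C[2:nx, ] <- Ci + ddx * (Cxp + Cxm + Cyp + Cym - 4 * Ci)
    # reaction on the agar mask (conserves C + w A exactly)
    if (w > 0 && any(agar_mask)) {
      dA <- (ka * C * (1 - A / M) - kd * A) * dt
      dA[!agar_mask] <- 0
      A <- pmin(pmax(A + dA, 0), M)
      C <- pmax(C - w * dA, 0)
    }
    mass_resid[s] <- (sum(C[2:nx, ]) + w * sum(A) - mass_before -
                        influx + outflux) / max(mass_before, influx, 1e-12)
    if (!is.null(probe))
      probe_trace[s, ] <- bilinear_eval(xg, yg, C, probe$x, probe$y)
    if (s %in% snap_steps) {
      snapshots[[length(snapshots) + 1L]] <-
        agar_state(scalar_field(xg, yg, C, t_now + dt),
                   scalar_field(xg, yg, A, t_now + dt), agar_mask, t_now + dt)
    }
  }
  t_end <- t0 + nsteps * dt
  st <- agar_state(scalar_field(xg, yg, C, t_end),
                   scalar_field(xg, yg, A, t_end), agar_mask, t_end)
  pt <- NULL
  if (!is.null(probe))
    pt <- data.frame(time = t0 + dt * seq_len(nsteps), probe_trace)
  list(state = st, snapshots = snapshots, probe_trace = pt,
       mass_balance = mass_resid, dt = dt, xg = xg, yg = yg)
}

#' Design a pre-equilibration source schedule
#'
#' Loads the agar quickly by flowing a boosted inflow concentration and
#' monitors the mean concentration at downstream probe positions; once the
#' monitored concentration first reaches the no-agar steady value for the
#' target inflow, the source switches back to the target. Mirrors the bench
#' protocol of swapping the odor reservoir for a stronger one and watching
#' the downstream sensors.
#'
#' @param params [agar_params()].
#' @param agar_mask logical grid mask.
#' @param target_Co desired inflow concentration, ppm.
#' @param boost_Co boosted concentration (> target), ppm.
#' @param geom [chamber_geometry()].
#' @param monitor data.frame of downstream probe positions (`x`, `y` cm).
#' @param tolerance fractional tolerance on reaching the target.
#' @param max_duration give-up horizon for the boost phase, s.
#' @param settle_duration additional simulated time after the switch, s.
#' @param ... further arguments to [simulate_field()] (`dx`, `source_y`,
#'   `source_width`, ...).
#' @return list with `schedule` ([source_schedule()]), `switch_time` (s),
#'   `target_level` (the monitored no-agar steady readout), `result` (the
#'   post-switch simulation) and `monitor_trace`.
#' @export
design_preequilibration <- function(params, agar_mask, target_Co, boost_Co,
                                    geom, monitor, tolerance = 0.05,
                                    max_duration = 3600,
                                    settle_duration = 300, ...) {
  if (boost_Co < target_Co)
    stop("boost_Co must be at least target_Co")
  # no-agar reference level at the monitor for the target source
  p0 <- params; p0$absorption_weight_w <- 0
  ref <- simulate_field(p0, agar_mask & FALSE,
                        source_schedule(0, target_Co), geom,
                        duration = steady_horizon(params, geom),
                        probe = monitor, ...)
  target_level <- mean(bilinear_eval(ref$xg, ref$yg,
                                     ref$state$air_field_C$values,
                                     monitor$x, monitor$y))
  if (boost_Co == target_Co) {
    res <- simulate_field(params, agar_mask, source_schedule(0, target_Co),
                          geom, duration = max_duration, probe = monitor, ...)
    return(list(schedule = source_schedule(0, target_Co), switch_time = 0,
                target_level = target_level, result = res,
                monitor_trace = monitor_mean(res)))
  }
  boost <- simulate_field(params, agar_mask, source_schedule(0, boost_Co),
                          geom, duration = max_duration, probe = monitor, ...)
  tr <- monitor_mean(boost)
  hit <- which(tr$level >= target_level)
  if (!length(hit))
    stop(sprintf(
      "protocol failure: monitored concentration (max %.3g ppm) never reached the no-agar target level %.3g ppm within %g s",
      max(tr$level), target_level, max_duration))
  switch_time <- tr$time[hit[1]]
  sched <- source_schedule(c(0, switch_time), c(boost_Co, target_Co))
  # rerun the boost phase up to the switch, then settle at the target
  res <- simulate_field(params, agar_mask, sched, geom,
                        duration = switch_time + settle_duration,
                        probe = monitor, ...)
  list(schedule = sched, switch_time = switch_time,
       target_level = target_level, result = res,
       monitor_trace = monitor_mean(res))
}

monitor_mean <- function(sim) {
  pt <- sim$probe_trace
  data.frame(time = pt$time, level = rowMeans(pt[, -1, drop = FALSE]))
}

# horizon long enough for the agar-free field to reach steady state:
# a few flow-through times plus diffusive relaxation across the chamber
steady_horizon <- function(params, geom) {
  ceiling(5 * geom$length / params$flow_speed_v)
}

#' Mean fractional difference between two fields over a region
#'
#' `mean(|a - b| / b)` over the region where the mask is TRUE and the
#' reference field exceeds a floor, as used to compare with-agar and
#' without-agar landscapes.
#'
#' @param a,b [scalar_field()] objects on the same grid (b is the
#'   reference).
#' @param region logical matrix over the grid (default: everywhere).
#' @param floor_frac reference floor as a fraction of the reference peak.
#' @return mean fractional difference (dimensionless).
#' @export
fractional_difference <- function(a, b, region = NULL, floor_frac = 0.05) {
  stopifnot(inherits(a, "scalar_field"), inherits(b, "scalar_field"))
  if (!isTRUE(all.equal(a$x, b$x)) || !isTRUE(all.equal(a$y, b$y)))
    stop("fields must share the same grid")
  if (is.null(region)) region <- matrix(TRUE, nrow(a$values), ncol(a$values))
  sel <- region & b$values > floor_frac * max(b$values)
  if (!any(sel)) stop("empty comparison region after flooring")
  mean(abs(a$values[sel] - b$values[sel]) / b$values[sel])
}

#' Spanwise boundary profiles around the agar slab
#'
#' Extracts the spanwise concentration profiles at free grid rows upstream
#' and downstream of the agar mask -- the rows where boundary sensor bars
#' sit during behavior experiments. The rows are taken `offset_cm` away
#' from the mask edge (sensor bars do not touch the agar; an offset beyond
#' the upstream diffusive influence length `D/v` also keeps the upstream
#' profile clean), clamped to the available free rows.
#'
#' @param state an [agar_state()] (or a list with `air_field_C` and
#'   `agar_mask`).
#' @param agar_mask optional mask override.
#' @param offset_cm distance from the mask edge to the profile row, cm.
#' @return list with data.frames `upstream` and `downstream`
#'   (columns `y`, `ppm`) and the row positions `x_upstream`,
#'   `x_downstream`.
#' @export
boundary_profiles <- function(state, agar_mask = NULL, offset_cm = 1) {
  stopifnot(inherits(state, "agar_state"))
  if (is.null(agar_mask)) agar_mask <- state$agar_mask
  f <- state$air_field_C
  rows <- which(apply(agar_mask, 1, any))
  if (!length(rows)) stop("agar mask is empty")
  if (min(rows) <= 1L || max(rows) >= length(f$x))
    stop("agar mask spans the full chamber length; no free boundary rows")
  dx <- stats::median(diff(f$x))
  k <- max(1L, round(offset_cm / dx))
  iu <- max(1L, min(rows) - k)
  id <- min(length(f$x), max(rows) + k)
  list(upstream = data.frame(y = f$y, ppm = f$values[iu, ]),
       downstream = data.frame(y = f$y, ppm = f$values[id, ]),
       x_upstream = f$x[iu], x_downstream = f$x[id])
}
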