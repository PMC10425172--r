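#' Flow chamber geometry
#'
#' @param width spanwise extent (y) in cm; the chamber is 15 cm wide.
#' @param depth vertical clearance in cm; 1 cm in the instrument.
#' @param length streamwise extent (x) in cm.
#' @param kinematic_viscosity of air, cm^2/s (~0.15 at room temperature).
#' @return A `chamber_geometry` object; `cross_section_area` (cm^2) is
#'   derived as `width * depth`.
#' @export
chamber_geometry <- function(width = 15, depth = 1, length = 17,
                             kinematic_viscosity = 0.15) {
  if (any(c(width, depth, length, kinematic_viscosity) <= 0))
    stop("all geometry parameters must be positive")
  structure(list(width = width, depth = depth, length = length,
                 cross_section_area = width * depth,
                 kinematic_viscosity = kinematic_viscosity),
            class = "chamber_geometry")
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat(sprintf("<chamber_geometry> %g x %g x %g cm (W x D x L), A = %g cm^2\n",
              x$width, x$depth, x$length, x$cross_section_area))
  invisible(x)
}

#' Steady plume parameters
#'
#' @param source_concentration_Co inflow odor concentration, ppm.
#' @param flow_speed_v bulk streamwise air speed, cm/s (~0.5 in experiments).
#' @param diffusivity_D effective odor diffusivity, cm^2/s (~0.08 for
#'   butanone in air).
#' @param source_y spanwise source position, cm (0 = centerline).
#' @param source_width spanwise footprint of the odorized inlet, cm
#'   (one inlet-port spacing; 15 ports across 15 cm gives 1 cm).
#' @return A `plume_params` object.
#' @export
plume_params <- function(source_concentration_Co = 100, flow_speed_v = 0.5,
                         diffusivity_D = 0.08, source_y = 0,
                         source_width = 1) {
  if (source_concentration_Co < 0) stop("Co must be non-negative")
  if (flow_speed_v <= 0 || diffusivity_D <= 0 || source_width <= 0)
    stop("v, D and source_width must be positive")
  structure(list(source_concentration_Co = source_concentration_Co,
                 flow_speed_v = flow_speed_v, diffusivity_D = diffusivity_D,
                 source_y = source_y, source_width = source_width),
            class = "plume_params")
}

#' @export
print.plume_params <- function(x, ...) {
  cat(sprintf("<plume_params> Co = %g ppm, v = %g cm/s, D = %g cm^2/s, y0 = %g cm\n",
              x$source_concentration_Co, x$flow_speed_v, x$diffusivity_D,
              x$source_y))
  invisible(x)
}

#' Gaussian plume cross-section
#'
#' Spanwise concentration profile of a steady plume at downstream distance
#' `x_c`. Streamwise convection maps distance onto diffusion time
#' `t = x_c / v`, so the profile is a Gaussian of variance
#' `sigma^2 = 2 D x_c / v`:
#' `C(y) = peak_ppm * exp(-(y - source_y)^2 / (4 D x_c / v))`.
#'
#' @param params [plume_params()].
#' @param x_c downstream distance, cm, positive.
#' @param y spanwise positions, cm (vectorized).
#' @param peak_ppm on-axis peak concentration, ppm.
#' @return concentrations in ppm.
#' @export
plume_cross_section <- function(params, x_c, y, peak_ppm) {
  stopifnot(inherits(params, "plume_params"))
  if (x_c <= 0) stop("x_c must be positive")
  s2 <- 4 * params$diffusivity_D * x_c / params$flow_speed_v
  peak_ppm * exp(-(y - params$source_y)^2 / s2)
}

#' Steady-state plume field by streamwise marching
#'
#' Solves the boundary-layer form of the steady convection-diffusion
#' equation, `v dC/dx = D d2C/dy2`, downstream of a source boundary
#' condition at `x = 0` (a top-hat of width `source_width` at `source_y`,
#' amplitude `Co`), with no-flux side walls at `y = +/- width/2`. Streamwise
#' convection turns this into 1-D diffusion marched in `x` with an explicit
#' scheme (internally refined below the stability limit
#' `dx <= v dy^2 / (2 D)`).
#'
#' @param params [plume_params()].
#' @param geom [chamber_geometry()].
#' @param nx,ny grid resolution; the grid spans `[dx, length]` by
#'   `[-width/2, width/2]`.
#' @return A [scalar_field()]. Errors when the spanwise grid is coarser than
#'   a quarter of the plume width at the first x node.
#' @export
steady_plume_field <- function(params, geom, nx = 80, ny = 81) {
  stopifnot(inherits(params, "plume_params"), inherits(geom, "chamber_geometry"))
  v <- params$flow_speed_v; D <- params$diffusivity_D
  xg <- seq(geom$length / nx, geom$length, length.out = nx)
  yg <- seq(-geom$width / 2, geom$width / 2, length.out = ny)
  dy <- yg[2] - yg[1]
  sigma1 <- sqrt(2 * D * xg[1] / v) + params$source_width / 2
  if (dy > sigma1 / 4)
    stop("resolution error: spanwise grid coarser than 1/4 of the plume width at the first x node")
  # source top-hat at x = 0, with partial cell coverage at its edges so the
  # injected mass is grid-independent
  frac <- pmax(0, pmin(1, (params$source_width / 2 -
                             abs(yg - params$source_y)) / dy + 0.5))
  c0 <- params$source_concentration_Co * frac
  dx_stab <- 0.4 * v * dy^2 / D
  vals <- matrix(0, nx, ny)
  cur <- c0
  xprev <- 0
  for (i in seq_len(nx)) {
    seg <- xg[i] - xprev
    nsub <- max(1L, ceiling(seg / dx_stab))
    h <- seg / nsub
    r <- D * h / (v * dy^2)
    for (k in seq_len(nsub)) {
      lap <- c(cur[2] - cur[1],
               cur[c(-1, -ny)] * -2 + cur[1:(ny - 2)] + cur[3:ny],
               cur[ny - 1] - cur[ny])
      cur <- cur + r * lap
    }
    vals[i, ] <- cur
    xprev <- xg[i]
  }
  scalar_field(xg, yg, pmax(vals, 0))
}

# Mass-conserving closed-form plume used for fitting: Gaussian cross-section
# of variance 2 D x / v plus the source footprint's own variance (a top-hat
# of width w contributes w^2/12), amplitude scaling as 1/sigma so the
# spanwise integral is constant in x.
plume_model_eval <- function(x, y, D, v, amp, y0, s0sq = 0) {
  s2 <- pmax(2 * D * x / v + s0sq, .Machine$double.eps)
  amp / sqrt(s2) * exp(-(y - y0)^2 / (2 * s2))
}

#' Fit the convection-diffusion plume model to a sensor snapshot
#'
#' Fits the closed-form steady plume (Gaussian cross-sections with variance
#' `2 D x / v` and mass-conserving `1/sqrt(x)` amplitude) to per-sensor
#' concentration measurements. The flow speed `v` is fixed from the flow
#' rate and chamber geometry; the diffusivity `D` is the free parameter
#' minimizing the mean squared error, with the source amplitude and spanwise
#' source position profiled out as nuisance parameters.
#'
#' @param observed data.frame with columns `x`, `y` (cm) and `ppm`, at least
#'   20 sensors over at least 3 distinct x positions.
#' @param flow_speed_v fixed bulk speed, cm/s.
#' @param source_width spanwise footprint of the odorized inlet, cm; its
#'   variance (`width^2/12`) offsets the Gaussian widths so the fit is not
#'   biased by the finite source (0 = ideal point source).
#' @param D_range search interval for the diffusivity, cm^2/s.
#' @param grid_nx,grid_ny resolution of the returned fitted field.
#' @return list with `diffusivity_D_hat`, `amp`, `source_y`, `mse` and
#'   `field` (the fitted [scalar_field()]). Warns when the MSE is flat in D
#'   (unidentifiable).
#' @export
fit_plume <- function(observed, flow_speed_v, source_width = 1,
                      D_range = c(5e-4, 2), grid_nx = 60, grid_ny = 61) {
  need <- c("x", "y", "ppm")
  if (!all(need %in% names(observed)))
    stop("observed must have columns x, y, ppm")
  observed <- observed[observed$x > 0, ]
  if (nrow(observed) < 20L || length(unique(observed$x)) < 3L)
    stop("need >= 20 sensors spanning >= 3 distinct x positions")
  xo <- observed$x; yo <- observed$y; zo <- observed$ppm
  s0sq <- source_width^2 / 12  # variance of the inlet top-hat footprint
  obj <- function(logD) inner_fit(exp(logD))$mse
  inner_fit <- function(D) {
    fy <- function(y0) {
      basis <- plume_model_eval(xo, yo, D, flow_speed_v, 1, y0, s0sq)
      amp <- sum(basis * zo) / max(sum(basis^2), .Machine$double.eps)
      mean((zo - amp * basis)^2)
    }
    oy <- stats::optimize(fy, range(yo))
    y0 <- oy$minimum
    basis <- plume_model_eval(xo, yo, D, flow_speed_v, 1, y0, s0sq)
    amp <- sum(basis * zo) / max(sum(basis^2), .Machine$double.eps)
    list(mse = mean((zo - amp * basis)^2), amp = amp, y0 = y0)
  }
  od <- stats::optimize(obj, log(D_range), tol = 1e-10)
  D_hat <- exp(od$minimum)
  best <- inner_fit(D_hat)
  # identifiability: MSE must respond to D
  probe <- vapply(c(0.5, 2), function(f) inner_fit(D_hat * f)$mse, numeric(1))
  scale <- max(best$mse, mean(zo^2) * 1e-12)
  if (all(abs(probe - best$mse) < 1e-6 * scale))
    warning("unidentifiable: MSE flat in D (data dynamic range too small)")
  xg <- seq(min(xo), max(xo), length.out = grid_nx)
  yg <- seq(min(yo), max(yo), length.out = grid_ny)
  vals <- outer(xg, yg, function(x, y)
    plume_model_eval(x, y, D_hat, flow_speed_v, best$amp, best$y0, s0sq))
  list(diffusivity_D_hat = D_hat, amp = best$amp, source_y = best$y0,
       mse = best$mse, field = scalar_field(xg, yg, pmax(vals, 0)))
}

#' Reynolds number of the chamber flow
#'
#' Bulk velocity is the volumetric flow rate over the cross-section area;
#' the Reynolds number uses the chamber depth as the characteristic length:
#' `Re = v * depth / nu`. For the 15 x 1 cm chamber with air
#' (`nu = 0.15 cm^2/s`) this works out to about 7.4 per L/min of flow,
#' far below the turbulence onset near 2000.
#'
#' @param geom [chamber_geometry()].
#' @param flow_rate_ml_min volumetric flow in mL/min.
#' @return dimensionless Reynolds number.
#' @export
reynolds_number <- function(geom, flow_rate_ml_min) {
  stopifnot(inherits(geom, "chamber_geometry"))
  if (flow_rate_ml_min <= 0) stop("flow rate must be positive")
  v <- bulk_velocity(geom, flow_rate_ml_min)
  v * geom$depth / geom$kinematic_viscosity
}

#' Bulk streamwise velocity from the flow rate
#'
#' @param geom [chamber_geometry()].
#' @param flow_rate_ml_min volumetric flow in mL/min.
#' @return velocity in cm/s.
#' @export
bulk_velocity <- function(geom, flow_rate_ml_min) {
  stopifnot(inherits(geom, "chamber_geometry"))
  (flow_rate_ml_min / 60) / geom$cross_section_area
}

#' Peclet number
#'
#' Ratio of convective to diffusive transport, `Pe = v L / D`. The chamber
#' operates near Pe ~ 80 (v = 0.5 cm/s, L ~ 13 cm, D ~ 0.08 cm^2/s), i.e.
#' strongly convection-dominated along the flow.
#'
#' @param flow_speed_v cm/s.
#' @param length_L cm.
#' @param diffusivity_D cm^2/s.
#' @return dimensionless Peclet number.
#' @export
peclet_number <- function(flow_speed_v, length_L, diffusivity_D) {
  if (any(c(flow_speed_v, length_L, diffusivity_D) <= 0))
    stop("all arguments must be positive")
  flow_speed_v * length_L / diffusivity_D
}

#' Equilibrium concentration of an evaporated droplet in a closed arena
#'
#' Ideal-gas estimate: `ppm = 1e6 * n_mol / n_air`, where the moles of air
#' in the chamber follow from the molar volume `R T / P` at 1 atm. A 2 uL
#' droplet of 10% butanone (~1e-6 mol) in a 225 mL arena evaporates to
#' roughly 100 ppm.
#'
#' @param n_mol moles of odorant released.
#' @param chamber_volume_ml arena volume in mL.
#' @param temperature_K temperature in K.
#' @return concentration in ppm.
#' @export
droplet_equilibrium_concentration <- function(n_mol, chamber_volume_ml,
                                              temperature_K = 298) {
  if (n_mol < 0 || chamber_volume_ml <= 0 || temperature_K <= 0)
    stop("arguments must be positive (n_mol may be zero)")
  molar_volume_ml <- 82.057 * temperature_K  # cm^3/mol at 1 atm (R in cm^3 atm / K mol)
  n_air <- chamber_volume_ml / molar_volume_ml
  1e6 * n_mol / n_air
}

# 1-D Green's function for diffusion in [0, L] with reflecting walls
# (cosine spectral series), integrates to 1.
box_green_1d <- function(x, x0, L, D, t, tol = 1e-12) {
  if (t <= 0) stop("t must be positive for the spectral solution")
  g <- rep(1 / L, length(x))
  n <- 1L
  repeat {
    decay <- exp(-D * (n * pi / L)^2 * t)
    if (decay < tol || n > 5000L) break
    g <- g + (2 / L) * cos(n * pi * x / L) * cos(n * pi * x0 / L) * decay
    n <- n + 1L
  }
  g
}

#' Transient field of a diffusing droplet release in a closed chamber
#'
#' Depth-averaged free diffusion from a point release at the arena center
#' with reflecting walls, solved spectrally (product of 1-D reflecting-box
#' Green's functions). Total mass is conserved by construction and the
#' long-time limit is uniform at [droplet_equilibrium_concentration()].
#'
#' @param n_mol moles of odorant released.
#' @param D diffusivity in cm^2/s.
#' @param geom [chamber_geometry()]; the release sits at the center of the
#'   `length` x `width` footprint and `chamber_volume = L * W * depth`.
#' @param t time since release, s (t = 0 returns the near-singular early
#'   field at a 0.1 s floor).
#' @param nx,ny output grid resolution.
#' @param temperature_K for the equilibrium normalization.
#' @return A [scalar_field()] in ppm.
#' @export
droplet_transient_field <- function(n_mol, D, geom, t, nx = 61, ny = 61,
                                    temperature_K = 298) {
  stopifnot(inherits(geom, "chamber_geometry"))
  if (t < 0) stop("t must be non-negative")
  t <- max(t, 0.1)
  Lx <- geom$length; Ly <- geom$width
  vol_ml <- Lx * Ly * geom$depth
  c_eq <- droplet_equilibrium_concentration(n_mol, vol_ml, temperature_K)
  xg <- seq(0, Lx, length.out = nx)
  yg <- seq(-Ly / 2, Ly / 2, length.out = ny)
  gx <- box_green_1d(xg, Lx / 2, Lx, D, t)
  gy <- box_green_1d(yg + Ly / 2, Ly / 2, Ly, D, t)
  vals <- c_eq * Lx * Ly * outer(gx, gy)
  scalar_field(xg, yg, pmax(vals, 0), time = t)
}
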