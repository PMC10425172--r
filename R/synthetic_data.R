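#' Run-and-turn agent parameters
#'
#' Parameters of the generative navigator used to validate the trajectory
#' statistics. Agents run at constant speed, fire discrete turns as a
#' Poisson process whose rate is modulated by the bearing to the local
#' gradient, `lambda(theta) = lambda0 (1 - b cos theta)` (biased random
#' walk), and curve continuously toward the gradient at
#' `-g sin(theta)` deg/mm (weathervaning), plus rotational noise.
#'
#' Speeds reflect the two study animals: ~0.1 mm/s for crawling worms,
#' ~3 mm/s for fly larvae. Baseline turn rates give realistic turn counts
#' (a larva population of ~60 animals over ~10 min produces several hundred
#' turns at 0.05 /s). Turn magnitudes are drawn from a wrapped-normal
#' kernel around +/-120 deg (worm pirouettes) or +/-60 deg (larva casts).
#'
#' @param speed mm/s, positive.
#' @param base_turn_rate_lambda0 1/s.
#' @param turn_bias_b in [0, 1]: rate modulation depth.
#' @param weathervane_gain_g deg/mm curvature bias toward the gradient.
#' @param heading_noise rotational diffusion, deg/sqrt(s).
#' @param turn_kernel_mu,turn_kernel_sd turn-magnitude kernel (deg).
#' @param turn_dir_bias in [0, 1]: probability excess of choosing the
#'   toward-gradient turn direction (0 = unbiased pirouettes).
#' @return An `agent_params` object.
#' @export
agent_params <- function(speed = 0.1, base_turn_rate_lambda0 = 0.03,
                         turn_bias_b = 0, weathervane_gain_g = 0,
                         heading_noise = 2, turn_kernel_mu = 120,
                         turn_kernel_sd = 30, turn_dir_bias = 0) {
  if (speed <= 0) stop("speed must be positive")
  if (turn_bias_b < 0 || turn_bias_b > 1)
    stop("turn_bias_b must be in [0, 1] (rate must stay non-negative)")
  if (heading_noise < 0) stop("heading_noise must be non-negative")
  if (turn_dir_bias < 0 || turn_dir_bias > 1)
    stop("turn_dir_bias must be in [0, 1]")
  structure(list(speed = speed,
                 base_turn_rate_lambda0 = base_turn_rate_lambda0,
                 turn_bias_b = turn_bias_b,
                 weathervane_gain_g = weathervane_gain_g,
                 heading_noise = heading_noise,
                 turn_kernel_mu = turn_kernel_mu,
                 turn_kernel_sd = turn_kernel_sd,
                 turn_dir_bias = turn_dir_bias),
            class = "agent_params")
}

#' @rdname agent_params
#' @export
worm_params <- function(...) {
  do.call(agent_params, utils::modifyList(
    list(speed = 0.1, base_turn_rate_lambda0 = 0.03, turn_kernel_mu = 120,
         turn_kernel_sd = 30), list(...)))
}

#' @rdname agent_params
#' @export
larva_params <- function(...) {
  do.call(agent_params, utils::modifyList(
    list(speed = 3, base_turn_rate_lambda0 = 0.05, turn_kernel_mu = 60,
         turn_kernel_sd = 20), list(...)))
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf(
    "<agent_params> speed %g mm/s, lambda0 %g /s, b %g, g %g deg/mm\n",
    x$speed, x$base_turn_rate_lambda0, x$turn_bias_b, x$weathervane_gain_g))
  invisible(x)
}

#' Simulate a population of run-and-turn agents on an odor field
#'
#' Euler stepping at the output rate (14 Hz). Per step and agent: the
#' bearing to the local gradient modulates the turn hazard
#' `lambda(theta) dt` and the weathervane drift `-g sin(theta) speed dt`;
#' Gaussian heading noise accumulates as `heading_noise sqrt(dt)`; fired
#' turns draw a magnitude from the wrapped-normal kernel, the turn
#' direction biased toward the gradient with probability
#' `(1 + turn_dir_bias)/2`. Positions advance ballistically and reflect
#' off the arena walls. Where the gradient is below the context floor the
#' hazard is `lambda0` and no weathervane drift applies.
#'
#' @param context a [gradient_context()] (arena = field extent).
#' @param params an [agent_params()].
#' @param n_agents number of agents.
#' @param duration_s simulated time.
#' @param seed RNG seed (reproducible output).
#' @param dt_s step, default 1/14 s; must keep `lambda(theta) dt <= 0.2`.
#' @param start_region optional function(n) returning a data.frame with
#'   `x`, `y` start positions in mm; by default starts are uniform over the
#'   arena restricted to concentrations below 70% of the field maximum
#'   (deposited away from the peak, like the animals).
#' @return list of [trajectory()] objects with attributes `params`, `seed`
#'   and `turn_times` (per-agent list of true turn firing times, for
#'   distributional checks independent of any turn detector).
#' @export
simulate_agents <- function(context, params, n_agents, duration_s,
                            seed = 1, dt_s = 1 / 14, start_region = NULL) {
  stopifnot(inherits(context, "gradient_context"),
            inherits(params, "agent_params"))
  lam_max <- params$base_turn_rate_lambda0 * (1 + params$turn_bias_b)
  if (lam_max * dt_s > 0.2)
    stop("step-size error: lambda * dt exceeds 0.2; decrease dt_s")
  set.seed(seed)
  f <- context$field
  mmu <- context$mm_per_unit
  xlim <- range(f$x) * mmu; ylim <- range(f$y) * mmu
  if (is.null(start_region)) {
    # rejection-sample start positions below 70% of the field maximum,
    # mirroring the track filter (animals are deposited away from the peak);
    # in a flat field every position qualifies
    qthr <- 0.7 * max(f$values)
    flat <- min(f$values) > qthr
    sx <- numeric(0); sy <- numeric(0)
    while (length(sx) < n_agents) {
      cx <- stats::runif(4 * n_agents, xlim[1], xlim[2])
      cy <- stats::runif(4 * n_agents, ylim[1], ylim[2])
      okc <- flat | field_eval(f, cx / mmu, cy / mmu) <= qthr
      sx <- c(sx, cx[okc]); sy <- c(sy, cy[okc])
    }
    px <- sx[1:n_agents]; py <- sy[1:n_agents]
  } else {
    st <- start_region(n_agents)
    px <- st$x; py <- st$y
  }
  heading <- stats::runif(n_agents, -180, 180)
  turn_times <- vector("list", n_agents)
  nsteps <- round(duration_s / dt_s)
  X <- matrix(NA_real_, nsteps + 1L, n_agents)
  Y <- matrix(NA_real_, nsteps + 1L, n_agents)
  X[1, ] <- px; Y[1, ] <- py
  sp <- params$speed
  for (s in seq_len(nsteps)) {
    g <- gradient_eval(context$grad, px / mmu, py / mmu)
    gmag <- sqrt(g$gx^2 + g$gy^2)
    gdir <- atan2(g$gy, g$gx) * 180 / pi
    defined <- gmag > context$grad_floor
    theta <- wrap_angle(heading - gdir)
    sint <- ifelse(defined, sin(theta * pi / 180), 0)
    cost <- ifelse(defined, cos(theta * pi / 180), NA)
    # weathervaning drift + rotational noise
    heading <- heading - params$weathervane_gain_g * sint * sp * dt_s +
      stats::rnorm(n_agents, 0, params$heading_noise * sqrt(dt_s))
    # bearing-modulated turn hazard
    lam <- params$base_turn_rate_lambda0 *
      (1 - params$turn_bias_b * ifelse(defined, cost, 0))
    fire <- stats::runif(n_agents) < lam * dt_s
    if (any(fire)) {
      nf <- sum(fire)
      for (i in which(fire))
        turn_times[[i]] <- c(turn_times[[i]], s * dt_s)
      mag <- abs(stats::rnorm(nf, params$turn_kernel_mu, params$turn_kernel_sd))
      toward <- -sign(theta[fire])
      toward[toward == 0 | !defined[fire]] <-
        sample(c(-1, 1), sum(toward == 0 | !defined[fire]), replace = TRUE)
      pick <- stats::runif(nf) < (1 + params$turn_dir_bias) / 2
      dir <- ifelse(pick, toward, -toward)
      heading[fire] <- heading[fire] + dir * mag
    }
    heading <- wrap_angle(heading)
    px <- px + sp * dt_s * cos(heading * pi / 180)
    py <- py + sp * dt_s * sin(heading * pi / 180)
    # reflecting walls
    low <- px < xlim[1]; high <- px > xlim[2]
    px[low] <- 2 * xlim[1] - px[low]; px[high] <- 2 * xlim[2] - px[high]
    heading[low | high] <- wrap_angle(180 - heading[low | high])
    low <- py < ylim[1]; high <- py > ylim[2]
    py[low] <- 2 * ylim[1] - py[low]; py[high] <- 2 * ylim[2] - py[high]
    heading[low | high] <- wrap_angle(-heading[low | high])
    X[s + 1L, ] <- px; Y[s + 1L, ] <- py
  }
  tt <- dt_s * (0:nsteps)
  out <- lapply(seq_len(n_agents), function(i)
    trajectory(sprintf("agent_%03d", i), tt, X[, i], Y[, i]))
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  attr(out, "turn_times") <- turn_times
  out
}

#' Synthetic-recording specification
#'
#' @param layout a [build_layout()] layout.
#' @param odor_rate_hz metal-oxide sampling rate (1 Hz on the instrument).
#' @param pid_rate_hz reference detector rate (up to 13 Hz).
#' @param noise_sd fractional multiplicative noise on the sensed ppm.
#' @param curves named list of true [calibration_curve()] per odor sensor
#'   (recycled from a single curve if unnamed length 1).
#' @param delay_s transport delay between the sensors and the downstream
#'   reference detector.
#' @return A `recording_spec` object.
#' @export
recording_spec <- function(layout, odor_rate_hz = 1, pid_rate_hz = 13,
                           noise_sd = 0, curves = NULL, delay_s = 5) {
  if (odor_rate_hz <= 0 || pid_rate_hz <= 0) stop("rates must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  odor_ids <- layout$sensor_id[layout$kind == "odor"]
  if (is.null(curves))
    curves <- stats::setNames(
      lapply(odor_ids, function(id) calibration_curve(2, 0.01, delay_s)),
      odor_ids)
  if (length(curves) == 1L && is.null(names(curves)))
    curves <- stats::setNames(rep(curves, length(odor_ids)), odor_ids)
  structure(list(layout = layout, odor_rate_hz = odor_rate_hz,
                 pid_rate_hz = pid_rate_hz, noise_sd = noise_sd,
                 curves = curves, delay_s = delay_s),
            class = "recording_spec")
}

#' Synthesize raw sensor and reference recordings from a field
#'
#' Generates what the instrument would record over a concentration field
#' whose amplitude is modulated in time (a calibration triangle wave by
#' default): the true ppm at each odor-sensor position, passed through the
#' inverse exponential response (`raw = log(ppm / scale_A) /
#' sensitivity_B`) with multiplicative noise, sampled at the sensor rate;
#' and the reference detector series -- the outlet mean ppm, delayed by the
#' transport delay -- at the reference rate.
#'
#' @param field a [scalar_field()] (spatial pattern; uniform for
#'   calibration runs).
#' @param spec a [recording_spec()].
#' @param duration_s recording length.
#' @param seed RNG seed.
#' @param modulation function of time (s) returning the source amplitude
#'   factor in [0, 1]; default a 500 s-period triangle wave.
#' @param ppm_scale_floor ppm below which sensed values are clamped (the
#'   sensor scale floor), flagged via the `clamped` attribute.
#' @return list with `raw` (named list of raw [sensor_series()]),
#'   `reference` (ppm [sensor_series()]) and `truth` (matrix of noiseless
#'   ppm per sensor).
#' @export
synthesize_recording <- function(field, spec, duration_s = 1500, seed = 1,
                                 modulation = NULL, ppm_scale_floor = 1e-3) {
  stopifnot(inherits(field, "scalar_field"), inherits(spec, "recording_spec"))
  set.seed(seed)
  if (is.null(modulation))
    modulation <- function(t) {
      phase <- (t %% 500) / 500
      0.05 + 0.95 * (1 - abs(2 * phase - 1))
    }
  odor <- spec$layout[spec$layout$kind == "odor", ]
  base_ppm <- field_eval(field, odor$x_cm, odor$y_cm)
  t_os <- seq(0, duration_s, by = 1 / spec$odor_rate_hz)
  m_os <- modulation(t_os)
  truth <- outer(m_os, base_ppm)
  colnames(truth) <- odor$sensor_id
  clamped <- 0L
  raw <- lapply(seq_len(nrow(odor)), function(i) {
    curve <- spec$curves[[odor$sensor_id[i]]]
    ppm <- truth[, i] * (1 + stats::rnorm(length(t_os), 0, spec$noise_sd))
    nclamp <- sum(ppm < ppm_scale_floor)
    clamped <<- clamped + nclamp
    ppm <- pmax(ppm, ppm_scale_floor)
    sensor_series(odor$sensor_id[i], t_os,
                  invert_calibration(ppm, curve), spec$odor_rate_hz)
  })
  names(raw) <- odor$sensor_id
  # reference: outlet (far-x) mean ppm, transport-delayed
  outlet_ppm <- mean(field$values[nrow(field$values), ])
  t_pid <- seq(0, duration_s, by = 1 / spec$pid_rate_hz)
  ref_vals <- outlet_ppm * modulation(t_pid - spec$delay_s)
  reference <- sensor_series("pid", t_pid, pmax(ref_vals, 0),
                             min(spec$pid_rate_hz, 13))
  out <- list(raw = raw, reference = reference, truth = truth, times = t_os)
  attr(out, "clamped") <- clamped
  out
}

#' Bundled ground-truth scenarios
#'
#' Deterministic fixture sets named after the landscapes the flow chamber
#' produces: `cone` (odorized air at the central inlet), `narrow_cone`
#' (faster carrier flow), `inverse_cone` (odor at the two distal inlets:
#' maxima on both sides, minimum on the centerline), `biased_cone` (inlet
#' 4 cm off-center), `uniform`, and `droplet` (transient diffusion from a
#' center release). Each scenario carries the field, the full 7-bar sensor
#' layout and a manifest of every true parameter.
#'
#' @param name scenario name.
#' @param geom [chamber_geometry()].
#' @param Co source concentration, ppm.
#' @param seed seed recorded in the manifest for downstream generators.
#' @return list with `name`, `field`, `layout`, `manifest`.
#' @export
make_scenario <- function(name = c("cone", "narrow_cone", "inverse_cone",
                                   "biased_cone", "uniform", "droplet"),
                          geom = chamber_geometry(), Co = 100, seed = 1) {
  name <- match.arg(name)
  layout <- build_layout(7)
  mk <- function(y0, v = 0.5) steady_plume_field(
    plume_params(source_concentration_Co = Co, flow_speed_v = v,
                 diffusivity_D = 0.08, source_y = y0), geom)
  field <- switch(
    name,
    cone = mk(0),
    narrow_cone = mk(0, v = 0.75),
    biased_cone = mk(4),
    inverse_cone = {
      a <- mk(-(geom$width / 2 - 1)); b <- mk(geom$width / 2 - 1)
      scalar_field(a$x, a$y, a$values + b$values)
    },
    uniform = {
      xg <- seq(0.2, geom$length, length.out = 60)
      yg <- seq(-geom$width / 2, geom$width / 2, length.out = 61)
      scalar_field(xg, yg, matrix(Co / 2, 60, 61))
    },
    droplet = droplet_transient_field(1e-6, 0.08, geom, t = 60))
  manifest <- list(scenario = name, Co = Co, flow_speed_v = 0.5,
                   diffusivity_D = 0.08,
                   source_y = switch(name, biased_cone = 4, 0),
                   geometry = unclass(geom), seed = seed)
  list(name = name, field = field, layout = layout, manifest = manifest)
}
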