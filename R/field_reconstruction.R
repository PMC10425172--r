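#' Sensor-array layout
#'
#' Builds the deterministic geometry of the odor sensor array: each odor
#' sensor bar (OSB) carries 16 metal-oxide sensors in two columns 1 cm
#' apart, 1.5 cm spacing within a column, the second column staggered by
#' 0.75 cm (0.75 cm effective spanwise resolution), plus 8 humidity sensors
#' between the columns. Bars are mounted orthogonal to the flow with 1 cm
#' between the facing columns of adjacent bars (2 cm bar pitch), producing
#' a triangular grid in which no sensor sits directly downstream of
#' another. Up to 7 bars (112 odor sensors) fit the chamber.
#'
#' @param n_bars number of bars, 1 to 7.
#' @param origin (x, y) in cm of the first column of the first bar; the
#'   default centers the 8-sensor columns on the chamber centerline.
#' @return A `sensor_layout`: data.frame with columns
#'   `sensor_id`, `x_cm`, `y_cm`, `bar`, `kind` (odor | humidity).
#' @export
build_layout <- function(n_bars = 7, origin = c(1, -5.25)) {
  if (n_bars < 1 || n_bars > 7) stop("n_bars must be between 1 and 7")
  rows <- list()
  y_col <- origin[2] + 1.5 * (0:7)          # 8 sensors per column
  for (b in seq_len(n_bars)) {
    x0 <- origin[1] + 2 * (b - 1)
    rows[[length(rows) + 1L]] <- data.frame(
      sensor_id = sprintf("os_b%d_c1_%02d", b, 1:8),
      x_cm = x0, y_cm = y_col, bar = b, kind = "odor")
    rows[[length(rows) + 1L]] <- data.frame(
      sensor_id = sprintf("os_b%d_c2_%02d", b, 1:8),
      x_cm = x0 + 1, y_cm = y_col + 0.75, bar = b, kind = "odor")
    rows[[length(rows) + 1L]] <- data.frame(
      sensor_id = sprintf("th_b%d_%02d", b, 1:8),
      x_cm = x0 + 0.5, y_cm = y_col + 0.375, bar = b, kind = "humidity")
  }
  out <- do.call(rbind, rows)
  if (anyDuplicated(out[, c("x_cm", "y_cm")]))
    stop("layout produced duplicate positions")
  class(out) <- c("sensor_layout", "data.frame")
  out
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat(sprintf("<sensor_layout> %d odor + %d humidity sensors on %d bar(s)\n",
              sum(x$kind == "odor"), sum(x$kind == "humidity"),
              length(unique(x$bar))))
  invisible(as.data.frame(x))
}

#' One concentration snapshot from the array
#'
#' @param layout a [build_layout()] layout.
#' @param values named (by `sensor_id`) or positional ppm values for the
#'   odor sensors; `NA` marks missing sensors.
#' @param time time stamp, s.
#' @return A `snapshot` object (data.frame of odor sensors with a `ppm`
#'   column).
#' @export
array_snapshot <- function(layout, values, time = NA_real_) {
  odor <- layout[layout$kind == "odor", , drop = FALSE]
  if (!is.null(names(values))) {
    ppm <- unname(values[odor$sensor_id])
  } else {
    if (length(values) != nrow(odor))
      stop("need one value per odor sensor")
    ppm <- as.numeric(values)
  }
  if (any(ppm < 0, na.rm = TRUE)) stop("concentrations must be non-negative")
  odor$ppm <- ppm
  attr(odor, "time") <- time
  class(odor) <- c("snapshot", "data.frame")
  odor
}

# median nearest-neighbor distance between measurement points
median_spacing <- function(x, y) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  stats::median(apply(d, 1, min))
}

# thin-plate spline smoother: eta(r) = r^2 log r basis + affine part,
# smoothing via (K + n * lambda * I); lambda = 0 interpolates exactly.
tps_fit <- function(x, y, z, length_scale, lambda) {
  n <- length(x)
  u <- x / length_scale; v <- y / length_scale
  d <- as.matrix(stats::dist(cbind(u, v)))
  K <- ifelse(d > 0, d^2 * log(d), 0)
  P <- cbind(1, u, v)
  Amat <- rbind(cbind(K + n * lambda * diag(n), P),
                cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(z, 0, 0, 0)
  sol <- solve(Amat, rhs)
  list(w = sol[1:n], beta = sol[n + 1:3], u = u, v = v,
       length_scale = length_scale)
}

tps_eval <- function(fit, px, py) {
  pu <- px / fit$length_scale; pv <- py / fit$length_scale
  out <- numeric(length(pu))
  for (i in seq_along(fit$w)) {
    r <- sqrt((pu - fit$u[i])^2 + (pv - fit$v[i])^2)
    out <- out + fit$w[i] * ifelse(r > 0, r^2 * log(r), 0)
  }
  out + fit$beta[1] + fit$beta[2] * pu + fit$beta[3] * pv
}

# ray-crossing point-in-polygon (polygon given by chull vertex order)
in_hull <- function(px, py, hx, hy) {
  n <- length(hx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (hy[i] > py) != (hy[j] > py)
    xint <- (hx[j] - hx[i]) * (py - hy[i]) / (hy[j] - hy[i]) + hx[i]
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  inside
}

#' Reconstruct a continuous field from a sparse sensor snapshot
#'
#' Thin-plate smoothing-spline surface through the per-sensor
#' concentrations, with the spline length scale tied to the median
#' inter-sensor spacing (~1 cm on the array). With `lambda = 0` the surface
#' interpolates the sensors exactly; the default applies light smoothing
#' against sensor noise. Negative interpolant values are clipped to zero
#' (count recorded in the `clipped` attribute) and grid nodes outside the
#' convex hull of the sensors are flagged in the `extrapolated` attribute.
#'
#' @param snapshot an [array_snapshot()] (missing sensors allowed).
#' @param grid_dx output grid spacing, cm.
#' @param length_scale spline length scale, cm; default the median
#'   inter-sensor spacing.
#' @param lambda dimensionless smoothing parameter (0 = exact
#'   interpolation).
#' @param pad extend the grid this far (cm) beyond the sensor bounding box.
#' @return A [scalar_field()] with attributes `extrapolated` (logical
#'   matrix) and `clipped` (count of negative nodes set to 0).
#' @export
interpolate_field <- function(snapshot, grid_dx = 0.2, length_scale = NULL,
                              lambda = 1e-4, pad = 0) {
  stopifnot(inherits(snapshot, "snapshot"))
  ok <- !is.na(snapshot$ppm)
  if (sum(ok) < 4L) stop("need at least 4 non-missing sensors")
  xs <- snapshot$x_cm[ok]; ys <- snapshot$y_cm[ok]; zs <- snapshot$ppm[ok]
  if (is.null(length_scale)) length_scale <- median_spacing(xs, ys)
  fit <- tps_fit(xs, ys, zs, length_scale, lambda)
  xg <- seq(min(xs) - pad, max(xs) + pad, by = grid_dx)
  yg <- seq(min(ys) - pad, max(ys) + pad, by = grid_dx)
  gg <- expand.grid(x = xg, y = yg)
  vals <- matrix(tps_eval(fit, gg$x, gg$y), length(xg), length(yg))
  clipped <- sum(vals < 0)
  vals[vals < 0] <- 0
  hull <- grDevices::chull(xs, ys)
  extrap <- matrix(!in_hull(gg$x, gg$y, xs[hull], ys[hull]),
                   length(xg), length(yg))
  f <- scalar_field(xg, yg, vals, time = attr(snapshot, "time"))
  attr(f, "extrapolated") <- extrap
  attr(f, "clipped") <- clipped
  f
}

#' Fit a Gaussian to a 1-D concentration profile
#'
#' Least-squares Gaussian `ppm = peak * exp(-(y - center)^2 / (2 sigma^2))
#' + baseline`, as used for spanwise boundary profiles. Initialized from
#' moments and refined with Levenberg-Marquardt. A profile without positive
#' dynamic range is flagged degenerate, with the peak reported as the mean.
#'
#' @param positions numeric positions (cm), at least 5.
#' @param values concentrations (ppm).
#' @param baseline fit an additive baseline term?
#' @return list with `peak`, `center`, `width` (Gaussian sigma, cm),
#'   `baseline`, `mse` and `degenerate`.
#' @export
gaussian_fit_profile <- function(positions, values, baseline = FALSE) {
  if (length(positions) < 5L) stop("need at least 5 points")
  if (length(positions) != length(values)) stop("length mismatch")
  rng <- diff(range(values))
  if (!is.finite(rng) || rng <= max(1e-12, 1e-9 * max(abs(values), 1))) {
    return(list(peak = mean(values), center = mean(positions),
                width = NA_real_, baseline = 0,
                mse = stats::var(values), degenerate = TRUE))
  }
  w <- pmax(values - min(values), 0)
  mu0 <- sum(positions * w) / sum(w)
  s0 <- sqrt(sum((positions - mu0)^2 * w) / sum(w))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(positions)) / 4
  model <- function(par) {
    g <- par["peak"] * exp(-(positions - par["center"])^2 /
                             (2 * par["width"]^2))
    if (baseline) g + par["b0"] else g
  }
  start <- c(peak = if (baseline) max(values) - min(values) else max(values),
             center = mu0, width = s0)
  if (baseline) start <- c(start, b0 = min(values))
  fit <- tryCatch(
    minpack.lm::nls.lm(start, fn = function(par) values - model(par),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) {
    return(list(peak = max(values), center = mu0, width = s0, baseline = 0,
                mse = NA_real_, degenerate = TRUE))
  }
  cf <- fit$par
  list(peak = unname(cf["peak"]), center = unname(cf["center"]),
       width = abs(unname(cf["width"])),
       baseline = if (baseline) unname(cf["b0"]) else 0,
       mse = mean((values - model(cf))^2), degenerate = FALSE)
}

#' Read a sensor layout from CSV
#'
#' Expects columns `sensor_id,x_cm,y_cm,bar,kind`.
#' @param path CSV path.
#' @return a `sensor_layout`.
#' @export
read_layout_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sensor_id", "x_cm", "y_cm", "bar", "kind")
  if (!all(need %in% names(df)))
    stop("layout CSV must have columns sensor_id,x_cm,y_cm,bar,kind")
  class(df) <- c("sensor_layout", "data.frame")
  df
}
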