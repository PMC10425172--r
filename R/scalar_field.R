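#' 2-D concentration field on a rectangular grid
#'
#' The central exchange type of the package: an odor concentration field
#' `C(x, y)` in ppm on a rectangular grid. The coordinate frame is the flow
#' chamber's: `x` in cm downstream of the inlet manifold, `y` in cm spanwise
#' with `y = 0` at the chamber centerline.
#'
#' @param x numeric vector of strictly increasing x coordinates (cm).
#' @param y numeric vector of strictly increasing y coordinates (cm).
#' @param values numeric matrix of concentrations (ppm), dimension
#'   `length(x)` by `length(y)`. Must be finite and non-negative.
#' @param time optional time stamp in seconds (`NA` for stationary fields).
#' @return An object of class `scalar_field`: a list with elements
#'   `x`, `y`, `values`, `time`.
#' @examples
#' f <- scalar_field(seq(0, 10, 0.5), seq(-5, 5, 0.5),
#'                   outer(seq(0, 10, 0.5), seq(-5, 5, 0.5),
#'                         function(x, y) exp(-y^2)))
#' field_max(f)
#' @export
scalar_field <- function(x, y, values, time = NA_real_) {
  x <- as.numeric(x); y <- as.numeric(y)
  values <- as.matrix(values)
  if (length(x) < 2L || length(y) < 2L)
    stop("scalar_field needs at least a 2x2 grid")
  if (any(diff(x) <= 0) || any(diff(y) <= 0))
    stop("grid coordinates must be strictly increasing")
  if (!all(dim(values) == c(length(x), length(y))))
    stop("values must be a length(x) by length(y) matrix")
  if (any(!is.finite(values)))
    stop("field values must be finite")
  if (any(values < 0)) {
    if (min(values) < -1e-9)
      stop("field values must be non-negative")
    values[values < 0] <- 0
  }
  structure(list(x = x, y = y, values = values, time = time),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf(
    "<scalar_field> %d x %d grid, x [%.2f, %.2f] cm, y [%.2f, %.2f] cm\n",
    length(x$x), length(x$y), min(x$x), max(x$x), min(x$y), max(x$y)))
  cat(sprintf("  concentration [%.3g, %.3g] ppm%s\n",
              min(x$values), max(x$values),
              if (is.na(x$time)) "" else sprintf(", t = %.1f s", x$time)))
  invisible(x)
}

#' @rdname scalar_field
#' @param field a `scalar_field`.
#' @export
field_max <- function(field) {
  stopifnot(inherits(field, "scalar_field"))
  max(field$values)
}

#' Crop a scalar field to a sub-window
#'
#' Restricts a field to the grid nodes inside the given limits, e.g. the
#' central agar arena of a chamber-wide field.
#'
#' @param field a [scalar_field()].
#' @param xlim,ylim inclusive coordinate limits (cm).
#' @return the cropped [scalar_field()].
#' @export
crop_field <- function(field, xlim = range(field$x), ylim = range(field$y)) {
  stopifnot(inherits(field, "scalar_field"))
  ix <- which(field$x >= xlim[1] & field$x <= xlim[2])
  iy <- which(field$y >= ylim[1] & field$y <= ylim[2])
  if (length(ix) < 2L || length(iy) < 2L)
    stop("crop window contains fewer than 2 grid lines")
  scalar_field(field$x[ix], field$y[iy], field$values[ix, iy, drop = FALSE],
               field$time)
}

#' Evaluate a scalar field at arbitrary positions
#'
#' Bilinear interpolation on the field grid. Positions outside the grid are
#' clamped to the boundary (the chamber walls).
#'
#' @param field a [scalar_field()].
#' @param px,py numeric vectors of query positions (same units as the grid).
#' @return numeric vector of interpolated concentrations (ppm).
#' @export
field_eval <- function(field, px, py) {
  stopifnot(inherits(field, "scalar_field"), length(px) == length(py))
  bilinear_eval(field$x, field$y, field$values, px, py)
}

# Bilinear interpolation core, shared with gradient lookups.
bilinear_eval <- function(xg, yg, v, px, py) {
  px <- pmin(pmax(px, xg[1]), xg[length(xg)])
  py <- pmin(pmax(py, yg[1]), yg[length(yg)])
  ix <- findInterval(px, xg, rightmost.closed = TRUE)
  iy <- findInterval(py, yg, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), length(xg) - 1L)
  iy <- pmin(pmax(iy, 1L), length(yg) - 1L)
  tx <- (px - xg[ix]) / (xg[ix + 1L] - xg[ix])
  ty <- (py - yg[iy]) / (yg[iy + 1L] - yg[iy])
  n <- nrow(v)
  i00 <- ix + (iy - 1L) * n
  v[i00] * (1 - tx) * (1 - ty) + v[i00 + 1L] * tx * (1 - ty) +
    v[i00 + n] * (1 - tx) * ty + v[i00 + n + 1L] * tx * ty
}

#' Spatial gradient of a concentration field
#'
#' Computes the gradient by centered finite differences after a Gaussian
#' pre-smoothing of the field (separable convolution, default sigma 0.5 cm),
#' one-sided differences at the grid edges. The gradient of a constant field
#' is exactly zero; pre-smoothing leaves linear ramps unchanged in the
#' interior so their gradient is exact.
#'
#' @param field a [scalar_field()].
#' @param smooth_sigma Gaussian pre-smoothing bandwidth in cm (0 disables).
#' @return A `gradient_field` object: list with `x`, `y`, matrices `gx`, `gy`
#'   (ppm/cm components) and the smoothed field.
#' @export
gradient_field <- function(field, smooth_sigma = 0.5) {
  stopifnot(inherits(field, "scalar_field"))
  v <- field$values
  if (smooth_sigma > 0) {
    v <- gauss_smooth_1d(v, field$x, smooth_sigma, margin = 1L)
    v <- gauss_smooth_1d(v, field$y, smooth_sigma, margin = 2L)
  }
  gx <- central_diff(v, field$x, margin = 1L)
  gy <- central_diff(v, field$y, margin = 2L)
  structure(list(x = field$x, y = field$y, gx = gx, gy = gy,
                 smoothed = v, smooth_sigma = smooth_sigma),
            class = "gradient_field")
}

# Separable Gaussian smoothing along one margin with kernel renormalization
# at the edges (so constants and, in the interior, linear ramps are preserved).
gauss_smooth_1d <- function(v, coords, sigma, margin) {
  h <- stats::median(diff(coords))
  half <- max(1L, ceiling(3 * sigma / h))
  k <- stats::dnorm(seq(-half, half) * h, sd = sigma)
  if (margin == 2L) v <- t(v)
  n <- nrow(v)
  out <- matrix(0, n, ncol(v))
  wsum <- numeric(n)
  for (j in seq_along(k)) {
    off <- j - half - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + k[j] * v[src[ok], ]
    wsum[ok] <- wsum[ok] + k[j]
  }
  out <- out / wsum
  if (margin == 2L) t(out) else out
}

central_diff <- function(v, coords, margin) {
  if (margin == 2L) v <- t(v)
  n <- nrow(v)
  g <- matrix(0, n, ncol(v))
  if (n >= 3L)
    g[2:(n - 1L), ] <- (v[3:n, ] - v[1:(n - 2L), ]) /
      (coords[3:n] - coords[1:(n - 2L)])
  g[1L, ] <- (v[2L, ] - v[1L, ]) / (coords[2L] - coords[1L])
  g[n, ] <- (v[n, ] - v[n - 1L, ]) / (coords[n] - coords[n - 1L])
  if (margin == 2L) t(g) else g
}

#' @export
print.gradient_field <- function(x, ...) {
  mag <- sqrt(x$gx^2 + x$gy^2)
  cat(sprintf("<gradient_field> %d x %d grid, |grad| max %.3g ppm/cm\n",
              length(x$x), length(x$y), max(mag)))
  invisible(x)
}

#' Evaluate a gradient field at arbitrary positions
#'
#' @param grad a [gradient_field()].
#' @param px,py query positions.
#' @return list with components `gx`, `gy` (ppm/cm) at the query points.
#' @export
gradient_eval <- function(grad, px, py) {
  stopifnot(inherits(grad, "gradient_field"))
  list(gx = bilinear_eval(grad$x, grad$y, grad$gx, px, py),
       gy = bilinear_eval(grad$x, grad$y, grad$gy, px, py))
}

#' Bundle a field with its gradient for trajectory analysis
#'
#' @param field a [scalar_field()] in the arena frame (positions in mm are
#'   converted with `mm_per_unit`).
#' @param smooth_sigma passed to [gradient_field()].
#' @param mm_per_unit how many mm one grid unit represents (10 for cm grids).
#' @return A `gradient_context` with the field, gradient, field maximum and
#'   a gradient-magnitude floor below which bearings are undefined.
#' @export
gradient_context <- function(field, smooth_sigma = 0.5, mm_per_unit = 10) {
  grad <- gradient_field(field, smooth_sigma)
  gmag <- sqrt(grad$gx^2 + grad$gy^2)
  structure(list(field = field, grad = grad, max_ppm = field_max(field),
                 grad_floor = 0.01 * max(gmag),
                 mm_per_unit = mm_per_unit),
            class = "gradient_context")
}

#' @export
print.gradient_context <- function(x, ...) {
  cat(sprintf("<gradient_context> max %.3g ppm, gradient floor %.3g ppm/cm\n",
              x$max_ppm, x$grad_floor))
  invisible(x)
}
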