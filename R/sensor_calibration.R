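#' Sensor time series
#'
#' One channel of a recording: a raw metal-oxide gas-sensor trace or a
#' reference photo-ionization detector (PID) trace. Raw sensor readings are
#' dimensionless; PID traces are volts, or ppm once the detector gain has
#' been applied.
#'
#' @param sensor_id identifier.
#' @param times sample times in seconds, strictly increasing.
#' @param values finite numeric readings.
#' @param rate_hz nominal sampling rate in Hz, within [0.5, 20] (sensors
#'   report at 1 Hz, the PID at up to 13 Hz).
#' @return A `sensor_series` object.
#' @export
sensor_series <- function(sensor_id, times, values, rate_hz = 1) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(!is.finite(values)))
    stop("values must be finite")
  if (rate_hz < 0.5 || rate_hz > 20)
    stop("rate_hz must lie in [0.5, 20]")
  structure(list(sensor_id = sensor_id, times = times, values = values,
                 rate_hz = rate_hz),
            class = "sensor_series")
}

#' @export
print.sensor_series <- function(x, ...) {
  cat(sprintf("<sensor_series> '%s': %d samples, %.3g s - %.3g s @ %g Hz\n",
              x$sensor_id, length(x$times), min(x$times), max(x$times),
              x$rate_hz))
  invisible(x)
}

series_duration <- function(s) diff(range(s$times))

# Linear resampling of two series onto a shared uniform grid at the coarser
# of the two nominal rates, over their overlapping support.
resample_common <- function(a, b) {
  rate <- min(a$rate_hz, b$rate_hz)
  t0 <- max(min(a$times), min(b$times))
  t1 <- min(max(a$times), max(b$times))
  if (t1 - t0 <= 2 / rate)
    stop("series share no usable overlapping interval")
  tt <- seq(t0, t1, by = 1 / rate)
  list(times = tt,
       a = stats::approx(a$times, a$values, tt)$y,
       b = stats::approx(b$times, b$values, tt)$y,
       dt = 1 / rate)
}

#' Estimate the transport delay between a sensor and the reference detector
#'
#' The sensor and the downstream reference detector see the same odor
#' fluctuation separated by a transport delay. The delay is estimated as the
#' lag maximizing the cross-correlation of the mean-subtracted series, after
#' linear resampling onto a common grid at the coarser of the two rates,
#' with sub-sample refinement by parabolic interpolation around the
#' correlation peak. Positive lags mean the reference trails the sensor
#' (reference downstream).
#'
#' @param sensor,reference [sensor_series()] objects covering a common
#'   interval.
#' @param max_lag_s optional search window (seconds); defaults to half the
#'   overlap.
#' @return delay in seconds (sign: reference after sensor). A warning is
#'   issued if the correlation peak sits at the edge of the search window.
#' @export
align_delay <- function(sensor, reference, max_lag_s = NULL) {
  stopifnot(inherits(sensor, "sensor_series"),
            inherits(reference, "sensor_series"))
  rs <- resample_common(sensor, reference)
  a <- rs$a - mean(rs$a)
  b <- rs$b - mean(rs$b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("no signal: a series has zero variance over the overlap")
  n <- length(a)
  # default search window: a tenth of the overlap (recordings are arranged
  # to cover >= 10x the expected transport delay), which also keeps the
  # period alias of cyclic calibration waveforms out of the window
  max_lag <- if (is.null(max_lag_s)) max(2L, floor(n / 10)) else
    min(floor(max_lag_s / rs$dt), n - 2L)
  lags <- -max_lag:max_lag
  # per-lag Pearson correlation with per-window standardization: slow
  # calibration waveforms (500 s triangle) have a nearly flat correlation
  # near the peak, so the overlap-length and window-mean biases of the
  # unnormalized estimator would otherwise dominate the true transport lag
  cc <- vapply(lags, function(k) {
    if (k >= 0) stats::cor(a[1:(n - k)], b[(1 + k):n])
    else        stats::cor(a[(1 - k):n], b[1:(n + k)])
  }, numeric(1))
  cc[!is.finite(cc)] <- -Inf
  i <- which.max(cc)
  if (i == 1L || i == length(lags))
    warning("unreliable delay: correlation peak at search-window edge")
  lag <- lags[i]
  # parabolic sub-sample refinement
  if (i > 1L && i < length(lags)) {
    y0 <- cc[i - 1L]; y1 <- cc[i]; y2 <- cc[i + 1L]
    den <- y0 - 2 * y1 + y2
    if (den < 0) lag <- lag + 0.5 * (y0 - y2) / den
  }
  lag * rs$dt
}

#' Per-sensor calibration curve
#'
#' Maps a raw metal-oxide reading `r` to concentration via
#' `ppm = scale_A * exp(sensitivity_B * r)`, with the sensor trace shifted by
#' the transport delay `delay_tau` relative to the reference. Constructed by
#' [fit_calibration()].
#'
#' @param scale_A ppm-scale factor, positive.
#' @param sensitivity_B exponent coefficient per raw unit (0 flags a
#'   degenerate, constant-reference fit).
#' @param delay_tau transport delay in seconds, non-negative.
#' @param fit_mse mean squared error of the fit in linear (ppm) space.
#' @param raw_range range of raw readings the fit was performed on.
#' @param degenerate logical degenerate-fit flag.
#' @return A `calibration_curve` object.
#' @export
calibration_curve <- function(scale_A, sensitivity_B, delay_tau = 0,
                              fit_mse = NA_real_, raw_range = c(NA, NA),
                              degenerate = FALSE) {
  if (scale_A <= 0) stop("scale_A must be positive")
  if (delay_tau < 0) stop("delay_tau must be non-negative")
  structure(list(scale_A = scale_A, sensitivity_B = sensitivity_B,
                 delay_tau = delay_tau, fit_mse = fit_mse,
                 raw_range = raw_range, degenerate = degenerate),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> ppm = %.4g * exp(%.4g * raw), delay %.2f s%s\n",
    x$scale_A, x$sensitivity_B, x$delay_tau,
    if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  if (!is.na(x$fit_mse)) cat(sprintf("  fit MSE %.4g ppm^2\n", x$fit_mse))
  invisible(x)
}

#' Fit an exponential calibration curve against the reference detector
#'
#' Fits `ppm_ref(t) = scale_A * exp(sensitivity_B * raw(t - delay))` on
#' delay-aligned sample pairs. The fit is performed in log space (linear
#' regression of `log(ppm)` on the raw reading, reference clipped at a small
#' positive floor to stabilize logs); `fit_mse` is reported in linear ppm
#' space. A constant reference yields a degenerate curve with
#' `sensitivity_B = 0` and `scale_A` equal to the mean reference.
#'
#' @param sensor raw [sensor_series()].
#' @param reference_ppm reference series already expressed in ppm (detector
#'   voltage times the detector's ppm-per-volt gain).
#' @param delay transport delay in seconds, e.g. from [align_delay()].
#' @param ppm_floor positive clipping floor applied to the reference before
#'   taking logs.
#' @return A [calibration_curve()]. Warns (`poor-fit`) when the raw/reference
#'   relation is non-monotone beyond noise.
#' @export
fit_calibration <- function(sensor, reference_ppm, delay = 0,
                            ppm_floor = 1e-3) {
  stopifnot(inherits(sensor, "sensor_series"),
            inherits(reference_ppm, "sensor_series"))
  if (delay < 0) stop("delay must be non-negative")
  # align: reference at time t + delay saw what the sensor read at t
  ref_shift <- sensor_series(reference_ppm$sensor_id,
                             reference_ppm$times - delay,
                             reference_ppm$values, reference_ppm$rate_hz)
  rs <- resample_common(sensor, ref_shift)
  raw <- rs$a; ref <- rs$b
  if (length(raw) < 50L)
    stop("insufficient data: fewer than 50 aligned pairs")
  if (stats::sd(ref) < ppm_floor || stats::sd(raw) < 1e-12) {
    return(calibration_curve(max(mean(ref), ppm_floor), 0, delay,
                             fit_mse = mean((ref - mean(ref))^2),
                             raw_range = range(raw), degenerate = TRUE))
  }
  fit <- stats::lm(log(pmax(ref, ppm_floor)) ~ raw)
  B <- unname(stats::coef(fit)[2])
  A <- exp(unname(stats::coef(fit)[1]))
  pred <- A * exp(B * raw)
  mse <- mean((ref - pred)^2)
  # monotonicity beyond noise: rank correlation of raw vs reference should
  # carry the sign of B decisively
  rho <- suppressWarnings(stats::cor(raw, ref, method = "spearman"))
  if (is.finite(rho) && sign(rho) != sign(B) || abs(rho) < 0.2)
    warning(sprintf("poor fit: raw/reference relation not monotone (MSE %.3g)",
                    mse))
  calibration_curve(A, B, delay, fit_mse = mse, raw_range = range(raw))
}

#' Convert a raw sensor series to concentration
#'
#' Applies a fitted [calibration_curve()]: `ppm = scale_A * exp(sensitivity_B
#' * raw)`, with the output time axis shifted by `-delay_tau` so the ppm
#' samples are stamped at the time the odor was at the sensor.
#'
#' @param raw raw [sensor_series()].
#' @param curve a [calibration_curve()].
#' @return ppm [sensor_series()]. Warns when raw readings fall outside the
#'   fitted range by more than 20% of the range (extrapolation).
#' @export
apply_calibration <- function(raw, curve) {
  stopifnot(inherits(raw, "sensor_series"), inherits(curve, "calibration_curve"))
  rr <- curve$raw_range
  if (all(is.finite(rr))) {
    span <- diff(rr)
    if (span > 0 &&
        (min(raw$values) < rr[1] - 0.2 * span ||
         max(raw$values) > rr[2] + 0.2 * span))
      warning("extrapolation: raw readings exceed the fitted range by >20%")
  }
  ppm <- curve$scale_A * exp(curve$sensitivity_B * raw$values)
  sensor_series(raw$sensor_id, raw$times - curve$delay_tau, ppm, raw$rate_hz)
}

#' Invert a calibration curve
#'
#' @param ppm concentrations (ppm), positive.
#' @param curve a [calibration_curve()] with non-zero sensitivity.
#' @return raw readings such that [apply_calibration()] recovers `ppm`.
#' @export
invert_calibration <- function(ppm, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$sensitivity_B == 0)
    stop("degenerate curve (sensitivity 0) cannot be inverted")
  log(ppm / curve$scale_A) / curve$sensitivity_B
}

#' Validate a calibration against an independent replicate recording
#'
#' Refits the calibration on a replicate (sensor, reference) recording and
#' reports the maximum fractional change of predicted concentration over the
#' common raw range. The calibration passes when the deviation is below 10%
#' of the concentration scale.
#'
#' @param curve the original [calibration_curve()].
#' @param replicate list of two [sensor_series()]: the raw sensor and the
#'   reference in ppm, an independent recording of the same sensor.
#' @param tolerance pass threshold on the fractional deviation.
#' @return list with `deviation` (max fractional change), `pass` (logical)
#'   and the refitted `curve`.
#' @export
validate_calibration <- function(curve, replicate, tolerance = 0.10) {
  stopifnot(inherits(curve, "calibration_curve"),
            is.list(replicate), length(replicate) == 2L)
  sensor <- replicate[[1]]; reference <- replicate[[2]]
  if (series_duration(sensor) < 100 || series_duration(reference) < 100)
    stop("insufficient data: replicate shorter than 100 s")
  delay <- tryCatch(max(0, align_delay(sensor, reference)),
                    warning = function(w) curve$delay_tau)
  refit <- fit_calibration(sensor, reference, delay)
  rr <- range(c(curve$raw_range, refit$raw_range), finite = TRUE)
  grid <- seq(rr[1], rr[2], length.out = 200L)
  p0 <- curve$scale_A * exp(curve$sensitivity_B * grid)
  p1 <- refit$scale_A * exp(refit$sensitivity_B * grid)
  deviation <- max(abs(p1 - p0) / pmax(p0, .Machine$double.eps))
  list(deviation = deviation, pass = deviation < tolerance, curve = refit)
}

#' Read sensor series from a tidy CSV
#'
#' Expects columns `sensor_id,time_s,value`.
#'
#' @param path CSV file path.
#' @param rate_hz nominal rate to stamp on each series.
#' @return named list of [sensor_series()].
#' @export
read_sensor_csv <- function(path, rate_hz = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sensor_id", "time_s", "value")
  if (!all(need %in% names(df)))
    stop("CSV must have columns sensor_id,time_s,value")
  out <- lapply(split(df, df$sensor_id), function(d) {
    d <- d[order(d$time_s), ]
    sensor_series(d$sensor_id[1], d$time_s, d$value, rate_hz)
  })
  out[order(names(out))]
}

#' Write a calibration table to CSV
#'
#' @param curves named list of [calibration_curve()] objects.
#' @param path output CSV path
#'   (`sensor_id,scale_A,sensitivity_B,delay_tau_s,fit_mse`).
#' @return the table, invisibly.
#' @export
write_calibration_csv <- function(curves, path) {
  tab <- data.frame(
    sensor_id = names(curves),
    scale_A = vapply(curves, `[[`, numeric(1), "scale_A"),
    sensitivity_B = vapply(curves, `[[`, numeric(1), "sensitivity_B"),
    delay_tau_s = vapply(curves, `[[`, numeric(1), "delay_tau"),
    fit_mse = vapply(curves, `[[`, numeric(1), "fit_mse"),
    row.names = NULL)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
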