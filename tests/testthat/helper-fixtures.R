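# Shared fixtures and independent oracles used across the test files.

# triangle calibration waveform (500 s period, as in calibration runs)
triangle_wave <- function(t, period = 500) {
  phase <- (t %% period) / period
  0.05 + 0.95 * (1 - abs(2 * phase - 1))
}

# synthetic paired recording: raw sensor + ppm reference through a known
# exponential response and transport delay
make_calibration_pair <- function(scale_A = 2, sensitivity_B = 0.01,
                                  delay = 5, duration = 1500,
                                  noise_sd = 0, seed = 1) {
  set.seed(seed)
  t_os <- seq(0, duration, by = 1)
  ppm <- 100 * triangle_wave(t_os)
  # the sensor reads the local concentration with multiplicative noise,
  # mapped through the inverse exponential response
  sensed <- ppm * (1 + rnorm(length(t_os), 0, noise_sd))
  raw <- log(pmax(sensed, 1e-3) / scale_A) / sensitivity_B
  t_pid <- seq(0, duration, by = 1 / 13)
  ref <- 100 * triangle_wave(t_pid - delay) *
    (1 + rnorm(length(t_pid), 0, noise_sd))
  list(sensor = sensor_series("os", t_os, raw, 1),
       reference = sensor_series("pid", t_pid, pmax(ref, 1e-3), 13),
       truth = list(scale_A = scale_A, sensitivity_B = sensitivity_B,
                    delay = delay))
}

# the behavioral study conditions: cone landscape, central agar arena
study_context <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- make_scenario("cone")
      arena <- crop_field(sc$field, c(3.7, 13.3), c(-4.8, 4.8))
      cache <<- gradient_context(arena)
    }
    cache
  }
})

# brute-force sliding-window turn oracle: literal re-implementation by
# exhaustive loops, kept independent of detect_turns' vectorized path
oracle_turns <- function(track, threshold_deg = 60, window_s = 1.0,
                         speed_floor = 0.01) {
  tt <- track$times
  dt <- median(diff(tt))
  k <- max(1L, round(window_s / dt))
  n <- length(tt)
  cand_t <- c(); cand_a <- c()
  for (i in (k + 1):(n - k)) {
    b <- c(track$x[i] - track$x[i - k], track$y[i] - track$y[i - k])
    f <- c(track$x[i + k] - track$x[i], track$y[i + k] - track$y[i])
    if (sqrt(sum(b^2)) / (k * dt) < speed_floor) next
    if (sqrt(sum(f^2)) / (k * dt) < speed_floor) next
    a <- (atan2(f[2], f[1]) - atan2(b[2], b[1])) * 180 / pi
    a <- (a + 180) %% 360 - 180
    if (a == -180) a <- 180
    if (abs(a) > threshold_deg) {
      cand_t <- c(cand_t, tt[i]); cand_a <- c(cand_a, a)
    }
  }
  if (!length(cand_t)) return(data.frame(time = numeric(), angle = numeric()))
  keep_t <- c(); keep_a <- c()
  i <- 1
  while (i <= length(cand_t)) {
    j <- i
    while (j < length(cand_t) && cand_t[j + 1] - cand_t[j] <= window_s) j <- j + 1
    grp <- i:j
    best <- grp[which.max(abs(cand_a[grp]))]
    keep_t <- c(keep_t, cand_t[best]); keep_a <- c(keep_a, cand_a[best])
    i <- j + 1
  }
  data.frame(time = keep_t, angle = keep_a)
}

# uniform-gradient context: concentration rises linearly along +y, so the
# gradient direction is +y (90 deg) everywhere
ramp_context <- function(slope = 1, lim = 60) {
  xg <- seq(0, lim / 10, length.out = 31)
  yg <- seq(0, lim / 10, length.out = 31)
  vals <- outer(xg, yg, function(x, y) 1 + slope * y)
  gradient_context(scalar_field(xg, yg, vals))
}
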