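# Fixture builders and independent oracles shared across the test files.
# Oracles are deliberately written with different algorithms than the package
# (Horner evaluation, dense-grid extrema, hand-rolled type-7 quantiles).

# Records tibble from explicit days and weights (kg).
make_records <- function(id, day, weight_kg) {
  tibble::tibble(
    participant_id = id, day = as.integer(day),
    weight_raw = weight_kg, unit = "kg", weight_kg = weight_kg
  )
}

# Records sampled from a polynomial mean curve in raw day units.
poly_records <- function(id, coefs, days, noise_sd = 0) {
  w <- horner(coefs, days)
  if (noise_sd > 0) w <- w + rnorm(length(days), 0, noise_sd)
  make_records(id, days, w)
}

# One archetype series, optionally noisy, on an irregular day grid.
archetype_records <- function(id, pattern, duration = 133, w0 = 89.4,
                              lf = 0.10, noise_sd = 0, regular_by = NULL) {
  cf <- archetype_coefs(pattern, duration, w0, lf)
  if (is.null(regular_by)) {
    days <- c(1L, 1L + cumsum(1L + rgeom(3 * duration, 0.7)))
    days <- days[days <= duration + 1L]
    days <- sort(unique(c(days, duration + 1L)))
  } else {
    days <- sort(unique(c(seq(1L, duration + 1L, by = regular_by), duration + 1L)))
  }
  w <- horner(cf, days - 1)
  if (noise_sd > 0) w <- w + rnorm(length(days), 0, noise_sd)
  make_records(id, days, w)
}

# Full pipeline: records -> pattern assignment.
classify_records <- function(records, thresholds = default_thresholds()) {
  classify_trajectories(trajectory_features(fit_trajectories(records)), thresholds)
}

# Independent polynomial evaluation (Horner scheme).
horner <- function(coefs, t) {
  coefs <- unname(coefs[!is.na(coefs)])
  acc <- rep(0, length(t))
  for (k in rev(seq_along(coefs))) acc <- acc * t + coefs[k]
  acc
}

# Dense-grid argmin/argmax of a polynomial on [lo, hi] (step in days).
grid_argmin <- function(coefs, lo, hi, step = 0.01) {
  g <- seq(lo, hi, by = step)
  g[which.min(horner(coefs, g))]
}
grid_argmax <- function(coefs, lo, hi, step = 0.01) {
  g <- seq(lo, hi, by = step)
  g[which.max(horner(coefs, g))]
}

# Interior extrema of a polynomial located by sign changes of first
# differences on a dense grid; returns approximate locations (grid midpoints).
grid_extrema <- function(coefs, lo, hi, step = 0.01) {
  g <- seq(lo, hi, by = step)
  y <- horner(coefs, g)
  d <- diff(y)
  flips <- which(d[-1] * d[-length(d)] < 0)
  (g[flips + 1] + g[flips + 2]) / 2
}

# Hand-rolled type-7 quantile (linear interpolation between order statistics).
quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
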