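# Synthetic cohorts with the statistical structure the pipeline assumes:
# seven archetypal mean curves (one per trajectory pattern), irregular
# observation days with bounded gaps, initial weights ~ N(89.4, 22.5) kg
# truncated to [48, 243], durations uniform on 77-364 days, and additive
# Gaussian measurement noise (default SD 0.5 kg).
#
# Archetype mean curves are exact polynomials so that noise-free series are
# fixed points of the classification pipeline; amplitudes default to roughly
# 5-15% of initial weight so landmark margins dominate the 1 kg threshold.

# Cubic mean curve defined by the stationary points of its derivative:
# derivative = 3*b3*(s - x1)*(s - x2). `measure` fixes the amplitude: the
# curve is rescaled so that `measure(curve)` equals `target` (kg).
cubic_from_vertices <- function(x1, x2, b3_sign, w0, T, target,
                                measure = c("net_drop", "depth")) {
  measure <- match.arg(measure)
  b3 <- b3_sign
  b2 <- -3 * b3 * (x1 + x2) / 2
  b1 <- 3 * b3 * x1 * x2
  rel <- function(s) b1 * s + b2 * s^2 + b3 * s^3
  amt <- switch(measure,
    net_drop = rel(0) - rel(T),
    depth = rel(x1) - rel(x2)
  )
  lambda <- target / amt
  c(beta0 = w0, beta1 = lambda * b1, beta2 = lambda * b2, beta3 = lambda * b3)
}

#' Archetypal mean curve for a trajectory pattern
#'
#' Returns the polynomial coefficients (on the participant-relative day offset
#' `s = t - t1`, `s` in `[0, duration]`) of the noise-free mean curve for one
#' of the seven pattern archetypes:
#' 1 linear decline; 2 decline-plateau-decline (cubic, `beta3 < 0`);
#' 3 decrease to a nadir then partial regain (convex quadratic);
#' 4 early rise then decline (cubic, early maximum);
#' 5 decline with a prominent terminal rise back to the start (cubic);
#' 6 flat; 7 linear rise.
#'
#' @param pattern Integer 1-7.
#' @param duration Series duration `ttotal` in days.
#' @param w0 Initial weight (kg).
#' @param loss_frac Amplitude as a fraction of `w0` (default 0.10); patterns
#'   6 and 7 ignore it (flat; rise of ~0.02 kg/day).
#' @return Named numeric vector `beta0`..`beta3` (trailing zeros for lower
#'   degrees).
#' @export
archetype_coefs <- function(pattern, duration, w0, loss_frac = 0.10) {
  T <- duration
  L <- max(loss_frac * w0, 6) # keep landmark margins well above the 1 kg threshold
  switch(as.character(pattern),
    "1" = c(beta0 = w0, beta1 = -min(L / T, 0.12), beta2 = 0, beta3 = 0),
    "2" = cubic_from_vertices(0.35 * T, 0.70 * T, -1, w0, T, L, "net_drop"),
    "3" = {
      tn <- 0.60 * T
      d <- L
      # w0 - d + d*((s - tn)/tn)^2, expanded
      c(
        beta0 = w0, beta1 = -2 * d / tn,
        beta2 = d / tn^2, beta3 = 0
      )
    },
    "4" = cubic_from_vertices(0.20 * T, 1.10 * T, 1, w0, T, L, "net_drop"),
    "5" = {
      # early maximum at a*T with a tiny initial rise; the late minimum at
      # b*T is placed so the terminal rise returns exactly to the start:
      # integral of (s - aT)(s - bT) over [0, T] = 0  <=>
      # 1/3 - (a + b)/2 + a*b = 0
      a <- 0.05
      b <- (1 / 3 - a / 2) / (1 / 2 - a)
      cubic_from_vertices(a * T, b * T, 1, w0, T, L, "depth")
    },
    "6" = c(beta0 = w0, beta1 = 0, beta2 = 0, beta3 = 0),
    "7" = c(beta0 = w0, beta1 = min(0.02 + L / (10 * T), 0.04), beta2 = 0, beta3 = 0),
    stop("pattern must be 1..7", call. = FALSE)
  )
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Irregular observation days: day 1 always present, geometric-like gaps
# truncated to <= 29 days, last day forced to 1 + duration so the realized
# span equals the drawn duration.
sample_days <- function(duration, gap_prob = 0.7, max_gap = 29) {
  tz <- 1L + as.integer(duration)
  days <- 1L
  t <- 1L
  while (t < tz) {
    g <- 1L + stats::rgeom(1, gap_prob)
    g <- min(g, max_gap, tz - t)
    t <- t + g
    days <- c(days, t)
  }
  days
}

#' Default pattern mixture for simulated cohorts
#'
#' Shares of the seven patterns in a typical behavioural weight-loss cohort
#' (steady decline and plateau shapes dominate; rising/flat shapes are rare):
#' 30.6/15.4/47.2/1.9/3.0/1.5/0.3 percent.
#'
#' @return Numeric vector of length 7 summing to 1.
#' @export
default_pattern_mixture <- function() {
  c(0.306, 0.154, 0.472, 0.019, 0.030, 0.015, 0.003) /
    sum(c(0.306, 0.154, 0.472, 0.019, 0.030, 0.015, 0.003))
}

#' Simulate a synthetic weight-record cohort
#'
#' Per participant: draws a pattern from `mixture`, a duration (uniform
#' integer on `duration_range`), an initial weight (normal, truncated to
#' `w0_range`), builds the archetype mean curve, samples irregular observation
#' days (day 1 always present, gaps at most 29 days, last day at
#' `1 + duration`) and adds independent Gaussian noise. Every generated series
#' passes the participant-selection rules by construction. Fully deterministic
#' given `seed`.
#'
#' @param n Number of participants.
#' @param mixture Pattern mixture weights over archetypes 1-7 (summing to 1);
#'   default [default_pattern_mixture()].
#' @param w0_mean,w0_sd,w0_range Initial-weight distribution (kg): normal
#'   mean/SD, truncated to the range (defaults 89.4, 22.5, \[48, 243\]).
#' @param duration_range Integer range of `ttotal` in days (default
#'   \[77, 364\]: day indices are 1-based and capped at day 365, so a span of
#'   365 is unreachable).
#' @param loss_frac_range Archetype amplitude as a fraction of initial weight,
#'   drawn uniformly per participant (default \[0.08, 0.13\]).
#' @param gap_prob Geometric parameter of the gap process (default 0.7; mean
#'   gap ~1.4 days).
#' @param noise_sd Additive measurement-noise SD in kg (default 0.5).
#' @param seed Integer seed.
#' @return A list with `records` (tibble: `participant_id`, `day`, `weight`,
#'   `unit` — the reader/CSV schema), `truth` (tibble: `participant_id`,
#'   `pattern`, `duration`, `w0`, `loss_frac`, and the mean-curve coefficients
#'   `beta0`..`beta3`) and `config`.
#' @export
simulate_cohort <- function(n = 100,
                            mixture = default_pattern_mixture(),
                            w0_mean = 89.4, w0_sd = 22.5, w0_range = c(48, 243),
                            duration_range = c(77, 364),
                            loss_frac_range = c(0.08, 0.13),
                            gap_prob = 0.7,
                            noise_sd = 0.5,
                            seed = NULL) {
  stopifnot(length(mixture) == 7, abs(sum(mixture) - 1) < 1e-8)
  if (duration_range[1] < 77 || duration_range[2] > 364) {
    stop("duration_range outside [77, 364] would violate the selection rules",
      call. = FALSE
    )
  }
  if (!is.null(seed)) set.seed(seed)

  patterns <- sample(1:7, n, replace = TRUE, prob = mixture)
  durations <- sample(seq(duration_range[1], duration_range[2]), n, replace = TRUE)
  w0s <- rtruncnorm1(n, w0_mean, w0_sd, w0_range[1], w0_range[2])
  lfs <- stats::runif(n, loss_frac_range[1], loss_frac_range[2])
  ids <- sprintf("S%04d", seq_len(n))

  recs <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    cf <- archetype_coefs(patterns[i], durations[i], w0s[i], lfs[i])
    days <- sample_days(durations[i], gap_prob = gap_prob)
    mu <- predict_poly(cf, days - 1) # curve defined on s = t - 1
    w <- mu + stats::rnorm(length(days), 0, noise_sd)
    recs[[i]] <- tibble::tibble(
      participant_id = ids[i], day = days,
      weight = round(w, 3), unit = "kg"
    )
    truth[[i]] <- tibble::tibble(
      participant_id = ids[i], pattern = patterns[i],
      duration = durations[i], w0 = w0s[i], loss_frac = lfs[i],
      beta0 = cf[["beta0"]], beta1 = cf[["beta1"]],
      beta2 = cf[["beta2"]], beta3 = cf[["beta3"]]
    )
  }
  list(
    records = purrr::list_rbind(recs),
    truth = purrr::list_rbind(truth),
    config = list(
      n = n, mixture = mixture, w0_mean = w0_mean, w0_sd = w0_sd,
      w0_range = w0_range, duration_range = duration_range,
      loss_frac_range = loss_frac_range, gap_prob = gap_prob,
      noise_sd = noise_sd, seed = seed
    )
  )
}

#' Simulate early-prediction features with labels from a known multinomial logit
#'
#' Draws the three early predictors (`X1` early weight-change rate in kg/day,
#' `X2` record count in the first 14 days, `X3` duration in days) from
#' realistic marginals and assigns a consolidated pattern label from the
#' multinomial-logit probabilities implied by `coefs`. Used to test parameter
#' recovery of [fit_pattern_multinom()].
#'
#' @param n Number of participants.
#' @param coefs Coefficient matrix of the data-generating process: rows
#'   `(Intercept)`, `X1`, `X2`, `X3`; one column per non-reference category
#'   (column names are the category labels). The reference category has
#'   coefficients 0.
#' @param reference Label of the reference category (default `"1"`).
#' @param seed Integer seed.
#' @return A tibble `X1`, `X2`, `X3`, `label` (factor, reference level
#'   first).
#' @export
simulate_prediction_cohort <- function(n = 600, coefs, reference = "1",
                                       seed = NULL) {
  stopifnot(is.matrix(coefs), nrow(coefs) == 4, !is.null(colnames(coefs)))
  if (!is.null(seed)) set.seed(seed)
  X1 <- stats::rnorm(n, 0.08, 0.06)
  X2 <- 1L + stats::rpois(n, 6)
  X3 <- sample(77:364, n, replace = TRUE)
  X <- cbind(1, X1, X2, X3)
  eta <- cbind(0, X %*% coefs)
  lev <- c(reference, colnames(coefs))
  m <- apply(eta, 1, max)
  P <- exp(eta - m)
  P <- P / rowSums(P)
  lab <- apply(P, 1, function(p) sample(lev, 1, prob = p))
  tibble::tibble(
    X1 = X1, X2 = as.numeric(X2), X3 = as.numeric(X3),
    label = factor(lab, levels = lev)
  )
}
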