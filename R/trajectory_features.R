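# Analytic landmarks of the fitted trajectories: endpoint predictions, the
# quadratic nadir (vertex of the parabola), and the cubic stationary points
# obtained from the discriminant of the derivative.

#' Evaluate a polynomial at given days
#'
#' @param coefs Numeric vector `c(beta0, beta1, ...)`, lowest order first;
#'   trailing `NA`s (unused degrees) are allowed and treated as absent.
#' @param t Numeric vector of days.
#' @return Predicted weight (kg) at each `t`.
#' @export
predict_poly <- function(coefs, t) {
  coefs <- coefs[!is.na(coefs)]
  drop(outer(t, seq_along(coefs) - 1L, `^`) %*% coefs)
}

#' Stationary point (nadir) of a quadratic trajectory
#'
#' The vertex of `beta0 + beta1 t + beta2 t^2` is at `-beta1 / (2 beta2)`.
#' It is a minimum (a true weight nadir) when `beta2 > 0` and a maximum when
#' `beta2 < 0`; callers check the sign. Vectorized.
#'
#' @param beta1,beta2 Quadratic-fit coefficients.
#' @return Day of the stationary point; `NA` where `beta2 = 0` (undefined
#'   landmark).
#' @export
quadratic_nadir <- function(beta1, beta2) {
  out <- -beta1 / (2 * beta2)
  out[beta2 == 0] <- NA_real_
  out
}

#' Stationary points of a cubic trajectory
#'
#' The derivative of `beta0 + beta1 t + beta2 t^2 + beta3 t^3` is
#' `3 beta3 t^2 + 2 beta2 t + beta1`, whose discriminant is
#' `D = 4 beta2^2 - 12 beta1 beta3`. When `D > 0` the two stationary points
#' (vertices) are `(-2 beta2 +/- sqrt(D)) / (6 beta3)`, returned time-ordered
#' as `x1 < x2`. When `D <= 0` the vertices are undefined (`NA`), which is not
#' an error: the cubic is then monotone (or has a saddle).
#'
#' @param beta1,beta2,beta3 Cubic-fit coefficients; `beta3` must be non-zero.
#' @return A tibble with columns `D`, `x1`, `x2`.
#' @export
cubic_vertices <- function(beta1, beta2, beta3) {
  if (any(beta3 == 0)) stop("cubic_vertices() requires beta3 != 0", call. = FALSE)
  D <- 4 * beta2^2 - 12 * beta1 * beta3
  sq <- sqrt(pmax(D, 0))
  r1 <- (-2 * beta2 - sq) / (6 * beta3)
  r2 <- (-2 * beta2 + sq) / (6 * beta3)
  x1 <- pmin(r1, r2)
  x2 <- pmax(r1, r2)
  x1[D <= 0] <- NA_real_
  x2[D <= 0] <- NA_real_
  tibble::tibble(D = D, x1 = x1, x2 = x2)
}

#' Landmark features of each participant's selected trajectory model
#'
#' Computes, for the selected model of each participant, the quantities the
#' pattern classifier consumes: predicted weights at the first and last
#' recording day (`y_start`, `y_end`), the quadratic nadir day and its
#' predicted weight, and for cubic fits the derivative discriminant `D` and
#' the time-ordered vertices `x1 < x2` with their predicted weights. Landmarks
#' that do not apply to the selected degree (or are undefined, e.g. vertices
#' when `D <= 0`) are `NA`.
#'
#' @param fits Fit tibble from [fit_trajectories()] (must carry the `chosen`
#'   flag), or any fit tibble subset with one row per participant.
#' @return One row per participant: `participant_id`, `degree`,
#'   `beta0`..`beta3`, `t1`, `tz`, `ttotal`, `y_start`, `y_end`, `nadir`,
#'   `y_nadir`, `D`, `x1`, `x2`, `y_x1`, `y_x2`.
#' @export
trajectory_features <- function(fits) {
  ch <- if ("chosen" %in% names(fits)) fits[fits$chosen, , drop = FALSE] else fits
  if (anyDuplicated(ch$participant_id)) {
    stop("expected one chosen fit per participant", call. = FALSE)
  }
  purrr::pmap(
    ch[, c(
      "participant_id", "degree", "beta0", "beta1", "beta2", "beta3",
      "t1", "tz", "ttotal"
    )],
    function(participant_id, degree, beta0, beta1, beta2, beta3, t1, tz, ttotal) {
      coefs <- c(beta0, beta1, beta2, beta3)[seq_len(degree + 1L)]
      y_start <- predict_poly(coefs, t1)
      y_end <- predict_poly(coefs, tz)
      nadir <- y_nadir <- D <- x1 <- x2 <- y_x1 <- y_x2 <- NA_real_
      if (degree == 2L) {
        nadir <- quadratic_nadir(beta1, beta2)
        if (!is.na(nadir)) y_nadir <- predict_poly(coefs, nadir)
      } else if (degree == 3L) {
        v <- cubic_vertices(beta1, beta2, beta3)
        D <- v$D
        x1 <- v$x1
        x2 <- v$x2
        if (!is.na(x1)) {
          y_x1 <- predict_poly(coefs, x1)
          y_x2 <- predict_poly(coefs, x2)
        }
      }
      tibble::tibble(
        participant_id = participant_id, degree = degree,
        beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
        t1 = t1, tz = tz, ttotal = ttotal,
        y_start = y_start, y_end = y_end,
        nadir = nadir, y_nadir = y_nadir,
        D = D, x1 = x1, x2 = x2, y_x1 = y_x1, y_x2 = y_x2
      )
    }
  ) |> purrr::list_rbind()
}
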