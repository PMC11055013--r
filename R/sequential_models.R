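# Nested polynomial fits per participant and adjusted-R2 model selection.
#
# Fitting is done on an internally centred/scaled day axis for conditioning
# (day^3 reaches ~5e7 on the raw scale) and coefficients are mapped back to
# the raw day scale, so reported beta_k are in kg/day^k.

# Map coefficients a_k of sum_k a_k ((t - m)/s)^k to raw-scale beta_j of
# sum_j beta_j t^j via the binomial expansion.
descale_coefs <- function(a, m, s) {
  deg <- length(a) - 1L
  beta <- numeric(deg + 1L)
  for (k in 0:deg) {
    for (j in 0:k) {
      beta[j + 1L] <- beta[j + 1L] + a[k + 1L] * choose(k, j) * (-m)^(k - j) / s^k
    }
  }
  beta
}

fit_poly_one <- function(day, weight, degree) {
  n <- length(day)
  if (n <= degree + 1L) {
    stop("degenerate fit: ", n, " records cannot support a degree-", degree,
      " polynomial",
      call. = FALSE
    )
  }
  if (length(unique(day)) <= degree) {
    stop("singular design: fewer distinct days than model parameters", call. = FALSE)
  }
  m <- mean(day)
  s <- stats::sd(day)
  ts <- (day - m) / s
  X <- outer(ts, 0:degree, `^`)
  fit <- stats::lm.fit(X, weight)
  a <- fit$coefficients
  if (anyNA(a)) stop("singular design in polynomial fit", call. = FALSE)
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((weight - mean(weight))^2)
  r2 <- if (tss <= .Machine$double.eps * max(1, sum(weight^2))) 1 else 1 - rss / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - degree - 1)
  beta <- descale_coefs(unname(a), m, s)
  list(
    degree = degree,
    beta = c(beta, rep(NA_real_, 3L - degree)),
    r2 = r2, adj_r2 = adj,
    sigma = sqrt(rss / max(1, n - degree - 1)),
    n = n, residuals = res
  )
}

#' Fit the nested linear, quadratic and cubic models to every participant
#'
#' For each participant, fits weight (kg) against the day index by ordinary
#' least squares with degree 1, 2 and 3 polynomials. Coefficients are reported
#' on the raw day scale (kg, kg/day, kg/day^2, kg/day^3) even though fitting
#' is internally rescaled for numerical conditioning.
#'
#' @param records Selected record tibble (see [select_participants()]); each
#'   participant needs at least 5 records.
#' @return A tibble with three rows per participant (`degree` 1, 2, 3) holding
#'   `beta0`..`beta3`, `r2`, `adj_r2` (Ezekiel form:
#'   `1 - (1 - r2) (n - 1)/(n - p - 1)`), residual `sigma`, record count `n`
#'   and the series bounds `t1`, `tz`, `ttotal`.
#' @export
fit_polynomials <- function(records) {
  stopifnot(all(c("participant_id", "day", "weight_kg") %in% names(records)))
  split(records, records$participant_id) |>
    purrr::imap(function(df, id) {
      if (nrow(df) < 5) {
        stop("participant ", id, " has fewer than 5 records", call. = FALSE)
      }
      purrr::map(1:3, function(d) {
        f <- fit_poly_one(df$day, df$weight_kg, d)
        tibble::tibble(
          participant_id = id, degree = d,
          beta0 = f$beta[1], beta1 = f$beta[2], beta2 = f$beta[3], beta3 = f$beta[4],
          r2 = f$r2, adj_r2 = f$adj_r2, sigma = f$sigma, n = f$n,
          t1 = min(df$day), tz = max(df$day),
          ttotal = max(df$day) - min(df$day)
        )
      }) |> purrr::list_rbind()
    }) |>
    purrr::list_rbind()
}

# One adjusted-R2 comparison. The complex model wins iff its relative
# improvement exceeds `threshold`; when the simpler model's adjusted R2 is
# <= 0 the relative change is ill-defined and an absolute-difference fallback
# (adj_complex - adj_simple > threshold) is used and noted in the trail.
compare_adj_r2 <- function(adj_simple, adj_complex, threshold) {
  if (adj_simple > 0) {
    rel <- (adj_complex - adj_simple) / abs(adj_simple)
    list(
      complex_wins = rel > threshold,
      note = sprintf("rel %+.4f %s %.2f", rel, if (rel > threshold) ">" else "<=", threshold)
    )
  } else {
    diff <- adj_complex - adj_simple
    list(
      complex_wins = diff > threshold,
      note = sprintf(
        "abs-fallback %+.4f %s %.2f", diff,
        if (diff > threshold) ">" else "<=", threshold
      )
    )
  }
}

#' Select the optimal polynomial degree per participant
#'
#' Sequential comparison by adjusted R-squared: the quadratic model is
#' compared against the linear model, then the cubic model against the winner.
#' The more complex model is preferred only when its relative adjusted-R2
#' improvement exceeds `threshold` (default 5%). The decision trail records
#' every comparison so the choice can be audited and reconstructed.
#'
#' @param fits Fit tibble from [fit_polynomials()].
#' @param threshold Relative adjusted-R2 improvement required to prefer the
#'   more complex model (default `0.05`).
#' @return A tibble with one row per participant: chosen `degree`,
#'   `adj_r2_m1`..`adj_r2_m3` and the decision `trail`.
#' @export
select_models <- function(fits, threshold = 0.05) {
  wide <- fits |>
    dplyr::select("participant_id", "degree", "adj_r2") |>
    tidyr::pivot_wider(
      names_from = "degree", values_from = "adj_r2",
      names_prefix = "adj_r2_m"
    )
  pick <- function(a1, a2, a3) {
    c12 <- compare_adj_r2(a1, a2, threshold)
    w <- if (c12$complex_wins) 2L else 1L
    aw <- if (w == 2L) a2 else a1
    c3 <- compare_adj_r2(aw, a3, threshold)
    final <- if (c3$complex_wins) 3L else w
    tibble::tibble(
      degree = final,
      trail = paste0(
        "m2 vs m1: ", c12$note, " -> m", w, "; ",
        "m3 vs m", w, ": ", c3$note, " -> m", final
      )
    )
  }
  sel <- purrr::pmap(
    list(wide$adj_r2_m1, wide$adj_r2_m2, wide$adj_r2_m3),
    pick
  ) |> purrr::list_rbind()
  dplyr::bind_cols(wide["participant_id"], sel, wide[-1])
}

#' Fit and select trajectory models in one step
#'
#' Convenience wrapper: [fit_polynomials()] followed by [select_models()].
#'
#' @inheritParams fit_polynomials
#' @inheritParams select_models
#' @return The fit tibble with an added logical `chosen` column marking each
#'   participant's selected model; the selection tibble (with decision trails)
#'   is attached as attribute `"selection"`.
#' @export
fit_trajectories <- function(records, threshold = 0.05) {
  fits <- fit_polynomials(records)
  sel <- select_models(fits, threshold = threshold)
  fits <- fits |>
    dplyr::left_join(
      dplyr::select(sel, "participant_id", chosen_degree = "degree"),
      by = "participant_id"
    ) |>
    dplyr::mutate(chosen = .data$degree == .data$chosen_degree) |>
    dplyr::select(-"chosen_degree")
  attr(fits, "selection") <- sel
  fits
}
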