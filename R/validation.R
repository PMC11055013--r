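# Per-participant k-fold cross-validation of the selected model and
# classification-threshold sensitivity analysis.

cv_one <- function(day, weight, degree, k, rng_seed) {
  n <- length(day)
  k_used <- min(k, n)
  reduced <- k_used < k
  if (!is.null(rng_seed)) set.seed(rng_seed)
  fold <- sample(rep(seq_len(k_used), length.out = n))
  rmse <- r2 <- rep(NA_real_, k_used)
  skipped <- 0L
  for (f in seq_len(k_used)) {
    test <- fold == f
    if (sum(!test) < degree + 2L || length(unique(day[!test])) <= degree) {
      skipped <- skipped + 1L
      next
    }
    fit <- fit_poly_one(day[!test], weight[!test], degree)
    coefs <- fit$beta[seq_len(degree + 1L)]
    pred <- predict_poly(coefs, day[test])
    err <- weight[test] - pred
    rmse[f] <- sqrt(mean(err^2))
    if (sum(test) >= 2) {
      sst <- sum((weight[test] - mean(weight[test]))^2)
      r2[f] <- if (sst > 0) 1 - sum(err^2) / sst else NA_real_
    }
  }
  tibble::tibble(
    degree = degree, k_used = k_used, k_reduced = reduced,
    folds_skipped = skipped,
    mean_rmse = mean(rmse, na.rm = TRUE),
    sd_rmse = stats::sd(rmse, na.rm = TRUE),
    mean_r2 = if (all(is.na(r2))) NA_real_ else mean(r2, na.rm = TRUE),
    sd_r2 = if (sum(!is.na(r2)) < 2) NA_real_ else stats::sd(r2, na.rm = TRUE)
  )
}

#' Per-participant k-fold cross-validation of the selected trajectory model
#'
#' For each participant, the records are randomly partitioned into `k` folds
#' of as-equal-as-possible size (every record is held out exactly once); the
#' participant's selected polynomial degree is refitted on the training folds
#' and evaluated on the held-out records. Held-out R-squared uses the fold's
#' own mean as baseline; folds with fewer than 2 test records report RMSE
#' only. If a participant has fewer than `k` records, `k` is reduced to the
#' record count (leave-one-out floor) and flagged; training folds too small to
#' identify the model are skipped and flagged.
#'
#' @param records Selected record tibble.
#' @param fits Fit tibble from [fit_trajectories()] (chosen degrees are used).
#' @param k Number of folds (default 10).
#' @param seed Integer seed making the fold assignment deterministic.
#' @return A tibble with one row per participant: `mean_rmse`, `sd_rmse`
#'   (kg), `mean_r2`, `sd_r2` across folds, plus fold bookkeeping flags.
#' @export
cross_validate <- function(records, fits, k = 10, seed = NULL) {
  chosen <- fits[fits$chosen, c("participant_id", "degree")]
  ids <- sort(unique(chosen$participant_id))
  deg <- stats::setNames(chosen$degree, chosen$participant_id)
  purrr::map(seq_along(ids), function(i) {
    id <- ids[i]
    df <- records[records$participant_id == id, ]
    dplyr::bind_cols(
      tibble::tibble(participant_id = id),
      cv_one(df$day, df$weight_kg, deg[[id]], k,
        rng_seed = if (is.null(seed)) NULL else seed + i
      )
    )
  }) |> purrr::list_rbind()
}

#' Cohort-level aggregates of the per-participant CV metrics
#'
#' @param cv Tibble from [cross_validate()].
#' @return A one-row tibble with the cohort means of the per-participant mean
#'   RMSE / R-squared and of their per-participant SDs.
#' @export
cv_summary <- function(cv) {
  tibble::tibble(
    n_participants = nrow(cv),
    mean_rmse = mean(cv$mean_rmse, na.rm = TRUE),
    mean_sd_rmse = mean(cv$sd_rmse, na.rm = TRUE),
    mean_r2 = mean(cv$mean_r2, na.rm = TRUE),
    mean_sd_r2 = mean(cv$sd_r2, na.rm = TRUE)
  )
}

#' Default threshold variants for the sensitivity analysis
#'
#' The magnitude threshold `K` is varied over 0.5, 1.5 and 2 kg; the
#' quadratic mid-point divisor `d2` over 1.5 and 2.5; the cubic third divisor
#' `d3` over 2.5 and 3.5.
#'
#' @return A tibble with columns `param` and `value`.
#' @export
default_sensitivity_variants <- function() {
  tibble::tibble(
    param = c("K", "K", "K", "d2", "d2", "d3", "d3"),
    value = c(0.5, 1.5, 2, 1.5, 2.5, 2.5, 3.5)
  )
}

#' Classification-threshold sensitivity analysis
#'
#' Reclassifies the cohort under perturbed thresholds and reports, per
#' variant, the percentage of participants whose pattern assignment changed
#' relative to the default thresholds. Model selection is *not* re-run: the
#' thresholds only affect the classification stage. The analysis is fully
#' deterministic.
#'
#' @param features Feature tibble from [trajectory_features()].
#' @param variants Tibble of threshold variants (`param`, `value`); defaults
#'   to [default_sensitivity_variants()].
#' @param thresholds Baseline thresholds (default [default_thresholds()]).
#' @return A tibble: `param`, `value`, `n_changed`, `pct_changed` (0-100).
#' @export
sensitivity_analysis <- function(features,
                                 variants = default_sensitivity_variants(),
                                 thresholds = default_thresholds()) {
  base <- classify_trajectories(features, thresholds)
  purrr::pmap(variants, function(param, value) {
    th <- thresholds
    th[[param]] <- value
    alt <- classify_trajectories(features, th)
    stopifnot(identical(alt$participant_id, base$participant_id))
    changed <- sum(alt$pattern != base$pattern)
    tibble::tibble(
      param = param, value = value,
      n_changed = changed,
      pct_changed = 100 * changed / nrow(base)
    )
  }) |> purrr::list_rbind()
}
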