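# Sequential pattern classification.
#
# The decision tree below maps each participant's selected model and its
# landmarks to one of seven trajectory patterns:
#   1 steady decrease      2 decrease-plateau-decline   3 decrease-plateau-rise
#   4 early rise, decline  5 decline, terminal rise     6 flat
#   7 steady increase
# Flatness ("criteria -") checks compare magnitudes against the threshold K
# in the direction of the fitted slope; ties at exact thresholds fall on the
# "criteria -" branch. Landmark windows are the open interval (0, ttotal) in
# participant-relative days.

#' Default classification thresholds
#'
#' @param K Weight-change magnitude (kg) below which a difference is treated
#'   as "no substantial change" (criteria C1.1, C2.1, C3.1; default 1 kg).
#' @param d2 Divisor of `ttotal` for the quadratic early/late-nadir split
#'   (criterion C2.4; default 2, i.e. compare the stationary point to
#'   `ttotal/2`).
#' @param d3 Divisor of `ttotal` for the cubic first-third / plateau-width
#'   checks (criterion C3.7; default 3).
#' @return A named list `list(K, d2, d3)`.
#' @export
default_thresholds <- function(K = 1, d2 = 2, d3 = 3) {
  stopifnot(K > 0, d2 > 0, d3 > 0)
  list(K = K, d2 = d2, d3 = d3)
}

# Classify one participant's features row. Returns list(pattern, path).
classify_one <- function(f, th) {
  K <- th$K
  path <- character()
  note <- function(id, val) {
    path[[length(path) + 1L]] <<- paste0(id, "=", if (isTRUE(val)) "+" else "-")
  }
  leaf <- function(p) list(pattern = p, path = paste(path, collapse = ";"))

  if (f$degree == 1L) {
    up <- f$beta1 > 0
    note("C1.2", up)
    if (!up && (f$y_start - f$y_end) > K) {
      note("C1.1", TRUE)
      return(leaf(1L))
    }
    if (up && (f$y_end - f$y_start) > K) {
      note("C1.1", TRUE)
      return(leaf(7L))
    }
    note("C1.1", FALSE)
    return(leaf(6L))
  }

  if (f$degree == 2L) {
    if (is.na(f$nadir)) { # beta2 == 0: quadratic degenerated to a line
      note("nadir_defined", FALSE)
      f2 <- f
      f2$degree <- 1L
      return(classify_one(f2, th))
    }
    flat <- abs(f$y_start - f$y_nadir) <= K && abs(f$y_end - f$y_nadir) <= K
    note("C2.1", !flat)
    if (flat) return(leaf(6L))
    convex <- f$beta2 > 0
    note("C2.2", convex)
    if (convex) {
      note("C2.3", f$nadir > 0)
      if (f$nadir <= 0) return(leaf(7L))
      if (f$nadir < f$ttotal) {
        note("nadir_in_window", TRUE)
        return(leaf(3L))
      }
      note("nadir_in_window", FALSE)
      return(leaf(1L))
    }
    # beta2 < 0: stationary point is a maximum
    note("C2.3", f$nadir > 0)
    if (f$nadir <= 0) return(leaf(1L))
    early_max <- f$nadir <= f$ttotal / th$d2
    note("C2.4", !early_max)
    if (early_max && (f$y_start - f$y_end) > 0) {
      note("net_decline", TRUE)
      return(leaf(4L))
    }
    return(leaf(7L))
  }

  # degree 3
  has_v <- !is.na(f$D) && f$D > 0
  note("C3.3", has_v)
  in_window <- has_v &&
    ((f$x1 > 0 && f$x1 < f$ttotal) || (f$x2 > 0 && f$x2 < f$ttotal))
  if (has_v) note("vertex_in_window", in_window)
  if (!has_v || !in_window) {
    decl <- (f$y_start - f$y_end) > 0
    note("C3.6", decl)
    return(leaf(if (decl) 1L else 7L))
  }
  flat <- abs(f$y_start - f$y_end) <= K && abs(f$y_x1 - f$y_x2) <= K
  note("C3.1", !flat)
  if (flat) return(leaf(6L))
  up3 <- f$beta3 > 0
  note("C3.2", up3)
  if (!up3) {
    # beta3 < 0: x1 is a local minimum, x2 a local maximum
    note("C3.7", (f$x2 - f$x1) > f$ttotal / th$d3)
    term_decl <- (f$y_x2 - f$y_end) > 0
    note("C3.8", term_decl)
    return(leaf(if (term_decl) 2L else 3L))
  }
  # beta3 > 0: x1 is a local maximum, x2 a local minimum
  early_rise <- f$x1 > 0 && f$x1 < f$ttotal / th$d3 && (f$y_x1 - f$y_start) > K
  note("early_max_rise", early_rise)
  if (early_rise) return(leaf(4L))
  returns <- (f$y_start - f$y_end) <= K
  note("C3.6", !returns)
  if (returns) return(leaf(5L))
  leaf(3L)
}

#' Classify trajectories into the seven patterns
#'
#' Applies the sequential decision tree to each participant's selected model
#' and landmark features. The tree is deterministic and total: every input
#' reaches exactly one leaf, and the criteria path that produced the label is
#' recorded for audit.
#'
#' @param features Feature tibble from [trajectory_features()].
#' @param thresholds Classification thresholds, see [default_thresholds()].
#' @return A tibble: `participant_id`, `model` (`"m1"`/`"m2"`/`"m3"`),
#'   `pattern` (integer 1-7), `consolidated` (`"1"`, `"2"`, `"3"`, `"4-7"`)
#'   and `criteria_path`.
#' @export
classify_trajectories <- function(features, thresholds = default_thresholds()) {
  rows <- purrr::map(seq_len(nrow(features)), function(i) {
    f <- as.list(features[i, ])
    res <- classify_one(f, thresholds)
    tibble::tibble(
      participant_id = f$participant_id,
      model = paste0("m", f$degree),
      pattern = res$pattern,
      criteria_path = res$path
    )
  }) |> purrr::list_rbind()
  rows$consolidated <- consolidate_patterns(rows$pattern)
  rows[, c("participant_id", "model", "pattern", "consolidated", "criteria_path")]
}

#' Consolidate low-representation patterns
#'
#' Patterns 4-7 ("no substantial decrease") are merged into a single category;
#' patterns 1-3 keep their own labels. Counts are preserved: this is a pure
#' relabelling.
#'
#' @param pattern Integer vector of pattern labels (1-7), or an assignment
#'   tibble from [classify_trajectories()].
#' @return A factor with levels `"1"`, `"2"`, `"3"`, `"4-7"` (or the input
#'   tibble with its `consolidated` column rebuilt).
#' @export
consolidate_patterns <- function(pattern) {
  if (is.data.frame(pattern)) {
    pattern$consolidated <- consolidate_patterns(pattern$pattern)
    return(pattern)
  }
  stopifnot(all(pattern %in% 1:7))
  factor(ifelse(pattern >= 4, "4-7", as.character(pattern)),
    levels = c("1", "2", "3", "4-7")
  )
}

#' Evaluate the per-model classification criteria for audit
#'
#' Evaluates every criterion of each participant's selected model family
#' (with `K` substituted for the nominal 1 kg, `ttotal/d2` for the quadratic
#' mid-point and `ttotal/d3` for the cubic third). Criteria that reference
#' undefined landmarks (e.g. cubic vertices when `D <= 0`) are returned as
#' `NA` and are never consumed by the decision tree in that state.
#'
#' @inheritParams classify_trajectories
#' @return A long tibble: `participant_id`, `criterion`, `value` (logical,
#'   `TRUE` = "criteria +", `NA` = undefined).
#' @export
evaluate_criteria <- function(features, thresholds = default_thresholds()) {
  K <- thresholds$K
  purrr::map(seq_len(nrow(features)), function(i) {
    f <- as.list(features[i, ])
    vals <- if (f$degree == 1L) {
      c(
        C1.1 = abs(f$y_end - f$y_start) > K,
        C1.2 = f$beta1 > 0
      )
    } else if (f$degree == 2L) {
      c(
        C2.1 = abs(f$y_start - f$y_nadir) > K || abs(f$y_end - f$y_nadir) > K,
        C2.2 = f$beta2 > 0,
        C2.3 = if (is.na(f$nadir)) NA else f$nadir > 0,
        C2.4 = if (is.na(f$nadir)) NA else f$nadir > f$ttotal / thresholds$d2
      )
    } else {
      vx <- !is.na(f$x1)
      c(
        C3.1 = if (vx) {
          abs(f$y_start - f$y_end) > K || abs(f$y_x1 - f$y_x2) > K
        } else {
          NA
        },
        C3.2 = f$beta3 > 0,
        C3.3 = f$D > 0,
        C3.4 = if (vx) f$ttotal > f$x1 else NA,
        C3.5 = if (vx) f$x1 > 0 else NA,
        C3.6 = (f$y_start - f$y_end) > 0,
        C3.7 = if (vx) (f$x2 - f$x1) > f$ttotal / thresholds$d3 else NA,
        C3.8 = if (vx) (f$y_x2 - f$y_end) > 0 else NA,
        C3.9 = if (vx) (f$y_start - f$y_x1) > 0 else NA,
        C3.10 = if (vx) (f$y_x1 - f$y_end) > 0 else NA
      )
    }
    tibble::tibble(
      participant_id = f$participant_id,
      criterion = names(vals),
      value = unname(vals)
    )
  }) |> purrr::list_rbind()
}

#' Summarize weight-loss characteristics by pattern
#'
#' Per-participant metrics (weight loss in kg — first minus last recorded
#' weight — and as % of initial weight, initial weight, duration, longest gap,
#' record count) are summarized per pattern (mean, SD, quartiles, min, max).
#' A one-way ANOVA across patterns is run for each metric, with Tukey HSD
#' pairwise comparisons flagged against Pattern 1 at `alpha = 0.05`. Patterns
#' with fewer than 2 members are excluded from the group tests (noted in the
#' result).
#'
#' @param records Selected record tibble.
#' @param assignments Assignment tibble from [classify_trajectories()].
#' @param consolidated Summarize by consolidated groups (`TRUE`, default) or
#'   by the raw seven patterns.
#' @return An object of class `pattern_summary`: a list with `stats` (per
#'   pattern x metric), `anova` (per metric F and p), `tukey` (pairwise
#'   comparisons vs Pattern 1) and `skipped` (patterns excluded from tests).
#' @export
summarize_patterns <- function(records, assignments, consolidated = TRUE) {
  per <- records |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      weight_loss_kg = dplyr::first(.data$weight_kg, order_by = .data$day) -
        dplyr::last(.data$weight_kg, order_by = .data$day),
      initial_weight = dplyr::first(.data$weight_kg, order_by = .data$day),
      duration = max(.data$day) - min(.data$day),
      longest_gap = if (dplyr::n() > 1) max(diff(sort(unique(.data$day)))) else 0,
      n_records = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(weight_loss_pct = 100 * .data$weight_loss_kg / .data$initial_weight) |>
    dplyr::inner_join(
      dplyr::select(assignments, "participant_id", "pattern", "consolidated"),
      by = "participant_id"
    )
  per$group <- if (consolidated) as.character(per$consolidated) else as.character(per$pattern)

  metrics <- c(
    "weight_loss_pct", "weight_loss_kg", "initial_weight",
    "duration", "longest_gap", "n_records"
  )
  long <- tidyr::pivot_longer(per,
    cols = dplyr::all_of(metrics),
    names_to = "metric", values_to = "value"
  )
  stats_tbl <- long |>
    dplyr::group_by(.data$metric, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value), sd = stats::sd(.data$value),
      q25 = unname(stats::quantile(.data$value, 0.25)),
      median = stats::median(.data$value),
      q75 = unname(stats::quantile(.data$value, 0.75)),
      min = min(.data$value), max = max(.data$value),
      .groups = "drop"
    )

  counts <- table(per$group)
  testable <- names(counts)[counts >= 2]
  skipped <- setdiff(names(counts), testable)
  anova_tbl <- NULL
  tukey_tbl <- NULL
  if (length(testable) >= 2) {
    sub <- per[per$group %in% testable, , drop = FALSE]
    sub$group <- factor(sub$group)
    res <- purrr::map(metrics, function(m) {
      fit <- stats::aov(sub[[m]] ~ group, data = sub)
      an <- summary(fit)[[1]]
      tk <- as.data.frame(stats::TukeyHSD(fit)$group)
      tk$comparison <- rownames(tk)
      list(
        anova = tibble::tibble(
          metric = m,
          f_value = an[["F value"]][1],
          p_value = an[["Pr(>F)"]][1]
        ),
        tukey = tibble::tibble(
          metric = m,
          comparison = tk$comparison,
          diff = tk$diff,
          p_adj = tk$`p adj`,
          significant = tk$`p adj` < 0.05
        )
      )
    })
    anova_tbl <- purrr::list_rbind(purrr::map(res, "anova"))
    tukey_tbl <- purrr::list_rbind(purrr::map(res, "tukey")) |>
      dplyr::filter(grepl("(^1-)|(-1$)", .data$comparison))
  }
  structure(
    list(
      stats = stats_tbl, anova = anova_tbl, tukey = tukey_tbl,
      skipped = skipped, per_participant = per
    ),
    class = "pattern_summary"
  )
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat("Per-pattern trajectory summary\n")
  print(x$stats, n = Inf)
  if (!is.null(x$anova)) {
    cat("\nOne-way ANOVA across patterns:\n")
    print(x$anova)
    cat("\nTukey HSD vs Pattern 1 (significant at 0.05):\n")
    print(dplyr::filter(x$tukey, .data$significant))
  }
  if (length(x$skipped)) {
    cat("\nPatterns excluded from group tests (<2 members):",
      paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pattern_summary <- function(x, ...) x$stats
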