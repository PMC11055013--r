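# Growth-chart percentile tables/plots and multi-panel trajectory reports.

PCTL_PROBS <- c(0.01, 0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95, 0.99)

#' Growth-chart percentile table for one pattern
#'
#' Each participant assigned to `pattern` contributes their selected model's
#' predicted weight on the grid of participant-relative days (`t = t1 + day`),
#' but only up to their own last observed day — no extrapolation past the end
#' of a participant's series. Cross-participant empirical percentiles (1st,
#' 5th, 10th, 25th, 50th, 75th, 90th, 95th, 99th; quantile type 7, linear
#' interpolation between order statistics) are computed at every grid day.
#' Percentile values are non-decreasing across levels at each day by
#' construction.
#'
#' @param fits Fit tibble from [fit_trajectories()].
#' @param assignments Assignment tibble from [classify_trajectories()].
#' @param pattern Pattern to chart (integer 1-7, or a consolidated label when
#'   `consolidated = TRUE`); needs at least 2 assigned participants.
#' @param grid_days Participant-relative day offsets for the grid (default
#'   `0:98`, the first 14 weeks).
#' @param consolidated Match `pattern` against consolidated labels instead of
#'   raw patterns.
#' @return A tibble: `pattern`, `day`, `week`, `percentile` (1, 5, ..., 99),
#'   `weight_kg`, `n_participants` contributing at that day.
#' @export
percentile_chart <- function(fits, assignments, pattern, grid_days = 0:98,
                             consolidated = FALSE) {
  ids <- if (consolidated) {
    assignments$participant_id[as.character(assignments$consolidated) == as.character(pattern)]
  } else {
    assignments$participant_id[assignments$pattern == pattern]
  }
  if (length(ids) < 2) {
    stop("percentile chart needs >= 2 participants in pattern ", pattern, call. = FALSE)
  }
  ch <- fits[fits$chosen & fits$participant_id %in% ids, , drop = FALSE]

  # predicted weight per participant on their own admissible grid days
  pred <- purrr::pmap(
    ch[, c("participant_id", "degree", "beta0", "beta1", "beta2", "beta3", "t1", "ttotal")],
    function(participant_id, degree, beta0, beta1, beta2, beta3, t1, ttotal) {
      d <- grid_days[grid_days <= ttotal]
      if (!length(d)) return(NULL)
      coefs <- c(beta0, beta1, beta2, beta3)[seq_len(degree + 1L)]
      tibble::tibble(
        participant_id = participant_id, day = d,
        pred = predict_poly(coefs, t1 + d)
      )
    }
  ) |> purrr::list_rbind()

  pred |>
    dplyr::group_by(.data$day) |>
    dplyr::reframe(
      percentile = PCTL_PROBS * 100,
      weight_kg = unname(stats::quantile(.data$pred, PCTL_PROBS, type = 7)),
      n_participants = dplyr::n()
    ) |>
    dplyr::mutate(
      pattern = as.character(pattern), week = .data$day / 7,
      .before = 1
    )
}

#' Plot a growth-chart percentile table
#'
#' @param chart Tibble from [percentile_chart()].
#' @return A ggplot: one line per percentile level over weeks.
#' @export
plot_percentile_chart <- function(chart) {
  chart$percentile <- factor(chart$percentile, levels = sort(unique(chart$percentile)))
  ggplot2::ggplot(
    chart,
    ggplot2::aes(x = .data$week, y = .data$weight_kg, colour = .data$percentile)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Weeks since first record", y = "Predicted weight (kg)",
      colour = "Percentile",
      title = paste0("Pattern ", chart$pattern[1], ": predicted weight percentiles")
    ) +
    ggplot2::theme_minimal()
}

#' Multi-panel weight-change report
#'
#' One panel per (consolidated) pattern: scatter of each participant's weight
#' change from their first record against time, a LOESS smoother summarizing
#' the panel's common shape, and a zero-change reference line. Patterns with
#' no members are rendered as an empty panel with a "no members" placeholder.
#'
#' @param records Selected record tibble.
#' @param assignments Assignment tibble from [classify_trajectories()].
#' @param consolidated Facet by consolidated groups (default `TRUE`) or by the
#'   raw seven patterns.
#' @param span LOESS span (default 0.75).
#' @return A ggplot object.
#' @export
plot_pattern_panels <- function(records, assignments, consolidated = TRUE,
                                span = 0.75) {
  df <- records |>
    dplyr::inner_join(
      dplyr::select(assignments, "participant_id", "pattern", "consolidated"),
      by = "participant_id"
    ) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::mutate(
      change = .data$weight_kg - dplyr::first(.data$weight_kg),
      rel_day = .data$day - min(.data$day)
    ) |>
    dplyr::ungroup()
  lev <- if (consolidated) c("1", "2", "3", "4-7") else as.character(1:7)
  df$panel <- factor(
    if (consolidated) as.character(df$consolidated) else as.character(df$pattern),
    levels = lev
  )
  empty <- setdiff(lev, unique(as.character(df$panel)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rel_day, y = .data$change)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5, colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "red") +
    ggplot2::geom_smooth(
      method = "loess", span = span, formula = y ~ x,
      se = FALSE, colour = "blue"
    ) +
    ggplot2::facet_wrap(~panel, drop = FALSE) +
    ggplot2::labs(
      x = "Days since first record", y = "Weight change (kg)",
      title = "Weight change by trajectory pattern"
    ) +
    ggplot2::theme_minimal()
  if (length(empty)) {
    p <- p + ggplot2::geom_text(
      data = tibble::tibble(
        panel = factor(empty, levels = lev),
        rel_day = mean(range(df$rel_day)), change = 0
      ),
      label = "no members", colour = "grey50"
    )
  }
  p
}
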