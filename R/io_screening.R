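#' @importFrom rlang .data
#' @importFrom stats sd quantile median aov TukeyHSD optim rnorm runif rgeom
#'   rpois setNames complete.cases p.adjust pnorm coef vcov logLik predict
#' @importFrom utils head tail
NULL

KG_PER_LB <- 0.45359237

#' Read raw weight records from a CSV file
#'
#' Reads a record-per-row CSV with columns `participant_id` (or `id`), a time
#' column (`day` or an ISO-8601 `date`), `weight` and `unit`, and normalizes it
#' into the weight-record schema used throughout the package. When a `date`
#' column is supplied, each participant's records are indexed in days since
#' their own first record, with the first record on day 1.
#'
#' Rows whose weight (or date) cannot be parsed are not silently dropped: they
#' are collected in the attached report (see [screening_report()]) and a
#' message reports their count. A missing required column is an error.
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble with columns `participant_id`, `day`, `weight_raw`,
#'   `unit` (`"kg"`, `"lb"` or `NA` when not reported) and `weight_kg`
#'   (`NA` when the unit is missing), with a `"report"` attribute listing
#'   rejected rows.
#' @seealso [normalize_records()] for data frames already in memory,
#'   [screen_records()] for the record-level quality screen.
#' @export
read_weight_records <- function(path) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  normalize_records(raw)
}

#' Normalize a raw record data frame into the weight-record schema
#'
#' Performs the same column mapping, unit conversion (1 lb = 0.45359237 kg)
#' and day anchoring as [read_weight_records()], for data already in memory
#' (for example the `records` element of [simulate_cohort()]).
#'
#' @param df Data frame with columns `participant_id`/`id`, `day` or `date`,
#'   `weight`, `unit`.
#' @return See [read_weight_records()].
#' @export
normalize_records <- function(df) {
  nm <- tolower(names(df))
  names(df) <- nm
  if (!"participant_id" %in% nm) {
    if ("id" %in% nm) names(df)[nm == "id"] <- "participant_id"
    else stop("required column `participant_id` (or `id`) is missing", call. = FALSE)
  }
  if (!"weight" %in% names(df)) {
    if ("weight_raw" %in% names(df)) {
      # round-trip support: screened-record CSVs carry weight_raw
      names(df)[names(df) == "weight_raw"] <- "weight"
    } else {
      stop("required column `weight` is missing", call. = FALSE)
    }
  }
  if (!"unit" %in% names(df)) stop("required column `unit` is missing", call. = FALSE)
  has_day <- "day" %in% names(df)
  has_date <- "date" %in% names(df)
  if (!has_day && !has_date) {
    stop("a time column is required: either `day` or `date`", call. = FALSE)
  }

  out <- tibble::as_tibble(df)
  out$.row <- seq_len(nrow(out))
  out$participant_id <- as.character(out$participant_id)
  out$weight_raw <- suppressWarnings(as.numeric(out$weight))
  out$unit <- normalize_unit(out$unit)

  bad_weight <- is.na(out$weight_raw)
  if (has_day) {
    out$day <- suppressWarnings(as.integer(as.numeric(as.character(out$day))))
    bad_time <- is.na(out$day)
  } else {
    dt <- suppressWarnings(as.Date(as.character(out$date)))
    bad_time <- is.na(dt)
    out$.date <- dt
  }

  bad <- bad_weight | bad_time
  reason_all <- dplyr::case_when(
    bad_weight & bad_time ~ "unparseable weight and time",
    bad_weight ~ "unparseable weight",
    bad_time ~ "unparseable time",
    TRUE ~ NA_character_
  )
  rejected <- out[bad, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$reason <- reason_all[bad]
    message(nrow(rejected), " malformed row(s) rejected; see screening_report()")
  }
  out <- out[!(bad_weight | bad_time), , drop = FALSE]

  if (has_date) {
    out <- out |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::mutate(day = as.integer(.data$.date - min(.data$.date)) + 1L) |>
      dplyr::ungroup()
    out$.date <- NULL
  }

  out$weight_kg <- dplyr::case_when(
    out$unit == "kg" ~ out$weight_raw,
    out$unit == "lb" ~ out$weight_raw * KG_PER_LB,
    TRUE ~ NA_real_
  )

  res <- out[, c("participant_id", "day", "weight_raw", "unit", "weight_kg")]
  res <- dplyr::arrange(res, .data$participant_id, .data$day)
  attr(res, "report") <- list(
    level = "record",
    input = nrow(df),
    rejected_malformed = nrow(rejected),
    retained = nrow(res),
    rejected_rows = if (nrow(rejected)) {
      tibble::tibble(row = rejected$.row, reason = rejected$reason)
    } else {
      tibble::tibble(row = integer(), reason = character())
    }
  )
  res
}

normalize_unit <- function(u) {
  u <- tolower(trimws(as.character(u)))
  u[u %in% c("kg", "kgs", "kilogram", "kilograms")] <- "kg"
  u[u %in% c("lb", "lbs", "pound", "pounds")] <- "lb"
  u[!u %in% c("kg", "lb")] <- NA_character_
  u
}

#' Retrieve the screening/selection report attached to a result
#'
#' [normalize_records()], [screen_records()] and [select_participants()] each
#' attach a consort-style accounting report to their return value; this
#' accessor retrieves it.
#'
#' @param x An object returned by one of the screening functions.
#' @return A list of counts (and, where relevant, per-rule tallies).
#' @export
screening_report <- function(x) attr(x, "report")

#' Screen weight records for data quality
#'
#' Applies the record-level exclusion rules, in this fixed order:
#' (1) drop records whose unit was not reported, (2) drop records with a raw
#' weight of 0, (3) drop records whose converted weight is below 40 kg or
#' above 250 kg. Each rule's tally is recorded so the accounting balances:
#' `input = retained + sum(dropped)`.
#'
#' @param records Normalized record tibble (see [normalize_records()]).
#' @return The surviving records, with a `"report"` attribute.
#' @export
screen_records <- function(records) {
  n_in <- nrow(records)
  r1 <- is.na(records$unit)
  kept <- records[!r1, , drop = FALSE]
  r2 <- kept$weight_raw == 0
  kept <- kept[!r2, , drop = FALSE]
  r3 <- kept$weight_kg < 40 | kept$weight_kg > 250
  kept <- kept[!r3, , drop = FALSE]
  attr(kept, "report") <- list(
    level = "record",
    input = n_in,
    dropped = c(
      missing_unit = sum(r1),
      zero_weight = sum(r2),
      out_of_range = sum(r3)
    ),
    retained = nrow(kept)
  )
  kept
}

#' Per-participant series summary
#'
#' @param records Normalized (usually screened/selected) record tibble.
#' @return One row per participant: first day `t1`, last day `tz`, duration
#'   `ttotal = tz - t1` (days), record count and longest gap between
#'   consecutive records.
#' @export
series_summary <- function(records) {
  records |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      t1 = min(.data$day),
      tz = max(.data$day),
      ttotal = max(.data$day) - min(.data$day),
      n_records = dplyr::n(),
      longest_gap = if (dplyr::n() > 1) max(diff(sort(unique(.data$day)))) else 0L,
      .groups = "drop"
    )
}

#' Select participants whose series support trajectory modelling
#'
#' Groups screened records into per-participant series and applies the
#' participant-level selection rules, in this fixed order:
#'
#' 1. same-day duplicate records are collapsed to their mean weight;
#' 2. days are re-anchored so each participant's first retained record is
#'    day 1;
#' 3. records beyond day 365 are truncated (duration between first and last
#'    record capped at one year);
#' 4. participants with `ttotal = tz - t1 < min_duration` (default 77 days)
#'    are excluded;
#' 5. participants with any gap between consecutive records of more than
#'    `max_gap` days (default 30; a gap of exactly 30 is retained) are
#'    excluded;
#' 6. participants with fewer than `min_records` records (default 5) are
#'    excluded.
#'
#' @param records Screened record tibble.
#' @param min_duration,max_day,max_gap,min_records Selection thresholds in
#'   days / record counts.
#' @return Records of the retained participants (days re-anchored, duplicates
#'   collapsed), with a `"report"` attribute tallying participant-level
#'   exclusions and record-level collapses/truncations.
#' @export
select_participants <- function(records, min_duration = 77, max_day = 365,
                                max_gap = 30, min_records = 5) {
  n_part_in <- dplyr::n_distinct(records$participant_id)
  n_rec_in <- nrow(records)

  collapsed <- records |>
    dplyr::group_by(.data$participant_id, .data$day) |>
    dplyr::summarise(
      weight_raw = mean(.data$weight_raw),
      unit = .data$unit[1],
      weight_kg = mean(.data$weight_kg),
      .n_dup = dplyr::n(),
      .groups = "drop"
    )
  n_collapsed <- sum(collapsed$.n_dup - 1L)
  collapsed$.n_dup <- NULL

  collapsed <- collapsed |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(day = .data$day - min(.data$day) + 1L) |>
    dplyr::ungroup()

  truncated <- collapsed[collapsed$day <= max_day, , drop = FALSE]
  n_truncated <- nrow(collapsed) - nrow(truncated)

  summ <- series_summary(truncated)
  summ$excluded <- dplyr::case_when(
    summ$ttotal < min_duration ~ "short_duration",
    summ$longest_gap > max_gap ~ "long_gap",
    summ$n_records < min_records ~ "few_records",
    TRUE ~ NA_character_
  )
  keep_ids <- summ$participant_id[is.na(summ$excluded)]
  out <- truncated[truncated$participant_id %in% keep_ids, , drop = FALSE]
  out <- dplyr::arrange(out, .data$participant_id, .data$day)

  drops <- table(factor(summ$excluded,
    levels = c("short_duration", "long_gap", "few_records")
  ))
  attr(out, "report") <- list(
    level = "participant",
    participants_in = n_part_in,
    participants_retained = length(keep_ids),
    participants_dropped = c(
      short_duration = unname(drops["short_duration"]),
      long_gap = unname(drops["long_gap"]),
      few_records = unname(drops["few_records"])
    ),
    records_in = n_rec_in,
    records_collapsed = n_collapsed,
    records_truncated = n_truncated,
    records_retained = nrow(out)
  )
  out
}
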