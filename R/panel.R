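#' Build the participant-day panel of missing groupings
#'
#' Collapses measurement groupings to one row per participant-day, the
#' unit of observation of the non-collection model. For each participant,
#' days run from the calendar day (in `tz`) of their first grouping to
#' that of their last, inclusive; days with no groupings at all are kept
#' and contribute `y_missing = e_expected`. Each grouping is assigned to
#' the day containing its start time, so a grouping never counts toward
#' two days. Days on which the phone delivered more groupings than the
#' schedule expects (clock drift, OS bursts) are clipped at zero missing
#' and flagged in the `overrun` column.
#'
#' @param groupings Output of [segment_events()].
#' @param schedule The [sensor_schedule()] that generated the stream;
#'   defines the expected groupings per day (the model offset).
#' @param covariates A covariate table with one row per participant:
#'   `participant_id`, `study_id`, `os`, `gender`, `education`,
#'   `race_ethnicity`, `age_years`. See [read_covariates()]. Optional
#'   (`NULL` skips the join).
#' @param tz Timezone in which calendar days are cut. Default `"UTC"`.
#' @param drop_partial_days Drop each participant's first and last
#'   observed day (which are usually partial)? Default `FALSE`: partial
#'   boundary days are retained as full days.
#'
#' @return A tibble with one row per participant-day: `participant_id`,
#'   `study_id`, `sensor`, `day_index` (days since the participant's
#'   first observed day), `week` (`day_index / 7`, the time-in-study
#'   covariate), `y_missing`, `e_expected`, `overrun`, and — when
#'   `covariates` is supplied — `os_ios`, `male`, `degree_4yr_plus`,
#'   `race`, `age_decades`.
#' @export
build_daily_panel <- function(groupings, schedule, covariates = NULL,
                              tz = "UTC", drop_partial_days = FALSE) {
  schedule <- as_schedule(schedule)
  e_exp <- expected_groupings_per_day(schedule)

  if (!is.null(covariates)) {
    covariates <- check_covariates(covariates)
    unknown <- setdiff(unique(groupings$participant_id),
                       covariates$participant_id)
    if (length(unknown) > 0) {
      stop("participants absent from the covariate table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    silent <- setdiff(covariates$participant_id,
                      unique(groupings$participant_id))
    if (length(silent) > 0) {
      warning(length(silent), " participant(s) with zero events contribute ",
              "no panel rows: ", paste(silent, collapse = ", "),
              call. = FALSE)
    }
  }
  if (nrow(groupings) == 0L) {
    return(empty_panel(has_covariates = !is.null(covariates)))
  }

  daily <- groupings |>
    dplyr::mutate(day = calendar_day(.data$start_ms, tz)) |>
    dplyr::count(.data$participant_id, .data$study_id, .data$sensor,
                 .data$day, name = "n_groupings")

  panel <- daily |>
    dplyr::group_by(.data$participant_id, .data$study_id, .data$sensor) |>
    dplyr::group_modify(function(df, key) {
      days <- seq(min(df$day), max(df$day))
      out <- tibble::tibble(day = days) |>
        dplyr::left_join(df[, c("day", "n_groupings")], by = "day") |>
        dplyr::mutate(n_groupings = dplyr::coalesce(.data$n_groupings, 0L))
      if (drop_partial_days && nrow(out) > 2L) {
        out <- out[-c(1L, nrow(out)), ]
      }
      out
    }) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(day_index = .data$day - min(.data$day)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      week = .data$day_index / 7,
      e_expected = e_exp,
      y_missing = pmax(0L, e_exp - .data$n_groupings),
      overrun = .data$n_groupings > e_exp
    )
  if (any(panel$overrun)) {
    warning(sum(panel$overrun), " participant-day(s) had more groupings ",
            "than expected; y_missing clipped at 0", call. = FALSE)
  }
  panel <- panel |>
    dplyr::select("participant_id", "study_id", "sensor", "day_index",
                  "week", "y_missing", "e_expected", "overrun")
  if (!is.null(covariates)) {
    panel <- dplyr::left_join(panel, encode_covariates(covariates),
                              by = c("participant_id", "study_id"))
  }
  panel
}

# calendar day number (days since 1970-01-01) of an epoch-ms instant,
# cut at local midnight in tz
calendar_day <- function(ms, tz) {
  t <- as.POSIXct(ms / 1000, tz = tz, origin = "1970-01-01")
  as.integer(as.Date(t, tz = tz))
}

empty_panel <- function(has_covariates) {
  out <- tibble::tibble(
    participant_id = character(), study_id = character(),
    sensor = character(), day_index = integer(), week = numeric(),
    y_missing = integer(), e_expected = integer(), overrun = logical()
  )
  if (has_covariates) {
    out <- dplyr::bind_cols(out, tibble::tibble(
      os_ios = integer(), male = integer(), degree_4yr_plus = integer(),
      race = factor(character(), levels = race_levels()), age_decades = numeric()
    ))
  }
  out
}

#' Per-participant missingness summary
#'
#' Mean proportion of expected measurement groupings that were missing,
#' per participant, averaged over their observed days — the quantity
#' usually displayed as a per-participant missingness bar chart.
#'
#' @param panel A participant-day panel from [build_daily_panel()] or
#'   [simulate_panel()].
#' @return A tibble with one row per participant — `participant_id`,
#'   `study_id`, `sensor`, `n_days`, `prop_missing` — sorted by
#'   `prop_missing` (ascending).
#' @export
participant_missingness_summary <- function(panel) {
  stopifnot(nrow(panel) > 0)
  panel |>
    dplyr::group_by(.data$participant_id, .data$study_id, .data$sensor) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      prop_missing = mean(.data$y_missing / .data$e_expected),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$prop_missing)
}
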