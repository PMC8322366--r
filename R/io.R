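#' Read a raw sensor event log
#'
#' Reads a delimited event log with one row per raw sensor measurement
#' and columns `participant_id`, `study_id`, `sensor`, `timestamp_ms`
#' (UTC epoch milliseconds). Only timestamps are used downstream; sensor
#' payloads (coordinates, accelerations) are never read.
#'
#' Beiwe-style per-hour files — one file per participant x sensor x hour
#' whose first column is a UTC timestamp — are also accepted: pass the
#' file together with the ids it encodes via `participant_id`, `study_id`
#' and `sensor`, and the first column (epoch milliseconds or an ISO
#' datetime) becomes `timestamp_ms`.
#'
#' @param path Path to the CSV file.
#' @param participant_id,study_id,sensor If supplied, the file is treated
#'   as a Beiwe-style per-stream file and these label every row.
#' @return A tibble of events suitable for [segment_events()].
#' @export
read_event_log <- function(path, participant_id = NULL, study_id = NULL,
                           sensor = NULL) {
  beiwe <- !is.null(participant_id)
  if (beiwe) {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
    ts_col <- raw[[1]]
    ts <- suppressWarnings(as.numeric(ts_col))
    if (anyNA(ts)) {  # ISO datetime first column
      ts <- as.numeric(as.POSIXct(ts_col, tz = "UTC")) * 1000
    }
    out <- tibble::tibble(
      participant_id = participant_id,
      study_id = study_id %||% NA_character_,
      sensor = sensor %||% NA_character_,
      timestamp_ms = ts
    )
  } else {
    out <- readr::read_csv(path, col_types = readr::cols(
      participant_id = readr::col_character(),
      study_id = readr::col_character(),
      sensor = readr::col_character(),
      timestamp_ms = readr::col_double()
    ))
  }
  check_events(out)
}

#' Read a participant covariate table
#'
#' One row per participant with columns `participant_id`, `study_id`,
#' `os`, `gender`, `education`, `race_ethnicity`, `age_years`. Empty
#' cells are missing values.
#'
#' @param path Path to the CSV file.
#' @return A validated covariate tibble.
#' @export
read_covariates <- function(path) {
  check_covariates(readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    study_id = readr::col_character(),
    os = readr::col_character(),
    gender = readr::col_character(),
    education = readr::col_character(),
    race_ethnicity = readr::col_character(),
    age_years = readr::col_double()
  )))
}

#' Read a study design configuration
#'
#' A YAML (or JSON) file mapping each study to its per-sensor sampling
#' schedules and an optional timezone:
#'
#' ```yaml
#' study_A:
#'   timezone: America/New_York
#'   sensors:
#'     gps: {on_cycle_s: 60, off_cycle_s: 540}
#'     accelerometer: {on_cycle_s: 10, off_cycle_s: 10}
#' ```
#'
#' @param path Path to the YAML/JSON file.
#' @return A named list per study with elements `timezone` (default
#'   `"UTC"`) and `sensors`, a named list of [sensor_schedule()] objects.
#' @export
read_design_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  purrr::imap(raw, function(study, study_id) {
    sensors <- study$sensors %||%
      study[setdiff(names(study), "timezone")]
    list(
      timezone = study$timezone %||% "UTC",
      sensors = purrr::imap(sensors, function(sch, sensor_name) {
        if (is.null(sch$on_cycle_s)) {
          stop(sprintf("design config: sensor '%s' of study '%s' lacks on_cycle_s",
                       sensor_name, study_id), call. = FALSE)
        }
        sensor_schedule(sensor_name, sch$on_cycle_s, sch$off_cycle_s %||% 0)
      })
    )
  })
}

#' Write / read a participant-day panel
#'
#' Round-trips the panel produced by [build_daily_panel()] or
#' [simulate_panel()] as CSV with a fixed column order.
#'
#' @param panel A panel tibble.
#' @param path Output (or input) CSV path.
#' @return `write_panel()` returns `path` invisibly; `read_panel()`
#'   returns the panel tibble.
#' @export
write_panel <- function(panel, path) {
  cols <- c("participant_id", "study_id", "sensor", "day_index", "week",
            "y_missing", "e_expected", "os_ios", "male",
            "degree_4yr_plus", "race", "age_decades")
  out <- panel[, intersect(cols, names(panel))]
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    study_id = readr::col_character(),
    sensor = readr::col_character(),
    day_index = readr::col_integer(),
    week = readr::col_double(),
    y_missing = readr::col_integer(),
    e_expected = readr::col_integer(),
    .default = readr::col_guess()
  ))
  if ("race" %in% names(out)) {
    out$race <- factor(out$race, levels = race_levels())
  }
  out
}
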