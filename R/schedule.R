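#' Define a sensor sampling schedule
#'
#' Duty-cycled smartphone platforms alternate each sensor between an
#' *on-cycle*, during which the sensor records, and an *off-cycle*, during
#' which it sleeps. The pair of durations defines the study's missingness
#' by design: the number of collection attempts ("measurement groupings")
#' expected per day is known before any data arrive.
#'
#' @param sensor Sensor label, e.g. `"gps"` or `"accelerometer"`.
#' @param on_cycle_s On-cycle duration in seconds (positive integer).
#' @param off_cycle_s Off-cycle duration in seconds (non-negative integer).
#'
#' @return A `sensor_schedule` object: a named list with fields `sensor`,
#'   `on_cycle_s`, `off_cycle_s` and derived `cycle_length_s`.
#' @examples
#' sensor_schedule("gps", on_cycle_s = 60, off_cycle_s = 540)
#' @export
sensor_schedule <- function(sensor, on_cycle_s, off_cycle_s) {
  if (!is.character(sensor) || length(sensor) != 1L || is.na(sensor)) {
    stop("`sensor` must be a single sensor name", call. = FALSE)
  }
  on_cycle_s <- check_whole(on_cycle_s, "on_cycle_s")
  off_cycle_s <- check_whole(off_cycle_s, "off_cycle_s")
  if (on_cycle_s < 1) {
    stop("invalid schedule: `on_cycle_s` must be >= 1 second", call. = FALSE)
  }
  if (off_cycle_s < 0) {
    stop("invalid schedule: `off_cycle_s` must be >= 0 seconds", call. = FALSE)
  }
  structure(
    list(
      sensor = sensor,
      on_cycle_s = on_cycle_s,
      off_cycle_s = off_cycle_s,
      cycle_length_s = on_cycle_s + off_cycle_s
    ),
    class = "sensor_schedule"
  )
}

check_whole <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != trunc(x)) {
    stop(sprintf("`%s` must be a single whole number of seconds", name),
         call. = FALSE)
  }
  as.numeric(x)
}

#' @export
print.sensor_schedule <- function(x, ...) {
  cov <- expected_daily_coverage(x)
  cat(sprintf(
    "<sensor_schedule> %s: on %ds / off %ds (%d groupings/day, %.1f%% coverage, %.2f h/24 h)\n",
    x$sensor, as.integer(x$on_cycle_s), as.integer(x$off_cycle_s),
    expected_groupings_per_day(x), 100 * cov$fraction, cov$hours_per_day
  ))
  invisible(x)
}

as_schedule <- function(x) {
  if (inherits(x, "sensor_schedule")) return(x)
  if (is.list(x) && all(c("on_cycle_s", "off_cycle_s") %in% names(x))) {
    return(sensor_schedule(x$sensor %||% "sensor", x$on_cycle_s, x$off_cycle_s))
  }
  stop("expected a `sensor_schedule`", call. = FALSE)
}

#' Expected measurement groupings per day
#'
#' The design-based offset of the non-collection model: the number of times
#' per 24-hour day the platform attempts to collect data, `floor(86400 /
#' (on + off))`. Partial trailing cycles are not counted, so the offset is
#' a conservative, known constant.
#'
#' @param schedule A [sensor_schedule()].
#' @return Integer count of expected groupings per day.
#' @examples
#' expected_groupings_per_day(sensor_schedule("gps", 60, 540)) # 144
#' @export
expected_groupings_per_day <- function(schedule) {
  schedule <- as_schedule(schedule)
  as.integer(86400 %/% schedule$cycle_length_s)
}

#' Expected daily sampling coverage
#'
#' Fraction of each day the sensor is scheduled to record,
#' `on / (on + off)`, and the corresponding hours of data per 24-hour
#' period. A 1-minute-on / 9-minutes-off schedule gives 10% coverage and
#' 2.4 h of data per day.
#'
#' @inheritParams expected_groupings_per_day
#' @return A one-row tibble with columns `sensor`, `fraction` and
#'   `hours_per_day`.
#' @examples
#' expected_daily_coverage(sensor_schedule("gps", 60, 540))
#' @export
expected_daily_coverage <- function(schedule) {
  schedule <- as_schedule(schedule)
  frac <- schedule$on_cycle_s / schedule$cycle_length_s
  tibble::tibble(
    sensor = schedule$sensor,
    fraction = frac,
    hours_per_day = frac * 24
  )
}
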