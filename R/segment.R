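#' Segment raw sensor timestamps into measurement groupings
#'
#' A *measurement grouping* is a maximal run of raw sensor measurements
#' collected within one on-cycle: a new grouping starts whenever the gap
#' to the previous measurement is at least half the scheduled off-cycle.
#' Groupings are the unit whose absence defines sensor non-collection —
#' the phone attempted a collection window and nothing arrived.
#'
#' Events are processed per participant x sensor stream in a single
#' left-to-right pass. A gap of exactly half the off-cycle starts a new
#' grouping ("at least half"). Unsorted timestamps are sorted with a
#' warning; duplicate timestamps are kept, as they are distinct
#' measurements.
#'
#' @param events A data frame of raw measurements with columns
#'   `participant_id`, `study_id`, `sensor` and `timestamp_ms` (UTC epoch
#'   milliseconds), one row per measurement. See [read_event_log()].
#' @param schedule A [sensor_schedule()] giving the on/off cycle that
#'   generated the stream.
#'
#' @return A tibble with one row per grouping: `participant_id`,
#'   `study_id`, `sensor`, `grouping`, `start_ms`, `end_ms`, `n_events`.
#'   An empty stream yields zero rows.
#' @examples
#' ev <- tibble::tibble(
#'   participant_id = "p1", study_id = "s1", sensor = "gps",
#'   timestamp_ms = c(0, 10, 20, 600, 610) * 1000
#' )
#' segment_events(ev, sensor_schedule("gps", 60, 540))
#' @export
segment_events <- function(events, schedule) {
  schedule <- as_schedule(schedule)
  events <- check_events(events)
  if (nrow(events) == 0L) {
    return(tibble::tibble(
      participant_id = character(), study_id = character(),
      sensor = character(), grouping = integer(),
      start_ms = numeric(), end_ms = numeric(), n_events = integer()
    ))
  }
  gap_ms <- schedule$off_cycle_s / 2 * 1000

  events |>
    dplyr::group_by(.data$participant_id, .data$study_id, .data$sensor) |>
    dplyr::group_modify(function(df, key) {
      ts <- df$timestamp_ms
      if (is.unsorted(ts)) {
        warning(sprintf("unsorted timestamps for participant '%s'; sorting",
                        key$participant_id), call. = FALSE)
        ts <- sort(ts)
      }
      # new grouping whenever the gap to the previous event is >= off/2
      grp <- cumsum(c(TRUE, diff(ts) >= gap_ms))
      tibble::tibble(
        grouping = seq_len(max(grp)),
        start_ms = ts[!duplicated(grp)],
        end_ms = ts[!duplicated(grp, fromLast = TRUE)],
        n_events = tabulate(grp)
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select("participant_id", "study_id", "sensor", "grouping",
                  "start_ms", "end_ms", "n_events")
}

check_events <- function(events) {
  need <- c("participant_id", "study_id", "sensor", "timestamp_ms")
  miss <- setdiff(need, names(events))
  if (length(miss) > 0) {
    stop("`events` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(events$timestamp_ms)) || any(events$timestamp_ms < 0)) {
    stop("`timestamp_ms` must be non-missing and >= 0", call. = FALSE)
  }
  tibble::as_tibble(events)
}
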