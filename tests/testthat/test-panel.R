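sched10 <- sensor_schedule("gps", 60, 540)  # 144 expected/day

covs1 <- tibble::tibble(
  participant_id = "p1", study_id = "s1", os = "android",
  gender = "female", education = "high_school",
  race_ethnicity = "asian", age_years = 30
)

test_that("observed groupings reduce the daily missing count", {
  # day 0: all 144 cycles produce one event at the cycle start
  ts_full <- (0:143) * 600 * 1000
  # day 1: no events; day 2: 10 groupings
  ts_d2 <- 2 * 86400000 + (0:9) * 600 * 1000
  gr <- segment_events(events_tbl(c(ts_full, ts_d2)), sched10)
  panel <- build_daily_panel(gr, sched10, covs1)
  expect_identical(nrow(panel), 3L)
  expect_identical(panel$y_missing, c(0L, 144L, 134L))
  expect_identical(panel$e_expected, rep(144L, 3))
  expect_equal(panel$week, c(0, 1, 2) / 7)
  expect_identical(panel$os_ios, rep(0L, 3))
  expect_equal(panel$age_decades, rep(3, 3))
})

test_that("panel bounds hold and overruns clip at zero missing", {
  # events every 15 s with a 10s/10s schedule: every event is its own
  # grouping, far more than the 4320 expected
  sched_small <- sensor_schedule("gps", 10, 10)
  gr <- segment_events(events_tbl((0:4500) * 15 * 1000), sched_small)
  expect_warning(panel <- build_daily_panel(gr, sched_small, covs1),
                 "clipped")
  expect_true(all(panel$y_missing >= 0))
  expect_true(all(panel$y_missing <= panel$e_expected))
  expect_true(any(panel$overrun))
})

test_that("groupings are assigned to the day containing their start", {
  # grouping starting 30 s before midnight, ending after midnight
  ts <- 86400000 - 30000 + c(0, 20000, 40000)
  gr <- segment_events(events_tbl(ts), sched10)
  expect_identical(nrow(gr), 1L)
  panel <- build_daily_panel(gr, sched10, covs1)
  expect_identical(nrow(panel), 1L)  # only day 0 observed
  expect_identical(panel$y_missing, 143L)
})

test_that("unknown participants error; silent participants warn", {
  gr <- segment_events(events_tbl(c(0, 1000), pid = "ghost"), sched10)
  expect_error(build_daily_panel(gr, sched10, covs1), "ghost")
  covs2 <- dplyr::bind_rows(covs1, dplyr::mutate(
    covs1, participant_id = "p2"))
  gr1 <- segment_events(events_tbl(c(0, 1000), pid = "p1"), sched10)
  expect_warning(panel <- build_daily_panel(gr1, sched10, covs2),
                 "zero events")
  expect_identical(unique(panel$participant_id), "p1")
})

test_that("partial boundary days can be excluded", {
  ts <- c(3600000, 86400000 + 3600000, 2 * 86400000 + 3600000)
  gr <- segment_events(events_tbl(ts), sched10)
  keep <- build_daily_panel(gr, sched10, covs1)
  drop <- build_daily_panel(gr, sched10, covs1, drop_partial_days = TRUE)
  expect_identical(nrow(keep), 3L)
  expect_identical(nrow(drop), 1L)
  expect_identical(drop$day_index, 0L)
})

test_that("timezone shifts the day boundary", {
  # 23:30 UTC on day 0 is already day 1 in a UTC+1 zone
  ts <- (86400 - 1800) * 1000
  gr <- segment_events(events_tbl(ts), sched10)
  p_utc <- build_daily_panel(gr, sched10, covs1, tz = "UTC")
  p_east <- build_daily_panel(gr, sched10, covs1, tz = "Etc/GMT-1")
  expect_identical(nrow(p_utc), 1L)
  expect_identical(nrow(p_east), 1L)
  expect_identical(p_utc$day_index, p_east$day_index)  # both rebased to 0
})

test_that("per-participant missingness summary averages y/E over days", {
  panel <- dplyr::bind_rows(
    toy_panel(c(0, 0, 0), e = 10, pid = "all_there"),
    toy_panel(c(10, 10), e = 10, pid = "all_gone"),
    toy_panel(c(1, 2, 6), e = 10, pid = "mixed")
  )
  sm <- participant_missingness_summary(panel)
  expect_identical(sm$participant_id, c("all_there", "mixed", "all_gone"))
  expect_equal(sm$prop_missing, c(0, 0.3, 1))
  expect_identical(sm$n_days, c(3L, 3L, 2L))
})

test_that("panels are byte-identical across rebuilds", {
  set.seed(7)
  ts <- sort(runif(500, 0, 5 * 86400000))
  gr <- segment_events(events_tbl(ts), sched10)
  p1 <- build_daily_panel(gr, sched10, covs1)
  p2 <- build_daily_panel(gr, sched10, covs1)
  expect_identical(p1, p2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_panel(p1, f1); write_panel(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
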