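# Brute-force segmentation oracle: explicit event-by-event scan, written
# independently of the vectorized implementation. Splits whenever the
# gap to the previous event is at least half the off-cycle.
oracle_segment <- function(timestamps_ms, off_cycle_s) {
  if (length(timestamps_ms) == 0) {
    return(data.frame(start_ms = numeric(), end_ms = numeric(),
                      n_events = integer()))
  }
  ts <- sort(timestamps_ms)
  thr <- off_cycle_s / 2 * 1000
  starts <- ts[1]
  ends <- ts[1]
  counts <- 1L
  g <- 1L
  for (i in seq_along(ts)[-1]) {
    if (ts[i] - ts[i - 1] >= thr) {
      g <- g + 1L
      starts[g] <- ts[i]
      ends[g] <- ts[i]
      counts[g] <- 1L
    } else {
      ends[g] <- ts[i]
      counts[g] <- counts[g] + 1L
    }
  }
  data.frame(start_ms = starts, end_ms = ends, n_events = counts)
}

events_tbl <- function(ts_ms, pid = "p1", sid = "s1", sensor = "gps") {
  tibble::tibble(participant_id = pid, study_id = sid, sensor = sensor,
                 timestamp_ms = as.numeric(ts_ms))
}

# minimal hand-built panel: one sensor, explicit counts
toy_panel <- function(y, e = 144L, pid = "p1", sid = "s1",
                      os_ios = 0L, male = 0L, degree = 0L,
                      race = "non_hispanic_white", age_dec = 2.5) {
  n <- length(y)
  tibble::tibble(
    participant_id = rep(pid, n), study_id = rep(sid, n), sensor = "gps",
    day_index = seq_len(n) - 1L, week = (seq_len(n) - 1L) / 7,
    y_missing = as.integer(y), e_expected = as.integer(e),
    overrun = FALSE,
    os_ios = os_ios, male = male, degree_4yr_plus = degree,
    race = factor(race, levels = race_levels()), age_decades = age_dec
  )
}

# small shared simulated dataset + fit, built once per test run
shared_fit_env <- new.env()
get_shared_fit <- function() {
  if (is.null(shared_fit_env$fit)) {
    cfg <- sim_config(n_studies = 3, participants_per_study = 8,
                      days_per_participant = 20, seed = 301)
    tp <- true_params(log(0.3), c(week = log(1.02), os_ios = log(0.7)),
                      sigma_gamma = 0.6, sigma_delta = 0.2, omega = 1)
    sim <- simulate_study(cfg, tp)
    fit <- fit_noncollection(
      sim$panel, model_spec(terms = c("week", "os_ios")),
      mcmc_spec(chains = 4, warmup = 250, iter = 250, seed = 99),
      metrics = TRUE)
    shared_fit_env$sim <- sim
    shared_fit_env$truth <- tp
    shared_fit_env$fit <- fit
  }
  list(sim = shared_fit_env$sim, truth = shared_fit_env$truth,
       fit = shared_fit_env$fit)
}
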