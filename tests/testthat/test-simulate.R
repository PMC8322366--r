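test_that("cohort generation is seeded, sized and marginally calibrated", {
  cfg <- sim_config(n_studies = 2, participants_per_study = 5000,
                    days_per_participant = 1, seed = 10)
  cohort <- generate_cohort(cfg)
  expect_identical(nrow(cohort), 10000L)
  # marginals within 3 SE of their configured values
  p_f <- 140 / 211
  expect_lt(abs(mean(cohort$gender == "female", na.rm = TRUE) - p_f /
                  (1 - 2 / 211)), 3 * sqrt(p_f * (1 - p_f) / 10000) + 0.01)
  expect_lt(abs(mean(cohort$os == "ios") - 48 / 211),
            3 * sqrt(48 / 211 * (1 - 48 / 211) / 10000))
  # determinism
  cohort2 <- generate_cohort(cfg)
  expect_identical(cohort, cohort2)
  # empty
  expect_identical(nrow(generate_cohort(sim_config(
    n_studies = 2, participants_per_study = 0))), 0L)
})

test_that("masked covariates keep complete values for the generative model", {
  cfg <- sim_config(n_studies = 1, participants_per_study = 2000, seed = 3)
  cohort <- generate_cohort(cfg)
  complete <- attr(cohort, "complete")
  expect_false(anyNA(complete$gender))
  expect_true(anyNA(cohort$gender))       # ~1% masked
  agree <- !is.na(cohort$gender)
  expect_identical(cohort$gender[agree], complete$gender[agree])
})

test_that("invalid marginals are rejected", {
  expect_error(sim_config(p_gender = c(female = 0.8, male = 0.3,
                                       missing = 0)), "summing to 1")
  expect_error(sim_config(p_ios = 1.4), "\\[0, 1\\]")
})

test_that("simulated counts match the degenerate-model expectations", {
  # beta = 0, no random effects: E[y]/E = exp(alpha0)
  cfg <- sim_config(n_studies = 2, participants_per_study = 40,
                    days_per_participant = 60, seed = 21)
  tp <- true_params(log(0.25), omega = 1e6)
  sim <- simulate_panel(generate_cohort(cfg), tp, cfg)
  rate <- mean(sim$panel$y_missing / sim$panel$e_expected)
  se <- sd(sim$panel$y_missing / sim$panel$e_expected) / sqrt(nrow(sim$panel))
  expect_lt(abs(rate - 0.25), 4 * se)

  # sigma_gamma = 1: lognormal mean multiplies the rate by exp(1/2)
  tp2 <- true_params(log(0.02), sigma_gamma = 1, omega = 1e6)
  cfg2 <- sim_config(n_studies = 2, participants_per_study = 1500,
                     days_per_participant = 4, seed = 22)
  sim2 <- simulate_panel(generate_cohort(cfg2), tp2, cfg2)
  rate2 <- mean(sim2$panel$y_missing / sim2$panel$e_expected)
  expect_lt(abs(rate2 / 0.02 - exp(0.5)), 0.12)
})

test_that("negative-binomial draws match the NB moments", {
  cfg <- sim_config(n_studies = 1, participants_per_study = 500,
                    days_per_participant = 40, seed = 31,
                    schedule = sensor_schedule("gps", 10, 10))  # E = 4320
  omega <- 2.5
  tp <- true_params(log(0.005), omega = omega)  # mu = 21.6, far from ceiling
  sim <- simulate_panel(generate_cohort(cfg), tp, cfg)
  y <- sim$panel$y_missing
  mu <- 0.005 * 4320
  expect_equal(sim$truth$clip_rate, 0)
  expect_lt(abs(mean(y) - mu), 4 * sd(y) / sqrt(length(y)))
  v_expected <- mu + mu^2 / omega
  expect_lt(abs(var(y) / v_expected - 1), 0.05)
})

test_that("panel simulation records ground truth consistent with its draws", {
  cfg <- sim_config(n_studies = 2, participants_per_study = 6,
                    days_per_participant = 10, seed = 41)
  tp <- true_params(log(0.3), c(week = 0.02, os_ios = -0.4),
                    sigma_gamma = 0.5, sigma_delta = 0.2, omega = 0.8)
  sim <- simulate_panel(generate_cohort(cfg), tp, cfg)
  # log mu decomposes exactly into the linear predictor
  enc <- encode_covariates(attr(generate_cohort(cfg), "complete"))
  row1 <- sim$panel[1, ]
  i <- match(row1$participant_id, enc$participant_id)
  eta <- log(row1$e_expected) + tp$alpha0 +
    tp$beta[["week"]] * row1$week + tp$beta[["os_ios"]] * enc$os_ios[i] +
    sim$truth$gamma[[row1$participant_id]] +
    sim$truth$delta[[row1$study_id]]
  expect_equal(log(sim$truth$mu[1]), eta, tolerance = 1e-12)
  # clipping is recorded
  expect_identical(sim$panel$y_missing,
                   as.integer(pmin(sim$truth$y_unclipped,
                                   sim$panel$e_expected)))
})

test_that("stream simulation emits events only in retained cycles", {
  panel <- toy_panel(c(0, 144, 10), e = 144)
  cfg <- sim_config(seed = 51)
  st <- simulate_streams(panel, cfg)
  ev_day <- floor(st$events$timestamp_ms / 86400000) - cfg$start_day
  # day 0 complete: 144 cycles x 60 events at 1 Hz
  expect_identical(sum(ev_day == 0), 144L * 60L)
  # day 1 fully missing: no events
  expect_identical(sum(ev_day == 1), 0L)
  expect_identical(sum(ev_day == 2), 134L * 60L)
  expect_identical(nrow(st$dropped[st$dropped$day_index == 1, ]), 144L)
})

test_that("streams round-trip through segmentation to the simulated panel", {
  for (seed in c(61, 62, 63)) {
    cfg <- sim_config(n_studies = 2, participants_per_study = 5,
                      days_per_participant = 8, seed = seed)
    tp <- true_params(log(0.35), c(week = 0.01), sigma_gamma = 0.7,
                      sigma_delta = 0.3, omega = 0.8)
    sim <- simulate_study(cfg, tp, streams = TRUE)
    rebuilt <- build_daily_panel(segment_events(sim$events, cfg$schedule),
                                 cfg$schedule)
    truth <- trim_unobservable_days(sim$panel)
    cmp <- dplyr::inner_join(
      dplyr::select(truth, "participant_id", "day_index",
                    y_true = "y_missing"),
      dplyr::select(rebuilt, "participant_id", "day_index",
                    y_seen = "y_missing"),
      by = c("participant_id", "day_index"))
    expect_identical(nrow(cmp), nrow(truth))
    expect_identical(nrow(cmp), nrow(rebuilt))
    expect_identical(cmp$y_true, cmp$y_seen)
  }
})

test_that("adding a participant leaves existing draws untouched", {
  cfg5 <- sim_config(n_studies = 1, participants_per_study = 5,
                     days_per_participant = 6, seed = 71)
  cfg6 <- sim_config(n_studies = 1, participants_per_study = 6,
                     days_per_participant = 6, seed = 71)
  tp <- true_params(log(0.3), sigma_gamma = 0.5, omega = 1)
  p5 <- simulate_panel(generate_cohort(cfg5), tp, cfg5)$panel
  p6 <- simulate_panel(generate_cohort(cfg6), tp, cfg6)$panel
  shared <- p6$participant_id %in% p5$participant_id
  expect_identical(p6$y_missing[shared], p5$y_missing)
})
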