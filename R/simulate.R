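#' True parameters of the simulated non-collection model
#'
#' Bundles the generative parameters of the hierarchical
#' negative-binomial model: grand-mean log rate `alpha0`, fixed-effect
#' log rate ratios `beta` (named), random-intercept standard deviations
#' `sigma_gamma` (participant) and `sigma_delta` (study), and the
#' inverse-overdispersion shape `omega` (`Var(y) = mu + mu^2/omega`).
#'
#' @param alpha0 Grand-mean log rate (log proportion of expected
#'   groupings missing at week 0 for the reference group).
#' @param beta Named numeric vector of log rate ratios; names must be
#'   panel covariate columns (`week`, `os_ios`, `male`,
#'   `degree_4yr_plus`, `race_*` dummies, `age_decades`).
#' @param sigma_gamma,sigma_delta Random-intercept SDs, `>= 0`.
#' @param omega Negative-binomial shape, `> 0`.
#' @return A `true_params` object (named list).
#' @export
true_params <- function(alpha0, beta = c(), sigma_gamma = 0,
                        sigma_delta = 0, omega = 1) {
  stopifnot(is.numeric(alpha0), length(alpha0) == 1L,
            sigma_gamma >= 0, sigma_delta >= 0, omega > 0)
  if (length(beta) > 0 && is.null(names(beta))) {
    stop("`beta` must be a named vector of log rate ratios", call. = FALSE)
  }
  structure(list(alpha0 = alpha0, beta = beta, sigma_gamma = sigma_gamma,
                 sigma_delta = sigma_delta, omega = omega),
            class = "true_params")
}

#' Published point estimates as simulation ground truth
#'
#' Returns the fitted point estimates (exponentiated coefficients
#' back-transformed to the log scale) of the hierarchical NB model for a
#' given sensor, as reported for the six-study accelerometer/GPS
#' meta-analysis. These serve as the default ground truth for
#' parameter-recovery simulation, since the underlying raw data cannot
#' be redistributed.
#'
#' @param sensor `"gps"` or `"accelerometer"`.
#' @param terms Which fixed-effect terms to include (default all).
#' @return A [true_params()] object.
#' @export
default_true_params <- function(sensor = c("gps", "accelerometer"),
                                terms = NULL) {
  sensor <- match.arg(sensor)
  tab <- if (sensor == "gps") {
    list(intercept = 0.269, beta = c(
      week = 1.009, os_ios = 0.660, male = 0.822, degree_4yr_plus = 0.688,
      race_non_hispanic_black = 1.329, race_asian = 0.898,
      race_american_indian = 1.241, race_other_hispanic = 0.926,
      age_decades = 1.011),
      sigma_gamma = 0.888, sigma_delta = 0.295, omega = 0.64)
  } else {
    list(intercept = 0.191, beta = c(
      week = 1.005, os_ios = 1.301, male = 0.821, degree_4yr_plus = 0.786,
      race_non_hispanic_black = 1.638, race_asian = 0.724,
      race_american_indian = 1.137, race_other_hispanic = 0.978,
      age_decades = 1.010),
      sigma_gamma = 1.012, sigma_delta = 0.721, omega = 0.53)
  }
  beta <- log(tab$beta)
  if (!is.null(terms)) beta <- beta[intersect(names(beta), terms)]
  true_params(alpha0 = log(tab$intercept), beta = beta,
              sigma_gamma = tab$sigma_gamma, sigma_delta = tab$sigma_delta,
              omega = tab$omega)
}

#' Simulation configuration
#'
#' Cohort size, follow-up length, covariate marginals and the sensor
#' schedule for the synthetic-data generator. Marginal defaults mirror
#' the demographic composition of the six-study cohort the model was
#' developed on: 23% iOS, 66% female / 33% male, 67% high-school
#' education, 55% non-Hispanic White, age 25.4 (SD 10.8), with small
#' missing-report rates for gender/education/race.
#'
#' @param n_studies,participants_per_study,days_per_participant Cohort
#'   dimensions (non-negative integers).
#' @param p_ios Probability a participant uses iOS.
#' @param p_gender,p_education,p_race Named probability vectors over the
#'   canonical levels plus `missing`; each must sum to 1.
#' @param age_mean,age_sd Age distribution in years.
#' @param schedule A [sensor_schedule()]; default the 1-min-on /
#'   9-min-off GPS schedule (144 groupings/day).
#' @param hz Within-on-cycle event frequency for stream simulation.
#' @param start_day Calendar day (days since 1970-01-01, UTC) of day 0.
#' @param seed Integer seed; all draws derive from it.
#' @return A `sim_config` object (named list).
#' @export
sim_config <- function(n_studies = 6, participants_per_study = 30,
                       days_per_participant = 90,
                       p_ios = 48 / 211,
                       p_gender = c(female = 140, male = 69, missing = 2) / 211,
                       p_education = c(high_school = 142, associates = 9,
                                       bachelors = 39, graduate = 14,
                                       missing = 7) / 211,
                       p_race = c(non_hispanic_white = 117,
                                  non_hispanic_black = 31, asian = 37,
                                  american_indian = 2, other_hispanic = 15,
                                  missing = 9) / 211,
                       age_mean = 25.4, age_sd = 10.8,
                       schedule = sensor_schedule("gps", 60, 540),
                       hz = 1, start_day = 17000, seed = 1) {
  for (p in list(p_ios)) {
    if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]",
                                 call. = FALSE)
  }
  for (nm in c("p_gender", "p_education", "p_race")) {
    p <- get(nm)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(sprintf("`%s` must be a non-negative vector summing to 1", nm),
           call. = FALSE)
    }
  }
  stopifnot(n_studies >= 0, participants_per_study >= 0,
            days_per_participant >= 0, age_sd >= 0, hz > 0)
  structure(
    list(n_studies = as.integer(n_studies),
         participants_per_study = as.integer(participants_per_study),
         days_per_participant = as.integer(days_per_participant),
         p_ios = p_ios, p_gender = p_gender, p_education = p_education,
         p_race = p_race, age_mean = age_mean, age_sd = age_sd,
         schedule = as_schedule(schedule), hz = hz,
         start_day = as.integer(start_day), seed = as.integer(seed)),
    class = "sim_config"
  )
}

sample_level <- function(n, probs) {
  names(probs)[1 + findInterval(runif(n), cumsum(probs)[-length(probs)])]
}

#' Generate a synthetic cohort
#'
#' Draws a covariate table of `n_studies x participants_per_study`
#' participants with independent covariates at the configured marginals.
#' Levels drawn as `missing` become `NA` in the returned table; the
#' complete (pre-masking) values are attached as attribute
#' `"complete"` so the generative model can still use them.
#'
#' @param config A [sim_config()].
#' @return A covariate tibble (see [build_daily_panel()]) with attribute
#'   `"complete"` holding the unmasked table.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_total <- config$n_studies * config$participants_per_study
  out <- tibble::tibble(participant_id = character(n_total),
                        study_id = character(n_total),
                        os = character(n_total),
                        gender = character(n_total),
                        education = character(n_total),
                        race_ethnicity = character(n_total),
                        age_years = numeric(n_total))
  if (n_total == 0L) {
    attr(out, "complete") <- out
    return(out)
  }
  drop_missing <- function(p) {
    keep <- p[setdiff(names(p), "missing")]
    keep / sum(keep)
  }
  # one sub-seed per participant, so growing the cohort never perturbs
  # the draws of existing participants
  r <- 0L
  for (j in seq_len(config$n_studies)) {
    study <- sprintf("study_%02d", j)
    for (i in seq_len(config$participants_per_study)) {
      r <- r + 1L
      out$participant_id[r] <- sprintf("%s_p%03d", study, i)
      out$study_id[r] <- study
      with_seed(derive_seed(config$seed, 1L, j, i), {
        out$os[r] <- if (runif(1) < config$p_ios) "ios" else "android"
        out$gender[r] <- sample_level(1, config$p_gender)
        out$education[r] <- sample_level(1, config$p_education)
        out$race_ethnicity[r] <- sample_level(1, config$p_race)
        out$age_years[r] <- pmax(18, rnorm(1, config$age_mean,
                                           config$age_sd))
      })
    }
  }
  complete <- out
  # a draw of "missing" is a masked report, not a missing true value:
  # the complete table gets a real level, the reported table an NA
  for (v in c("gender", "education", "race_ethnicity")) {
    probs <- config[[switch(v, gender = "p_gender",
                            education = "p_education",
                            race_ethnicity = "p_race")]]
    masked <- which(out[[v]] == "missing")
    for (r in masked) {
      with_seed(derive_seed(config$seed, 2L, r, match(
        v, c("gender", "education", "race_ethnicity"))), {
        complete[[v]][r] <- sample_level(1, drop_missing(probs))
      })
    }
    out[[v]][masked] <- NA
  }
  attr(out, "complete") <- complete
  out
}

#' Simulate a participant-day panel from the generative model
#'
#' Draws study intercepts `delta_j ~ N(0, sigma_delta^2)`, participant
#' intercepts `gamma_ij ~ N(0, sigma_gamma^2)`, computes `log mu = log E
#' + alpha0 + X beta + gamma + delta` per participant-day (time in weeks
#' since each participant's first day), and draws `y ~ NegBin(mu,
#' omega)`. Draws exceeding the design ceiling `E` are clipped to `E`
#' and the clip rate recorded: bounded counts cannot literally be
#' negative binomial, and the clip rate makes the resulting ceiling
#' effect visible in recovery studies.
#'
#' @param cohort Covariate table from [generate_cohort()] (its
#'   `"complete"` attribute, when present, supplies unmasked covariates
#'   to the generative model).
#' @param params A [true_params()] object.
#' @param config A [sim_config()].
#' @return A list: `panel` (participant-day tibble as from
#'   [build_daily_panel()], reported covariates), `truth` (list with
#'   `params`, `delta`, `gamma`, `mu` per row, `y_unclipped`,
#'   `clip_rate`).
#' @export
simulate_panel <- function(cohort, params, config) {
  stopifnot(inherits(params, "true_params"), inherits(config, "sim_config"))
  complete <- attr(cohort, "complete") %||% cohort
  enc_rep <- encode_covariates(cohort)
  enc_true <- encode_covariates(complete)
  e_exp <- expected_groupings_per_day(config$schedule)
  d <- config$days_per_participant
  studies <- unique(cohort$study_id)

  delta <- with_seed(derive_seed(config$seed, 3L),
                     setNames(rnorm(length(studies), 0, params$sigma_delta),
                              studies))
  gamma <- setNames(
    purrr::map_dbl(seq_len(nrow(cohort)), function(i) {
      with_seed(derive_seed(config$seed, 4L, i), rnorm(1, 0, params$sigma_gamma))
    }),
    cohort$participant_id
  )

  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    if (d == 0L) return(NULL)
    pid <- cohort$participant_id[i]
    week <- (seq_len(d) - 1) / 7
    x <- c(as.list(enc_true[i, c("os_ios", "male", "degree_4yr_plus",
                                 "age_decades")]),
           as.list(setNames(as.numeric(race_dummies(enc_true$race[i])),
                            paste0("race_", race_levels()[-1]))))
    eta <- log(e_exp) + params$alpha0 + gamma[[pid]] +
      delta[[cohort$study_id[i]]]
    for (nm in names(params$beta)) {
      xv <- if (nm == "week") week else {
        if (is.null(x[[nm]])) stop(sprintf(
          "unknown covariate '%s' in true params", nm), call. = FALSE)
        as.numeric(x[[nm]])
      }
      eta <- eta + params$beta[[nm]] * xv
    }
    mu <- exp(eta)
    if (any(!is.finite(mu))) {
      stop(sprintf("non-finite mean for participant %s (check params)", pid),
           call. = FALSE)
    }
    y_raw <- with_seed(derive_seed(config$seed, 5L, i),
                       rnbinom(d, size = params$omega, mu = mu))
    tibble::tibble(
      participant_id = pid, study_id = cohort$study_id[i],
      sensor = config$schedule$sensor,
      day_index = seq_len(d) - 1L, week = week,
      y_missing = as.integer(pmin(y_raw, e_exp)), e_expected = e_exp,
      overrun = FALSE, mu = mu, y_unclipped = y_raw
    )
  })
  rows <- dplyr::bind_rows(rows)
  panel <- rows |>
    dplyr::select(-"mu", -"y_unclipped") |>
    dplyr::left_join(enc_rep, by = c("participant_id", "study_id"))
  list(
    panel = panel,
    truth = list(
      params = params, delta = delta, gamma = gamma,
      mu = rows$mu, y_unclipped = rows$y_unclipped,
      clip_rate = if (nrow(rows)) mean(rows$y_unclipped > e_exp) else NA_real_
    )
  )
}

race_dummies <- function(race) {
  lv <- race_levels()[-1]
  if (is.na(race)) return(setNames(rep(NA_integer_, length(lv)), lv))
  setNames(as.integer(lv == as.character(race)), lv)
}

#' Simulate raw duty-cycled event streams from a panel
#'
#' Inverts the panel: for each participant-day, `y_missing` of the `E`
#' scheduled on-cycles are dropped uniformly at random and events are
#' emitted inside every retained on-cycle at `hz` events per second.
#' Segmenting the resulting streams and rebuilding the panel reproduces
#' `y_missing` exactly on every day inside each participant's observed
#' span (leading or trailing fully-missing days leave no trace in a
#' stream; see [trim_unobservable_days()]).
#'
#' @param panel A participant-day panel (e.g. from [simulate_panel()]).
#' @param config A [sim_config()]; supplies the schedule, `hz`,
#'   `start_day` and `seed`.
#' @return A list: `events` (tibble for [segment_events()]) and
#'   `dropped` (tibble of dropped cycle indices per participant-day).
#' @export
simulate_streams <- function(panel, config) {
  stopifnot(inherits(config, "sim_config"))
  schedule <- config$schedule
  e_exp <- expected_groupings_per_day(schedule)
  stopifnot(all(panel$y_missing <= e_exp))
  cyc_ms <- schedule$cycle_length_s * 1000
  within_ms <- seq(0, schedule$on_cycle_s * 1000 - 1, by = 1000 / config$hz)

  pids <- unique(panel$participant_id)
  per_pid <- purrr::map(seq_along(pids), function(i) {
    rows <- panel[panel$participant_id == pids[i], ]
    with_seed(derive_seed(config$seed, 6L, i), {
      out <- purrr::map(seq_len(nrow(rows)), function(r) {
        y <- rows$y_missing[r]
        drop_idx <- sort(sample.int(e_exp, y))
        keep <- setdiff(seq_len(e_exp), drop_idx)
        day_start <- (config$start_day + rows$day_index[r]) * 86400000
        ts <- as.numeric(outer(within_ms, day_start + (keep - 1) * cyc_ms,
                               `+`))
        list(ts = sort(ts), dropped = drop_idx)
      })
      list(
        events = tibble::tibble(
          participant_id = pids[i], study_id = rows$study_id[1],
          sensor = rows$sensor[1],
          timestamp_ms = unlist(purrr::map(out, "ts"))
        ),
        dropped = tibble::tibble(
          participant_id = pids[i],
          day_index = rep(rows$day_index,
                          vapply(out, function(o) length(o$dropped), 1L)),
          cycle = unlist(purrr::map(out, "dropped"))
        )
      )
    })
  })
  list(events = dplyr::bind_rows(purrr::map(per_pid, "events")),
       dropped = dplyr::bind_rows(purrr::map(per_pid, "dropped")))
}

#' Trim simulated truth to what an event stream can reveal
#'
#' A panel rebuilt from raw streams necessarily starts at each
#' participant's first observed grouping and ends at their last: days of
#' total non-collection at the very start or end of follow-up leave no
#' events and are indistinguishable from non-enrollment. This helper
#' drops those boundary days from a simulated truth panel and re-bases
#' `day_index`/`week`, so the result is directly comparable to
#' `build_daily_panel(segment_events(...))` output.
#'
#' @param panel A simulated participant-day panel.
#' @return The panel restricted to each participant's observable span.
#'   Participants missing every grouping on every day are dropped.
#' @export
trim_unobservable_days <- function(panel) {
  panel |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::filter(any(.data$y_missing < .data$e_expected)) |>
    dplyr::filter(
      .data$day_index >= min(.data$day_index[.data$y_missing <
                                               .data$e_expected]),
      .data$day_index <= max(.data$day_index[.data$y_missing <
                                               .data$e_expected])
    ) |>
    dplyr::mutate(day_index = .data$day_index - min(.data$day_index),
                  week = .data$day_index / 7) |>
    dplyr::ungroup()
}

#' Simulate a full study: cohort, panel and raw streams
#'
#' Convenience wrapper chaining [generate_cohort()], [simulate_panel()]
#' and (optionally) [simulate_streams()].
#'
#' @param config A [sim_config()].
#' @param params A [true_params()]; default the published GPS estimates.
#' @param streams Also simulate raw event streams? Default `FALSE`
#'   (streams are large).
#' @return A list with `cohort`, `panel`, `truth` and, if requested,
#'   `events` and `dropped`.
#' @export
simulate_study <- function(config, params = default_true_params("gps"),
                           streams = FALSE) {
  cohort <- generate_cohort(config)
  sim <- simulate_panel(cohort, params, config)
  out <- list(cohort = cohort, panel = sim$panel, truth = sim$truth)
  if (streams) {
    st <- simulate_streams(sim$panel, config)
    out$events <- st$events
    out$dropped <- st$dropped
  }
  out
}
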