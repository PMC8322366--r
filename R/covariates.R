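os_levels <- function() c("android", "ios")
gender_levels <- function() c("female", "male")
education_levels <- function() c("high_school", "associates", "bachelors", "graduate")

#' Race/ethnicity levels
#'
#' Canonical race/ethnicity categories used throughout the package. The
#' reference level for modelling is `non_hispanic_white`.
#' @return Character vector of levels.
#' @export
race_levels <- function() {
  c("non_hispanic_white", "non_hispanic_black", "asian",
    "american_indian", "other_hispanic")
}

check_covariates <- function(covariates) {
  need <- c("participant_id", "study_id", "os", "gender", "education",
            "race_ethnicity", "age_years")
  miss <- setdiff(need, names(covariates))
  if (length(miss) > 0) {
    stop("covariate table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(covariates$participant_id)) {
    stop("participant ids in the covariate table must be unique",
         call. = FALSE)
  }
  check_levels <- function(x, levels, what) {
    bad <- setdiff(unique(x[!is.na(x)]), levels)
    if (length(bad) > 0) {
      stop(sprintf("unknown %s level(s): %s", what,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  check_levels(covariates$os, os_levels(), "os")
  check_levels(covariates$gender, gender_levels(), "gender")
  check_levels(covariates$education, education_levels(), "education")
  check_levels(covariates$race_ethnicity, race_levels(), "race/ethnicity")
  tibble::as_tibble(covariates)
}

#' Encode a covariate table for modelling
#'
#' Maps the raw per-participant covariate table to the coding used by the
#' non-collection model: indicator contrasts with reference levels
#' Android (OS), female (gender), less-than-4-year degree (education) and
#' non-Hispanic White (race/ethnicity); age in decades. Missing values
#' propagate as `NA` and are handled downstream by
#' [complete_case_filter()].
#'
#' @param covariates A covariate table (see [build_daily_panel()]).
#' @return A tibble with columns `participant_id`, `study_id`, `os_ios`,
#'   `male`, `degree_4yr_plus`, `race` (factor) and `age_decades`.
#' @export
encode_covariates <- function(covariates) {
  covariates <- check_covariates(covariates)
  tibble::tibble(
    participant_id = covariates$participant_id,
    study_id = covariates$study_id,
    os_ios = ifelse(is.na(covariates$os), NA_integer_,
                    as.integer(covariates$os == "ios")),
    male = ifelse(is.na(covariates$gender), NA_integer_,
                  as.integer(covariates$gender == "male")),
    degree_4yr_plus = ifelse(is.na(covariates$education), NA_integer_,
                             as.integer(covariates$education %in%
                                          c("bachelors", "graduate"))),
    race = factor(covariates$race_ethnicity, levels = race_levels()),
    age_decades = covariates$age_years / 10
  )
}

#' Summarize covariate marginals
#'
#' Tabulates the categorical covariates of a cohort the way demographic
#' tables in study reports do: counts and percentages of the full sample
#' per level, with missing values tallied as their own level.
#'
#' @param covariates A covariate table (see [build_daily_panel()]).
#' @param by_study Tabulate per study instead of overall? Default `FALSE`.
#' @return A tibble with columns `variable`, `level`, `n`, `pct` (percent
#'   of all participants, 0-100) and, if `by_study`, `study_id`.
#' @examples
#' demo <- read_demographic_counts(
#'   system.file("extdata", "study_demographics.csv", package = "dutymiss")
#' )
#' cohort <- cohort_from_counts(demo)
#' summarize_covariates(cohort)
#' @export
summarize_covariates <- function(covariates, by_study = FALSE) {
  covariates <- check_covariates(covariates)
  vars <- c(os = "os", gender = "gender", education = "education",
            race_ethnicity = "race_ethnicity")
  groups <- if (by_study) "study_id" else character()
  denom <- if (by_study) {
    dplyr::count(covariates, .data$study_id, name = ".n_total")
  } else {
    tibble::tibble(.n_total = nrow(covariates))
  }
  purrr::map_dfr(vars, function(v) {
    covariates |>
      dplyr::mutate(level = dplyr::coalesce(as.character(.data[[v]]),
                                            "missing")) |>
      dplyr::count(dplyr::across(dplyr::all_of(c(groups, "level")))) |>
      dplyr::mutate(variable = v, .before = 1)
  }) |>
    (\(d) if (by_study) dplyr::left_join(d, denom, by = "study_id")
     else dplyr::mutate(d, .n_total = denom$.n_total))() |>
    dplyr::mutate(pct = 100 * .data$n / .data$.n_total) |>
    dplyr::select(-".n_total")
}

#' Read a per-study demographic count table
#'
#' Reads a long-format table of printed demographic counts (columns
#' `study_id`, `variable`, `level`, `n`), as published in study
#' demographic tables. Used together with [cohort_from_counts()] to
#' reconstruct a covariate table whose marginals match the printed
#' counts.
#'
#' @param path Path to the CSV file.
#' @return A tibble of counts.
#' @export
read_demographic_counts <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    study_id = readr::col_character(),
    variable = readr::col_character(),
    level = readr::col_character(),
    n = readr::col_double()
  ))
}

#' Expand demographic counts into a covariate table
#'
#' Builds one row per participant from per-study counts of each
#' categorical covariate, assigning levels within each study so that the
#' per-study (and hence overall) marginals match the counts exactly.
#' Covariates are assigned independently of one another, so joint
#' distributions are not reconstructed — only marginals are meaningful.
#' Ages are filled with each study's printed mean (the counts table
#' carries no individual ages).
#'
#' @param counts Count table from [read_demographic_counts()]; the level
#'   `missing` becomes `NA`. Rows with `variable = "age_mean"` supply the
#'   per-study mean age.
#' @return A covariate table (see [build_daily_panel()]).
#' @export
cohort_from_counts <- function(counts) {
  cat_counts <- dplyr::filter(counts, .data$variable != "age_mean")
  sizes <- cat_counts |>
    dplyr::filter(.data$variable == "os") |>
    dplyr::group_by(.data$study_id) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  ages <- counts |>
    dplyr::filter(.data$variable == "age_mean") |>
    dplyr::select("study_id", age_mean = "n")

  fill_var <- function(study, v, n_study) {
    rows <- dplyr::filter(cat_counts, .data$study_id == study,
                          .data$variable == v)
    if (sum(rows$n) != n_study) {
      stop(sprintf("counts for %s in study %s sum to %d, expected %d",
                   v, study, sum(rows$n), n_study), call. = FALSE)
    }
    lv <- rep(rows$level, rows$n)
    lv[lv == "missing"] <- NA
    lv
  }

  purrr::map_dfr(seq_len(nrow(sizes)), function(i) {
    study <- sizes$study_id[i]
    n_study <- sizes$n[i]
    tibble::tibble(
      participant_id = sprintf("%s_%03d", study, seq_len(n_study)),
      study_id = study,
      os = fill_var(study, "os", n_study),
      gender = fill_var(study, "gender", n_study),
      education = fill_var(study, "education", n_study),
      race_ethnicity = fill_var(study, "race_ethnicity", n_study),
      age_years = ages$age_mean[match(study, ages$study_id)]
    )
  })
}
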