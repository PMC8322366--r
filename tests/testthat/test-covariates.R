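demo_counts <- read_demographic_counts(
  system.file("extdata", "study_demographics.csv", package = "dutymiss"))

test_that("the demographic-count fixture expands to a consistent cohort", {
  cohort <- cohort_from_counts(demo_counts)
  expect_identical(nrow(cohort), 211L)
  expect_identical(length(unique(cohort$participant_id)), 211L)
  expect_identical(sort(unique(cohort$study_id)), LETTERS[1:6])
  # per-study sizes
  expect_equal(unname(table(cohort$study_id)[LETTERS[1:6]]),
               c(16, 11, 12, 59, 39, 74), ignore_attr = TRUE)
})

test_that("covariate summarizer reproduces cohort marginals", {
  cohort <- cohort_from_counts(demo_counts)
  sm <- summarize_covariates(cohort)
  get <- function(v, l) sm$n[sm$variable == v & sm$level == l]
  pct <- function(v, l) sm$pct[sm$variable == v & sm$level == l]
  expect_identical(get("gender", "female"), 140L)
  expect_equal(pct("gender", "female"), 100 * 140 / 211)
  expect_identical(get("os", "android"), 163L)
  expect_equal(pct("os", "android"), 100 * 163 / 211)
  expect_identical(get("race_ethnicity", "non_hispanic_white"), 117L)
  expect_identical(get("education", "missing"), 7L)
  # by-study tabulation keeps per-study denominators
  by_study <- summarize_covariates(cohort, by_study = TRUE)
  d_female <- by_study[by_study$study_id == "D" &
                         by_study$variable == "gender" &
                         by_study$level == "female", ]
  expect_identical(d_female$n, 57L)
  expect_equal(d_female$pct, 100 * 57 / 59)
})

test_that("encoding uses the model reference levels", {
  cov <- tibble::tibble(
    participant_id = c("a", "b", "c"), study_id = "s",
    os = c("android", "ios", NA),
    gender = c("female", "male", NA),
    education = c("high_school", "graduate", "associates"),
    race_ethnicity = c("non_hispanic_white", "asian", NA),
    age_years = c(20, 35, NA)
  )
  enc <- encode_covariates(cov)
  expect_identical(enc$os_ios, c(0L, 1L, NA))
  expect_identical(enc$male, c(0L, 1L, NA))
  expect_identical(enc$degree_4yr_plus, c(0L, 1L, 0L))
  expect_identical(levels(enc$race), race_levels())
  expect_identical(as.character(enc$race), c("non_hispanic_white", "asian", NA))
  expect_equal(enc$age_decades, c(2, 3.5, NA))
})

test_that("invalid covariate tables are rejected", {
  bad <- tibble::tibble(participant_id = c("a", "a"), study_id = "s",
                        os = "android", gender = "female",
                        education = "high_school",
                        race_ethnicity = "asian", age_years = 20)
  expect_error(encode_covariates(bad), "unique")
  bad2 <- dplyr::mutate(bad[1, ], os = "windows_phone")
  expect_error(encode_covariates(bad2), "os level")
})
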