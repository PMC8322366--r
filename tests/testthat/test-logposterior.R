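make_small_panel <- function(seed, n_pid = 4, days = 6) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_pid), function(i) {
    toy_panel(rpois(days, 20), e = 144, pid = paste0("p", i),
              sid = paste0("s", 1 + i %% 2),
              os_ios = rbinom(1, 1, 0.3), male = rbinom(1, 1, 0.4),
              age_dec = runif(1, 1.8, 4))
  })
}

spec_small <- model_spec(terms = c("week", "os_ios"))

# prior log-density, written out independently of the implementation
prior_lp <- function(theta, md) {
  nm <- names(theta)
  o <- md$opts
  lp <- dt((theta[["alpha0"]] - o$intercept_loc) / o$intercept_scale,
           o$intercept_df, log = TRUE) - log(o$intercept_scale)
  # participant effects are centered (prior N(0, sigma_gamma));
  # study effects are non-centered raw N(0, 1) deviates
  gam <- theta[grepl("^gamma\\[", nm)]
  if (length(gam)) {
    lp <- lp + sum(dnorm(gam, 0, exp(theta[["log_sigma_gamma"]]),
                         log = TRUE))
  }
  lp <- lp + sum(dnorm(theta[grepl("^delta\\[", nm)], log = TRUE))
  for (s in c("log_sigma_gamma", "log_sigma_delta")) {
    if (s %in% nm) {
      sig <- exp(theta[[s]])
      lp <- lp + log(2) + dt(sig / o$sigma_scale, o$sigma_df, log = TRUE) -
        log(o$sigma_scale) + theta[[s]]
    }
  }
  if ("log_omega" %in% nm) {
    om <- exp(theta[["log_omega"]])
    lp <- lp + o$omega_shape * log(o$omega_rate) - lgamma(o$omega_shape) +
      (o$omega_shape - 1) * log(om) - o$omega_rate * om + theta[["log_omega"]]
  }
  unname(lp)
}

random_theta <- function(md, seed) {
  set.seed(seed)
  nm <- dutymiss:::param_names(md)
  setNames(rnorm(length(nm), 0, 0.4), nm)
}

test_that("log-posterior decomposes into NB terms plus priors", {
  for (seed in 1:5) {
    panel <- make_small_panel(seed)
    md <- dutymiss:::make_model_data(panel, spec_small)
    theta <- random_theta(md, seed + 100)
    # assemble mu by hand: centered participant effects, non-centered
    # (sigma * raw) study effects
    sdl <- exp(theta[["log_sigma_delta"]])
    om <- exp(theta[["log_omega"]])
    gam <- theta[paste0("gamma[", md$participants, "]")]
    draw <- theta[paste0("delta[", md$studies, "]")]
    eta <- md$logE + theta[["alpha0"]] +
      as.numeric(md$X %*% theta[colnames(md$X)]) +
      gam[md$gidx + 1] + sdl * draw[md$jidx + 1]
    expected_ll <- sum(nb_log_pmf(md$y, exp(eta), om))
    lp <- log_posterior(panel, theta, spec_small)
    expect_equal(lp - prior_lp(theta, md), expected_ll, tolerance = 1e-10)
    # compiled and pure-R paths agree
    expect_equal(lp, dutymiss:::log_posterior_r(panel, theta, spec_small),
                 tolerance = 1e-10)
  }
})

test_that("with no effects, every mean reduces to E * exp(alpha0)", {
  panel <- make_small_panel(11)
  md <- dutymiss:::make_model_data(panel, spec_small)
  theta <- random_theta(md, 1) * 0
  theta[["alpha0"]] <- log(0.2)
  # all raw effects and betas zero, omega = 1
  lp <- log_posterior(panel, theta, spec_small)
  expected_ll <- sum(nb_log_pmf(md$y, exp(md$logE) * 0.2, 1))
  expect_equal(lp - prior_lp(theta, md), expected_ll, tolerance = 1e-10)
})

test_that("three-row toy panel matches term-by-term arithmetic", {
  panel <- toy_panel(c(5, 0, 17), e = 10, pid = "p1")
  panel2 <- toy_panel(3, e = 10, pid = "p2")
  panel2$y_missing <- 3L
  panel <- dplyr::bind_rows(panel, panel2)
  panel$y_missing <- pmin(panel$y_missing, panel$e_expected)
  spec <- model_spec(terms = "week")
  md <- dutymiss:::make_model_data(panel, spec)
  theta <- setNames(c(-1.2, 0.05, 0.3, -0.2, 0.4, log(0.7), log(0.4),
                      log(2)), dutymiss:::param_names(md))
  mu <- c(10 * exp(-1.2 + 0.05 * 0 / 7 + 0.3 + 0.4 * 0.4),
          10 * exp(-1.2 + 0.05 * 1 / 7 + 0.3 + 0.4 * 0.4),
          10 * exp(-1.2 + 0.05 * 2 / 7 + 0.3 + 0.4 * 0.4),
          10 * exp(-1.2 + 0.05 * 0 / 7 + -0.2 + 0.4 * 0.4))
  ll <- sum(nb_log_pmf(c(5, 0, 10, 3), mu, 2))
  expect_equal(log_posterior(panel, theta, spec) - prior_lp(theta, md),
               ll, tolerance = 1e-10)
})

test_that("likelihood is invariant to alpha0/study shifts", {
  panel <- make_small_panel(13)
  md <- dutymiss:::make_model_data(panel, spec_small)
  theta1 <- random_theta(md, 5)
  c_shift <- 0.37
  theta2 <- theta1
  theta2[["alpha0"]] <- theta1[["alpha0"]] + c_shift
  dk <- paste0("delta[", md$studies, "]")
  sdl <- exp(theta1[["log_sigma_delta"]])
  theta2[dk] <- theta1[dk] - c_shift / sdl
  lp_diff <- log_posterior(panel, theta2, spec_small) -
    log_posterior(panel, theta1, spec_small)
  prior_diff <- prior_lp(theta2, md) - prior_lp(theta1, md)
  expect_equal(lp_diff, prior_diff, tolerance = 1e-9)
})

test_that("compiled gradient matches finite differences", {
  panel <- make_small_panel(17)
  md <- dutymiss:::make_model_data(panel, spec_small)
  theta <- random_theta(md, 7)
  res <- dutymiss:::nbglmm_lp_grad(theta, md$y, md$logE, md$X, md$gidx,
                                   md$jidx, md$yuniq, md$ymap, md$opts)
  num <- vapply(seq_along(theta), function(k) {
    h <- 1e-6
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    (dutymiss:::nbglmm_lp_grad(tp, md$y, md$logE, md$X, md$gidx, md$jidx,
                               md$yuniq, md$ymap, md$opts)$lp -
       dutymiss:::nbglmm_lp_grad(tm, md$y, md$logE, md$X, md$gidx, md$jidx,
                                 md$yuniq, md$ymap, md$opts)$lp) / (2 * h)
  }, numeric(1))
  expect_equal(res$grad, num, tolerance = 1e-5)
})

test_that("complete-case filtering drops whole participants by set union", {
  panel <- dplyr::bind_rows(
    toy_panel(c(1, 2), pid = "ok"),
    toy_panel(c(1, 2), pid = "no_gender"),
    toy_panel(c(1, 2), pid = "no_race_educ"),
    toy_panel(c(1, 2), pid = "no_age")
  )
  panel$male[panel$participant_id == "no_gender"] <- NA
  panel$race[panel$participant_id == "no_race_educ"] <- NA
  panel$degree_4yr_plus[panel$participant_id == "no_race_educ"] <- NA
  panel$age_decades[panel$participant_id == "no_age"] <- NA

  cc <- complete_case_filter(panel, model_spec())
  expect_identical(sort(cc$exclusions$participant_id),
                   c("no_age", "no_gender", "no_race_educ"))
  expect_identical(unique(cc$panel$participant_id), "ok")
  # overlapping missingness counted once per participant
  expect_identical(nrow(cc$exclusions), 3L)
  expect_true(grepl("degree_4yr_plus",
                    cc$exclusions$missing_fields[
                      cc$exclusions$participant_id == "no_race_educ"]))

  # a field outside the model never excludes
  cc2 <- complete_case_filter(panel, model_spec(terms = c("week", "os_ios")))
  expect_identical(nrow(cc2$exclusions), 0L)
  expect_identical(nrow(cc2$panel), nrow(panel))

  # nothing missing: identity
  cc3 <- complete_case_filter(panel[panel$participant_id == "ok", ],
                              model_spec())
  expect_identical(nrow(cc3$exclusions), 0L)
})
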