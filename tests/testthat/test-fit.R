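test_that("a null simulation is recovered as null", {
  cfg <- sim_config(n_studies = 2, participants_per_study = 12,
                    days_per_participant = 15, seed = 201)
  tp <- true_params(log(0.3), c(week = 0, os_ios = 0, male = 0),
                    sigma_gamma = 0.3, sigma_delta = 0, omega = 1.5)
  sim <- simulate_study(cfg, tp)
  fit <- fit_noncollection(sim$panel,
                           model_spec(terms = c("week", "os_ios", "male")),
                           mcmc_spec(chains = 4, warmup = 250, iter = 250,
                                     seed = 31), metrics = FALSE)
  td <- tidy(fit)
  betas <- td[td$term != "intercept", ]
  expect_true(all(betas$conf.low <= 1 & 1 <= betas$conf.high))
})

test_that("scaling the offset shifts only the intercept", {
  cfg <- sim_config(n_studies = 2, participants_per_study = 10,
                    days_per_participant = 12, seed = 211)
  tp <- true_params(log(0.3), sigma_gamma = 0.4, sigma_delta = 0,
                    omega = 1.5)
  sim <- simulate_study(cfg, tp)
  spec <- model_spec(terms = "week")
  mc <- mcmc_spec(chains = 4, warmup = 250, iter = 250, seed = 33)
  f1 <- fit_noncollection(sim$panel, spec, mc, metrics = FALSE)
  scaled <- dplyr::mutate(sim$panel, e_expected = e_expected * 4L)
  f2 <- fit_noncollection(scaled, spec, mc, metrics = FALSE)
  a1 <- median(as.vector(f1$draws[, , "alpha0"]))
  a2 <- median(as.vector(f2$draws[, , "alpha0"]))
  sd1 <- sd(as.vector(f1$draws[, , "alpha0"]))
  expect_lt(abs((a2 + log(4)) - a1), 4 * sd1)
})

test_that("the fitted object is coherent", {
  sh <- get_shared_fit()
  fit <- sh$fit
  nm <- dimnames(fit$draws)[[3]]
  # every modeled quantity has draws and diagnostics
  expect_setequal(
    nm,
    c("alpha0", "week", "os_ios",
      paste0("gamma[", fit$data$participants, "]"),
      paste0("delta[", fit$data$studies, "]"),
      "sigma_gamma", "sigma_delta", "omega"))
  expect_identical(sort(fit$diagnostics$parameter), sort(nm))
  expect_true(all(is.finite(fit$draws)))
  # sigmas and omega are on the natural scale
  expect_true(all(fit$draws[, , "sigma_gamma"] > 0))
  expect_true(all(fit$draws[, , "omega"] > 0))

  td <- tidy(fit)
  expect_identical(td$term, c("intercept", "week", "os_ios"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  # rate ratios are summaries of exponentiated draws (medians commute)
  wk <- as.vector(fit$draws[, , "week"])
  expect_equal(td$estimate[td$term == "week"], median(exp(wk)),
               tolerance = 1e-12)
  expect_equal(td$estimate_mean[td$term == "week"], mean(exp(wk)),
               tolerance = 1e-12)

  gl <- glance(fit)
  expect_identical(gl$nobs, nrow(sh$sim$panel))
  expect_identical(gl$n_participants, 24L)
  expect_true(gl$waic >= gl$loo - 4 * gl$loo_se)

  # estimates land near the generating values
  expect_lt(abs(log(td$estimate[1]) - sh$truth$alpha0), 3 * td$std.error[1])
  expect_lt(abs(log(td$estimate[3]) - sh$truth$beta[["os_ios"]]),
            3 * td$std.error[3])
})

test_that("study effects are rescaled from their non-centered draws", {
  fit <- get_shared_fit()$fit
  s1 <- fit$data$studies[1]
  raw <- fit$draws_u[, , paste0("delta[", s1, "]")]
  sdl <- exp(fit$draws_u[, , "log_sigma_delta"])
  expect_equal(as.vector(fit$draws[, , paste0("delta[", s1, "]")]),
               as.vector(raw * sdl), tolerance = 1e-12)
})

test_that("random-effect toggles change the parameter set", {
  panel <- get_shared_fit()$sim$panel
  spec <- model_spec(terms = "week", re_study = FALSE)
  mc <- mcmc_spec(chains = 2, warmup = 150, iter = 100, seed = 41)
  fit <- fit_noncollection(panel, spec, mc, metrics = FALSE)
  nm <- dimnames(fit$draws)[[3]]
  expect_false(any(grepl("^delta\\[", nm)))
  expect_false("sigma_delta" %in% nm)
})
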