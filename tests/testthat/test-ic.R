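test_that("WAIC equals the direct lppd / p_waic formula", {
  set.seed(5)
  ll <- matrix(rnorm(200 * 5, -2, 0.4), 200, 5)
  w <- waic(ll)
  # direct formula, computed longhand
  lppd <- sum(log(colMeans(exp(ll))))
  p <- sum(apply(ll, 2, var))
  expect_equal(w$waic, -2 * (lppd - p), tolerance = 1e-8)
  expect_equal(w$p_waic, p, tolerance = 1e-8)
  pointwise <- log(colMeans(exp(ll))) - apply(ll, 2, var)
  expect_equal(w$se, 2 * sqrt(5 * var(pointwise)), tolerance = 1e-8)
})

test_that("WAIC is additive over duplicated observations", {
  set.seed(6)
  ll <- matrix(rnorm(300 * 8, -3, 0.5), 300, 8)
  w1 <- waic(ll)
  w2 <- waic(cbind(ll, ll))
  expect_equal(w2$waic, 2 * w1$waic, tolerance = 1e-8)
})

test_that("the generalized Pareto fit recovers a known shape", {
  set.seed(7)
  k <- 0.3
  u <- runif(4000)
  x <- 1 / k * ((1 - u)^(-k) - 1)  # GPD(k, sigma = 1) inverse cdf
  f <- dutymiss:::gpd_fit(x)
  expect_lt(abs(f$k - k), 0.05)
  expect_lt(abs(f$sigma - 1), 0.1)
})

test_that("PSIS-LOO matches exact leave-one-out refits on tiny data", {
  panel <- toy_panel(c(3, 12, 7, 0, 25), e = 144)
  panel$participant_id <- c("a", "a", "a", "b", "b")
  spec <- model_spec(terms = character(), re_participant = FALSE,
                     re_study = FALSE)
  mc <- mcmc_spec(chains = 4, warmup = 300, iter = 1500, seed = 17)
  fit <- fit_noncollection(panel, spec, mc, metrics = FALSE)
  ll <- dutymiss:::fit_log_lik(fit)
  loo <- suppressWarnings(loo_psis(ll))

  # brute force: refit without observation i, then average p(y_i | theta)
  # over the leave-one-out posterior
  elpd_exact <- vapply(1:5, function(i) {
    f_i <- fit_noncollection(panel[-i, ], spec, mc, metrics = FALSE)
    alpha <- as.vector(f_i$draws[, , "alpha0"])
    omega <- as.vector(f_i$draws[, , "omega"])
    mu <- panel$e_expected[i] * exp(alpha)
    dutymiss:::logsumexp(nb_log_pmf(panel$y_missing[i], mu, omega)) -
      log(length(alpha))
  }, numeric(1))
  expect_lt(abs(loo$elpd - sum(elpd_exact)), 0.2)
  expect_equal(loo$loo, -2 * loo$elpd, tolerance = 1e-10)
})

test_that("Bayes R2 matches longhand arithmetic on a toy draw set", {
  mu <- rbind(c(1, 2, 3, 4), c(2, 2, 2, 2), c(0.5, 1, 1.5, 6))
  omega <- c(1, 2, 4)
  r2 <- bayes_r2(mu, omega)
  byhand <- vapply(1:3, function(s) {
    m <- mu[s, ]
    vfit <- mean((m - mean(m))^2)
    vres <- mean(m + m^2 / omega[s])
    vfit / (vfit + vres)
  }, numeric(1))
  expect_equal(sort(r2$draws), sort(byhand), tolerance = 1e-12)
  expect_equal(r2$estimate, median(byhand), tolerance = 1e-12)
  # constant fitted values give exactly zero
  expect_equal(bayes_r2(matrix(3, 2, 5), c(1, 1))$draws, c(0, 0))
})
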