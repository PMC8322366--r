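logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Widely applicable information criterion (WAIC)
#'
#' Deviance-scale WAIC, `-2 (lppd - p_waic)`, where `lppd` is the log
#' pointwise predictive density and the effective number of parameters
#' `p_waic` is the summed posterior variance of the per-observation log
#' likelihood. The standard error follows from the pointwise
#' contributions.
#'
#' @param log_lik Posterior log-likelihood matrix, draws x observations,
#'   or a fitted model from [fit_noncollection()].
#' @param ... Unused.
#' @return A list with `waic`, `se`, `elpd`, `p_waic` and the pointwise
#'   `elpd_i`.
#' @export
waic <- function(log_lik, ...) UseMethod("waic")

#' @export
waic.default <- function(log_lik, ...) {
  ll <- as.matrix(log_lik)
  s <- nrow(ll)
  lppd_i <- apply(ll, 2, logsumexp) - log(s)
  p_i <- apply(ll, 2, var)
  elpd_i <- lppd_i - p_i
  n <- ncol(ll)
  list(
    waic = -2 * sum(elpd_i),
    se = 2 * sqrt(n * var(elpd_i)),
    elpd = sum(elpd_i),
    p_waic = sum(p_i),
    elpd_i = elpd_i
  )
}

#' @export
waic.dm_fit <- function(log_lik, ...) waic.default(fit_log_lik(log_lik))

# Zhang & Stephens (2009) posterior-mean fit of the generalized Pareto
# distribution to sample exceedances, with the weak shape prior of the
# PSIS recipe.
gpd_fit <- function(x) {
  x <- sort.int(x)
  n <- length(x)
  prior_bs <- 3
  prior_k <- 10
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[floor(n / 4 + 0.5)]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / prior_bs / xstar
  prof <- vapply(theta, function(b) {
    k <- -mean(log1p(-b * x))
    n * (log(b / k) + k - 1)
  }, numeric(1))
  w <- 1 / vapply(jj, function(j) sum(exp(prof - prof[j])), numeric(1))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  k <- (n * k + prior_k * 0.5) / (n + prior_k)
  list(k = k, sigma = sigma)
}

# Pareto-smooth one vector of (shifted) log importance ratios
psis_smooth <- function(lw) {
  s <- length(lw)
  m <- ceiling(min(0.2 * s, 3 * sqrt(s)))
  lw <- lw - max(lw)
  if (m < 5 || length(unique(lw)) < 5) {
    return(list(lw = lw, k = NA_real_))
  }
  ord <- order(lw)
  tail_ids <- ord[seq(s - m + 1, s)]
  cutoff <- lw[ord[s - m]]
  exceed <- exp(lw[tail_ids]) - exp(cutoff)
  if (all(exceed == 0)) return(list(lw = lw, k = NA_real_))
  fit <- gpd_fit(exceed)
  p <- (seq_len(m) - 0.5) / m
  q <- if (abs(fit$k) < 1e-12) -fit$sigma * log1p(-p) else
    fit$sigma / fit$k * ((1 - p)^(-fit$k) - 1)
  smoothed <- log(exp(cutoff) + q)
  # order statistics replace the sorted tail; cap at the raw maximum (0)
  lw[tail_ids[order(lw[tail_ids])]] <- pmin(smoothed, 0)
  list(lw = lw, k = fit$k)
}

#' PSIS leave-one-out cross-validation (LOO)
#'
#' Deviance-scale approximate leave-one-out cross-validation using
#' Pareto-smoothed importance sampling: per observation, the importance
#' ratios `1/p(y_i | theta_s)` are stabilized by replacing their largest
#' values with order statistics of a fitted generalized Pareto
#' distribution. Observations whose Pareto shape `k` exceeds 0.7 have
#' unreliable contributions and are reported, not fatal.
#'
#' @inheritParams waic
#' @return A list with `loo`, `se`, `elpd`, `pareto_k` (per
#'   observation) and pointwise `elpd_i`.
#' @export
loo_psis <- function(log_lik, ...) UseMethod("loo_psis")

#' @export
loo_psis.default <- function(log_lik, ...) {
  ll <- as.matrix(log_lik)
  n <- ncol(ll)
  res <- purrr::map(seq_len(n), function(i) {
    sm <- psis_smooth(-ll[, i])
    elpd <- logsumexp(ll[, i] + sm$lw) - logsumexp(sm$lw)
    list(elpd = elpd, k = sm$k)
  })
  elpd_i <- vapply(res, `[[`, numeric(1), "elpd")
  ks <- vapply(res, `[[`, numeric(1), "k")
  n_bad <- sum(ks > 0.7, na.rm = TRUE)
  if (n_bad > 0) {
    warning(n_bad, " observation(s) with Pareto k > 0.7; their LOO ",
            "contributions are unreliable", call. = FALSE)
  }
  list(
    loo = -2 * sum(elpd_i),
    se = 2 * sqrt(n * var(elpd_i)),
    elpd = sum(elpd_i),
    pareto_k = ks,
    elpd_i = elpd_i
  )
}

#' @export
loo_psis.dm_fit <- function(log_lik, ...) loo_psis.default(fit_log_lik(log_lik))

#' Bayesian R-squared
#'
#' Per posterior draw, the ratio of the variance of the fitted means to
#' the sum of that variance and the mean response-scale residual
#' variance of the negative binomial, `mean(mu + mu^2/omega)`; the
#' posterior of that ratio is summarized by its median and central 95%
#' interval.
#'
#' @param mu Matrix of posterior fitted means, draws x observations, or
#'   a fitted model from [fit_noncollection()].
#' @param omega Vector of posterior draws of the NB shape (recycled if
#'   scalar). Ignored when `mu` is a fitted model.
#' @param ... Unused.
#' @return A list with `estimate` (posterior median), `ci` (2.5% and
#'   97.5% quantiles) and the per-draw values `draws`.
#' @export
bayes_r2 <- function(mu, ...) UseMethod("bayes_r2")

#' @export
bayes_r2.default <- function(mu, omega, ...) {
  mu <- as.matrix(mu)
  omega <- rep_len(omega, nrow(mu))
  r2 <- vapply(seq_len(nrow(mu)), function(s) {
    m <- mu[s, ]
    vfit <- var(m) * (length(m) - 1) / length(m)
    vres <- mean(m + m^2 / omega[s])
    if (vfit == 0) 0 else vfit / (vfit + vres)
  }, numeric(1))
  list(
    estimate = median(r2),
    ci = quantile(r2, c(0.025, 0.975), names = FALSE),
    draws = r2
  )
}
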