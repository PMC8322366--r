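#' Fit the hierarchical negative-binomial non-collection model
#'
#' Fits, by the package's No-U-Turn sampler, the model
#' `y_ij ~ NegBin(mu_ij, omega)` with
#' `log(mu_ij) = log(E_j) + alpha0 + X beta + gamma_ij + delta_j`,
#' where `gamma_ij ~ N(0, sigma_gamma^2)` are participant intercepts
#' (sampled centered) and `delta_j ~ N(0, sigma_delta^2)` study
#' intercepts (sampled non-centered). Rows failing the complete-case
#' filter are removed first.
#' Non-convergence never raises: the result carries a `converged` flag
#' and the per-parameter diagnostics behind it.
#'
#' @param panel A participant-day panel ([build_daily_panel()] /
#'   [simulate_panel()]).
#' @param spec A [model_spec()].
#' @param mcmc An [mcmc_spec()].
#' @param metrics Compute WAIC, PSIS-LOO and Bayes R-squared? Default
#'   `TRUE`.
#' @return A `dm_fit` object; see [tidy.dm_fit()], [glance.dm_fit()],
#'   [build_fixed_effects_report()], [build_random_effects_report()].
#' @export
fit_noncollection <- function(panel, spec = model_spec(),
                              mcmc = mcmc_spec(), metrics = TRUE) {
  cc <- complete_case_filter(panel, spec)
  panel <- cc$panel
  if (length(unique(panel$participant_id)) < 2) {
    stop("need at least 2 participants to fit", call. = FALSE)
  }
  md <- make_model_data(panel, spec)
  nm_u <- param_names(md)
  d <- length(nm_u)

  lp_grad <- function(theta) {
    nbglmm_lp_grad(theta, md$y, md$logE, md$X, md$gidx, md$jidx,
                   md$yuniq, md$ymap, md$opts)
  }

  init_fun <- function(attempt_seed) {
    with_seed(attempt_seed, {
      th <- numeric(d)
      names(th) <- nm_u
      th[1] <- log(max(mean(md$y / exp(md$logE)), 1e-4)) + rnorm(1, 0, 0.1)
      p <- ncol(md$X)
      if (p > 0) th[1 + seq_len(p)] <- rnorm(p, 0, 0.1)
      re <- grepl("^(gamma|delta)\\[", nm_u)
      th[re] <- rnorm(sum(re), 0, 0.1)
      th[nm_u %in% c("log_sigma_gamma", "log_sigma_delta")] <-
        log(0.5) + rnorm(sum(nm_u %in% c("log_sigma_gamma",
                                         "log_sigma_delta")), 0, 0.1)
      if ("log_omega" %in% nm_u) th[nm_u == "log_omega"] <- rnorm(1, 0, 0.1)
      th
    })
  }

  chains <- purrr::map(seq_len(mcmc$chains), function(ch) {
    res <- NULL
    for (attempt in seq_len(mcmc$init_attempts)) {
      init <- init_fun(derive_seed(mcmc$seed, 7L, ch, attempt))
      st <- lp_grad(init)
      if (!is.finite(st$lp) || any(!is.finite(st$grad))) next
      res <- nuts_chain(lp_grad, init, mcmc$warmup, mcmc$iter,
                        seed = derive_seed(mcmc$seed, 8L, ch),
                        adapt_delta = mcmc$adapt_delta,
                        max_treedepth = mcmc$max_treedepth)
      break
    }
    if (is.null(res)) {
      stop("could not find a finite starting point after ",
           mcmc$init_attempts, " attempts", call. = FALSE)
    }
    res
  })

  draws_u <- array(NA_real_, c(mcmc$iter, mcmc$chains, d),
                   dimnames = list(NULL, NULL, nm_u))
  for (ch in seq_len(mcmc$chains)) draws_u[, ch, ] <- chains[[ch]]$draws

  fit <- structure(
    list(draws = transform_draws(draws_u, md), draws_u = draws_u,
         data = md, panel = panel, spec = spec, mcmc = mcmc,
         exclusions = cc$exclusions,
         sampler = tibble::tibble(
           chain = seq_len(mcmc$chains),
           step_size = vapply(chains, `[[`, numeric(1), "step_size"),
           divergences = vapply(chains, `[[`, integer(1), "n_divergent"),
           mean_accept = vapply(chains, function(c) mean(c$accept_stat), 0),
           mean_treedepth = vapply(chains,
                                   function(c) mean(c$treedepth), 0),
           max_treedepth = vapply(chains,
                                  function(c) max(c$treedepth), 0L)
         )),
    class = "dm_fit"
  )
  fit$diagnostics <- diagnose_draws(fit$draws)
  gate <- fit$diagnostics |>
    dplyr::summarise(
      rhat_ok = max(pmax(.data$rhat, .data$rhat_folded)) <= mcmc$rhat_max,
      ess_ok = min(pmin(.data$ess_bulk, .data$ess_tail)) >=
        mcmc$min_ess_per_chain * mcmc$chains
    )
  fit$converged <- isTRUE(gate$rhat_ok) && isTRUE(gate$ess_ok)
  if (metrics) fit$metrics <- fit_metrics(fit)
  fit
}

# unconstrained draws -> reporting scale: centered random effects,
# sigmas and omega on their natural scale
transform_draws <- function(draws_u, md) {
  nm_u <- dimnames(draws_u)[[3]]
  nm <- sub("^log_", "", nm_u)
  out <- draws_u
  for (k in which(nm_u %in% c("log_sigma_gamma", "log_sigma_delta",
                              "log_omega"))) {
    out[, , k] <- exp(draws_u[, , k])
  }
  gk <- grep("^gamma\\[", nm_u)
  if (length(gk) && !isTRUE(md$opts$centered_participant)) {
    sg <- exp(draws_u[, , nm_u == "log_sigma_gamma"])
    for (k in gk) out[, , k] <- out[, , k] * sg
  }
  dk <- grep("^delta\\[", nm_u)
  if (length(dk)) {
    sdl <- exp(draws_u[, , nm_u == "log_sigma_delta"])
    for (k in dk) out[, , k] <- out[, , k] * sdl
  }
  dimnames(out)[[3]] <- nm
  out
}

# draws matrix (all chains stacked) for a parameter
draws_of <- function(fit, parameter) {
  stopifnot(parameter %in% dimnames(fit$draws)[[3]])
  as.vector(fit$draws[, , parameter])
}

# posterior linear predictors eta (draws x obs) for one chain at a time,
# passed to `consume(eta_chunk, omega_chunk)`
walk_eta <- function(fit, consume) {
  md <- fit$data
  nm <- dimnames(fit$draws)[[3]]
  p <- ncol(md$X)
  for (ch in seq_len(dim(fit$draws)[2])) {
    dr <- fit$draws[, ch, , drop = TRUE]
    if (is.null(dim(dr))) dr <- matrix(dr, 1, dimnames = list(NULL, nm))
    eta <- matrix(rep(md$logE, each = nrow(dr)), nrow(dr))
    eta <- eta + dr[, "alpha0"]
    if (p > 0) {
      eta <- eta + dr[, colnames(md$X), drop = FALSE] %*% t(md$X)
    }
    if (md$opts$re_participant) {
      g <- dr[, paste0("gamma[", md$participants, "]"), drop = FALSE]
      eta <- eta + g[, md$gidx + 1, drop = FALSE]
    }
    if (md$opts$re_study) {
      dl <- dr[, paste0("delta[", md$studies, "]"), drop = FALSE]
      eta <- eta + dl[, md$jidx + 1, drop = FALSE]
    }
    omega <- if (md$opts$omega_fixed) {
      rep(md$opts$omega_value, nrow(dr))
    } else {
      dr[, "omega"]
    }
    consume(eta, omega)
  }
  invisible(NULL)
}

# draws x observations log-likelihood matrix
fit_log_lik <- function(fit) {
  out <- NULL
  walk_eta(fit, function(eta, omega) {
    out <<- rbind(out, nbglmm_loglik_matrix(eta, omega, fit$data$y))
  })
  out
}

fit_metrics <- function(fit) {
  ll <- NULL
  r2 <- NULL
  walk_eta(fit, function(eta, omega) {
    ll <<- rbind(ll, nbglmm_loglik_matrix(eta, omega, fit$data$y))
    mu <- exp(eta)
    n <- ncol(mu)
    vfit <- apply(mu, 1, var) * (n - 1) / n
    vres <- rowMeans(mu + mu^2 / omega)
    r2 <<- c(r2, vfit / (vfit + vres))
  })
  omega_draws <- if (fit$data$opts$omega_fixed) {
    rep(fit$data$opts$omega_value, 2)
  } else {
    draws_of(fit, "omega")
  }
  list(
    waic = waic.default(ll),
    loo = loo_psis.default(ll),
    bayes_r2 = list(estimate = median(r2),
                    ci = quantile(r2, c(0.025, 0.975), names = FALSE),
                    draws = r2),
    omega = list(estimate = median(omega_draws),
                 ci = quantile(omega_draws, c(0.025, 0.975), names = FALSE))
  )
}

#' @export
print.dm_fit <- function(x, ...) {
  cat(sprintf(
    "<dm_fit> hierarchical NB non-collection model: %d obs, %d participants, %d studies\n",
    length(x$data$y), x$data$opts$n_participants, x$data$opts$n_studies))
  cat(sprintf("  chains: %d, warmup %d + %d draws; converged: %s\n",
              x$mcmc$chains, x$mcmc$warmup, x$mcmc$iter,
              if (x$converged) "yes" else "NO"))
  worst <- x$diagnostics[which.max(pmax(x$diagnostics$rhat,
                                        x$diagnostics$rhat_folded)), ]
  cat(sprintf("  worst R-hat %.3f (%s); min bulk ESS %.0f, min tail ESS %.0f\n",
              max(worst$rhat, worst$rhat_folded), worst$parameter,
              min(x$diagnostics$ess_bulk), min(x$diagnostics$ess_tail)))
  print(tidy(x))
  invisible(x)
}

#' Tidy the fixed effects of a fitted non-collection model
#'
#' One row per fixed-effect term (including the intercept) on the
#' exponentiated rate-ratio scale: posterior medians and central 95%
#' credible intervals of `exp(beta)` (exponentiation applied per draw,
#' then summarized), the posterior SD of `beta` on the log scale, and
#' the posterior mean of `exp(beta)` as the alternative point summary.
#'
#' @param x A `dm_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `conf.low`,
#'   `conf.high`, `std.error` (log scale), `estimate_mean`.
#' @export
tidy.dm_fit <- function(x, ...) {
  terms <- c("alpha0", colnames(x$data$X))
  purrr::map_dfr(terms, function(tm) {
    dr <- draws_of(x, tm)
    er <- exp(dr)
    tibble::tibble(
      term = if (tm == "alpha0") "intercept" else tm,
      estimate = median(er),
      conf.low = quantile(er, 0.025, names = FALSE),
      conf.high = quantile(er, 0.975, names = FALSE),
      std.error = sd(dr),
      estimate_mean = mean(er)
    )
  })
}

#' One-line model summary
#'
#' @param x A `dm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: observation and group counts, random-effect
#'   SD medians, `omega`, Bayes R-squared, WAIC and LOO (with SEs) when
#'   metrics were computed, and the convergence flag.
#' @export
glance.dm_fit <- function(x, ...) {
  out <- tibble::tibble(
    nobs = length(x$data$y),
    n_participants = x$data$opts$n_participants,
    n_studies = x$data$opts$n_studies,
    sigma_gamma = if (x$spec$re_participant)
      median(draws_of(x, "sigma_gamma")) else NA_real_,
    sigma_delta = if (x$spec$re_study)
      median(draws_of(x, "sigma_delta")) else NA_real_,
    omega = if (!x$data$opts$omega_fixed) median(draws_of(x, "omega"))
      else x$data$opts$omega_value,
    converged = x$converged
  )
  if (!is.null(x$metrics)) {
    out$bayes_r2 <- x$metrics$bayes_r2$estimate
    out$waic <- x$metrics$waic$waic
    out$waic_se <- x$metrics$waic$se
    out$loo <- x$metrics$loo$loo
    out$loo_se <- x$metrics$loo$se
  }
  out
}

#' @export
bayes_r2.dm_fit <- function(mu, ...) {
  fit <- mu
  if (!is.null(fit$metrics)) return(fit$metrics$bayes_r2)
  r2 <- NULL
  walk_eta(fit, function(eta, omega) {
    m <- exp(eta)
    n <- ncol(m)
    vfit <- apply(m, 1, var) * (n - 1) / n
    r2 <<- c(r2, vfit / (vfit + rowMeans(m + m^2 / omega)))
  })
  list(estimate = median(r2), ci = quantile(r2, c(0.025, 0.975),
                                            names = FALSE), draws = r2)
}
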