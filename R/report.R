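#' Fixed-effects report on the rate-ratio scale
#'
#' One row per modeled fixed effect (intercept first), with the
#' posterior median and central 95% credible interval of the
#' exponentiated coefficient, the log-scale posterior SD, the percent
#' change per unit `(exp(beta) - 1) * 100` (per week for the time term),
#' and a significance flag set when the interval excludes 1. Refuses to
#' run on a non-converged fit unless overridden.
#'
#' @param fit A `dm_fit` from [fit_noncollection()].
#' @param override_convergence Emit the report even if the convergence
#'   gate failed? Default `FALSE`.
#' @return A tibble with columns `term`, `estimate`, `conf.low`,
#'   `conf.high`, `std.error`, `pct_change`, `significant`.
#' @export
build_fixed_effects_report <- function(fit, override_convergence = FALSE) {
  check_converged(fit, override_convergence)
  tidy(fit) |>
    dplyr::mutate(
      pct_change = (.data$estimate - 1) * 100,
      significant = .data$conf.low > 1 | .data$conf.high < 1
    ) |>
    dplyr::select("term", "estimate", "conf.low", "conf.high",
                  "std.error", "pct_change", "significant")
}

check_converged <- function(fit, override) {
  if (!fit$converged && !override) {
    stop("fit did not pass the convergence gate (R-hat <= ",
         fit$mcmc$rhat_max, ", ESS >= ", fit$mcmc$min_ess_per_chain,
         "/chain); pass override_convergence = TRUE to report anyway",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Random-effects report
#'
#' Posterior medians and central 95% credible intervals of every
#' participant deviation `gamma_ij` and study deviation `delta_j` (log
#' scale), each level ordered from least to most non-collection, plus
#' posterior summaries of the random-effect SDs.
#'
#' @inheritParams build_fixed_effects_report
#' @return A list of two tibbles: `groups` (`level`, `group`,
#'   `estimate`, `conf.low`, `conf.high`, `excludes_zero`, ordered by
#'   `estimate` within level) and `sd_summary` (`level`, `estimate`,
#'   `conf.low`, `conf.high`).
#' @export
build_random_effects_report <- function(fit, override_convergence = FALSE) {
  check_converged(fit, override_convergence)
  nm <- dimnames(fit$draws)[[3]]
  one_level <- function(prefix, level) {
    keys <- grep(paste0("^", prefix, "\\["), nm, value = TRUE)
    purrr::map_dfr(keys, function(k) {
      dr <- draws_of(fit, k)
      tibble::tibble(
        level = level,
        group = sub(paste0("^", prefix, "\\[(.*)\\]$"), "\\1", k),
        estimate = median(dr),
        conf.low = quantile(dr, 0.025, names = FALSE),
        conf.high = quantile(dr, 0.975, names = FALSE)
      )
    }) |>
      dplyr::mutate(excludes_zero = .data$conf.low > 0 |
                      .data$conf.high < 0) |>
      dplyr::arrange(.data$estimate)
  }
  groups <- dplyr::bind_rows(
    if (fit$spec$re_participant) one_level("gamma", "participant"),
    if (fit$spec$re_study) one_level("delta", "study")
  )
  sd_summary <- purrr::map_dfr(
    c(participant = "sigma_gamma", study = "sigma_delta"),
    function(par) {
      if (!par %in% nm) return(NULL)
      dr <- draws_of(fit, par)
      tibble::tibble(estimate = median(dr),
                     conf.low = quantile(dr, 0.025, names = FALSE),
                     conf.high = quantile(dr, 0.975, names = FALSE))
    }, .id = "level")
  list(groups = groups, sd_summary = sd_summary)
}

#' Forest plot of fixed effects
#'
#' @param object A `dm_fit`.
#' @param ... Unused.
#' @return A ggplot: exponentiated estimates with 95% credible
#'   intervals, reference line at 1.
#' @export
autoplot.dm_fit <- function(object, ...) {
  td <- tidy(object) |>
    dplyr::filter(.data$term != "intercept") |>
    dplyr::mutate(term = factor(.data$term, levels = rev(.data$term)))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "rate ratio (95% CrI)", y = NULL,
                  title = "Sensor non-collection: fixed effects")
}

#' Per-participant missingness bar chart
#'
#' @param panel A participant-day panel.
#' @return A ggplot of per-participant mean proportion missing, ordered.
#' @export
plot_missingness <- function(panel) {
  sm <- participant_missingness_summary(panel) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$rank, y = .data$prop_missing,
                                   fill = .data$prop_missing)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::labs(x = "participant (ordered)", y = "proportion missing",
                  title = "Proportion of expected groupings missing")
}

#' Random-effect interval plot
#'
#' @param fit A `dm_fit`.
#' @param level `"participant"` or `"study"`.
#' @param ... Passed to [build_random_effects_report()].
#' @return A ggplot of ordered group deviations with 95% intervals.
#' @export
plot_random_effects <- function(fit, level = c("participant", "study"),
                                ...) {
  level <- match.arg(level)
  re <- build_random_effects_report(fit, ...)$groups |>
    dplyr::filter(.data$level == !!level) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(re, ggplot2::aes(x = .data$rank, y = .data$estimate,
                                   colour = .data$excludes_zero)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high),
                             size = 0.2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "black"),
                                 guide = "none") +
    ggplot2::labs(x = paste0(level, " (ordered)"),
                  y = "deviation from average log rate")
}

#' Replicate parameter-recovery study
#'
#' Simulates `n_replicates` cohorts from known true parameters, fits
#' each, and tabulates recovery of every fixed effect: posterior
#' medians, credible intervals, standardized errors and coverage of the
#' truth.
#'
#' @param n_replicates Number of simulation/fit replicates.
#' @param config A [sim_config()]; replicate r uses `config$seed + r`.
#' @param params True parameters ([true_params()]).
#' @param spec,mcmc Model and MCMC settings for the refits.
#' @return A tibble with one row per replicate x term: `replicate`,
#'   `term`, `truth` (exp scale), `estimate`, `conf.low`, `conf.high`,
#'   `z` (log-scale error / posterior SD), `covered`, `converged`.
#' @export
run_recovery <- function(n_replicates, config, params,
                         spec = model_spec(terms = names(params$beta)),
                         mcmc = mcmc_spec(chains = 4)) {
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- simulate_study(cfg, params)
    f <- fit_noncollection(sim$panel, spec,
                           modify_mcmc(mcmc, seed = mcmc$seed + r),
                           metrics = FALSE)
    truth_log <- c(alpha0 = params$alpha0, params$beta)
    td <- tidy(f)
    td$term[td$term == "intercept"] <- "alpha0"
    td |>
      dplyr::filter(.data$term %in% names(truth_log)) |>
      dplyr::mutate(
        replicate = r,
        truth = exp(truth_log[.data$term]),
        z = (log(.data$estimate) - truth_log[.data$term]) / .data$std.error,
        covered = .data$conf.low <= .data$truth &
          .data$truth <= .data$conf.high,
        converged = f$converged
      ) |>
      dplyr::select("replicate", "term", "truth", "estimate", "conf.low",
                    "conf.high", "z", "covered", "converged")
  })
}

modify_mcmc <- function(mcmc, ...) {
  dots <- list(...)
  for (nm in names(dots)) mcmc[[nm]] <- dots[[nm]]
  mcmc
}
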