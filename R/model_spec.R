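#' Specify the non-collection model
#'
#' Declares which fixed-effect terms and random-intercept levels enter
#' the hierarchical negative-binomial regression, and its priors. The
#' default reproduces the primary analysis: all sociodemographic terms,
#' participant and study random intercepts, flat priors on slopes, a
#' diffuse Student-t prior on the intercept and half-Student-t priors on
#' the random-effect SDs. Reference levels are Android (OS), female
#' (gender), less-than-4-year degree (education) and non-Hispanic White
#' (race/ethnicity).
#'
#' @param terms Character vector of fixed-effect terms among `"week"`,
#'   `"os_ios"`, `"male"`, `"degree_4yr_plus"`, `"race"`,
#'   `"age_decades"`. `"race"` expands into indicator contrasts against
#'   non-Hispanic White.
#' @param re_participant,re_study Include the participant- / study-level
#'   random intercept? Toggleable for sensitivity refits.
#' @param intercept_prior_loc Location of the Student-t intercept prior.
#'   The default 6.7 is the conventional diffuse centering for this
#'   outcome; `"auto"` recomputes it from the panel as
#'   `median(log(y + 0.5))` at fit time.
#' @param intercept_prior_scale,intercept_prior_df Scale and df of the
#'   intercept prior.
#' @param sigma_prior_scale,sigma_prior_df Scale and df of the half-t
#'   priors on `sigma_gamma`, `sigma_delta`.
#' @param omega_prior_shape,omega_prior_rate Gamma prior on the NB shape
#'   `omega` (the conventional diffuse `Gamma(0.01, 0.01)` by default).
#' @param fix_omega Fix `omega` at a value instead of estimating it
#'   (e.g. `1e8` for a Poisson-limit check). Default `NULL` (estimate).
#' @return A `model_spec` object.
#' @export
model_spec <- function(terms = c("week", "os_ios", "male",
                                 "degree_4yr_plus", "race", "age_decades"),
                       re_participant = TRUE, re_study = TRUE,
                       intercept_prior_loc = 6.7,
                       intercept_prior_scale = 2.5,
                       intercept_prior_df = 3,
                       sigma_prior_scale = 2.5, sigma_prior_df = 3,
                       omega_prior_shape = 0.01, omega_prior_rate = 0.01,
                       fix_omega = NULL) {
  allowed <- c("week", "os_ios", "male", "degree_4yr_plus", "race",
               "age_decades")
  bad <- setdiff(terms, allowed)
  if (length(bad) > 0) {
    stop("unknown model term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(terms = terms, re_participant = re_participant,
         re_study = re_study,
         intercept_prior_loc = intercept_prior_loc,
         intercept_prior_scale = intercept_prior_scale,
         intercept_prior_df = intercept_prior_df,
         sigma_prior_scale = sigma_prior_scale,
         sigma_prior_df = sigma_prior_df,
         omega_prior_shape = omega_prior_shape,
         omega_prior_rate = omega_prior_rate,
         fix_omega = fix_omega),
    class = "model_spec"
  )
}

#' Read a model specification from YAML
#'
#' A YAML file with any subset of the [model_spec()] arguments, e.g.
#' `terms: [week, os_ios]` / `re_study: false` for the
#' no-study-random-effect sensitivity variant.
#'
#' @param path Path to the YAML file.
#' @return A `model_spec` object.
#' @export
read_model_spec <- function(path) {
  args <- yaml::read_yaml(path)
  do.call(model_spec, args)
}

#' MCMC settings
#'
#' @param chains Number of chains (>= 2 so split-R-hat is defined).
#' @param warmup,iter Warmup iterations and post-warmup draws per chain.
#' @param seed Integer seed; chain c uses a sub-seed derived from it.
#' @param adapt_delta Dual-averaging target acceptance statistic.
#' @param max_treedepth Maximum trajectory doublings per iteration.
#' @param rhat_max,min_ess_per_chain Convergence gate: largest allowed
#'   rank-normalized (plain and folded) split-R-hat, and smallest
#'   allowed bulk/tail effective sample size per chain.
#' @param init_attempts Re-initialization attempts if the sampler starts
#'   at a point with non-finite density or gradient.
#' @return An `mcmc_spec` object.
#' @export
mcmc_spec <- function(chains = 8, warmup = 500, iter = 500, seed = 1,
                      adapt_delta = 0.8, max_treedepth = 10,
                      rhat_max = 1.01, min_ess_per_chain = 100,
                      init_attempts = 10) {
  stopifnot(chains >= 2, warmup >= 50, iter >= 10)
  structure(
    list(chains = as.integer(chains), warmup = as.integer(warmup),
         iter = as.integer(iter), seed = as.integer(seed),
         adapt_delta = adapt_delta, max_treedepth = as.integer(max_treedepth),
         rhat_max = rhat_max, min_ess_per_chain = min_ess_per_chain,
         init_attempts = as.integer(init_attempts)),
    class = "mcmc_spec"
  )
}
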