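#' Negative-binomial log-probability (mean / shape parameterization)
#'
#' Log pmf of the negative binomial with mean `mu` and inverse
#' overdispersion `omega`: `Var(y) = mu + mu^2/omega`; `omega -> Inf`
#' recovers the Poisson. Evaluated via log-gamma for numerical
#' stability.
#'
#' @param y Non-negative integer count(s).
#' @param mu Mean(s), `> 0`.
#' @param omega Shape(s), `> 0`.
#' @return Log-probability, vectorized over the longest argument.
#' @examples
#' nb_log_pmf(0, 1, 1) # log(1/2)
#' @export
nb_log_pmf <- function(y, mu, omega) {
  if (any(mu <= 0) || any(omega <= 0)) {
    stop("`mu` and `omega` must be > 0", call. = FALSE)
  }
  if (any(y < 0) || any(y != trunc(y))) {
    stop("`y` must be non-negative integer counts", call. = FALSE)
  }
  lgamma(y + omega) - lgamma(omega) - lgamma(y + 1) +
    omega * (log(omega) - log(omega + mu)) +
    y * (log(mu) - log(omega + mu))
}

#' Drop participants with missing modeled covariates
#'
#' Complete-case filter: every row of any participant missing one or
#' more covariates used by the model is removed before fitting. Missing
#' covariates are participant-level, so exclusion is participant-level.
#'
#' @param panel A participant-day panel with covariate columns.
#' @param spec A [model_spec()]; determines which covariates count.
#' @return A list: `panel` (retained rows) and `exclusions` (tibble with
#'   one row per dropped participant and the fields that were missing).
#' @export
complete_case_filter <- function(panel, spec = model_spec()) {
  cols <- model_covariate_columns(spec)
  cols <- intersect(cols, names(panel))
  if (length(cols) == 0) {
    return(list(panel = panel, exclusions = tibble::tibble(
      participant_id = character(), missing_fields = character())))
  }
  by_pid <- panel |>
    dplyr::distinct(.data$participant_id,
                    dplyr::across(dplyr::all_of(cols)))
  bad <- by_pid |>
    dplyr::filter(!complete.cases(dplyr::pick(dplyr::all_of(cols))))
  exclusions <- purrr::map_dfr(seq_len(nrow(bad)), function(i) {
    fields <- cols[vapply(bad[i, cols], anyNA, TRUE)]
    tibble::tibble(participant_id = bad$participant_id[i],
                   missing_fields = paste(fields, collapse = ","))
  })
  if (nrow(exclusions) == 0) {
    exclusions <- tibble::tibble(participant_id = character(),
                                 missing_fields = character())
  }
  kept <- panel |>
    dplyr::filter(!.data$participant_id %in% exclusions$participant_id)
  if (nrow(kept) == 0) {
    stop("complete-case filter removed every row", call. = FALSE)
  }
  list(panel = kept, exclusions = exclusions)
}

model_covariate_columns <- function(spec) {
  cols <- setdiff(spec$terms, "week")
  cols  # week is derived from day_index and never missing
}

# fixed-effect design matrix; race expands to indicator contrasts
build_design_matrix <- function(panel, spec) {
  cols <- list()
  for (term in spec$terms) {
    if (term == "race") {
      for (lv in race_levels()[-1]) {
        cols[[paste0("race_", lv)]] <- as.numeric(panel$race == lv)
      }
    } else {
      v <- panel[[term]]
      if (is.null(v)) {
        stop(sprintf("panel lacks modeled covariate '%s'", term),
             call. = FALSE)
      }
      cols[[term]] <- as.numeric(v)
    }
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, nrow(panel), 0)
  if (length(cols)) colnames(X) <- names(cols)
  if (anyNA(X)) {
    stop("missing covariate values in modeled rows; run ",
         "complete_case_filter() first", call. = FALSE)
  }
  X
}

# packs a filtered panel into the flat structures the samplers consume
make_model_data <- function(panel, spec) {
  X <- build_design_matrix(panel, spec)
  y <- as.integer(panel$y_missing)
  pid <- factor(panel$participant_id, levels = unique(panel$participant_id))
  sid <- factor(panel$study_id, levels = unique(panel$study_id))
  yuniq <- sort(unique(y))
  loc <- spec$intercept_prior_loc
  if (identical(loc, "auto")) loc <- median(log(y + 0.5))
  list(
    y = y,
    logE = log(as.numeric(panel$e_expected)),
    X = X,
    gidx = as.integer(pid) - 1L,
    jidx = as.integer(sid) - 1L,
    participants = levels(pid),
    studies = levels(sid),
    yuniq = yuniq,
    ymap = match(y, yuniq) - 1L,
    opts = list(
      re_participant = isTRUE(spec$re_participant),
      re_study = isTRUE(spec$re_study),
      # participant effects are strongly data-identified (tens of
      # observations each): sample them centered; study effects stay
      # non-centered (few groups, weakly identified scale)
      centered_participant = TRUE,
      n_participants = nlevels(pid),
      n_studies = nlevels(sid),
      omega_fixed = !is.null(spec$fix_omega),
      omega_value = spec$fix_omega %||% NA_real_,
      intercept_df = spec$intercept_prior_df,
      intercept_loc = loc,
      intercept_scale = spec$intercept_prior_scale,
      sigma_df = spec$sigma_prior_df,
      sigma_scale = spec$sigma_prior_scale,
      omega_shape = spec$omega_prior_shape,
      omega_rate = spec$omega_prior_rate
    )
  )
}

# unconstrained parameter vector layout for a model-data object
param_names <- function(md) {
  nm <- c("alpha0", colnames(md$X))
  if (md$opts$re_participant) {
    nm <- c(nm, paste0("gamma[", md$participants, "]"))
  }
  if (md$opts$re_study) nm <- c(nm, paste0("delta[", md$studies, "]"))
  if (md$opts$re_participant) nm <- c(nm, "log_sigma_gamma")
  if (md$opts$re_study) nm <- c(nm, "log_sigma_delta")
  if (!md$opts$omega_fixed) nm <- c(nm, "log_omega")
  nm
}

#' Joint log-posterior of the non-collection model
#'
#' Evaluates the (unnormalized) joint log-posterior — negative-binomial
#' likelihood plus priors and standard-normal non-centered random
#' effects — at one unconstrained parameter vector. Exposed for testing
#' and exploration; [fit_noncollection()] uses the compiled equivalent.
#'
#' @param panel A complete-case participant-day panel.
#' @param theta Unconstrained parameter vector: `alpha0`, fixed effects
#'   in [model_spec()] term order, raw participant then study effects,
#'   `log_sigma_gamma`, `log_sigma_delta`, `log_omega` (present only for
#'   enabled components).
#' @param spec A [model_spec()].
#' @return A scalar log-density.
#' @export
log_posterior <- function(panel, theta, spec = model_spec()) {
  md <- make_model_data(panel, spec)
  stopifnot(length(theta) == length(param_names(md)))
  res <- nbglmm_lp_grad(as.numeric(theta), md$y, md$logE, md$X, md$gidx,
                        md$jidx, md$yuniq, md$ymap, md$opts)
  res$lp
}

# pure-R mirror of the compiled log-posterior, kept as an independent
# reference for tests
log_posterior_r <- function(panel, theta, spec = model_spec()) {
  md <- make_model_data(panel, spec)
  nm <- param_names(md)
  stopifnot(length(theta) == length(nm))
  theta <- setNames(as.numeric(theta), nm)
  p <- ncol(md$X)
  alpha0 <- theta[[1]]
  beta <- theta[seq_len(p) + 1]
  pos <- 1 + p
  I <- if (md$opts$re_participant) md$opts$n_participants else 0
  J <- if (md$opts$re_study) md$opts$n_studies else 0
  graw <- theta[pos + seq_len(I)]; pos <- pos + I
  draw <- theta[pos + seq_len(J)]; pos <- pos + J
  sg <- if (I) exp(theta[[pos <- pos + 1]]) else 0
  sd_ <- if (J) exp(theta[[pos <- pos + 1]]) else 0
  omega <- if (md$opts$omega_fixed) md$opts$omega_value else
    exp(theta[[pos + 1]])

  cen_g <- isTRUE(md$opts$centered_participant)
  eta <- md$logE + alpha0 + as.numeric(md$X %*% beta)
  if (I) eta <- eta + (if (cen_g) graw[md$gidx + 1] else
    sg * graw[md$gidx + 1])
  if (J) eta <- eta + sd_ * draw[md$jidx + 1]
  ll <- sum(nb_log_pmf(md$y, exp(eta), omega))

  lp <- ll +
    dt((alpha0 - md$opts$intercept_loc) / md$opts$intercept_scale,
       md$opts$intercept_df, log = TRUE) - log(md$opts$intercept_scale) +
    (if (I) sum(dnorm(graw, 0, if (cen_g) sg else 1, log = TRUE)) else 0) +
    sum(dnorm(draw, log = TRUE))
  if (I) {
    lp <- lp + log(2) + dt(sg / md$opts$sigma_scale, md$opts$sigma_df,
                           log = TRUE) - log(md$opts$sigma_scale) + log(sg)
  }
  if (J) {
    lp <- lp + log(2) + dt(sd_ / md$opts$sigma_scale, md$opts$sigma_df,
                           log = TRUE) - log(md$opts$sigma_scale) + log(sd_)
  }
  if (!md$opts$omega_fixed) {
    lp <- lp + md$opts$omega_shape * log(md$opts$omega_rate) -
      lgamma(md$opts$omega_shape) +
      (md$opts$omega_shape - 1) * log(omega) -
      md$opts$omega_rate * omega + log(omega)
  }
  unname(lp)
}
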