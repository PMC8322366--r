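# Convergence diagnostics: rank-normalized split R-hat (plain and
# folded) and bulk/tail effective sample size, following the
# rank-normalization framework of Vehtari, Gelman, Simpson, Carpenter &
# Buerkner (2021).

split_chains <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  lower <- mat[seq_len(half), , drop = FALSE]
  upper <- mat[seq(n - half + 1, n), , drop = FALSE]
  cbind(lower, upper)
}

# rank -> normal-quantile transform over all draws jointly
z_scale <- function(mat) {
  r <- rank(as.vector(mat), ties.method = "average")
  s <- length(r)
  z <- qnorm((r - 3 / 8) / (s - 2 * 3 / 8 + 1))
  matrix(z, nrow(mat), ncol(mat))
}

fold <- function(mat) abs(mat - median(mat))

rhat_basic <- function(mat) {
  m <- ncol(mat)
  n <- nrow(mat)
  if (n < 2 || m < 2) return(NA_real_)
  chain_means <- colMeans(mat)
  chain_vars <- apply(mat, 2, var)
  w <- mean(chain_vars)
  b <- n * var(chain_means)
  if (!is.finite(w) || w == 0) return(Inf)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Rank-normalized split R-hat
#'
#' Potential-scale-reduction diagnostic computed on rank-normalized
#' split chains; `folded = TRUE` applies the transform to absolute
#' deviations from the median, which is sensitive to scale rather than
#' location differences between chains. Values near 1 indicate mixing;
#' a conventional gate is `<= 1.01`. Constant chains make the
#' diagnostic undefined and are reported as `Inf` with a warning.
#'
#' @param mat Draws matrix, iterations x chains.
#' @param folded Compute the folded variant?
#' @return A scalar R-hat.
#' @export
rhat <- function(mat, folded = FALSE) {
  mat <- as.matrix(mat)
  if (folded) mat <- fold(mat)
  if (all(mat == mat[1])) {
    warning("constant draws: R-hat undefined, reporting Inf", call. = FALSE)
    return(Inf)
  }
  rhat_basic(z_scale(split_chains(mat)))
}

# biased (1/n) autocovariance by FFT
autocovariance <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  m <- stats::nextn(2 * n)
  f <- stats::fft(c(xc, rep(0, m - n)))
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / m / n
}

# effective sample size of the mean for split chains, Geyer-truncated
ess_core <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  m <- ncol(mat)
  if (n < 3 || any(!is.finite(mat))) return(NA_real_)
  if (all(mat == mat[1])) return(NA_real_)
  acov <- apply(mat, 2, autocovariance)
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n
  if (m > 1) var_plus <- var_plus + var(colMeans(mat))
  rho <- rep(0, n)
  rho[1] <- 1
  rho[2] <- 1 - (mean_var - mean(acov[2, ])) / var_plus
  t <- 0
  rho_even <- 1
  rho_odd <- rho[2]
  while (t < n - 4 && (rho_even + rho_odd) > 0) {
    t <- t + 2
    rho_even <- 1 - (mean_var - mean(acov[t + 1, ])) / var_plus
    rho_odd <- 1 - (mean_var - mean(acov[t + 2, ])) / var_plus
    if (rho_even + rho_odd >= 0) {
      rho[t + 1] <- rho_even
      rho[t + 2] <- rho_odd
    }
  }
  max_t <- t
  if (rho_even > 0) rho[max_t + 1] <- rho_even
  # Geyer initial monotone sequence
  t <- 0
  while (t <= max_t - 4) {
    t <- t + 2
    if (rho[t + 1] + rho[t + 2] > rho[t - 1] + rho[t]) {
      rho[t + 1] <- (rho[t - 1] + rho[t]) / 2
      rho[t + 2] <- rho[t + 1]
    }
  }
  s <- n * m
  tau <- -1 + 2 * sum(rho[seq_len(max_t)]) + rho[max_t + 1]
  tau <- max(tau, 1 / log10(s))
  min(s / tau, s * log10(s))
}

#' Effective sample size (bulk and tail)
#'
#' Bulk ESS is the effective sample size of the rank-normalized split
#' chains; tail ESS is the smaller of the effective sample sizes of the
#' 5% and 95% quantile indicator functions, measuring sampling
#' efficiency in the distribution tails.
#'
#' @param mat Draws matrix, iterations x chains.
#' @return A scalar ESS.
#' @export
ess_bulk <- function(mat) {
  mat <- as.matrix(mat)
  ess_core(z_scale(split_chains(mat)))
}

#' @rdname ess_bulk
#' @export
ess_tail <- function(mat) {
  mat <- as.matrix(mat)
  ess_q <- function(prob) {
    q <- quantile(as.vector(mat), prob, names = FALSE)
    ess_core(z_scale(split_chains((mat <= q) * 1)))
  }
  min(ess_q(0.05), ess_q(0.95))
}

#' Per-parameter convergence diagnostics
#'
#' Computes rank-normalized split R-hat, its folded variant, and
#' bulk/tail ESS for every parameter of a draws array.
#'
#' @param draws A 3-d array (iterations x chains x parameters) with
#'   parameter names in `dimnames[[3]]`, or a matrix for one parameter.
#' @return A tibble with columns `parameter`, `rhat`, `rhat_folded`,
#'   `ess_bulk`, `ess_tail`.
#' @export
diagnose_draws <- function(draws) {
  if (is.matrix(draws)) {
    draws <- array(draws, c(nrow(draws), ncol(draws), 1),
                   dimnames = list(NULL, NULL, "parameter"))
  }
  params <- dimnames(draws)[[3]] %||% paste0("theta", seq_len(dim(draws)[3]))
  purrr::map_dfr(seq_len(dim(draws)[3]), function(k) {
    mat <- draws[, , k]
    tibble::tibble(
      parameter = params[k],
      rhat = rhat(mat),
      rhat_folded = rhat(mat, folded = TRUE),
      ess_bulk = ess_bulk(mat),
      ess_tail = ess_tail(mat)
    )
  })
}
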