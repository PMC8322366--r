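# No-U-Turn sampler with dual-averaging step-size adaptation and
# windowed diagonal mass-matrix adaptation (Hoffman & Gelman 2014;
# adaptation schedule follows the standard warmup phasing: an initial
# step-size-only phase, expanding covariance windows, then a final
# step-size-only phase).
#
# lp_grad(theta) must return list(lp = scalar, grad = vector).

nuts_chain <- function(lp_grad, init, n_warmup, n_iter, seed,
                       adapt_delta = 0.8, max_treedepth = 10L) {
  set.seed(seed)
  d <- length(init)
  invmass <- rep(1, d)
  theta <- init
  state <- lp_grad(theta)
  if (!is.finite(state$lp)) stop("non-finite log-density at init")

  leapfrog <- function(x, p, grad, eps) {
    p <- p + 0.5 * eps * grad
    x <- x + eps * (invmass * p)
    s <- lp_grad(x)
    p <- p + 0.5 * eps * s$grad
    list(x = x, p = p, lp = s$lp, grad = s$grad)
  }
  hamiltonian <- function(lp, p) lp - 0.5 * sum(invmass * p * p)

  find_eps <- function(x, lp, grad) {
    eps <- 1
    p <- rnorm(d) / sqrt(invmass)
    h0 <- hamiltonian(lp, p)
    st <- leapfrog(x, p, grad, eps)
    h1 <- hamiltonian(st$lp, st$p)
    if (!is.finite(h1)) {
      while (!is.finite(h1)) {
        eps <- eps / 2
        st <- leapfrog(x, p, grad, eps)
        h1 <- hamiltonian(st$lp, st$p)
        if (eps < 1e-10) stop("cannot find a working step size")
      }
    }
    a <- if (h1 - h0 > log(0.5)) 1 else -1
    while (a * (h1 - h0) > -a * log(2)) {
      eps <- eps * 2^a
      st <- leapfrog(x, p, grad, eps)
      h1 <- hamiltonian(st$lp, st$p)
      if (!is.finite(h1)) { eps <- eps / 2; break }
      if (eps > 1e7 || eps < 1e-10) break
    }
    eps
  }

  # one NUTS transition; returns new state + accept-statistic
  transition <- function(theta, state, eps) {
    p0 <- rnorm(d) / sqrt(invmass)
    h0 <- hamiltonian(state$lp, p0)
    log_u <- h0 - rexp(1)
    xm <- xp <- theta
    pm <- pp <- p0
    gm <- gp <- state$grad
    lpm <- lpp <- state$lp
    sample_x <- theta; sample_state <- state
    n_keep <- 1L; depth <- 0L; s <- TRUE
    alpha_sum <- 0; n_alpha <- 0L; divergent <- FALSE

    build <- function(x, p, grad, lp, v, j) {
      if (j == 0L) {
        st <- leapfrog(x, p, grad, v * eps)
        h <- hamiltonian(st$lp, st$p)
        div <- !is.finite(h) || log_u > h + 1000
        n1 <- if (!div && log_u <= h) 1L else 0L
        a <- if (is.finite(h)) min(1, exp(h - h0)) else 0
        list(xm = st$x, pm = st$p, gm = st$grad, lpm = st$lp,
             xp = st$x, pp = st$p, gp = st$grad, lpp = st$lp,
             xs = st$x, ss = st, n = n1, s = !div,
             alpha = a, n_alpha = 1L, div = div)
      } else {
        t1 <- build(x, p, grad, lp, v, j - 1L)
        if (!t1$s) return(t1)
        if (v == -1) {
          t2 <- build(t1$xm, t1$pm, t1$gm, t1$lpm, v, j - 1L)
          t1$xm <- t2$xm; t1$pm <- t2$pm; t1$gm <- t2$gm; t1$lpm <- t2$lpm
        } else {
          t2 <- build(t1$xp, t1$pp, t1$gp, t1$lpp, v, j - 1L)
          t1$xp <- t2$xp; t1$pp <- t2$pp; t1$gp <- t2$gp; t1$lpp <- t2$lpp
        }
        if (t2$n > 0L && runif(1) < t2$n / max(1L, t1$n + t2$n)) {
          t1$xs <- t2$xs; t1$ss <- t2$ss
        }
        dx <- t1$xp - t1$xm
        t1$s <- t2$s &&
          sum(dx * (invmass * t1$pm)) >= 0 &&
          sum(dx * (invmass * t1$pp)) >= 0
        t1$n <- t1$n + t2$n
        t1$alpha <- t1$alpha + t2$alpha
        t1$n_alpha <- t1$n_alpha + t2$n_alpha
        t1$div <- t1$div || t2$div
        t1
      }
    }

    while (s && depth < max_treedepth) {
      v <- if (runif(1) < 0.5) -1 else 1
      tr <- if (v == -1) build(xm, pm, gm, lpm, v, depth)
            else build(xp, pp, gp, lpp, v, depth)
      if (v == -1) {
        xm <- tr$xm; pm <- tr$pm; gm <- tr$gm; lpm <- tr$lpm
      } else {
        xp <- tr$xp; pp <- tr$pp; gp <- tr$gp; lpp <- tr$lpp
      }
      if (tr$s && tr$n > 0L && runif(1) < tr$n / n_keep) {
        sample_x <- tr$xs
        sample_state <- list(lp = tr$ss$lp, grad = tr$ss$grad)
      }
      n_keep <- n_keep + tr$n
      alpha_sum <- alpha_sum + tr$alpha
      n_alpha <- n_alpha + tr$n_alpha
      divergent <- divergent || tr$div
      dx <- xp - xm
      s <- tr$s && sum(dx * (invmass * pm)) >= 0 &&
        sum(dx * (invmass * pp)) >= 0
      depth <- depth + 1L
    }
    list(theta = sample_x, state = sample_state,
         accept_stat = alpha_sum / max(1L, n_alpha),
         depth = depth, divergent = divergent)
  }

  # dual-averaging bookkeeping
  da_init <- function(eps) list(mu = log(10 * eps), log_eps = log(eps),
                                log_eps_bar = 0, h_bar = 0, m = 0L)
  da_update <- function(da, a) {
    da$m <- da$m + 1L
    gamma <- 0.05; t0 <- 10; kappa <- 0.75
    da$h_bar <- (1 - 1 / (da$m + t0)) * da$h_bar +
      (adapt_delta - a) / (da$m + t0)
    da$log_eps <- da$mu - sqrt(da$m) / gamma * da$h_bar
    w <- da$m^(-kappa)
    da$log_eps_bar <- w * da$log_eps + (1 - w) * da$log_eps_bar
    da
  }

  # warmup phasing: step-size only | expanding mass windows | step-size only
  init_buf <- min(75L, max(15L, round(0.15 * n_warmup)))
  term_buf <- min(50L, max(10L, round(0.1 * n_warmup)))
  win_end <- integer()
  w0 <- init_buf; wlen <- 25L
  while (w0 + wlen < n_warmup - term_buf) {
    if (w0 + 3L * wlen >= n_warmup - term_buf) wlen <- n_warmup - term_buf - w0
    win_end <- c(win_end, w0 + wlen)
    w0 <- w0 + wlen
    wlen <- 2L * wlen
  }
  if (length(win_end) == 0) win_end <- n_warmup - term_buf

  eps <- find_eps(theta, state$lp, state$grad)
  da <- da_init(eps)
  win_draws <- NULL
  draws <- matrix(NA_real_, n_iter, d)
  n_div <- 0L; depths <- integer(n_iter); accepts <- numeric(n_iter)

  for (it in seq_len(n_warmup + n_iter)) {
    tr <- transition(theta, state, eps)
    theta <- tr$theta; state <- tr$state
    if (it <= n_warmup) {
      da <- da_update(da, tr$accept_stat)
      eps <- exp(da$log_eps)
      in_window <- it > init_buf && it <= max(win_end)
      if (in_window) win_draws <- rbind(win_draws, theta)
      if (it %in% win_end && !is.null(win_draws) && nrow(win_draws) > 9) {
        nw <- nrow(win_draws)
        v <- apply(win_draws, 2, var)
        invmass <- nw / (nw + 5) * v + 1e-3 * (5 / (nw + 5))
        win_draws <- NULL
        eps <- find_eps(theta, state$lp, state$grad)
        da <- da_init(eps)
      }
      if (it == n_warmup) eps <- exp(da$log_eps_bar)
    } else {
      k <- it - n_warmup
      draws[k, ] <- theta
      depths[k] <- tr$depth
      accepts[k] <- tr$accept_stat
      if (tr$divergent) n_div <- n_div + 1L
    }
  }
  list(draws = draws, step_size = eps, invmass = invmass,
       n_divergent = n_div, treedepth = depths, accept_stat = accepts)
}
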