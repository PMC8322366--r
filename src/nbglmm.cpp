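#include <Rcpp.h>
using namespace Rcpp;

// Joint log-posterior and gradient of the hierarchical negative-binomial
// regression on the unconstrained scale.
//
// theta layout: [alpha0, beta(p), gamma(I)?, delta_raw(J)?,
//                log_sigma_gamma?, log_sigma_delta?, log_omega?]
// (random-effect blocks and log_omega present only when enabled).
//
// Participant intercepts gamma are sampled centered by default
// (eta += gamma[g], prior N(0, sigma_g)); study intercepts are
// non-centered (eta += sigma_d * delta_raw[j], prior N(0, 1)):
// log mu = logE + alpha0 + X beta + gamma[g] + sigma_d * delta_raw[j],
// y ~ NB(mu, omega) with Var = mu + mu^2/omega.
//
// Priors: alpha0 ~ Student-t(df_a, loc_a, scale_a); beta flat;
// sigma_{g,d} ~ half-Student-t(df_s, 0, scale_s) (+ log Jacobian);
// omega ~ Gamma(a_om, b_om) (+ log Jacobian).
//
// lgamma/digamma terms depending on (y + omega) are computed once per
// distinct y value: daily missing counts live in {0, ..., E}, so the
// number of distinct values is tiny relative to n.

// [[Rcpp::export]]
List nbglmm_lp_grad(NumericVector theta, IntegerVector y,
                    NumericVector logE, NumericMatrix X,
                    IntegerVector gidx, IntegerVector jidx,
                    IntegerVector yuniq, IntegerVector ymap,
                    List opts) {
  const int n = y.size();
  const int p = X.ncol();
  const bool re_g = as<bool>(opts["re_participant"]);
  const bool re_j = as<bool>(opts["re_study"]);
  const int I = re_g ? as<int>(opts["n_participants"]) : 0;
  const int J = re_j ? as<int>(opts["n_studies"]) : 0;
  const bool est_om = !as<bool>(opts["omega_fixed"]);
  // participant effects are sampled centered (they are strongly
  // data-identified); study effects non-centered (few, weakly identified)
  const bool cen_g = as<bool>(opts["centered_participant"]);
  const double df_a = as<double>(opts["intercept_df"]);
  const double loc_a = as<double>(opts["intercept_loc"]);
  const double sc_a = as<double>(opts["intercept_scale"]);
  const double df_s = as<double>(opts["sigma_df"]);
  const double sc_s = as<double>(opts["sigma_scale"]);
  const double a_om = as<double>(opts["omega_shape"]);
  const double b_om = as<double>(opts["omega_rate"]);

  int pos = 0;
  const double alpha0 = theta[pos++];
  std::vector<double> beta(p);
  for (int k = 0; k < p; ++k) beta[k] = theta[pos++];
  const int off_g = pos; pos += I;
  const int off_j = pos; pos += J;
  double log_sg = 0, log_sd = 0;
  int pos_sg = -1, pos_sd = -1, pos_om = -1;
  if (re_g) { pos_sg = pos; log_sg = theta[pos++]; }
  if (re_j) { pos_sd = pos; log_sd = theta[pos++]; }
  double omega;
  if (est_om) { pos_om = pos; omega = std::exp(theta[pos++]); }
  else omega = as<double>(opts["omega_value"]);
  const double sg = std::exp(log_sg), sd = std::exp(log_sd);

  NumericVector grad(theta.size());
  double lp = 0.0;

  // per-unique-y pieces of the NB log-pmf and its omega-derivative
  const int nu = yuniq.size();
  std::vector<double> lgam_yom(nu), digam_yom(nu), lgam_y1(nu);
  const double lgam_om = R::lgammafn(omega);
  const double digam_om = est_om ? R::digamma(omega) : 0.0;
  for (int u = 0; u < nu; ++u) {
    lgam_yom[u] = R::lgammafn(yuniq[u] + omega);
    lgam_y1[u] = R::lgammafn(yuniq[u] + 1.0);
    if (est_om) digam_yom[u] = R::digamma(yuniq[u] + omega);
  }
  const double log_om = std::log(omega);

  double g_alpha = 0, g_logsg = 0, g_logsd = 0, g_logom = 0;
  std::vector<double> g_beta(p, 0.0);

  for (int i = 0; i < n; ++i) {
    double eta = logE[i] + alpha0;
    for (int k = 0; k < p; ++k) eta += X(i, k) * beta[k];
    int gi = -1, ji = -1;
    if (re_g) {
      gi = gidx[i];
      eta += cen_g ? theta[off_g + gi] : sg * theta[off_g + gi];
    }
    if (re_j) { ji = jidx[i]; eta += sd * theta[off_j + ji]; }
    const double mu = std::exp(eta);
    if (!std::isfinite(mu)) return List::create(
        _["lp"] = R_NegInf, _["grad"] = grad);
    const double yi = y[i];
    const int u = ymap[i];
    const double om_mu = omega + mu;
    lp += lgam_yom[u] - lgam_om - lgam_y1[u]
        + omega * (log_om - std::log(om_mu))
        + yi * (eta - std::log(om_mu));
    // d loglik / d eta
    const double r = yi - mu * (yi + omega) / om_mu;
    g_alpha += r;
    for (int k = 0; k < p; ++k) g_beta[k] += r * X(i, k);
    if (re_g) {
      if (cen_g) {
        grad[off_g + gi] += r;
      } else {
        grad[off_g + gi] += sg * r;
        g_logsg += r * sg * theta[off_g + gi];
      }
    }
    if (re_j) {
      grad[off_j + ji] += sd * r;
      g_logsd += r * sd * theta[off_j + ji];
    }
    if (est_om) {
      g_logom += omega * (digam_yom[u] - digam_om + log_om + 1.0
                          - std::log(om_mu) - (omega + yi) / om_mu);
    }
  }

  // intercept prior: Student-t
  {
    const double z = (alpha0 - loc_a) / sc_a;
    lp += R::dt(z, df_a, 1) - std::log(sc_a);
    g_alpha += -(df_a + 1.0) * z / (df_a + z * z) / sc_a;
  }
  // random-effect priors: N(0, sigma) on centered effects,
  // standard normal on raw effects
  for (int g = 0; g < I; ++g) {
    const double v = theta[off_g + g];
    if (cen_g) {
      lp += -0.5 * v * v / (sg * sg) - log_sg - 0.5 * std::log(2.0 * M_PI);
      grad[off_g + g] += -v / (sg * sg);
      g_logsg += v * v / (sg * sg) - 1.0;
    } else {
      lp += -0.5 * v * v - 0.5 * std::log(2.0 * M_PI);
      grad[off_g + g] += -v;
    }
  }
  for (int j = 0; j < J; ++j) {
    const double v = theta[off_j + j];
    lp += -0.5 * v * v - 0.5 * std::log(2.0 * M_PI);
    grad[off_j + j] += -v;
  }
  // half-t priors on sigmas, with log-scale Jacobian
  if (re_g) {
    lp += M_LN2 + R::dt(sg / sc_s, df_s, 1) - std::log(sc_s) + log_sg;
    g_logsg += 1.0 - (df_s + 1.0) * sg * sg / (df_s * sc_s * sc_s + sg * sg);
    grad[pos_sg] = g_logsg;
  }
  if (re_j) {
    lp += M_LN2 + R::dt(sd / sc_s, df_s, 1) - std::log(sc_s) + log_sd;
    g_logsd += 1.0 - (df_s + 1.0) * sd * sd / (df_s * sc_s * sc_s + sd * sd);
    grad[pos_sd] = g_logsd;
  }
  // Gamma prior on omega, with log-scale Jacobian
  if (est_om) {
    lp += a_om * std::log(b_om) - R::lgammafn(a_om)
        + (a_om - 1.0) * log_om - b_om * omega + log_om;
    g_logom += a_om - b_om * omega;
    grad[pos_om] = g_logom;
  }

  grad[0] = g_alpha;
  for (int k = 0; k < p; ++k) grad[1 + k] = g_beta[k];

  return List::create(_["lp"] = lp, _["grad"] = grad);
}

// Per-observation NB log-likelihood for a matrix of posterior draws,
// used by WAIC / PSIS-LOO / Bayes R2. Returns S x n matrix.
// [[Rcpp::export]]
NumericMatrix nbglmm_loglik_matrix(NumericMatrix eta, NumericVector omega,
                                   IntegerVector y) {
  const int S = eta.nrow(), n = eta.ncol();
  NumericMatrix out(S, n);
  for (int s = 0; s < S; ++s) {
    const double om = omega[s];
    const double lgam_om = R::lgammafn(om), log_om = std::log(om);
    for (int i = 0; i < n; ++i) {
      const double mu = std::exp(eta(s, i));
      const double om_mu = om + mu;
      out(s, i) = R::lgammafn(y[i] + om) - lgam_om - R::lgammafn(y[i] + 1.0)
                + om * (log_om - std::log(om_mu))
                + y[i] * (eta(s, i) - std::log(om_mu));
    }
  }
  return out;
}
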