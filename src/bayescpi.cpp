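#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Single-chain BayesC-pi Gibbs sampler for the entry-mean model
//   y_i = mu + sum_j z_ij u_j delta_j + e_i
// with delta_j = 0 w.p. pi, u_j ~ N(0, sigma_u2) shared across included
// markers, pi ~ Uniform(0,1), and sigma_u2 ~ scaled-inv-chi2(nu_u, S_u2).
// The scale S_u2 = (nu_u - 2) sigma_tilde_u2 / nu_u is re-evaluated each sweep
// from the current pi: sigma_tilde_u2 = var(y) / (m * (1 - pi) * mean marker
// variance), with (1 - pi) floored at 1/m. The residual variance gets a flat
// scaled-inv-chi2(-2, 0) prior, i.e. sigma_e2 | e ~ e'e / chisq(n - 2).
//
// Update order per sweep: mu, then loci in index order (delta_j, u_j jointly),
// then sigma_u2, sigma_e2, pi. Flags allow fixing delta = 1, pi, or the two
// variances, which turns the sampler into a ridge-posterior sampler used for
// cross-checking against RR-BLUP.
// [[Rcpp::export]]
List cpp_bayescpi(const NumericMatrix& Z, const NumericVector& y,
                  int n_iter, int burn_in, double nu_u,
                  double pi_init, bool update_pi, bool update_delta,
                  bool update_vars, double sigma_u2_init, double sigma_e2_init) {
  const int n = Z.nrow(), m = Z.ncol();

  // fixed empirical quantities: variance of line means and mean marker variance
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double sP2 = 0.0;
  for (int i = 0; i < n; ++i) sP2 += (y[i] - ybar) * (y[i] - ybar);
  sP2 /= (n - 1);
  std::vector<double> zz(m);
  double sm2bar = 0.0;
  for (int j = 0; j < m; ++j) {
    const double* zj = &Z(0, j);
    double s = 0.0, ss = 0.0;
    for (int i = 0; i < n; ++i) { s += zj[i]; ss += zj[i] * zj[i]; }
    zz[j] = ss;
    sm2bar += (ss - s * s / n) / (n - 1);
  }
  sm2bar /= m;
  if (sm2bar <= 0.0) stop("all marker columns are constant");

  double pi = pi_init;
  double sigma_e2 = (sigma_e2_init > 0.0) ? sigma_e2_init : std::max(sP2 / 2.0, 1e-12);
  double pi_f0 = std::min(pi, 1.0 - 1.0 / m);
  double sigma_u2 = (sigma_u2_init > 0.0) ? sigma_u2_init
                                          : sP2 / (m * (1.0 - pi_f0) * sm2bar);
  double mu = ybar;

  std::vector<double> u(m, 0.0);
  std::vector<int> delta(m, update_delta ? 0 : 1);
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  std::vector<double> sum_ud(m, 0.0), sum_d(m, 0.0);
  double sum_mu = 0.0, sum_pi = 0.0, sum_su2 = 0.0, sum_se2 = 0.0;
  int n_keep = 0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = mu + ebar + norm_rand() * std::sqrt(sigma_e2 / n);
    double shift = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= shift;
    mu = mu_new;

    // loci: joint (delta_j, u_j)
    const double lambda = sigma_e2 / sigma_u2;
    for (int j = 0; j < m; ++j) {
      const double* zj = &Z(0, j);
      const double uold = delta[j] ? u[j] : 0.0;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += zj[i] * e[i];
      rhs += zz[j] * uold;
      const double C = zz[j] + lambda;
      int incl;
      if (update_delta) {
        // posterior odds of inclusion vs exclusion with u_j integrated out
        double log_odds = std::log(1.0 - pi) - std::log(pi)
          + 0.5 * std::log(lambda / C) + 0.5 * rhs * rhs / (sigma_e2 * C);
        double p1 = 1.0 / (1.0 + std::exp(-log_odds));
        incl = (unif_rand() < p1) ? 1 : 0;
      } else {
        incl = 1;
      }
      double unew = 0.0;
      if (incl) unew = rhs / C + norm_rand() * std::sqrt(sigma_e2 / C);
      const double du = uold - unew;
      if (du != 0.0) for (int i = 0; i < n; ++i) e[i] += zj[i] * du;
      u[j] = incl ? unew : 0.0;
      delta[j] = incl;
    }

    int m_incl = 0;
    double ssu = 0.0;
    for (int j = 0; j < m; ++j) if (delta[j]) { ++m_incl; ssu += u[j] * u[j]; }

    if (update_vars) {
      // marker-effect variance: scaled-inv-chi2 prior with data-driven scale
      double pi_f = std::min(pi, 1.0 - 1.0 / m);
      double sigma_tilde_u2 = sP2 / (m * (1.0 - pi_f) * sm2bar);
      double S_u2 = (nu_u - 2.0) * sigma_tilde_u2 / nu_u;
      sigma_u2 = (nu_u * S_u2 + ssu) / R::rchisq(nu_u + m_incl);
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigma_e2 = sse / R::rchisq((double) n - 2.0);
    }

    if (update_pi) pi = R::rbeta((double) (m - m_incl) + 1.0, (double) m_incl + 1.0);

    if (it >= burn_in) {
      ++n_keep;
      for (int j = 0; j < m; ++j) {
        if (delta[j]) { sum_ud[j] += u[j]; sum_d[j] += 1.0; }
      }
      sum_mu += mu; sum_pi += pi; sum_su2 += sigma_u2; sum_se2 += sigma_e2;
    }
  }

  NumericVector effects(m), pip(m);
  for (int j = 0; j < m; ++j) {
    effects[j] = sum_ud[j] / n_keep;
    pip[j] = sum_d[j] / n_keep;
  }
  return List::create(_["effects"] = effects, _["pip"] = pip,
                      _["mu"] = sum_mu / n_keep, _["pi"] = sum_pi / n_keep,
                      _["sigma_u2"] = sum_su2 / n_keep,
                      _["sigma_e2"] = sum_se2 / n_keep,
                      _["n_samples"] = n_keep);
}
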