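// Negative log-likelihood and gradient kernels for the NBID regression.
// Mean model: log mu_i = offset_i + x_i' beta; dispersion theta_{g_i} with
// g_i in {0,1} (full model) or fixed per-cell theta (null model).
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
double nbid_full_nll(NumericVector par, NumericVector y, NumericMatrix X,
                     NumericVector off, IntegerVector grp) {
  const int n = y.size(), p = X.ncol();
  const double th0 = std::exp(par[p]), th1 = std::exp(par[p + 1]);
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    double eta = off[i];
    for (int j = 0; j < p; ++j) eta += X(i, j) * par[j];
    const double mu = std::exp(eta);
    const double th = grp[i] == 0 ? th0 : th1;
    double ll = R::lgammafn(th + y[i]) - R::lgammafn(th) -
                R::lgammafn(y[i] + 1.0) + y[i] * eta + th * std::log(th) -
                (th + y[i]) * std::log(th + mu);
    nll -= ll;
  }
  return nll;
}

// [[Rcpp::export]]
NumericVector nbid_full_grad(NumericVector par, NumericVector y,
                             NumericMatrix X, NumericVector off,
                             IntegerVector grp) {
  const int n = y.size(), p = X.ncol();
  const double th[2] = {std::exp(par[p]), std::exp(par[p + 1])};
  NumericVector g(p + 2);
  for (int i = 0; i < n; ++i) {
    double eta = off[i];
    for (int j = 0; j < p; ++j) eta += X(i, j) * par[j];
    const double mu = std::exp(eta);
    const int gi = grp[i] == 0 ? 0 : 1;
    const double t = th[gi];
    const double s = y[i] - mu * (y[i] + t) / (t + mu);
    for (int j = 0; j < p; ++j) g[j] -= s * X(i, j);
    const double dth = R::digamma(t + y[i]) - R::digamma(t) + std::log(t) +
                       1.0 - std::log(t + mu) - (t + y[i]) / (t + mu);
    g[p + gi] -= t * dth;
  }
  return g;
}

// [[Rcpp::export]]
double nbid_null_nll(NumericVector par, NumericVector y, NumericMatrix X,
                     NumericVector off, NumericVector theta) {
  const int n = y.size(), p = X.ncol();
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    double eta = off[i];
    for (int j = 0; j < p; ++j) eta += X(i, j) * par[j];
    const double mu = std::exp(eta);
    const double th = theta[i];
    double ll = R::lgammafn(th + y[i]) - R::lgammafn(th) -
                R::lgammafn(y[i] + 1.0) + y[i] * eta + th * std::log(th) -
                (th + y[i]) * std::log(th + mu);
    nll -= ll;
  }
  return nll;
}

// [[Rcpp::export]]
NumericVector nbid_null_grad(NumericVector par, NumericVector y,
                             NumericMatrix X, NumericVector off,
                             NumericVector theta) {
  const int n = y.size(), p = X.ncol();
  NumericVector g(p);
  for (int i = 0; i < n; ++i) {
    double eta = off[i];
    for (int j = 0; j < p; ++j) eta += X(i, j) * par[j];
    const double mu = std::exp(eta);
    const double t = theta[i];
    const double s = y[i] - mu * (y[i] + t) / (t + mu);
    for (int j = 0; j < p; ++j) g[j] -= s * X(i, j);
  }
  return g;
}

// ---- fast factorized fitter (no covariates) --------------------------------
// Intercept-plus-offset NB model for one group of cells: log mu_i = b +
// log E_i, dispersion theta. Block coordinate ascent: exact Newton for b
// given theta, safeguarded Newton (with bisection bracket) for log theta
// given b. Gamma-function terms are collapsed over unique count values and
// evaluated in log1p form so the Poisson-like boundary (theta -> 1e8) stays
// numerically stable.

static void collapse_y(const std::vector<double>& y, std::vector<double>& vals,
                       std::vector<double>& wts) {
  std::vector<double> s(y);
  std::sort(s.begin(), s.end());
  for (size_t i = 0; i < s.size();) {
    size_t j = i;
    while (j < s.size() && s[j] == s[i]) ++j;
    vals.push_back(s[i]);
    wts.push_back((double)(j - i));
    i = j;
  }
}

static double group_loglik(const std::vector<double>& y,
                           const std::vector<double>& E,
                           const std::vector<double>& vals,
                           const std::vector<double>& wts, double sy_logE,
                           double Sy, double b, double theta) {
  double ll = sy_logE + b * Sy;
  for (size_t k = 0; k < vals.size(); ++k)
    ll += wts[k] * (R::lgammafn(theta + vals[k]) - R::lgammafn(theta) -
                    vals[k] * std::log(theta) - R::lgammafn(vals[k] + 1.0));
  const double c = std::exp(b);
  for (size_t i = 0; i < y.size(); ++i) {
    const double mu = c * E[i];
    ll -= (theta + y[i]) * std::log1p(mu / theta);
  }
  return ll;
}

// Newton solve for b given theta; score is concave in b
static double solve_b(const std::vector<double>& y,
                      const std::vector<double>& E, double theta, double b) {
  for (int it = 0; it < 100; ++it) {
    const double c = std::exp(b);
    double s = 0.0, h = 0.0;
    for (size_t i = 0; i < y.size(); ++i) {
      const double mu = c * E[i];
      const double d = theta + mu;
      s += theta * (y[i] - mu) / d;
      h += theta * mu * (theta + y[i]) / (d * d);
    }
    if (h <= 0) break;
    double step = s / h;
    if (step > 2.0) step = 2.0;
    if (step < -2.0) step = -2.0;
    b += step;
    if (std::fabs(step) < 1e-12) break;
  }
  return b;
}

// d loglik / d theta at (b, theta), all terms O(1/theta)-stable
static double theta_score(const std::vector<double>& y,
                          const std::vector<double>& E,
                          const std::vector<double>& vals,
                          const std::vector<double>& wts, double b,
                          double theta, double* deriv) {
  double g = 0.0, gp = 0.0;
  for (size_t k = 0; k < vals.size(); ++k) {
    g += wts[k] * (R::digamma(theta + vals[k]) - R::digamma(theta));
    if (deriv)
      gp += wts[k] * (R::trigamma(theta + vals[k]) - R::trigamma(theta));
  }
  const double c = std::exp(b);
  for (size_t i = 0; i < y.size(); ++i) {
    const double mu = c * E[i];
    const double d = theta + mu;
    g += -std::log1p(mu / theta) + (mu - y[i]) / d;
    if (deriv) gp += mu / (theta * d) - (mu - y[i]) / (d * d);
  }
  if (deriv) *deriv = gp;
  return g;
}

// safeguarded Newton on t = log theta within [t_lo, t_hi]
static double solve_theta(const std::vector<double>& y,
                          const std::vector<double>& E,
                          const std::vector<double>& vals,
                          const std::vector<double>& wts, double b, double t,
                          double t_lo, double t_hi) {
  // boundary check via the overdispersion score at phi = 0,
  // d loglik / d phi = 0.5 * sum((y - mu)^2 - y): the score in theta at the
  // upper bound is O(1/theta^2) and drowns in cancellation noise there
  const double c_at_b = std::exp(b);
  double dean = 0.0;
  for (size_t i = 0; i < y.size(); ++i) {
    const double mu = c_at_b * E[i];
    dean += (y[i] - mu) * (y[i] - mu) - y[i];
  }
  if (dean <= 0) return t_hi;  // no overdispersion signal: Poisson-like bound
  double g_lo = theta_score(y, E, vals, wts, b, std::exp(t_lo), 0);
  if (g_lo <= 0) return t_lo;
  if (t <= t_lo || t >= t_hi) t = 0.5 * (t_lo + t_hi);
  for (int it = 0; it < 100; ++it) {
    double gp;
    const double theta = std::exp(t);
    const double g = theta_score(y, E, vals, wts, b, theta, &gp);
    if (g > 0) t_lo = t; else t_hi = t;
    // Newton step on t: f(t) = g(theta), f'(t) = theta * g'(theta)
    double t_new = t - g / (theta * gp);
    if (!std::isfinite(t_new) || t_new <= t_lo || t_new >= t_hi)
      t_new = 0.5 * (t_lo + t_hi);
    if (std::fabs(t_new - t) < 1e-10) { t = t_new; break; }
    t = t_new;
  }
  return t;
}

static void fit_group(const std::vector<double>& y,
                      const std::vector<double>& E, double theta_min,
                      double theta_max, double* b_out, double* theta_out,
                      double* ll_out, bool* conv_out) {
  const double t_lo = std::log(theta_min), t_hi = std::log(theta_max);
  double Sy = 0.0, SE = 0.0, sy_logE = 0.0;
  for (size_t i = 0; i < y.size(); ++i) {
    Sy += y[i];
    SE += E[i];
    if (y[i] > 0) sy_logE += y[i] * std::log(E[i]);
  }
  std::vector<double> vals, wts;
  collapse_y(y, vals, wts);
  if (Sy == 0) {  // separated group: likelihood supremum 0 at mu -> 0
    *b_out = -40.0;
    *theta_out = theta_max;
    *ll_out = group_loglik(y, E, vals, wts, sy_logE, Sy, -40.0, theta_max);
    *conv_out = true;
    return;
  }
  double b = std::log(Sy / SE);
  // moment start for the dispersion
  double num = 0.0, den = 0.0;
  const double c0 = std::exp(b);
  for (size_t i = 0; i < y.size(); ++i) {
    const double mu = c0 * E[i];
    num += (y[i] - mu) * (y[i] - mu) - mu;
    den += mu * mu;
  }
  double phi = num / den;
  if (!(phi > 1e-4)) phi = 1e-4;
  double t = std::log(std::fmin(std::fmax(1.0 / phi, theta_min), theta_max));
  double ll = group_loglik(y, E, vals, wts, sy_logE, Sy, b, std::exp(t));
  bool conv = false;
  for (int round = 0; round < 100; ++round) {
    b = solve_b(y, E, std::exp(t), b);
    t = solve_theta(y, E, vals, wts, b, t, t_lo, t_hi);
    const double ll_new =
        group_loglik(y, E, vals, wts, sy_logE, Sy, b, std::exp(t));
    if (std::fabs(ll_new - ll) < 1e-10) { ll = ll_new; conv = true; break; }
    ll = ll_new;
  }
  *b_out = b;
  *theta_out = std::exp(t);
  *ll_out = ll;
  *conv_out = conv;
}

// [[Rcpp::export]]
List nbid_fit_two_groups(NumericVector y, NumericVector E, IntegerVector grp,
                         double theta_min, double theta_max) {
  std::vector<double> y0, y1, E0, E1;
  for (int i = 0; i < y.size(); ++i) {
    if (grp[i] == 0) { y0.push_back(y[i]); E0.push_back(E[i]); }
    else             { y1.push_back(y[i]); E1.push_back(E[i]); }
  }
  double b0, b1, th0, th1, ll0, ll1;
  bool c0, c1;
  fit_group(y0, E0, theta_min, theta_max, &b0, &th0, &ll0, &c0);
  fit_group(y1, E1, theta_min, theta_max, &b1, &th1, &ll1, &c1);
  return List::create(_["b0"] = b0, _["b1"] = b1, _["theta0"] = th0,
                      _["theta1"] = th1, _["loglik"] = ll0 + ll1,
                      _["converged"] = (c0 && c1));
}

// [[Rcpp::export]]
List nbid_fit_null_1d(NumericVector y, NumericVector E, NumericVector theta) {
  const int n = y.size();
  double Sy = 0.0, SE = 0.0;
  for (int i = 0; i < n; ++i) { Sy += y[i]; SE += E[i]; }
  double b = std::log((Sy + 0.5) / SE);
  bool conv = false;
  for (int it = 0; it < 100; ++it) {  // concave score: plain damped Newton
    const double c = std::exp(b);
    double s = 0.0, h = 0.0;
    for (int i = 0; i < n; ++i) {
      const double mu = c * E[i];
      const double d = theta[i] + mu;
      s += theta[i] * (y[i] - mu) / d;
      h += theta[i] * mu * (theta[i] + y[i]) / (d * d);
    }
    if (h <= 0) break;
    double step = s / h;
    if (step > 2.0) step = 2.0;
    if (step < -2.0) step = -2.0;
    b += step;
    if (std::fabs(step) < 1e-12) { conv = true; break; }
  }
  double ll = 0.0;
  const double c = std::exp(b);
  for (int i = 0; i < n; ++i) {
    const double mu = c * E[i];
    const double th = theta[i];
    ll += R::lgammafn(th + y[i]) - R::lgammafn(th) - R::lgammafn(y[i] + 1.0) -
          y[i] * std::log(th) + y[i] * (std::log(E[i]) + b) -
          (th + y[i]) * std::log1p(mu / th);
  }
  return List::create(_["b0"] = b, _["loglik"] = ll, _["converged"] = conv);
}
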