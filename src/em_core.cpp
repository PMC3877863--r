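#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// EM for a univariate Gaussian mixture.
//
// The E-step evaluates component log-densities and normalizes
// responsibilities through log-sum-exp; the observed-data log-likelihood is
// the sum of the per-point log-sum-exp terms and is therefore computed for
// the *current* parameters at the top of each iteration, so the reported
// loglik always corresponds to the returned parameters.
//
// equal_var = TRUE pools one variance across components ("E" family);
// otherwise each component has its own variance ("V" family).
//
// Variances are floored at var_floor. A component that needs flooring in two
// or more iterations, or whose effective weight underflows, is treated as
// collapsed and the fit is flagged (collapsed = TRUE, converged = FALSE).
// [[Rcpp::export(name = ".em_core")]]
List em_core(NumericVector x, NumericVector w0, NumericVector mu0,
             NumericVector var0, bool equal_var, double tol, int max_iter,
             double var_floor) {
  const int n = x.size(), K = w0.size();
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> v(var0.begin(), var0.end());
  std::vector<double> resp(static_cast<size_t>(n) * K);
  std::vector<double> lp(K), lw(K), inv2v(K);
  std::vector<int> floor_hits(K, 0);
  std::vector<double> ll_trace;
  ll_trace.reserve(64);

  double loglik = R_NegInf, prev = R_NegInf;
  bool converged = false, collapsed = false;
  int iter = 0;
  const double log2pi = std::log(2.0 * M_PI);

  for (iter = 1; iter <= max_iter; ++iter) {
    // E-step + loglik of current parameters
    for (int k = 0; k < K; ++k) {
      lw[k] = std::log(w[k]) - 0.5 * (log2pi + std::log(v[k]));
      inv2v[k] = 0.5 / v[k];
    }
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        const double d = x[i] - mu[k];
        lp[k] = lw[k] - d * d * inv2v[k];
        if (lp[k] > m) m = lp[k];
      }
      double s = 0.0;
      double *ri = &resp[static_cast<size_t>(i) * K];
      for (int k = 0; k < K; ++k) {
        const double e = std::exp(lp[k] - m);
        ri[k] = e;
        s += e;
      }
      ll += m + std::log(s);
      const double inv_s = 1.0 / s;
      for (int k = 0; k < K; ++k) ri[k] *= inv_s;
    }
    loglik = ll;
    ll_trace.push_back(ll);

    if (iter > 1) {
      const double rel = std::fabs(ll - prev) / (std::fabs(prev) + tol);
      if (rel < tol) { converged = true; break; }
    }
    prev = ll;

    // M-step
    double pooled = 0.0;
    for (int k = 0; k < K; ++k) {
      double nk = 0.0, sx = 0.0;
      for (int i = 0; i < n; ++i) {
        const double r = resp[static_cast<size_t>(i) * K + k];
        nk += r;
        sx += r * x[i];
      }
      if (nk <= 0.0 || !std::isfinite(nk)) { collapsed = true; break; }
      w[k] = nk / n;
      mu[k] = sx / nk;
      double sv = 0.0;
      for (int i = 0; i < n; ++i) {
        const double d = x[i] - mu[k];
        sv += resp[static_cast<size_t>(i) * K + k] * d * d;
      }
      if (equal_var) {
        pooled += sv;
      } else {
        double vk = sv / nk;
        if (vk < var_floor) { vk = var_floor; ++floor_hits[k]; }
        v[k] = vk;
      }
    }
    if (collapsed) break;
    if (equal_var) {
      double vp = pooled / n;
      if (vp < var_floor) {
        vp = var_floor;
        for (int k = 0; k < K; ++k) ++floor_hits[k];
      }
      for (int k = 0; k < K; ++k) v[k] = vp;
    }
    for (int k = 0; k < K; ++k)
      if (floor_hits[k] >= 2) { collapsed = true; }
    if (collapsed) break;
  }
  if (iter > max_iter) iter = max_iter;
  if (collapsed) converged = false;

  return List::create(
      _["weights"] = NumericVector(w.begin(), w.end()),
      _["means"] = NumericVector(mu.begin(), mu.end()),
      _["variances"] = NumericVector(v.begin(), v.end()),
      _["loglik"] = loglik, _["n_iter"] = iter,
      _["converged"] = converged, _["collapsed"] = collapsed,
      _["loglik_trace"] = NumericVector(ll_trace.begin(), ll_trace.end()));
}
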