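#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward pass of the Kalman-based mixed filter. The implicit filtered-mean
// equation is scalar and monotone; Newton iteration from the prediction with
// a bisection fallback on the bracketing interval always finds the unique
// root. Shared by the batch and streaming R interfaces so both produce
// identical arithmetic.
// [[Rcpp::export]]
List mixed_filter_core(NumericVector n, NumericVector z, double alpha,
                       double beta, double gamma, double se2, double sw2,
                       double x0, double v0, bool use_binary,
                       bool use_continuous, double tol, int max_iter) {
  int K = z.size();
  NumericVector x_pred(K), v_pred(K), x_filt(K), v_filt(K), gain(K);
  double xp = x0, vp = v0;
  for (int k = 0; k < K; ++k) {
    x_pred[k] = xp;
    v_pred[k] = vp;
    double b = use_continuous ? beta : 0.0;
    double C = vp / (b * b * vp + sw2);
    double base = xp + (use_continuous ? C * b * (z[k] - alpha - b * xp) : 0.0);
    double info_cont = use_continuous ? beta * beta / sw2 : 0.0;
    double x, v;
    if (!use_binary) {
      x = base;
      v = 1.0 / (1.0 / vp + info_cont);
    } else {
      double Csw = C * sw2;
      // root of f(x) = base + Csw * (n - p(x)) - x; f strictly decreasing
      double lo = base + Csw * (n[k] - 1.0);
      double hi = base + Csw * n[k];
      x = xp;
      if (x < lo || x > hi) x = 0.5 * (lo + hi);
      bool ok = false;
      for (int i = 0; i < max_iter; ++i) {
        double p = 1.0 / (1.0 + std::exp(-(gamma + x)));
        double f = base + Csw * (n[k] - p) - x;
        if (std::fabs(f) < tol) { ok = true; break; }
        if (f > 0) lo = x; else hi = x;
        double xn = x - f / (-Csw * p * (1.0 - p) - 1.0);
        if (!std::isfinite(xn) || xn <= lo || xn >= hi) xn = 0.5 * (lo + hi);
        if (xn == x) { ok = true; break; } // bracket at machine precision
        x = xn;
      }
      double p = 1.0 / (1.0 + std::exp(-(gamma + x)));
      if (!ok && std::fabs(base + Csw * (n[k] - p) - x) >= tol) {
        stop("mixed-filter update did not converge at bin %d (last iterate %g)",
             k + 1, x);
      }
      v = 1.0 / (1.0 / vp + p * (1.0 - p) + info_cont);
    }
    x_filt[k] = x;
    v_filt[k] = v;
    gain[k] = C;
    xp = x;
    vp = v + se2;
  }
  return List::create(_["x_pred"] = x_pred, _["v_pred"] = v_pred,
                      _["x_filt"] = x_filt, _["v_filt"] = v_filt,
                      _["gain"] = gain);
}
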