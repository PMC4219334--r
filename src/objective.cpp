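#include <Rcpp.h>
#include <cmath>
#include <vector>

// Fast path for the parametric fitting objective: evaluates the L2 mismatch
// between the observed density and q * exp(-eps * f((d - t)/sigma)) / Z on
// the shared uniform support, with a soft quadratic penalty outside the
// parameter box. Must stay in sync with the R-level shape table; the test
// suite asserts agreement with the R route.

static inline double shape_f(int id, double r) {
  switch (id) {
  case 0: return r < 0 ? -1.0 : 0.0;                          // step
  case 1: return r > 0 ? -1.0 / (r + 1.0) : -(1.0 - r);       // hernquist
  case 2: return r > 1 ? 0.0 : -(1.0 - r);                    // linear1
  case 3: return r > 1 ? 0.0 : (r < 0 ? -1.0 : -(1.0 - r));   // linear2
  case 4: return r > 0 ? -1.0 / std::sqrt(r * r + 1.0) : -1.0; // plummer
  }
  return 0.0;
}

// [[Rcpp::export(name = ".ia_objective_cpp")]]
double ia_objective_cpp(Rcpp::NumericVector theta, int shape_id, bool is_step,
                        Rcpp::NumericVector s, Rcpp::NumericVector qv,
                        Rcpp::NumericVector pv, double dd,
                        Rcpp::NumericVector lo, Rcpp::NumericVector hi) {
  double pen = 0.0, th[2];
  for (int j = 0; j < 2; ++j) {
    double t = theta[j];
    double e1 = t - hi[j];
    if (e1 > 0) pen += e1 * e1;
    double e2 = lo[j] - t;
    if (e2 > 0) pen += e2 * e2;
    th[j] = std::min(std::max(t, lo[j]), hi[j]);
  }
  double eps = std::exp(th[0]);
  double sig = is_step ? 1.0 : std::exp(th[1]);
  double t0 = is_step ? th[1] : 0.0;
  int n = s.size();
  std::vector<double> w(n);
  double Z = 0.0;
  for (int i = 0; i < n; ++i) {
    double phi = eps * shape_f(shape_id, (s[i] - t0) / sig);
    w[i] = qv[i] * std::exp(-phi);
    Z += w[i];
  }
  Z = dd * (Z - (w[0] + w[n - 1]) / 2.0);
  double obj = 0.0;
  for (int i = 0; i < n; ++i) {
    double r = pv[i] - w[i] / Z;
    obj += r * r;
  }
  return obj * dd + 100.0 * pen;
}
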