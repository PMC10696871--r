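#include <Rcpp.h>
using namespace Rcpp;

// Weighted soft-margin linear SVM by dual coordinate descent
// (liblinear-style), solving
//   min_w 1/2 ||w||^2 + sum_i c_i * hinge(1 - y_i (w'x_i + b))
// with the bias handled through an augmented constant feature of value
// `bias_scale` (penalized intercept; large scale makes the distortion
// negligible). Samples are passed as columns of Xt ((d+1) x n, last row =
// bias_scale) so each sample is contiguous in memory.
//
// Dual: min 1/2 a'Qa - 1'a, 0 <= a_i <= c_i, Q_ij = y_i y_j x_i'x_j.
// Maintains v = sum_i a_i y_i x_i; per-coordinate Newton step with
// projection. Deterministic cyclic-with-shuffle order from a seeded LCG.

// [[Rcpp::export]]
List svm_cd(NumericMatrix Xt, NumericVector y, NumericVector c,
            int max_pass = 200, double tol = 1e-6, int seed = 1) {
  const int d1 = Xt.nrow();   // d + 1 (bias row included)
  const int n = Xt.ncol();
  std::vector<double> v(d1, 0.0), alpha(n, 0.0), qdiag(n);
  for (int i = 0; i < n; ++i) {
    const double* xi = &Xt(0, i);
    double s = 0.0;
    for (int k = 0; k < d1; ++k) s += xi[k] * xi[k];
    qdiag[i] = s;
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  unsigned long long state = (unsigned long long)seed * 2862933555777941757ULL + 3037000493ULL;
  auto next_u = [&state]() {
    state = state * 6364136223846793005ULL + 1442695040888963407ULL;
    return (unsigned int)(state >> 33);
  };

  int pass = 0;
  for (; pass < max_pass; ++pass) {
    // Fisher-Yates shuffle
    for (int i = n - 1; i > 0; --i) {
      int j = next_u() % (i + 1);
      std::swap(order[i], order[j]);
    }
    double max_pg = 0.0;
    for (int t = 0; t < n; ++t) {
      const int i = order[t];
      if (c[i] <= 0.0 || qdiag[i] <= 0.0) continue;
      const double* xi = &Xt(0, i);
      double g = 0.0;
      for (int k = 0; k < d1; ++k) g += v[k] * xi[k];
      g = y[i] * g - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0) pg = std::min(g, 0.0);
      else if (alpha[i] >= c[i]) pg = std::max(g, 0.0);
      if (std::fabs(pg) > max_pg) max_pg = std::fabs(pg);
      if (std::fabs(pg) > 1e-14) {
        double a_new = alpha[i] - g / qdiag[i];
        if (a_new < 0.0) a_new = 0.0;
        else if (a_new > c[i]) a_new = c[i];
        const double delta = (a_new - alpha[i]) * y[i];
        if (delta != 0.0) {
          alpha[i] = a_new;
          for (int k = 0; k < d1; ++k) v[k] += delta * xi[k];
        }
      }
    }
    if (max_pg < tol) { ++pass; break; }
  }
  return List::create(_["v"] = NumericVector(v.begin(), v.end()),
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["passes"] = pass);
}
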