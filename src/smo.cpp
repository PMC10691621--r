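// Sequential minimal optimization for the soft-margin kernel SVM dual:
//   min_a 1/2 a' Q a - e' a,  0 <= a_i <= C,  y' a = 0,  Q_ij = y_i y_j K_ij
// First-order (maximal-violating-pair) working-set selection with a full
// gradient vector; the kernel matrix is precomputed by the caller, which is
// adequate for the few-hundred-sample training sets this package handles.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List smo_train(NumericMatrix K, NumericVector y, double C,
               double eps = 1e-3, int max_iter = 1000000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("kernel/label size mismatch");
  std::vector<double> alpha(n, 0.0), G(n, -1.0);  // G = Q a - e
  int iter = 0;
  double m_up = 0.0, m_low = 0.0;

  for (iter = 0; iter < max_iter; ++iter) {
    // select i in I_up maximizing -y G, j in I_low minimizing -y G
    int i = -1, j = -1;
    m_up = -HUGE_VAL;
    m_low = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool low = (y[t] < 0 && alpha[t] < C) || (y[t] > 0 && alpha[t] > 0);
      if (up && v > m_up) { m_up = v; i = t; }
      if (low && v < m_low) { m_low = v; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < eps) break;

    double a_ij = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (a_ij <= 0) a_ij = 1e-12;
    double d = (m_up - m_low) / a_ij;  // step along (y_i, -y_j) direction

    // box constraints: alpha_i' = alpha_i + y_i d, alpha_j' = alpha_j - y_j d
    double lo_i = (y[i] > 0) ? -alpha[i] : alpha[i] - C;
    double hi_i = (y[i] > 0) ? C - alpha[i] : alpha[i];
    double lo_j = (y[j] > 0) ? alpha[j] - C : -alpha[j];
    double hi_j = (y[j] > 0) ? alpha[j] : C - alpha[j];
    double lo = std::max(lo_i, lo_j), hi = std::min(hi_i, hi_j);
    if (d < lo) d = lo;
    if (d > hi) d = hi;
    if (d == 0.0) break;

    double dai = y[i] * d, daj = -y[j] * d;
    alpha[i] += dai;
    alpha[j] += daj;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
  }

  // bias from the final violating-pair bounds
  double b = (m_up + m_low) / 2.0;
  if (!std::isfinite(b)) b = 0.0;
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["gap"] = m_up - m_low);
}
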