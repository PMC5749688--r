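// Deterministic dual coordinate descent for the L1-loss linear
// maximum-margin classifier (box constraint 0 <= alpha_i <= C), bias
// handled by feature augmentation. Instances are visited in a fixed order
// so training is exactly reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Xt: d x n matrix (one instance per column), y in {-1, +1}.
// [[Rcpp::export]]
List svm_dcd_train(NumericMatrix Xt, NumericVector y, double C,
                   int max_passes = 500, double tol = 1e-6) {
  const int d = Xt.nrow(), n = Xt.ncol();
  std::vector<double> w(d + 1, 0.0), alpha(n, 0.0), Q(n);
  const double *xp = Xt.begin();
  for (int i = 0; i < n; ++i) {
    double q = 1.0;  // bias feature
    const double *xi = xp + (size_t)i * d;
    for (int j = 0; j < d; ++j) q += xi[j] * xi[j];
    Q[i] = q;
  }
  int pass = 0;
  for (; pass < max_passes; ++pass) {
    double max_viol = 0.0;
    for (int i = 0; i < n; ++i) {
      const double *xi = xp + (size_t)i * d;
      double wx = w[d];
      for (int j = 0; j < d; ++j) wx += w[j] * xi[j];
      double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0) PG = G < 0.0 ? G : 0.0;
      else if (alpha[i] >= C) PG = G > 0.0 ? G : 0.0;
      if (std::fabs(PG) > max_viol) max_viol = std::fabs(PG);
      if (std::fabs(PG) > 1e-14) {
        double a_new = alpha[i] - G / Q[i];
        if (a_new < 0.0) a_new = 0.0;
        else if (a_new > C) a_new = C;
        double delta = (a_new - alpha[i]) * y[i];
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
          w[d] += delta;
          alpha[i] = a_new;
        }
      }
    }
    if (max_viol < tol) break;
  }
  NumericVector wv(d);
  for (int j = 0; j < d; ++j) wv[j] = w[j];
  return List::create(_["w"] = wv, _["b"] = w[d],
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["passes"] = pass + 1);
}
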