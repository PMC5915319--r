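#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Elastic-net coordinate descent along a decreasing lambda path.
//
// Objective, for one lambda and mixing weight alpha:
//   (1/2n) * sum_i (y_i - b0 - x_i' b)^2
//     + lambda * ( alpha * ||b||_1 + (1 - alpha)/2 * ||b||_2^2 )
// The intercept b0 is unpenalized and predictors are used as supplied
// (the +/-1 subfunction codes are already balanced; no standardization).
// Solutions are warm-started from the previous (larger) lambda.
//
// [[Rcpp::export(name = ".enet_path_cd")]]
List enet_path_cd(NumericMatrix X, NumericVector y, NumericVector lambda,
                  double alpha, double tol, int max_iter) {
  const int n = X.nrow(), k = X.ncol(), L = lambda.size();
  NumericMatrix beta(k, L);
  NumericVector b0(L);
  IntegerVector iters(L);

  std::vector<double> b(k, 0.0), r(n);
  double intercept = 0.0;
  for (int i = 0; i < n; ++i) intercept += y[i];
  intercept /= n;
  for (int i = 0; i < n; ++i) r[i] = y[i] - intercept;

  std::vector<double> xsq(k); // (1/n) sum_i x_ij^2
  for (int j = 0; j < k; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xsq[j] = s / n;
  }

  for (int l = 0; l < L; ++l) {
    if (l > 0 && lambda[l] > lambda[l - 1])
      stop("lambda path must be non-increasing");
    const double l1 = lambda[l] * alpha;
    const double l2 = lambda[l] * (1.0 - alpha);
    int it = 0;
    for (; it < max_iter; ++it) {
      double maxd = 0.0;
      // unpenalized intercept
      double rm = 0.0;
      for (int i = 0; i < n; ++i) rm += r[i];
      rm /= n;
      if (rm != 0.0) {
        intercept += rm;
        for (int i = 0; i < n; ++i) r[i] -= rm;
        if (std::fabs(rm) > maxd) maxd = std::fabs(rm);
      }
      for (int j = 0; j < k; ++j) {
        double z = 0.0;
        for (int i = 0; i < n; ++i) z += X(i, j) * r[i];
        z = z / n + xsq[j] * b[j];
        const double denom = xsq[j] + l2;
        double bn;
        if (denom <= 0.0) bn = 0.0;
        else if (z > l1) bn = (z - l1) / denom;
        else if (z < -l1) bn = (z + l1) / denom;
        else bn = 0.0;
        const double d = bn - b[j];
        if (d != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= d * X(i, j);
          b[j] = bn;
          if (std::fabs(d) > maxd) maxd = std::fabs(d);
        }
      }
      if (maxd < tol) break;
    }
    iters[l] = it + 1;
    for (int j = 0; j < k; ++j) beta(j, l) = b[j];
    b0[l] = intercept;
  }

  return List::create(_["beta"] = beta, _["intercept"] = b0,
                      _["iterations"] = iters);
}
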