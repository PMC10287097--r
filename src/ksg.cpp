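#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger mutual information estimator (algorithm 1)
// for two scalar series. Distances use the max-norm in the joint space;
// marginal counts are strict (< eps_i). Returns nats. O(N^2), fine for the
// series lengths this package produces (a few thousand samples).
// [[Rcpp::export(name = ".ksg_mi_cpp")]]
double ksg_mi_cpp(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (n < k + 2) stop("series too short for k");

  std::vector<double> d(n), dx(n), dy(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    // distance to k-th nearest neighbour in joint (max-norm)
    int m = 0;
    const double xi = x[i], yi = y[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double ax = std::fabs(x[j] - xi);
      double ay = std::fabs(y[j] - yi);
      dx[m] = ax; dy[m] = ay;
      d[m++] = ax > ay ? ax : ay;
    }
    std::nth_element(d.begin(), d.begin() + (k - 1), d.begin() + m);
    double eps = d[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < m; ++j) {
      if (dx[j] < eps) ++nx;
      if (dy[j] < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}
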