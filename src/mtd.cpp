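#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Mean HPD between within-method relative transforms over all ordered pairs
// i < j (optionally strided), independent of each method's reference pose.
// rot*: n x 9 row-major rotation matrices, tr*: n x 3 translations.
// [[Rcpp::export(name = ".mtd_cpp")]]
double mtd_cpp(NumericMatrix rotA, NumericMatrix trA,
               NumericMatrix rotB, NumericMatrix trB,
               NumericVector center, double radius, int stride) {
  const int n = rotA.nrow();
  if (rotB.nrow() != n) stop("traces must have equal length");
  if (n < 2) stop("need at least 2 common samples");
  if (stride < 1) stride = 1;

  // flat row-major copies for fast access
  std::vector<double> RA(9 * n), RB(9 * n), TA(3 * n), TB(3 * n);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < 9; ++c) { RA[9 * i + c] = rotA(i, c); RB[9 * i + c] = rotB(i, c); }
    for (int c = 0; c < 3; ++c) { TA[3 * i + c] = trA(i, c); TB[3 * i + c] = trB(i, c); }
  }
  const double cx = center[0], cy = center[1], cz = center[2];
  const double r2over5 = radius * radius / 5.0;

  double acc = 0.0;
  long cnt = 0;
  double Da[9], Db[9], da[3], db[3], Rm[9], tm[3];
  for (int i = 0; i < n - 1; i += stride) {
    const double *Ri_a = &RA[9 * i], *Ri_b = &RB[9 * i];
    const double *ti_a = &TA[3 * i], *ti_b = &TB[3 * i];
    for (int j = i + 1; j < n; j += stride) {
      const double *Rj_a = &RA[9 * j], *Rj_b = &RB[9 * j];
      const double *tj_a = &TA[3 * j], *tj_b = &TB[3 * j];
      // D = T_j o inv(T_i): R = Rj Ri^T, t = tj - R ti, per method
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 3; ++c) {
          double sa = 0.0, sb = 0.0;
          for (int k = 0; k < 3; ++k) {
            sa += Rj_a[3 * r + k] * Ri_a[3 * c + k];
            sb += Rj_b[3 * r + k] * Ri_b[3 * c + k];
          }
          Da[3 * r + c] = sa; Db[3 * r + c] = sb;
        }
      for (int r = 0; r < 3; ++r) {
        double sa = 0.0, sb = 0.0;
        for (int k = 0; k < 3; ++k) {
          sa += Da[3 * r + k] * ti_a[k];
          sb += Db[3 * r + k] * ti_b[k];
        }
        da[r] = tj_a[r] - sa; db[r] = tj_b[r] - sb;
      }
      // M = Db o inv(Da); hpd of M over the ball
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 3; ++c) {
          double s = 0.0;
          for (int k = 0; k < 3; ++k) s += Db[3 * r + k] * Da[3 * c + k];
          Rm[3 * r + c] = s;
        }
      for (int r = 0; r < 3; ++r) {
        double s = 0.0;
        for (int k = 0; k < 3; ++k) s += Rm[3 * r + k] * da[k];
        tm[r] = db[r] - s;
      }
      double frob = 0.0, vnorm = 0.0;
      for (int r = 0; r < 3; ++r) {
        double a0 = Rm[3 * r + 0] - (r == 0 ? 1.0 : 0.0);
        double a1 = Rm[3 * r + 1] - (r == 1 ? 1.0 : 0.0);
        double a2 = Rm[3 * r + 2] - (r == 2 ? 1.0 : 0.0);
        frob += a0 * a0 + a1 * a1 + a2 * a2;
        double v = tm[r] + a0 * cx + a1 * cy + a2 * cz;
        vnorm += v * v;
      }
      acc += std::sqrt(r2over5 * frob + vnorm);
      ++cnt;
    }
  }
  return acc / cnt;
}
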