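#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Nearest neighbour of every row of `x` under a Theiler exclusion window:
// candidate j is admissible for query i iff |i - j| >= theiler. Returns
// 1-based indices (NA when no candidate exists). Exact O(T^2) scan over
// raw column pointers; fast enough for the 4e4-point state spaces this
// package builds.
// [[Rcpp::export]]
IntegerVector nn_theiler(NumericMatrix x, int theiler) {
  const int n = x.nrow(), d = x.ncol();
  std::vector<const double*> col(d);
  for (int k = 0; k < d; ++k) col[k] = &x(0, k);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bj = NA_INTEGER;
    const int lo_end = i - theiler;      // admissible: j <= lo_end
    const int hi_beg = i + theiler;      // admissible: j >= hi_beg
    if (d == 3) {
      const double xi0 = col[0][i], xi1 = col[1][i], xi2 = col[2][i];
      for (int j = 0; j < n; ++j) {
        if (j > lo_end && j < hi_beg) { j = hi_beg - 1; continue; }
        const double t0 = col[0][j] - xi0;
        double s = t0 * t0;
        if (s >= best) continue;
        const double t1 = col[1][j] - xi1;
        s += t1 * t1;
        if (s >= best) continue;
        const double t2 = col[2][j] - xi2;
        s += t2 * t2;
        if (s < best) { best = s; bj = j + 1; }
      }
    } else {
      for (int j = 0; j < n; ++j) {
        if (j > lo_end && j < hi_beg) { j = hi_beg - 1; continue; }
        double s = 0.0;
        for (int k = 0; k < d; ++k) {
          const double t = col[k][j] - col[k][i];
          s += t * t;
          if (s >= best) break;
        }
        if (s < best) { best = s; bj = j + 1; }
      }
    }
    out[i] = bj;
  }
  return out;
}
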