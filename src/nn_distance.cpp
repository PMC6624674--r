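#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Nearest-neighbour Euclidean distances from each row of `from` to the point
// set `to` (both n x 3, physical mm).  Sorted-sweep search: `to` is sorted on
// x; for each query the scan expands outward from the insertion point and
// prunes once the x-gap alone exceeds the best distance found.  Typical cost
// is far below the all-pairs O(n_a * n_b); worst case degrades gracefully.
// [[Rcpp::export(name = ".nnDistances")]]
NumericVector nnDistances(NumericMatrix from, NumericMatrix to) {
  const int na = from.nrow(), nb = to.nrow();
  std::vector<int> ord(nb);
  for (int i = 0; i < nb; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return to(a, 0) < to(b, 0);
  });
  std::vector<double> sx(nb), sy(nb), sz(nb);
  for (int i = 0; i < nb; ++i) {
    sx[i] = to(ord[i], 0);
    sy[i] = to(ord[i], 1);
    sz[i] = to(ord[i], 2);
  }
  NumericVector out(na);
  for (int q = 0; q < na; ++q) {
    const double px = from(q, 0), py = from(q, 1), pz = from(q, 2);
    int lo = (int)(std::lower_bound(sx.begin(), sx.end(), px) - sx.begin());
    int hi = lo - 1;
    double best = R_PosInf;
    while (lo < nb || hi >= 0) {
      if (lo < nb) {
        double dx = sx[lo] - px;
        if (dx * dx >= best) {
          lo = nb;
        } else {
          double dy = sy[lo] - py, dz = sz[lo] - pz;
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < best) best = d2;
          ++lo;
        }
      }
      if (hi >= 0) {
        double dx = px - sx[hi];
        if (dx * dx >= best) {
          hi = -1;
        } else {
          double dy = sy[hi] - py, dz = sz[hi] - pz;
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < best) best = d2;
          --hi;
        }
      }
    }
    out[q] = std::sqrt(best);
  }
  return out;
}
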