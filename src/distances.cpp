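// Nearest-neighbour distances between 3D surface point sets, used by the
// robust Hausdorff metric.

#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// For every row of A (n x 3), the Euclidean distance to the closest row
// of B (m x 3).
// [[Rcpp::export]]
NumericVector cn_min_dists(const NumericMatrix& A, const NumericMatrix& B) {
  const int nA = A.nrow(), nB = B.nrow();
  if (A.ncol() != 3 || B.ncol() != 3) stop("point sets must be n x 3");
  NumericVector out(nA);
  const double* ax = &A(0, 0); const double* ay = &A(0, 1); const double* az = &A(0, 2);
  const double* bx = &B(0, 0); const double* by = &B(0, 1); const double* bz = &B(0, 2);
  for (int i = 0; i < nA; ++i) {
    double best = std::numeric_limits<double>::infinity();
    const double xi = ax[i], yi = ay[i], zi = az[i];
    for (int j = 0; j < nB; ++j) {
      const double dx = xi - bx[j], dy = yi - by[j], dz = zi - bz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
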