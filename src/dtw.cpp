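#include <Rcpp.h>
using namespace Rcpp;

// Accumulated-cost matrix of classic dynamic time warping between two
// sequences given as n x d and m x d matrices.  Local cost is the L2 norm
// of the pointwise difference (absolute difference for d = 1, Euclidean for
// d = 2).  Recurrence: D(i,j) = cost(i,j) + min(D(i-1,j), D(i,j-1),
// D(i-1,j-1)) with D(1,1) = cost(1,1).  band >= 0 restricts |j - i*m/n| to
// a Sakoe-Chiba corridor (scaled to unequal lengths); band < 0 disables.
// Cells outside the corridor are +Inf.
// [[Rcpp::export]]
NumericMatrix dtwAccumulatedCost(NumericMatrix a, NumericMatrix b, int band) {
  const int n = a.nrow(), m = b.nrow(), d = a.ncol();
  NumericMatrix D(n, m);
  std::fill(D.begin(), D.end(), R_PosInf);
  for (int i = 0; i < n; ++i) {
    int j0 = 0, j1 = m - 1;
    if (band >= 0) {
      double c = (n > 1) ? (double)i * (m - 1) / (n - 1) : 0.0;
      j0 = std::max(0, (int)std::ceil(c - band));
      j1 = std::min(m - 1, (int)std::floor(c + band));
    }
    for (int j = j0; j <= j1; ++j) {
      double cost = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = a(i, k) - b(j, k);
        cost += diff * diff;
      }
      cost = std::sqrt(cost);
      double best;
      if (i == 0 && j == 0) {
        best = 0.0;
      } else {
        best = R_PosInf;
        if (i > 0) best = std::min(best, D(i - 1, j));
        if (j > 0) best = std::min(best, D(i, j - 1));
        if (i > 0 && j > 0) best = std::min(best, D(i - 1, j - 1));
      }
      D(i, j) = cost + best;
    }
  }
  return D;
}
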