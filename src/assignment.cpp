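#include <Rcpp.h>
#include <vector>
#include <limits>

// Hungarian algorithm (potentials form, O(n^3)) for the square min-cost
// assignment problem.  Used for the maximum-weight one-to-one edge matching
// in the topology-similarity score: callers pad the score matrix to square
// with zeros and negate it.

// [[Rcpp::export]]
Rcpp::IntegerVector hungarian_assignment(Rcpp::NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) Rcpp::stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();

  // 1-based arrays; p[j] = row matched to column j (p[0] = current row)
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = 0;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  Rcpp::IntegerVector row_to_col(n);
  for (int j = 1; j <= n; ++j) row_to_col[p[j] - 1] = j;  // 1-based cols
  return row_to_col;
}
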