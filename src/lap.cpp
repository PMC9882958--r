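#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Jonker-Volgenant style shortest augmenting path solver for the
// rectangular linear assignment problem. Requires nrow <= ncol; every row
// is assigned to a distinct column minimising the total cost.
// Returns 1-based column index per row.
// [[Rcpp::export(name = ".lapSolve")]]
IntegerVector lapSolve(NumericMatrix cost) {
  const int n = cost.nrow();
  const int m = cost.ncol();
  if (n == 0) return IntegerVector(0);
  if (n > m) stop("cost matrix must have nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();

  // potentials and matching; col0 index 0 is a virtual column
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0);     // p[j]: row matched to column j (1-based)
  std::vector<int> way(m + 1, 0);

  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else { minv[j] -= delta; }
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }

  IntegerVector assign(n);
  for (int j = 1; j <= m; ++j)
    if (p[j] > 0) assign[p[j] - 1] = j;
  return assign;
}
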