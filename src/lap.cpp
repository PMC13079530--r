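#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Rectangular minimum-cost assignment (rows <= cols) by successive shortest
// augmenting paths with dual potentials (Jonker-Volgenant family). Every row
// is assigned to a distinct column; the total cost is globally minimal.
// Complexity O(nr^2 * nc); dense doubles. Deterministic: ties resolved by
// the lowest column index (columns are scanned in order and a strictly
// smaller reduced cost is required to move the minimum).
// [[Rcpp::export(name = ".lapAssign")]]
IntegerVector lapAssign(NumericMatrix cost) {
  const int nr = cost.nrow(), nc = cost.ncol();
  if (nr == 0) return IntegerVector(0);
  if (nr > nc) stop("assignment requires nrow(cost) <= ncol(cost)");
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      if (!std::isfinite(cost(i, j))) stop("cost matrix must be finite");

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(nr, 0.0), v(nc, 0.0), shortest(nc);
  std::vector<int> col4row(nr, -1), row4col(nc, -1), pred(nc, -1);
  std::vector<char> doneRow(nr), doneCol(nc);

  for (int curRow = 0; curRow < nr; ++curRow) {
    std::fill(doneRow.begin(), doneRow.end(), 0);
    std::fill(doneCol.begin(), doneCol.end(), 0);
    std::fill(shortest.begin(), shortest.end(), INF);
    double minVal = 0.0;
    int i = curRow, sink = -1;
    while (sink == -1) {
      doneRow[i] = 1;
      double lowest = INF;
      int jLow = -1;
      for (int j = 0; j < nc; ++j) {
        if (doneCol[j]) continue;
        double r = minVal + cost(i, j) - u[i] - v[j];
        if (r < shortest[j]) { shortest[j] = r; pred[j] = i; }
        if (shortest[j] < lowest ||
            (shortest[j] == lowest && row4col[j] == -1 && jLow != -1 &&
             row4col[jLow] != -1)) {
          lowest = shortest[j];
          jLow = j;
        }
      }
      if (jLow == -1 || lowest == INF) stop("assignment infeasible");
      minVal = lowest;
      doneCol[jLow] = 1;
      if (row4col[jLow] == -1) sink = jLow; else i = row4col[jLow];
    }
    u[curRow] += minVal;
    for (int ip = 0; ip < nr; ++ip)
      if (doneRow[ip] && ip != curRow)
        u[ip] += minVal - shortest[col4row[ip]];
    for (int j = 0; j < nc; ++j)
      if (doneCol[j])
        v[j] -= minVal - shortest[j];
    int j = sink;
    while (true) {
      int ip = pred[j];
      row4col[j] = ip;
      int jTmp = col4row[ip];
      col4row[ip] = j;
      if (ip == curRow) break;
      j = jTmp;
    }
  }

  IntegerVector out(nr);
  for (int i2 = 0; i2 < nr; ++i2) out[i2] = col4row[i2] + 1;  // 1-based
  return out;
}
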