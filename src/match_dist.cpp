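#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Case x control matching-distance matrix: Euclidean over standardized
// continuous variables plus a fixed penalty per mismatched categorical
// variable. Accumulation order mirrors the R reference (continuous
// variables in order, sqrt, then categorical penalties in order).
// [[Rcpp::export(name = ".distKernel")]]
NumericMatrix distKernel(NumericMatrix contCase, NumericMatrix contCtl,
                         IntegerMatrix catCase, IntegerMatrix catCtl,
                         double penalty) {
  const int nCa = std::max(contCase.nrow(), catCase.nrow());
  const int nCo = std::max(contCtl.nrow(), catCtl.nrow());
  const int nCont = contCase.ncol(), nCat = catCase.ncol();
  NumericMatrix D(nCa, nCo);
  for (int j = 0; j < nCo; ++j) {
    for (int i = 0; i < nCa; ++i) {
      double d2 = 0.0;
      for (int v = 0; v < nCont; ++v) {
        double dd = contCase(i, v) - contCtl(j, v);
        d2 += dd * dd;
      }
      double d = std::sqrt(d2);
      for (int v = 0; v < nCat; ++v)
        if (catCase(i, v) != catCtl(j, v)) d += penalty;
      D(i, j) = d;
    }
  }
  return D;
}
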