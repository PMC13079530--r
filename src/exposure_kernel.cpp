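#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double EARTH_RADIUS_KM = 6371.0088;

// Mirrors the R haversine kernel operation by operation so results are
// bit-identical to the reference implementation.
static inline double haversine(double lon1, double lat1,
                               double lon2, double lat2) {
  const double d = M_PI / 180.0;
  double sLat = std::sin((lat2 - lat1) * d / 2.0);
  double sLon = std::sin((lon2 - lon1) * d / 2.0);
  double sLat2 = sLat * sLat, sLon2 = sLon * sLon;
  double a = sLat2 + std::cos(lat1 * d) * std::cos(lat2 * d) * sLon2;
  return 2.0 * EARTH_RADIUS_KM * std::asin(std::min(1.0, std::sqrt(a)));
}

// R's `^` special-cases integer-valued exponents.
static inline double rpow(double x, double y) {
  if (y == 1.0) return x;
  if (y == 2.0) return x * x;
  return std::pow(x, y);
}

// Raw exposures for all definitions of ONE agent. Facilities are the
// agent's distinct sites; records reference them by 1-based index and must
// arrive in input-table order (inverse-distance-weighted sums accumulate in
// record order, matching the reference double loop exactly).
//
// defMetric: 0 = presence, 1 = count, 2 = idw_hazard
// defBuf/defLag: 1-based indices into buffers/lags.
// [[Rcpp::export(name = ".exposureKernel")]]
NumericMatrix exposureKernel(NumericVector pLon, NumericVector pLat,
                             IntegerVector pVisit,
                             NumericVector fLon, NumericVector fLat,
                             IntegerVector recFac, IntegerVector recYear,
                             NumericVector recHaz,
                             NumericVector buffers, IntegerVector lags,
                             IntegerVector defMetric, IntegerVector defBuf,
                             IntegerVector defLag,
                             double floorKm, double expo) {
  const int nI = pLon.size(), nF = fLon.size(), nR = recFac.size();
  const int nB = buffers.size(), nL = lags.size(), nD = defMetric.size();
  NumericMatrix out(nD, nI);
  const int maxLag = nL ? *std::max_element(lags.begin(), lags.end()) : 0;
  double maxBuf = 0.0;
  for (int b = 0; b < nB; ++b) maxBuf = std::max(maxBuf, buffers[b]);

  std::vector<double> dist(nF), term(nF);
  std::vector<int> minDelta(nF);
  // long-double accumulation mirrors base R's summation exactly
  std::vector<long double> idw(nB * nL);
  std::vector<int> cnt(nB * nL);

  for (int i = 0; i < nI; ++i) {
    for (int f = 0; f < nF; ++f) {
      dist[f] = haversine(pLon[i], pLat[i], fLon[f], fLat[f]);
      term[f] = rpow(std::max(dist[f], floorKm), expo);
      minDelta[f] = std::numeric_limits<int>::max();
    }
    std::fill(idw.begin(), idw.end(), (long double) 0.0);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int r = 0; r < nR; ++r) {
      int delta = pVisit[i] - recYear[r];
      if (delta < 1 || delta > maxLag) continue;
      int f = recFac[r] - 1;
      if (delta < minDelta[f]) minDelta[f] = delta;
      if (dist[f] > maxBuf) continue;
      double w = recHaz[r] / term[f];
      for (int b = 0; b < nB; ++b) {
        if (dist[f] > buffers[b]) continue;
        for (int l = 0; l < nL; ++l)
          if (delta <= lags[l]) idw[b * nL + l] += w;
      }
    }
    for (int f = 0; f < nF; ++f) {
      if (minDelta[f] > maxLag || dist[f] > maxBuf) continue;
      for (int b = 0; b < nB; ++b) {
        if (dist[f] > buffers[b]) continue;
        for (int l = 0; l < nL; ++l)
          if (minDelta[f] <= lags[l]) ++cnt[b * nL + l];
      }
    }
    for (int dIx = 0; dIx < nD; ++dIx) {
      int cell = (defBuf[dIx] - 1) * nL + (defLag[dIx] - 1);
      switch (defMetric[dIx]) {
        case 0: out(dIx, i) = cnt[cell] > 0 ? 1.0 : 0.0; break;
        case 1: out(dIx, i) = cnt[cell]; break;
        default: out(dIx, i) = (double) idw[cell];
      }
    }
  }
  return out;
}
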