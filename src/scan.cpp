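#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive disk-scan: for every grid center (xc[j], yc[i]) count the points
// within `radius` (closed disk). Deliberately the naive O(centers x points)
// double loop — this is the reference computation the fast per-point
// accumulation in R is validated against.
// [[Rcpp::export(name = ".disk_scan_counts")]]
IntegerMatrix disk_scan_counts(NumericVector px, NumericVector py,
                               NumericVector xc, NumericVector yc,
                               double radius) {
  const int nr = yc.size(), nc = xc.size(), np = px.size();
  const double r2 = radius * radius;
  IntegerMatrix counts(nr, nc);
  const double *ppx = px.begin(), *ppy = py.begin();
  const double *pxc = xc.begin(), *pyc = yc.begin();
  int *out = counts.begin();
  for (int j = 0; j < nc; ++j) {
    const double x0 = pxc[j];
    for (int i = 0; i < nr; ++i) {
      const double y0 = pyc[i];
      int c = 0;
      for (int k = 0; k < np; ++k) {
        const double dx = x0 - ppx[k];
        const double dy = y0 - ppy[k];
        if (dx * dx + dy * dy <= r2) ++c;
      }
      out[j * nr + i] = c;
    }
  }
  return counts;
}
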