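#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Type-7 (linear interpolation) percentile via exact order statistics.
// buf is scratch of the same length as the column.
static double percentile7_partial(std::vector<double>& buf, double prob) {
  const size_t n = buf.size();
  const double h = (n - 1) * prob;
  const size_t lo = static_cast<size_t>(std::floor(h));
  const double w = h - lo;
  std::nth_element(buf.begin(), buf.begin() + lo, buf.end());
  const double vlo = buf[lo];
  if (w == 0.0) return vlo;
  const double vhi = *std::min_element(buf.begin() + lo + 1, buf.end());
  return vlo + w * (vhi - vlo);
}

// Percentile-based contrast (I95 - I5) / (I95 + I5) of every column of m.
// Columns whose denominator is not positive yield NA.
// [[Rcpp::export]]
NumericVector col_contrast_cpp(NumericMatrix m) {
  const int n = m.nrow(), k = m.ncol();
  NumericVector out(k);
  std::vector<double> buf(n);
  for (int j = 0; j < k; ++j) {
    for (int i = 0; i < n; ++i) buf[i] = m(i, j);
    const double p5 = percentile7_partial(buf, 0.05);
    for (int i = 0; i < n; ++i) buf[i] = m(i, j);
    const double p95 = percentile7_partial(buf, 0.95);
    const double den = p95 + p5;
    out[j] = (den > 0.0) ? (p95 - p5) / den : NA_REAL;
  }
  return out;
}

// Contrast curves for every ROI of a [y, x, z] stack in one pass.
// rs/re/cs/ce: 1-based inclusive row/column ranges of the ROI grid.
// Returns an (nROI x nz) matrix, ROIs in row-major (i, j) order.
template <typename V>
static NumericMatrix roi_contrast_impl(const V& a, int ny, int nx, int nz,
                                       const IntegerVector& rs, const IntegerVector& re,
                                       const IntegerVector& cs, const IntegerVector& ce) {
  const int gr = rs.size(), gc = cs.size();
  NumericMatrix out(gr * gc, nz);
  std::vector<double> buf;
  const R_xlen_t plane = static_cast<R_xlen_t>(ny) * nx;
  for (int k = 0; k < nz; ++k) {
    const R_xlen_t zoff = static_cast<R_xlen_t>(k) * plane;
    for (int gi = 0; gi < gr; ++gi) {
      for (int gj = 0; gj < gc; ++gj) {
        buf.clear();
        for (int c = cs[gj] - 1; c < ce[gj]; ++c) {
          const R_xlen_t coff = zoff + static_cast<R_xlen_t>(c) * ny;
          for (int r = rs[gi] - 1; r < re[gi]; ++r)
            buf.push_back(static_cast<double>(a[coff + r]));
        }
        std::vector<double> tmp(buf);
        const double p5 = percentile7_partial(tmp, 0.05);
        tmp = buf;
        const double p95 = percentile7_partial(tmp, 0.95);
        const double den = p95 + p5;
        out(gi * gc + gj, k) = (den > 0.0) ? (p95 - p5) / den : NA_REAL;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix roi_contrast_cpp(SEXP data, IntegerVector dim,
                               IntegerVector rs, IntegerVector re,
                               IntegerVector cs, IntegerVector ce) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  if (TYPEOF(data) == INTSXP) {
    IntegerVector a(data);
    return roi_contrast_impl(a, ny, nx, nz, rs, re, cs, ce);
  }
  NumericVector a(data);
  return roi_contrast_impl(a, ny, nx, nz, rs, re, cs, ce);
}
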