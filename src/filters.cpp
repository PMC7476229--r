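#include <Rcpp.h>
using namespace Rcpp;

// Zero-phase cascaded-biquad filtering over the columns of a matrix.
//
// x   : samples x channels
// sos : sections x 6, rows are (b0, b1, b2, a0, a1, a2) with a0 == 1
//
// Each section is applied forward then backward (direct form II
// transposed), so the cascade has zero phase and squared magnitude.
// Edge handling (reflection padding) is done by the R caller.
// [[Rcpp::export]]
NumericMatrix sosFiltFiltCpp(NumericMatrix x, NumericMatrix sos) {
  int n = x.nrow(), nc = x.ncol(), ns = sos.nrow();
  NumericMatrix y = clone(x);
  for (int c = 0; c < nc; ++c) {
    double *col = &y(0, c);
    for (int s = 0; s < ns; ++s) {
      double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
      double a1 = sos(s, 4), a2 = sos(s, 5);
      double z1 = 0.0, z2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double xi = col[i];
        double yi = b0 * xi + z1;
        z1 = b1 * xi - a1 * yi + z2;
        z2 = b2 * xi - a2 * yi;
        col[i] = yi;
      }
      z1 = z2 = 0.0;
      for (int i = n - 1; i >= 0; --i) {
        double xi = col[i];
        double yi = b0 * xi + z1;
        z1 = b1 * xi - a1 * yi + z2;
        z2 = b2 * xi - a2 * yi;
        col[i] = yi;
      }
    }
  }
  return y;
}

// Minimum over all length-w sliding windows of (max - min), per column.
// Used for the flatline artifact criterion: a channel is flat when some
// window's peak-to-peak range falls below the threshold.
// [[Rcpp::export]]
NumericVector slidingMinRangeCpp(NumericMatrix x, int w) {
  int n = x.nrow(), nc = x.ncol();
  NumericVector out(nc);
  if (w > n) {
    out.fill(NA_REAL);
    return out;
  }
  for (int c = 0; c < nc; ++c) {
    double best = R_PosInf;
    for (int s = 0; s + w <= n; ++s) {
      double mn = x(s, c), mx = x(s, c);
      for (int i = s + 1; i < s + w; ++i) {
        double v = x(i, c);
        if (v < mn) mn = v;
        if (v > mx) mx = v;
      }
      double r = mx - mn;
      if (r < best) best = r;
    }
    out[c] = best;
  }
  return out;
}
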