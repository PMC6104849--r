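#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Line-of-sight reference semantics, compiled for speed. Must mirror the R
// implementation in R/viewshed.R expression-for-expression: the test suite
// asserts exact (bitwise-decision) agreement between the two.
//
// Grid convention: z is nrows x ncols, row 1 (index 0) southernmost.
// Observer/target indices are 1-based (row, col) as in R.

// [[Rcpp::export]]
LogicalMatrix viewshed_cpp(NumericMatrix z, double ox, double oy, double cs,
                           int r0, int c0, double eye, double max_range) {
  const int nr = z.nrow(), nc = z.ncol();
  LogicalMatrix mask(nr, nc);
  const double z00 = z(r0 - 1, c0 - 1);
  if (ISNAN(z00)) stop("observer cell is nodata");
  const double zo = z00 + eye;
  const double x0c = ox + (c0 - 0.5) * cs;
  const double y0c = oy + (r0 - 0.5) * cs;
  const double step = cs / 2.0;

  const int rad = (int)std::ceil(max_range / cs) + 1;
  const int rlo = std::max(1, r0 - rad), rhi = std::min(nr, r0 + rad);
  const int clo = std::max(1, c0 - rad), chi = std::min(nc, c0 + rad);

  for (int rt = rlo; rt <= rhi; ++rt) {
    for (int ct = clo; ct <= chi; ++ct) {
      const double dx = (double)(ct - c0) * cs;
      const double dy = (double)(rt - r0) * cs;
      const double d = std::sqrt(dx * dx + dy * dy);
      if (d > max_range) continue;
      if (rt == r0 && ct == c0) { mask(rt - 1, ct - 1) = true; continue; }
      const double zt = z(rt - 1, ct - 1);
      if (ISNAN(zt)) continue;
      const double tan_t = (zt - zo) / d;

      long K = (long)std::floor(d / step);
      while (K >= 1 && (double)K * step >= d) --K;
      while (((double)(K + 1) * step) < d) ++K;

      bool vis = true;
      for (long k = 1; k <= K; ++k) {
        const double s = (double)k * step;
        const double f = s / d;
        const double px = x0c + dx * f;
        const double py = y0c + dy * f;
        const int sc = (int)std::floor((px - ox) / cs) + 1;
        const int sr = (int)std::floor((py - oy) / cs) + 1;
        if (sr < 1 || sr > nr || sc < 1 || sc > nc) continue;
        if ((sr == r0 && sc == c0) || (sr == rt && sc == ct)) continue;
        const double zs = z(sr - 1, sc - 1);
        if (ISNAN(zs)) continue;            // nodata neither occludes nor shows
        if ((zs - zo) / s > tan_t) { vis = false; break; }
      }
      mask(rt - 1, ct - 1) = vis;
    }
  }
  return mask;
}
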