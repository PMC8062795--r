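// Edge-width estimation by tracing along the dominant gradient axis.
//
// For each marked edge pixel the trace walks, one pixel at a time, in the
// direction of increasing intensity until the first local maximum and in the
// opposite direction until the first local minimum ("nearest plateau end":
// the walk stops as soon as the next pixel fails to continue strictly
// monotonically).  The edge width is the distance in pixels between the two
// extrema; the local contrast is the intensity difference between them.

#include <Rcpp.h>
using namespace Rcpp;

// img: H x W matrix (0-255 working scale); mask: logical H x W;
// gx, gy: Sobel responses (column resp. row derivative).
// Returns per measurable edge pixel: row, col (1-based), width, contrast.
// [[Rcpp::export]]
DataFrame trace_edge_widths(NumericMatrix img, LogicalMatrix mask,
                            NumericMatrix gx, NumericMatrix gy) {
  const int H = img.nrow(), W = img.ncol();
  std::vector<int> ri, ci;
  std::vector<double> wd, ct;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      const bool vertical = std::abs(gy(i, j)) >= std::abs(gx(i, j));
      const double g = vertical ? gy(i, j) : gx(i, j);
      if (g == 0.0) continue;                 // no derivative along the axis
      const int s = g > 0 ? 1 : -1;
      // walk towards increasing intensity
      int hi = vertical ? i : j;
      const int lim = vertical ? H : W;
      while (true) {
        int nxt = hi + s;
        if (nxt < 0 || nxt >= lim) break;
        double cur = vertical ? img(hi, j) : img(i, hi);
        double nv  = vertical ? img(nxt, j) : img(i, nxt);
        if (nv > cur) hi = nxt; else break;
      }
      // walk towards decreasing intensity
      int lo = vertical ? i : j;
      while (true) {
        int nxt = lo - s;
        if (nxt < 0 || nxt >= lim) break;
        double cur = vertical ? img(lo, j) : img(i, lo);
        double nv  = vertical ? img(nxt, j) : img(i, nxt);
        if (nv < cur) lo = nxt; else break;
      }
      const int width = std::abs(hi - lo);
      if (width < 1) continue;                // border / flat: not measurable
      double a = vertical ? img(hi, j) : img(i, hi);
      double b = vertical ? img(lo, j) : img(i, lo);
      ri.push_back(i + 1);
      ci.push_back(j + 1);
      wd.push_back((double)width);
      ct.push_back(std::abs(a - b));
    }
  }
  return DataFrame::create(_["row"] = ri, _["col"] = ci,
                           _["width"] = wd, _["contrast"] = ct);
}
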