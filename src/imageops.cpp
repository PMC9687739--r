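#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Neighbour offsets: 4-connectivity first, diagonals appended for 8.
static const int DR8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC8[8] = {0, 0, -1, 1, -1, 1, -1, 1};

// Label connected components of a logical mask (row/col grid stored
// column-major as in R). Labels are 1..n in order of first encounter
// scanning rows within columns top-left first in row-major order.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  int nn = (connectivity == 8) ? 8 : 4;
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  // row-major scan so the first pixel of component k is its row-major
  // top-left-most pixel
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc2 = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int r2 = cr + DR8[k], c2 = cc2 + DC8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Flood fill from (sr, sc) (0-based) over pixels with intensity >= thr.
// [[Rcpp::export(name = ".flood_fill")]]
LogicalMatrix flood_fill(NumericMatrix img, int sr, int sc, double thr,
                         int connectivity) {
  int nr = img.nrow(), nc = img.ncol();
  int nn = (connectivity == 8) ? 8 : 4;
  LogicalMatrix out(nr, nc);
  if (sr < 0 || sr >= nr || sc < 0 || sc >= nc) stop("seed outside image");
  if (img(sr, sc) < thr) stop("seed intensity below threshold");
  std::vector<int> stack;
  out(sr, sc) = true;
  stack.push_back(sr + sc * nr);
  while (!stack.empty()) {
    int idx = stack.back();
    stack.pop_back();
    int cr = idx % nr, cc2 = idx / nr;
    for (int k = 0; k < nn; ++k) {
      int r2 = cr + DR8[k], c2 = cc2 + DC8[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!out(r2, c2) && img(r2, c2) >= thr) {
        out(r2, c2) = true;
        stack.push_back(r2 + c2 * nr);
      }
    }
  }
  return out;
}
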