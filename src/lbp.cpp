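#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rotation-invariant uniform LBP codes (P=8, R=1) for one 2D slice.
// Sampling points lie on the radius-1 circle (diagonals bilinearly
// interpolated); a neighbor counts as 1 when its value >= center.
// Codes: 0..8 = number of ones for uniform patterns (<= 2 circular 0/1
// transitions), 9 = non-uniform. Border pixels (no full neighborhood)
// get code -1; callers pad the slice so the region of interest is interior.
// [[Rcpp::export]]
IntegerMatrix lbp_codes_cpp(const NumericMatrix& img) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), -1);
  const double s = std::sqrt(0.5);
  // (dr, dc) around the circle in circular order
  const double dr[8] = {0, s, 1, s, 0, -s, -1, -s};
  const double dc[8] = {1, s, 0, -s, -1, -s, 0, s};
  for (int c = 1; c < nc - 1; ++c) {
    for (int r = 1; r < nr - 1; ++r) {
      const double cen = img(r, c);
      int bits[8];
      for (int k = 0; k < 8; ++k) {
        const double rr = r + dr[k], cc = c + dc[k];
        const int r0 = (int)std::floor(rr), c0 = (int)std::floor(cc);
        const double fr = rr - r0, fc = cc - c0;
        double v;
        if (fr == 0.0 && fc == 0.0) {
          v = img(r0, c0);
        } else {
          v = (1 - fr) * (1 - fc) * img(r0, c0)
            + (1 - fr) * fc * img(r0, c0 + 1)
            + fr * (1 - fc) * img(r0 + 1, c0)
            + fr * fc * img(r0 + 1, c0 + 1);
        }
        bits[k] = (v >= cen) ? 1 : 0;
      }
      int ones = 0, trans = 0;
      for (int k = 0; k < 8; ++k) {
        ones += bits[k];
        trans += (bits[k] != bits[(k + 1) % 8]) ? 1 : 0;
      }
      out(r, c) = (trans <= 2) ? ones : 9;
    }
  }
  return out;
}
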