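#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Zhang-Suen thinning of a 2D binary image; returns the 1-pixel-wide
// skeleton (medial axis approximation) used for per-slice length estimates.
// [[Rcpp::export]]
LogicalMatrix thin_zs_cpp(const LogicalMatrix& img) {
  const int nr = img.nrow(), nc = img.ncol();
  // pad by 1 to avoid bounds checks
  std::vector<uint8_t> a((nr + 2) * (nc + 2), 0);
  auto at = [&](int r, int c) -> uint8_t& { return a[(c) * (nr + 2) + (r)]; };
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      at(r + 1, c + 1) = img(r, c) ? 1 : 0;

  std::vector<std::pair<int, int>> del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int c = 1; c <= nc; ++c) {
        for (int r = 1; r <= nr; ++r) {
          if (!at(r, c)) continue;
          // neighbors P2..P9 clockwise from north
          const int p2 = at(r - 1, c),     p3 = at(r - 1, c + 1);
          const int p4 = at(r, c + 1),     p5 = at(r + 1, c + 1);
          const int p6 = at(r + 1, c),     p7 = at(r + 1, c - 1);
          const int p8 = at(r, c - 1),     p9 = at(r - 1, c - 1);
          const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = 0;
          const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          for (int k = 0; k < 8; ++k)
            if (seq[k] == 0 && seq[k + 1] == 1) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back({r, c});
        }
      }
      for (auto& rc : del) at(rc.first, rc.second) = 0;
      if (!del.empty()) changed = true;
    }
  }

  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = at(r + 1, c + 1) != 0;
  return out;
}
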