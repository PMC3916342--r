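#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a 3D logical array (dims z,y,x) with
// 6, 18 or 26 connectivity. Labels are positive integers assigned in scan
// order (deterministic); background = 0.
// [[Rcpp::export]]
IntegerVector label_cc3d_cpp(const LogicalVector& mask, const IntegerVector& dims,
                             int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbor offsets
  std::vector<int> dz, dy, dx;
  for (int az = -1; az <= 1; ++az)
    for (int ay = -1; ay <= 1; ++ay)
      for (int ax = -1; ax <= 1; ++ax) {
        const int s = std::abs(az) + std::abs(ay) + std::abs(ax);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        dz.push_back(az); dy.push_back(ay); dx.push_back(ax);
      }
  const int ndir = (int)dz.size();

  IntegerVector labels(n);
  const int* m = LOGICAL(mask);
  int* lab = INTEGER(labels);
  std::vector<R_xlen_t> stack;
  int next = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!m[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      const R_xlen_t v = stack.back();
      stack.pop_back();
      const int z = (int)(v % nz);
      const int y = (int)((v / nz) % ny);
      const int x = (int)(v / ((R_xlen_t)nz * ny));
      for (int d = 0; d < ndir; ++d) {
        const int zz = z + dz[d], yy = y + dy[d], xx = x + dx[d];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        const R_xlen_t u = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (m[u] && lab[u] == 0) { lab[u] = next; stack.push_back(u); }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
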