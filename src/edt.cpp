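#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1D squared distance transform (Felzenszwalb & Huttenlocher) on a grid with
// physical sample spacing w.
static void dt1d(std::vector<double>& f, double w) {
  const int n = (int)f.size();
  if (n == 1) return;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;  // +inf parabolas never enter the envelope
    const double xq = w * q;
    double s = 0.0;
    while (k >= 0) {
      const double xv = w * v[k];
      if (f[v[k]] == INF) { --k; continue; }  // dominated everywhere
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (s <= z[k]) --k; else break;
    }
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
    }
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = w * q;
    while (z[k + 1] < xq) ++k;
    const double dx = xq - w * v[k];
    d[q] = dx * dx + f[v[k]];
  }
  f = d;
}

// Squared anisotropic Euclidean distance to the nearest true voxel of a 3D
// mask (dims z,y,x). weights give physical spacing per axis; a non-finite
// weight disables propagation along that axis.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(const LogicalVector& mask, const IntegerVector& dims,
                         const NumericVector& weights) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  double* o = REAL(out);
  const int* m = LOGICAL(mask);
  for (R_xlen_t i = 0; i < n; ++i) o[i] = m[i] ? 0.0 : INF;

  std::vector<double> line;
  // axis z (stride 1)
  if (R_finite(weights[0]) && nz > 1) {
    line.resize(nz);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        const R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        for (int z = 0; z < nz; ++z) line[z] = o[base + z];
        dt1d(line, weights[0]);
        for (int z = 0; z < nz; ++z) o[base + z] = line[z];
      }
  }
  // axis y (stride nz)
  if (R_finite(weights[1]) && ny > 1) {
    line.resize(ny);
    for (int x = 0; x < nx; ++x)
      for (int z = 0; z < nz; ++z) {
        const R_xlen_t base = z + (R_xlen_t)nz * ny * x;
        for (int y = 0; y < ny; ++y) line[y] = o[base + (R_xlen_t)nz * y];
        dt1d(line, weights[1]);
        for (int y = 0; y < ny; ++y) o[base + (R_xlen_t)nz * y] = line[y];
      }
  }
  // axis x (stride nz*ny)
  if (R_finite(weights[2]) && nx > 1) {
    line.resize(nx);
    const R_xlen_t sx = (R_xlen_t)nz * ny;
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        const R_xlen_t base = z + (R_xlen_t)nz * y;
        for (int x = 0; x < nx; ++x) line[x] = o[base + sx * x];
        dt1d(line, weights[2]);
        for (int x = 0; x < nx; ++x) o[base + sx * x] = line[x];
      }
  }
  out.attr("dim") = dims;
  return out;
}
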