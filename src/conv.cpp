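#include <Rcpp.h>
using namespace Rcpp;

// Reflect (half-sample symmetric) index into [0, n).
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  // period of the reflected signal is 2n
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// 1D correlation of a 3D array (dims z,y,x; z fastest as in R) along one
// axis with reflective boundary handling. axis: 0=z, 1=y, 2=x.
// [[Rcpp::export]]
NumericVector conv_axis_cpp(const NumericVector& x, const IntegerVector& dims,
                            const NumericVector& kernel, int axis) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = nz * ny * nx;
  const int klen = kernel.size();
  const int r = (klen - 1) / 2;
  if (klen % 2 != 1) stop("kernel length must be odd");
  if (axis < 0 || axis > 2) stop("axis must be 0, 1 or 2");

  int na, inner, outer;
  if (axis == 0)      { na = nz; inner = 1;       outer = ny * nx; }
  else if (axis == 1) { na = ny; inner = nz;      outer = nx; }
  else                { na = nx; inner = nz * ny; outer = 1; }

  // source coordinate for each (axis position, tap)
  std::vector<int> src((size_t)na * klen);
  for (int c = 0; c < na; ++c)
    for (int t = 0; t < klen; ++t)
      src[(size_t)c * klen + t] = reflect_index(c + t - r, na);

  NumericVector out(n);
  const double* __restrict__ in = REAL(x);
  double* __restrict__ o = REAL(out);
  const double* __restrict__ k = REAL(kernel);

  const size_t stride = (size_t)na * inner;
  for (int ob = 0; ob < outer; ++ob) {
    const size_t base = (size_t)ob * stride;
    for (int c = 0; c < na; ++c) {
      double* __restrict__ orow = o + base + (size_t)c * inner;
      if (inner == 1) {
        double acc = 0.0;
        const int* s = &src[(size_t)c * klen];
        for (int t = 0; t < klen; ++t) acc += k[t] * in[base + s[t]];
        orow[0] = acc;
      } else {
        for (int t = 0; t < klen; ++t) {
          const double kv = k[t];
          const double* __restrict__ irow =
            in + base + (size_t)src[(size_t)c * klen + t] * inner;
          for (int i = 0; i < inner; ++i) orow[i] += kv * irow[i];
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
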