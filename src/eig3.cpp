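#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Eigenvalues of symmetric 3x3 matrices, one per voxel, sorted descending.
// Analytic (trigonometric) method; exact diagonal shortcut for the
// off-diagonal-free case.
// [[Rcpp::export]]
NumericMatrix eig3_sym_cpp(const NumericVector& a11, const NumericVector& a12,
                           const NumericVector& a13, const NumericVector& a22,
                           const NumericVector& a23, const NumericVector& a33) {
  const R_xlen_t n = a11.size();
  NumericMatrix out(n, 3);
  const double two_pi_3 = 2.0 * M_PI / 3.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double A11 = a11[i], A12 = a12[i], A13 = a13[i];
    const double A22 = a22[i], A23 = a23[i], A33 = a33[i];
    double e1, e2, e3;
    const double p1 = A12 * A12 + A13 * A13 + A23 * A23;
    if (p1 == 0.0) {
      e1 = A11; e2 = A22; e3 = A33;
    } else {
      const double q = (A11 + A22 + A33) / 3.0;
      const double b11 = A11 - q, b22 = A22 - q, b33 = A33 - q;
      const double p2 = b11 * b11 + b22 * b22 + b33 * b33 + 2.0 * p1;
      const double p = std::sqrt(p2 / 6.0);
      // det(B)/2 with B = (A - qI)/p
      const double c11 = b11 / p, c22 = b22 / p, c33 = b33 / p;
      const double c12 = A12 / p, c13 = A13 / p, c23 = A23 / p;
      double r = 0.5 * (c11 * (c22 * c33 - c23 * c23)
                        - c12 * (c12 * c33 - c23 * c13)
                        + c13 * (c12 * c23 - c22 * c13));
      if (r < -1.0) r = -1.0;
      if (r > 1.0) r = 1.0;
      const double phi = std::acos(r) / 3.0;
      e1 = q + 2.0 * p * std::cos(phi);
      e3 = q + 2.0 * p * std::cos(phi + two_pi_3);
      e2 = 3.0 * q - e1 - e3;
    }
    // sort descending
    if (e1 < e2) std::swap(e1, e2);
    if (e2 < e3) std::swap(e2, e3);
    if (e1 < e2) std::swap(e1, e2);
    out(i, 0) = e1; out(i, 1) = e2; out(i, 2) = e3;
  }
  return out;
}
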