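#include <Rcpp.h>
using namespace Rcpp;

// Evaluate a flattened random forest (ranger trees exported via treeInfo)
// on a feature matrix, averaging per-tree leaf class fractions. Traversal
// follows ranger's rule: go left when x[splitvar] <= splitval.
// Arrays are concatenated over trees; `offsets` gives each tree's first
// node index; children/splitvar are node-local indices within the tree
// (-1 marks a terminal child slot).
// [[Rcpp::export]]
NumericMatrix predict_flat_forest_cpp(const NumericMatrix& X,
                                      const IntegerVector& offsets,
                                      const IntegerVector& left,
                                      const IntegerVector& right,
                                      const IntegerVector& splitvar,
                                      const NumericVector& splitval,
                                      const NumericMatrix& leafprob) {
  const int n = X.nrow();
  const int ntree = offsets.size();
  const int nclass = leafprob.ncol();
  NumericMatrix out(n, nclass);
  const double* x = REAL(X);
  const int nrx = n;
  for (int t = 0; t < ntree; ++t) {
    const int off = offsets[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (left[off + node] >= 0) {
        const double v = x[(size_t)splitvar[off + node] * nrx + i];
        node = (v <= splitval[off + node]) ? left[off + node]
                                           : right[off + node];
      }
      for (int c = 0; c < nclass; ++c)
        out(i, c) += leafprob(off + node, c);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < nclass; ++c) out(i, c) /= ntree;
  return out;
}
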