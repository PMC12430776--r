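// Gather/scatter kernels for expressing 3x3 (dilated) convolutions and
// patch embedding as dense matrix products. Index matrices are 1-based;
// the value n+1 addresses an implicit zero-padding row.
#include <Rcpp.h>
using namespace Rcpp;

// x: n x C feature matrix; idx: m x T tap index matrix.
// Returns m x (T*C), tap-major blocks [tap1 ch1..C | tap2 ch1..C | ...].
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& x, const IntegerMatrix& idx) {
  const int n = x.nrow(), C = x.ncol(), m = idx.nrow(), T = idx.ncol();
  NumericMatrix out(m, T * C);
  for (int t = 0; t < T; ++t) {
    for (int c = 0; c < C; ++c) {
      const int oc = t * C + c;
      const double* xc = &x(0, c);
      double* o = &out(0, oc);
      const int* ix = &idx(0, t);
      for (int p = 0; p < m; ++p) {
        const int r = ix[p] - 1;
        o[p] = (r < n) ? xc[r] : 0.0;
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add g (m x T*C) back to an n x C grid.
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& g, const IntegerMatrix& idx,
                         const int n) {
  const int m = idx.nrow(), T = idx.ncol();
  const int C = g.ncol() / T;
  NumericMatrix out(n, C);
  for (int t = 0; t < T; ++t) {
    for (int c = 0; c < C; ++c) {
      const int gc = t * C + c;
      const double* gv = &g(0, gc);
      double* o = &out(0, c);
      const int* ix = &idx(0, t);
      for (int p = 0; p < m; ++p) {
        const int r = ix[p] - 1;
        if (r < n) o[r] += gv[p];
      }
    }
  }
  return out;
}
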