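// Hot loops of the 1D convolution pipeline. Everything operates on the
// "channel matrix" layout: a batch of n trials with ch channels and L
// samples per trial stored column-major as ch x (L * n), trial-major in
// columns. Matrix products stay in R (BLAS); these kernels only do the
// gather/scatter work that is slow in interpreted code.

#include <Rcpp.h>
using namespace Rcpp;

// ch x (L*n) -> (ch*k) x (Lo*n), Lo = L - k + 1 (stride 1, no padding).
// Row block j holds the input shifted by j samples.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& cmat, int k, int L, int n) {
  const int ch = cmat.nrow();
  const int Lo = L - k + 1;
  NumericMatrix out(ch * k, Lo * n);
  for (int t = 0; t < n; ++t) {
    for (int s = 0; s < Lo; ++s) {
      const int oc = t * Lo + s;
      for (int j = 0; j < k; ++j) {
        const int ic = t * L + s + j;
        for (int c = 0; c < ch; ++c)
          out(j * ch + c, oc) = cmat(c, ic);
      }
    }
  }
  return out;
}

// adjoint of im2col: (ch*k) x (Lo*n) -> ch x (L*n), accumulating overlaps
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dcol, int ch, int k, int L, int n) {
  const int Lo = L - k + 1;
  NumericMatrix out(ch, L * n);
  for (int t = 0; t < n; ++t) {
    for (int s = 0; s < Lo; ++s) {
      const int oc = t * Lo + s;
      for (int j = 0; j < k; ++j) {
        const int ic = t * L + s + j;
        for (int c = 0; c < ch; ++c)
          out(c, ic) += dcol(j * ch + c, oc);
      }
    }
  }
  return out;
}

// max pooling with window == stride == k; ties keep the earliest sample.
// Returns pooled values and 1-based argmax offsets within each window.
// [[Rcpp::export]]
List cpp_maxpool_fwd(const NumericMatrix& mat, int k, int L, int n) {
  const int ch = mat.nrow();
  const int Lp = L / k;
  NumericMatrix pooled(ch, Lp * n);
  IntegerMatrix arg(ch, Lp * n);
  for (int t = 0; t < n; ++t) {
    for (int u = 0; u < Lp; ++u) {
      const int oc = t * Lp + u;
      const int base = t * L + u * k;
      for (int c = 0; c < ch; ++c) {
        double best = mat(c, base);
        int bj = 0;
        for (int j = 1; j < k; ++j) {
          const double v = mat(c, base + j);
          if (v > best) { best = v; bj = j; }
        }
        pooled(c, oc) = best;
        arg(c, oc) = bj + 1;
      }
    }
  }
  return List::create(_["pooled"] = pooled, _["arg"] = arg);
}

// route pooled gradients back to the argmax positions
// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(const NumericMatrix& d, const IntegerMatrix& arg,
                              int k, int L, int n) {
  const int ch = d.nrow();
  const int Lp = L / k;
  NumericMatrix out(ch, L * n);
  for (int t = 0; t < n; ++t) {
    for (int u = 0; u < Lp; ++u) {
      const int oc = t * Lp + u;
      const int base = t * L + u * k;
      for (int c = 0; c < ch; ++c)
        out(c, base + arg(c, oc) - 1) = d(c, oc);
    }
  }
  return out;
}
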