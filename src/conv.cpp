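#include <Rcpp.h>
using namespace Rcpp;

// Strided valid-padding convolution layers are expressed as one big matrix
// product; these two kernels only gather/scatter image patches. Array layout
// is column-major (H, W, C, N): row index fastest, then column, channel,
// sample. Patch columns are ordered (ho fastest, wo, n) and patch rows
// (kernel row fastest, kernel column, channel) so that a kernel array
// (kh, kw, C, Cout) flattened to a (kh*kw*C) x Cout matrix lines up directly.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int stride) {
  const int Ho = (H - kh) / stride + 1;
  const int Wo = (W - kw) / stride + 1;
  NumericMatrix out(kh * kw * C, Ho * Wo * N);
  const double* xp = x.begin();
  double* op = out.begin();
  const int prow = kh * kw * C;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double* col = op + (size_t)prow * ((size_t)n * Ho * Wo + (size_t)wo * Ho + ho);
        for (int c = 0; c < C; ++c) {
          for (int j = 0; j < kw; ++j) {
            const double* src = xp + ((size_t)(n * C + c) * W + (wo * stride + j)) * H
                                   + ho * stride;
            double* dst = col + (c * kw + j) * kh;
            for (int i = 0; i < kh; ++i) dst[i] = src[i];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-add patch columns back onto the image grid.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int kh, int kw, int stride) {
  const int Ho = (H - kh) / stride + 1;
  const int Wo = (W - kw) / stride + 1;
  NumericVector x((size_t)H * W * C * N);
  double* xp = x.begin();
  const double* op = cols.begin();
  const int prow = kh * kw * C;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double* col = op + (size_t)prow * ((size_t)n * Ho * Wo + (size_t)wo * Ho + ho);
        for (int c = 0; c < C; ++c) {
          for (int j = 0; j < kw; ++j) {
            double* dst = xp + ((size_t)(n * C + c) * W + (wo * stride + j)) * H
                             + ho * stride;
            const double* src = col + (c * kw + j) * kh;
            for (int i = 0; i < kh; ++i) dst[i] += src[i];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  return x;
}
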