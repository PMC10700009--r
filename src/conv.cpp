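#include <Rcpp.h>
using namespace Rcpp;

// Same-padded 2-D convolution over an image batch.
//
// x: (H, W, N, C) column-major (channels slowest), k: (kh, kw, Cin, Cout),
// returns (H, W, N, Cout). Loops are ordered so that for every output
// column (fixed image n and column w) all Cout destination strips stay in
// L1 cache while the kh*kw*Cin source taps are accumulated; the innermost
// loop is a contiguous axpy over the image rows.
// [[Rcpp::export]]
NumericVector conv_same_cpp(const NumericVector& x, const IntegerVector& xdim,
                            const NumericVector& k, const IntegerVector& kdim,
                            const NumericVector& bias) {
  const int H = xdim[0], W = xdim[1], N = xdim[2], C = xdim[3];
  const int kh = kdim[0], kw = kdim[1], Ci = kdim[2], Co = kdim[3];
  if (Ci != C) stop("channel mismatch in conv_same_cpp");
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const R_xlen_t HWN = static_cast<R_xlen_t>(H) * W * N;
  NumericVector y(HWN * Co);
  const double* __restrict__ xp = x.begin();
  const double* __restrict__ kp = k.begin();
  double* __restrict__ yp = y.begin();

  if (bias.size() == Co) {
    for (int co = 0; co < Co; ++co) {
      if (bias[co] != 0.0) {
        double b = bias[co];
        double* yc = yp + HWN * co;
        for (R_xlen_t i = 0; i < HWN; ++i) yc[i] = b;
      }
    }
  }

  for (int n = 0; n < N; ++n) {
    for (int w = 0; w < W; ++w) {
      const R_xlen_t dst_base = static_cast<R_xlen_t>(H) * (w + static_cast<R_xlen_t>(W) * n);
      for (int ci = 0; ci < C; ++ci) {
        for (int kj = 0; kj < kw; ++kj) {
          const int wsrc = w + kj - pw;
          if (wsrc < 0 || wsrc >= W) continue;
          const R_xlen_t src_base = HWN * ci + static_cast<R_xlen_t>(H) * (wsrc + static_cast<R_xlen_t>(W) * n);
          for (int ki = 0; ki < kh; ++ki) {
            const int dh = ki - ph;
            const int h0 = dh < 0 ? -dh : 0;
            const int h1 = dh > 0 ? H - dh : H;
            const double* __restrict__ src = xp + src_base + dh;
            for (int co = 0; co < Co; ++co) {
              const double wv = kp[ki + kh * (kj + kw * (ci + static_cast<R_xlen_t>(C) * co))];
              if (wv == 0.0) continue;
              double* __restrict__ dst = yp + HWN * co + dst_base;
              for (int h = h0; h < h1; ++h) dst[h] += wv * src[h];
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, N, Co);
  return y;
}
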