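#include <Rcpp.h>
using namespace Rcpp;

// im2col for an (H, W, C, N) array with implicit zero padding.
// Output: (Ho*Wo*N) x (kh*kw*C); column order kernel-offset fastest (row
// offset fastest within the kernel), then input channel; row order output
// position (column-major) fastest, then image. Matches the weight layout
// used by conv2d_init().
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int stride, int dil,
                         int padh, int padw, int Ho, int Wo) {
  const int KK = kh * kw;
  const int plane = H * W;
  NumericMatrix cols(Ho * Wo * N, KK * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int j = ki + kj * kh + c * KK;
        double *pc = &cols(0, j);
        for (int n = 0; n < N; ++n) {
          const double *pim = px + (size_t)(n * C + c) * plane;
          double *prow = pc + (size_t)n * Ho * Wo;
          for (int wo = 0; wo < Wo; ++wo) {
            const int cc = wo * stride + kj * dil - padw;
            if (cc < 0 || cc >= W) {
              for (int ho = 0; ho < Ho; ++ho) prow[ho + wo * Ho] = 0.0;
              continue;
            }
            const double *pcol = pim + (size_t)cc * H;
            for (int ho = 0; ho < Ho; ++ho) {
              const int rr = ho * stride + ki * dil - padh;
              prow[ho + wo * Ho] =
                (rr < 0 || rr >= H) ? 0.0 : pcol[rr];
            }
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of cpp_im2col: scatter-add column gradients back to the input.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dcols, int H, int W, int C, int N,
                         int kh, int kw, int stride, int dil,
                         int padh, int padw, int Ho, int Wo) {
  const int KK = kh * kw;
  const int plane = H * W;
  NumericVector dx((size_t)plane * C * N);
  double *px = dx.begin();
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int j = ki + kj * kh + c * KK;
        const double *pc = &dcols(0, j);
        for (int n = 0; n < N; ++n) {
          double *pim = px + (size_t)(n * C + c) * plane;
          const double *prow = pc + (size_t)n * Ho * Wo;
          for (int wo = 0; wo < Wo; ++wo) {
            const int cc = wo * stride + kj * dil - padw;
            if (cc < 0 || cc >= W) continue;
            double *pcol = pim + (size_t)cc * H;
            for (int ho = 0; ho < Ho; ++ho) {
              const int rr = ho * stride + ki * dil - padh;
              if (rr >= 0 && rr < H) pcol[rr] += prow[ho + wo * Ho];
            }
          }
        }
      }
    }
  }
  return dx;
}
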