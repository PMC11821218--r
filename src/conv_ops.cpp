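#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored as (B*H*W) x C matrices. Row index for pixel
// (r, c) of image b is b*H*W + c*H + r (0-based): column-major within an
// image, images stacked. Kernel taps are centred; zero padding keeps the
// spatial size (stride 1 throughout).

// [[Rcpp::export]]
NumericMatrix dc_im2col(const NumericMatrix& x, int B, int H, int W,
                        int kh, int kw, int rate) {
  const int C = x.ncol();
  const int HW = H * W;
  const int n = B * HW;
  const int hh = (kh - 1) / 2, hw = (kw - 1) / 2;
  NumericMatrix cols(n, kh * kw * C);
  for (int ch = 0; ch < C; ++ch) {
    for (int j = 0; j < kw; ++j) {
      const int dj = (j - hw) * rate;
      for (int i = 0; i < kh; ++i) {
        const int di = (i - hh) * rate;
        const int col = ch * kh * kw + j * kh + i;
        for (int b = 0; b < B; ++b) {
          const int base = b * HW;
          for (int cc = 0; cc < W; ++cc) {
            const int sc = cc + dj;
            if (sc < 0 || sc >= W) continue;
            const int src0 = base + sc * H;
            const int dst0 = base + cc * H;
            for (int rr = 0; rr < H; ++rr) {
              const int sr = rr + di;
              if (sr < 0 || sr >= H) continue;
              cols(dst0 + rr, col) = x(src0 + sr, ch);
            }
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of dc_im2col: scatter-adds column gradients back to the input
// feature map. Used for the input gradient of the dilated convolution.
// [[Rcpp::export]]
NumericMatrix dc_col2im(const NumericMatrix& dcols, int B, int H, int W,
                        int C, int kh, int kw, int rate) {
  const int HW = H * W;
  NumericMatrix dx(B * HW, C);
  const int hh = (kh - 1) / 2, hw = (kw - 1) / 2;
  for (int ch = 0; ch < C; ++ch) {
    for (int j = 0; j < kw; ++j) {
      const int dj = (j - hw) * rate;
      for (int i = 0; i < kh; ++i) {
        const int di = (i - hh) * rate;
        const int col = ch * kh * kw + j * kh + i;
        for (int b = 0; b < B; ++b) {
          const int base = b * HW;
          for (int cc = 0; cc < W; ++cc) {
            const int sc = cc + dj;
            if (sc < 0 || sc >= W) continue;
            const int src0 = base + sc * H;
            const int dst0 = base + cc * H;
            for (int rr = 0; rr < H; ++rr) {
              const int sr = rr + di;
              if (sr < 0 || sr >= H) continue;
              dx(src0 + sr, ch) += dcols(dst0 + rr, col);
            }
          }
        }
      }
    }
  }
  return dx;
}
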