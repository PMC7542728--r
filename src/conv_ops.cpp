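// Stride-1 2-D convolution kernels used by the generator, critic and U-Net.
// Tensors follow R's array layout: x[H, W, C, N] with H fastest, weights
// w[kh, kw, Cin, Cout]. im2col + BLAS gemm; padding is zero-fill.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void im2col(const double* x, int H, int W, int C,
                          int kh, int kw, int pad, int Ho, int Wo,
                          arma::mat& col) {
  // col is (kh*kw*C) x (Ho*Wo); row index r = a + kh*(b + kw*c)
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        int r = a + kh * (b + kw * c);
        for (int j = 0; j < Wo; ++j) {
          int wj = j + b - pad;
          if (wj < 0 || wj >= W) continue;
          const double* src = xc + (size_t)wj * H;
          double* dst = col.colptr(0) + r; // will index by column below
          for (int i = 0; i < Ho; ++i) {
            int hi = i + a - pad;
            if (hi < 0 || hi >= H) continue;
            col((size_t)r, (size_t)(i + Ho * j)) = src[hi];
          }
          (void)dst;
        }
      }
    }
  }
}

static inline void col2im(const arma::mat& col, int H, int W, int C,
                          int kh, int kw, int pad, int Ho, int Wo,
                          double* gx) {
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (size_t)c * H * W;
    for (int b = 0; b < kw; ++b) {
      for (int a = 0; a < kh; ++a) {
        int r = a + kh * (b + kw * c);
        for (int j = 0; j < Wo; ++j) {
          int wj = j + b - pad;
          if (wj < 0 || wj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            int hi = i + a - pad;
            if (hi < 0 || hi >= H) continue;
            xc[(size_t)wj * H + hi] += col((size_t)r, (size_t)(i + Ho * j));
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector bias,
                         int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch in conv2d_fwd");
  int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");

  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat col(kh * kw * Cin, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, pad, Ho, Wo, col);
    arma::mat ymat = Wm.t() * col; // Cout x (Ho*Wo)
    double* yp = y.begin() + (size_t)n * Ho * Wo * Cout;
    for (int c = 0; c < Cout; ++c) {
      double bc = bias[c];
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p)
        yp[(size_t)c * Ho * Wo + p] = ymat(c, p) + bc;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;

  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * Cin, Cout, false, true);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xd;
  NumericVector gw((size_t)kh * kw * Cin * Cout);
  gw.attr("dim") = wd;
  NumericVector gb(Cout);
  arma::mat gWm(gw.begin(), kh * kw * Cin, Cout, false, true);

  arma::mat col(kh * kw * Cin, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* gyp = gy.begin() + (size_t)n * Ho * Wo * Cout;
    arma::mat gymat(Cout, (size_t)Ho * Wo);
    for (int c = 0; c < Cout; ++c) {
      double s = 0.0;
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p) {
        double v = gyp[(size_t)c * Ho * Wo + p];
        gymat(c, p) = v;
        s += v;
      }
      gb[c] += s;
    }
    im2col(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, pad, Ho, Wo, col);
    gWm += col * gymat.t();
    arma::mat gcol = Wm * gymat; // (kh*kw*Cin) x (Ho*Wo)
    col2im(gcol, H, W, C, kh, kw, pad, Ho, Wo, gx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
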