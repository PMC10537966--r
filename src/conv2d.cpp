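#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 2-D convolution with stride and dilation via im2col + GEMM.
// Array layout is R column-major throughout:
//   x  : (H, W, Cin, N)      w : (K, K, Cin, Cout)     b : (Cout)
//   y  : (Ho, Wo, Cout, N)
// Output size: Ho = (H + 2*pad - (dilation*(K-1)+1)) / stride + 1.

static void im2col(const double* xp, arma::mat& col,
                   int H, int W, int C, int K,
                   int Ho, int Wo, int stride, int dilation, int pad) {
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * H * W;
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        int r = ki + K * kj + K * K * c;
        double* cc = col.colptr(r);
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow * stride - pad + kj * dilation;
          if (iw < 0 || iw >= W) continue;
          for (int oh = 0; oh < Ho; ++oh) {
            int ih = oh * stride - pad + ki * dilation;
            if (ih < 0 || ih >= H) continue;
            cc[oh + (size_t)Ho * ow] = xc[ih + (size_t)H * iw];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int dilation, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int K = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("conv2d: input has %d channels, kernel expects %d", C, wd[2]);
  int eff = dilation * (K - 1) + 1;
  int Ho = (H + 2 * pad - eff) / stride + 1;
  int Wo = (W + 2 * pad - eff) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)K * K * C, Cout, false, true);
  arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);

  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col((size_t)Ho * Wo, (size_t)K * K * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, col, H, W, C, K, Ho, Wo,
           stride, dilation, pad);
    arma::mat Y = col * Wm;
    Y.each_row() += bv;
    std::copy(Y.begin(), Y.end(), y.begin() + (size_t)n * Ho * Wo * Cout);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    int stride, int dilation, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  IntegerVector yd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int K = wd[0], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)K * K * C, Cout, false, true);
  arma::mat gW((size_t)K * K * C, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);

  NumericVector gx((R_xlen_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat col((size_t)Ho * Wo, (size_t)K * K * C);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * C, col, H, W, C, K, Ho, Wo,
           stride, dilation, pad);
    arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)n * Ho * Wo * Cout,
                 (size_t)Ho * Wo, Cout, false, true);
    gW += col.t() * Gy;
    gb += arma::sum(Gy, 0).t();
    arma::mat Gcol = Gy * Wm.t();  // (HoWo, K*K*C)
    double* gxp = gx.begin() + (size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      double* gxc = gxp + (size_t)c * H * W;
      for (int kj = 0; kj < K; ++kj) {
        for (int ki = 0; ki < K; ++ki) {
          int r = ki + K * kj + K * K * c;
          const double* gc = Gcol.colptr(r);
          for (int ow = 0; ow < Wo; ++ow) {
            int iw = ow * stride - pad + kj * dilation;
            if (iw < 0 || iw >= W) continue;
            for (int oh = 0; oh < Ho; ++oh) {
              int ih = oh * stride - pad + ki * dilation;
              if (ih < 0 || ih >= H) continue;
              gxc[ih + (size_t)H * iw] += gc[oh + (size_t)Ho * ow];
            }
          }
        }
      }
    }
  }

  NumericVector gWr(gW.begin(), gW.end());
  gWr.attr("dim") = IntegerVector::create(K, K, C, Cout);
  return List::create(_["gx"] = gx, _["gw"] = gWr,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}
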