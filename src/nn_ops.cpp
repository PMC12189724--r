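// Low-level neural-network primitives for the virtual-staining cGAN.
// Tensors are R 4-D arrays in (H, W, C, B) column-major layout; convolution
// is im2col + GEMM. All operators have exact hand-derived adjoints, verified
// against finite differences in the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Convolutions run in single precision: weights and activations of this
// model are O(1) in magnitude, sgemm roughly doubles GEMM throughput on one
// CPU core, and the optimizer noise floor of GAN training sits far above
// float rounding. Batch-norm statistics stay in double.

// gather the (Ho*Wo) x (kh*kw*Cin) patch matrix for one image; pixels are
// rows so each (ki, kj, c) column is filled by contiguous runs along the
// image's fastest axis
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad, arma::fmat& K) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  float* out = K.memptr();
  const std::size_t nrow = (std::size_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        float* col = out + (std::size_t)(ki + kh * (kj + kw * c)) * nrow;
        for (int wo = 0; wo < Wo; ++wo) {
          int j = wo * stride - pad + kj;
          float* dst = col + (std::size_t)wo * Ho;
          if (j < 0 || j >= W) {
            for (int ho = 0; ho < Ho; ++ho) dst[ho] = 0.0f;
            continue;
          }
          const double* xcol = xc + (std::size_t)j * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int i = ho * stride - pad + ki;
            dst[ho] = (i < 0 || i >= H) ? 0.0f : (float)xcol[i];
          }
        }
      }
    }
  }
}

// scatter-add the patch matrix back into an image (adjoint of im2col)
static void col2im(const arma::fmat& K, int H, int W, int C,
                   int kh, int kw, int stride, int pad, double* x) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  const float* in = K.memptr();
  const std::size_t nrow = (std::size_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    double* xc = x + (std::size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const float* col = in + (std::size_t)(ki + kh * (kj + kw * c)) * nrow;
        for (int wo = 0; wo < Wo; ++wo) {
          int j = wo * stride - pad + kj;
          if (j < 0 || j >= W) continue;
          double* xcol = xc + (std::size_t)j * H;
          const float* src = col + (std::size_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            int i = ho * stride - pad + ki;
            if (i >= 0 && i < H) xcol[i] += src[ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv_fw")]]
NumericVector cpp_conv_fw(NumericVector x, NumericVector w,
                          NumericVector bias, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv: channel mismatch");
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  NumericVector y(Ho * Wo * (std::size_t)Cout * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(
      arma::mat(w.begin(), kh * kw * Cin, Cout, false, true));
  arma::fmat K(Ho * Wo, kh * kw * Cin);
  arma::frowvec bv = arma::conv_to<arma::frowvec>::from(
      arma::rowvec(bias.begin(), Cout));
  arma::fmat Yb(Ho * Wo, Cout);
  for (int b = 0; b < B; ++b) {
    im2col(x.begin() + (std::size_t)b * H * W * C, H, W, C, kh, kw,
           stride, pad, K);
    Yb = K * Wm;
    Yb.each_row() += bv;
    double* py = y.begin() + (std::size_t)b * Ho * Wo * Cout;
    const float* pf = Yb.memptr();
    for (std::size_t i = 0; i < (std::size_t)Ho * Wo * Cout; ++i)
      py[i] = pf[i];
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv_bw")]]
List cpp_conv_bw(NumericVector x, NumericVector w, NumericVector dy,
                 int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(
      arma::mat(w.begin(), kh * kw * Cin, Cout, false, true));
  arma::fmat dWm(kh * kw * Cin, Cout, arma::fill::zeros);
  arma::frowvec dbv(Cout, arma::fill::zeros);
  arma::fmat K(Ho * Wo, kh * kw * Cin);
  arma::fmat dYb(Ho * Wo, Cout);
  for (int b = 0; b < B; ++b) {
    const double* pdy = dy.begin() + (std::size_t)b * Ho * Wo * Cout;
    float* pf = dYb.memptr();
    for (std::size_t i = 0; i < (std::size_t)Ho * Wo * Cout; ++i)
      pf[i] = (float)pdy[i];
    im2col(x.begin() + (std::size_t)b * H * W * C, H, W, C, kh, kw,
           stride, pad, K);
    dWm += K.t() * dYb;
    dbv += arma::sum(dYb, 0);
    K = dYb * Wm.t();             // reuse buffer: d(col-matrix)
    col2im(K, H, W, C, kh, kw, stride, pad,
           dx.begin() + (std::size_t)b * H * W * C);
  }
  std::copy(dWm.begin(), dWm.end(), dw.begin());
  std::copy(dbv.begin(), dbv.end(), db.begin());
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// batch norm over (H, W, B) per channel, training statistics
// [[Rcpp::export(name = ".cpp_bn_fw")]]
List cpp_bn_fw(NumericVector x, NumericVector gamma, NumericVector beta,
               double eps) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const std::size_t hw = (std::size_t)H * W, chw = hw * C;
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = xd;
  xhat.attr("dim") = xd;
  NumericVector mean(C), invstd(C);
  const double n = (double)hw * B;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int b = 0; b < B; ++b) {
      const double* p = x.begin() + b * chw + c * hw;
      for (std::size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    double mu = s / n;
    double var = s2 / n - mu * mu;
    double is = 1.0 / std::sqrt(var > 0 ? var + eps : eps);
    mean[c] = mu;
    invstd[c] = is;
    const double g = gamma[c], be = beta[c];
    for (int b = 0; b < B; ++b) {
      const double* p = x.begin() + b * chw + c * hw;
      double* ph = xhat.begin() + b * chw + c * hw;
      double* py = y.begin() + b * chw + c * hw;
      for (std::size_t i = 0; i < hw; ++i) {
        ph[i] = (p[i] - mu) * is;
        py[i] = g * ph[i] + be;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mean"] = mean,
                      _["invstd"] = invstd);
}

// [[Rcpp::export(name = ".cpp_bn_bw")]]
List cpp_bn_bw(NumericVector xhat, NumericVector invstd,
               NumericVector gamma, NumericVector dy) {
  IntegerVector xd = xhat.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  const std::size_t hw = (std::size_t)H * W, chw = hw * C;
  NumericVector dx(xhat.size());
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  const double n = (double)hw * B;
  for (int c = 0; c < C; ++c) {
    double sdy = 0, sdyx = 0;
    for (int b = 0; b < B; ++b) {
      const double* pd = dy.begin() + b * chw + c * hw;
      const double* ph = xhat.begin() + b * chw + c * hw;
      for (std::size_t i = 0; i < hw; ++i) {
        sdy += pd[i];
        sdyx += pd[i] * ph[i];
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    const double g = gamma[c], is = invstd[c];
    for (int b = 0; b < B; ++b) {
      const double* pd = dy.begin() + b * chw + c * hw;
      const double* ph = xhat.begin() + b * chw + c * hw;
      double* px = dx.begin() + b * chw + c * hw;
      for (std::size_t i = 0; i < hw; ++i) {
        px[i] = g * is * (pd[i] - sdy / n - ph[i] * sdyx / n);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".cpp_lrelu_fw")]]
NumericVector cpp_lrelu_fw(NumericVector x, double slope) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] > 0 ? x[i] : slope * x[i];
  return y;
}

// [[Rcpp::export(name = ".cpp_lrelu_bw")]]
NumericVector cpp_lrelu_bw(NumericVector x, NumericVector dy, double slope) {
  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    dx[i] = x[i] > 0 ? dy[i] : slope * dy[i];
  return dx;
}

// nearest-neighbour 2x upsampling and its adjoint (2x2 sum pooling)
// [[Rcpp::export(name = ".cpp_up2_fw")]]
NumericVector cpp_up2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  NumericVector y((std::size_t)4 * x.size());
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, B);
  const int H2 = 2 * H, W2 = 2 * W;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + ((std::size_t)b * C + c) * H * W;
      double* q = y.begin() + ((std::size_t)b * C + c) * H2 * W2;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          double v = p[i + (std::size_t)j * H];
          double* q0 = q + 2 * i + (std::size_t)(2 * j) * H2;
          q0[0] = v;
          q0[1] = v;
          q0[H2] = v;
          q0[H2 + 1] = v;
        }
    }
  return y;
}

// [[Rcpp::export(name = ".cpp_up2_bw")]]
NumericVector cpp_up2_bw(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int H2 = yd[0], W2 = yd[1], C = yd[2], B = yd[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector dx((std::size_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      double* p = dx.begin() + ((std::size_t)b * C + c) * H * W;
      const double* q = dy.begin() + ((std::size_t)b * C + c) * H2 * W2;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const double* q0 = q + 2 * i + (std::size_t)(2 * j) * H2;
          p[i + (std::size_t)j * H] = q0[0] + q0[1] + q0[H2] + q0[H2 + 1];
        }
    }
  return dx;
}
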