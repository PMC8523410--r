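// Low-level tensor kernels for the convolutional network.
//
// Tensors are R arrays with dim c(H, W, C, N), column-major (H fastest).
// Convolutions are 3x3 (or kxk), stride 1, zero "same" padding, implemented
// as im2col + GEMM. Weights arrive flattened as a (kh*kw*Cin) x Cout matrix
// whose row index runs kh fastest, then kw, then input channel -- i.e. the
// column-major flattening of an R array dim c(kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col_one(const double* x, int H, int W, int C,
                       int kh, int kw, arma::mat& col) {
  // col: (H*W) x (kh*kw*C); zero padding, stride 1, pad = (k-1)/2
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int iw = 0; iw < kw; ++iw) {
      for (int ih = 0; ih < kh; ++ih) {
        const int q = ih + iw * kh + c * kh * kw;
        double* colq = col.colptr(q);
        const int dh = ih - ph, dw = iw - pw;
        const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        for (int w = w0; w < w1; ++w) {
          const double* src = xc + (size_t)(w + dw) * H + (h0 + dh);
          double* dst = colq + (size_t)w * H + h0;
          std::copy(src, src + (h1 - h0), dst);
        }
      }
    }
  }
}

static void col2im_one(const arma::mat& col, int H, int W, int C,
                       int kh, int kw, double* x) {
  // adjoint of im2col_one: scatter-add columns back into the image
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int iw = 0; iw < kw; ++iw) {
      for (int ih = 0; ih < kh; ++ih) {
        const int q = ih + iw * kh + c * kh * kw;
        const double* colq = col.colptr(q);
        const int dh = ih - ph, dw = iw - pw;
        const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        for (int w = w0; w < w1; ++w) {
          const double* src = colq + (size_t)w * H + h0;
          double* dst = xc + (size_t)(w + dw) * H + (h0 + dh);
          for (int h = 0; h < h1 - h0; ++h) dst[h] += src[h];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward(NumericVector x, NumericMatrix w,
                             NumericVector b, int kh, int kw) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = w.ncol();
  NumericVector y((R_xlen_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat wm(w.begin(), w.nrow(), Cout, false, true);
  arma::mat col(H * W, kh * kw * C);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, col);
    arma::mat out = col * wm;                     // (H*W) x Cout
    for (int c = 0; c < Cout; ++c) out.col(c) += b[c];
    std::copy(out.begin(), out.end(), y.begin() + (size_t)n * H * W * Cout);
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericVector x, NumericMatrix w, NumericVector dy,
                     int kh, int kw) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = w.ncol();
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::mat wm(w.begin(), w.nrow(), Cout, false, true);
  arma::mat dwm(w.nrow(), Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat col(H * W, kh * kw * C);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, kh, kw, col);
    arma::mat dym(dy.begin() + (size_t)n * H * W * Cout, H * W, Cout,
                  false, true);
    dwm += col.t() * dym;
    db += arma::sum(dym, 0).t();
    arma::mat dcol = dym * wm.t();
    col2im_one(dcol, H, W, C, kh, kw, dx.begin() + (size_t)n * H * W * C);
  }
  NumericMatrix dwR(w.nrow(), Cout);
  std::copy(dwm.begin(), dwm.end(), dwR.begin());
  return List::create(_["dx"] = dx, _["dw"] = dwR,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(Ho * (R_xlen_t)Wo * C * N);  // 1-based offset into x
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + ((size_t)n * C + c) * H * W;
      const R_xlen_t base = ((R_xlen_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h, ++o) {
          int best = 2 * h + 2 * w * H;
          double bv = xs[best];
          const int cand[3] = {2 * h + 1 + 2 * w * H,
                               2 * h + (2 * w + 1) * H,
                               2 * h + 1 + (2 * w + 1) * H};
          for (int k = 0; k < 3; ++k)
            if (xs[cand[k]] > bv) { bv = xs[cand[k]]; best = cand[k]; }
          y[o] = bv;
          idx[o] = (int)(base + best) + 1;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
NumericVector maxpool2_backward(NumericVector dy, IntegerVector idx,
                                IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

// Bilinear x2 upsampling, half-pixel-center convention:
// output pixel i samples input coordinate (i + 0.5)/2 - 0.5, edge-clamped.
// [[Rcpp::export(name = ".upsample2_forward")]]
NumericVector upsample2_forward(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> i0(Ho), i1(Ho);
  std::vector<double> wt(Ho);  // weight of i1
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    i0[i] = (int)std::floor(s);
    i1[i] = std::min(i0[i] + 1, H - 1);
    wt[i] = s - i0[i];
  }
  std::vector<int> j0(Wo), j1(Wo);
  std::vector<double> wu(Wo);
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    j0[j] = (int)std::floor(s);
    j1[j] = std::min(j0[j] + 1, W - 1);
    wu[j] = s - j0[j];
  }
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + ((size_t)n * C + c) * H * W;
      double* ys = y.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          const double a = xs[i0[i] + j0[j] * H], b = xs[i1[i] + j0[j] * H];
          const double cc = xs[i0[i] + j1[j] * H], dd = xs[i1[i] + j1[j] * H];
          ys[i + (size_t)j * Ho] =
            (1 - wu[j]) * ((1 - wt[i]) * a + wt[i] * b) +
            wu[j] * ((1 - wt[i]) * cc + wt[i] * dd);
        }
    }
  return y;
}

// [[Rcpp::export(name = ".upsample2_backward")]]
NumericVector upsample2_backward(NumericVector dy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> i0(Ho), i1(Ho);
  std::vector<double> wt(Ho);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    i0[i] = (int)std::floor(s);
    i1[i] = std::min(i0[i] + 1, H - 1);
    wt[i] = s - i0[i];
  }
  std::vector<int> j0(Wo), j1(Wo);
  std::vector<double> wu(Wo);
  for (int j = 0; j < Wo; ++j) {
    double s = (j + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > W - 1) s = W - 1;
    j0[j] = (int)std::floor(s);
    j1[j] = std::min(j0[j] + 1, W - 1);
    wu[j] = s - j0[j];
  }
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xs = dx.begin() + ((size_t)n * C + c) * H * W;
      const double* ys = dy.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          const double g = ys[i + (size_t)j * Ho];
          xs[i0[i] + (size_t)j0[j] * H] += (1 - wu[j]) * (1 - wt[i]) * g;
          xs[i1[i] + (size_t)j0[j] * H] += (1 - wu[j]) * wt[i] * g;
          xs[i0[i] + (size_t)j1[j] * H] += wu[j] * (1 - wt[i]) * g;
          xs[i1[i] + (size_t)j1[j] * H] += wu[j] * wt[i] * g;
        }
    }
  return dx;
}

// Batch normalization over channels of a (H, W, C, N) tensor.
// [[Rcpp::export(name = ".bn_train_forward")]]
List bn_train_forward(NumericVector x, NumericVector gamma,
                      NumericVector beta, NumericVector rm,
                      NumericVector rv, double momentum, double eps) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = d;
  NumericVector mu(C), va(C), inv_std(C), rm2(C), rv2(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xs = x.begin() + ((R_xlen_t)n * C + c) * HW;
      for (R_xlen_t i = 0; i < HW; ++i) { s += xs[i]; s2 += xs[i] * xs[i]; }
    }
    const double m = s / (HW * N);
    const double v = s2 / (HW * N) - m * m;
    mu[c] = m; va[c] = v;
    inv_std[c] = 1.0 / std::sqrt(v + eps);
    rm2[c] = momentum * rm[c] + (1 - momentum) * m;
    rv2[c] = momentum * rv[c] + (1 - momentum) * v;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = ((R_xlen_t)n * C + c) * HW;
      const double* xs = x.begin() + off;
      double* xh = xhat.begin() + off;
      double* ys = y.begin() + off;
      for (R_xlen_t i = 0; i < HW; ++i) {
        xh[i] = (xs[i] - m) * inv_std[c];
        ys[i] = gamma[c] * xh[i] + beta[c];
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat,
                      _["inv_std"] = inv_std, _["rm"] = rm2,
                      _["rv"] = rv2);
}

// [[Rcpp::export(name = ".bn_infer_forward")]]
NumericVector bn_infer_forward(NumericVector x, NumericVector gamma,
                               NumericVector beta, NumericVector rm,
                               NumericVector rv, double eps) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = d;
  for (int c = 0; c < C; ++c) {
    const double inv_std = 1.0 / std::sqrt(rv[c] + eps);
    const double a = gamma[c] * inv_std;
    const double b = beta[c] - a * rm[c];
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = ((R_xlen_t)n * C + c) * HW;
      const double* xs = x.begin() + off;
      double* ys = y.begin() + off;
      for (R_xlen_t i = 0; i < HW; ++i) ys[i] = a * xs[i] + b;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".bn_train_backward")]]
List bn_train_backward(NumericVector dy, NumericVector xhat,
                       NumericVector inv_std, NumericVector gamma) {
  IntegerVector d = dy.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const R_xlen_t HW = (R_xlen_t)H * W;
  const double M = (double)HW * N;
  NumericVector dx(dy.size()), dgamma(C), dbeta(C);
  dx.attr("dim") = d;
  for (int c = 0; c < C; ++c) {
    double sg = 0, sb = 0;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = ((R_xlen_t)n * C + c) * HW;
      const double* dys = dy.begin() + off;
      const double* xh = xhat.begin() + off;
      for (R_xlen_t i = 0; i < HW; ++i) {
        sg += dys[i] * xh[i];
        sb += dys[i];
      }
    }
    dgamma[c] = sg; dbeta[c] = sb;
    const double k1 = sb / M, k2 = sg / M;
    const double a = gamma[c] * inv_std[c];
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = ((R_xlen_t)n * C + c) * HW;
      const double* dys = dy.begin() + off;
      const double* xh = xhat.begin() + off;
      double* dxs = dx.begin() + off;
      for (R_xlen_t i = 0; i < HW; ++i)
        dxs[i] = a * (dys[i] - k1 - xh[i] * k2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// channel concatenation and split for the skip connections
// [[Rcpp::export(name = ".concat_channels")]]
NumericVector concat_channels_cpp(NumericVector a, NumericVector b) {
  IntegerVector da = a.attr("dim"), db = b.attr("dim");
  const int H = da[0], W = da[1], Ca = da[2], Cb = db[2], N = da[3];
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector y(HW * (Ca + Cb) * N);
  y.attr("dim") = IntegerVector::create(H, W, Ca + Cb, N);
  for (int n = 0; n < N; ++n) {
    std::copy(a.begin() + (R_xlen_t)n * Ca * HW,
              a.begin() + (R_xlen_t)(n + 1) * Ca * HW,
              y.begin() + (R_xlen_t)n * (Ca + Cb) * HW);
    std::copy(b.begin() + (R_xlen_t)n * Cb * HW,
              b.begin() + (R_xlen_t)(n + 1) * Cb * HW,
              y.begin() + ((R_xlen_t)n * (Ca + Cb) + Ca) * HW);
  }
  return y;
}

// [[Rcpp::export(name = ".split_channels")]]
List split_channels_cpp(NumericVector dy, int c1) {
  IntegerVector d = dy.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const R_xlen_t HW = (R_xlen_t)H * W;
  NumericVector a(HW * (R_xlen_t)c1 * N), b(HW * (R_xlen_t)(C - c1) * N);
  a.attr("dim") = IntegerVector::create(H, W, c1, N);
  b.attr("dim") = IntegerVector::create(H, W, C - c1, N);
  for (int n = 0; n < N; ++n) {
    std::copy(dy.begin() + (R_xlen_t)n * C * HW,
              dy.begin() + ((R_xlen_t)n * C + c1) * HW,
              a.begin() + (R_xlen_t)n * c1 * HW);
    std::copy(dy.begin() + ((R_xlen_t)n * C + c1) * HW,
              dy.begin() + (R_xlen_t)(n + 1) * C * HW,
              b.begin() + (R_xlen_t)n * (C - c1) * HW);
  }
  return List::create(_["a"] = a, _["b"] = b);
}
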