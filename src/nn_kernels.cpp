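// Low-level kernels for the U-Net generator and patch critic.
//
// Array convention throughout: images and activations are R numeric arrays
// with dim (H, W, C, N), column-major. Conv weights are (Cout x K) matrices
// with K = k*k*Cin and flat kernel index kh + k*kw + k*k*c (all 0-based);
// up-convolution (kernel 2, stride 2) weights are (Cout x 4*Cin) with flat
// index ci + Cin*(di + 2*dj) for output offset (di, dj).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H, W, C, N) array");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill `colsT` ((Ho*Wo) x K) with the im2col expansion of one (H, W, C)
// slice. Each K-column (one (kh, kw, c) tap) is written with contiguous
// runs over ho, which keeps this memory-bound step near memcpy speed for
// stride 1 and feeds the GEMM in a cache-friendly (tall x K) layout.
static void im2colT(const double* x, int H, int W, int C,
                    int k, int stride, int pad, int Ho, int Wo,
                    arma::mat& colsT) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        double* dst = colsT.colptr(kh + k * kw + k * k * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kw;
          double* d = dst + (size_t)Ho * wo;
          if (w < 0 || w >= W) {
            std::fill(d, d + Ho, 0.0);
            continue;
          }
          const double* s = xc + (size_t)H * w;
          if (stride == 1) {
            // valid ho satisfy 0 <= ho + kh - pad < H
            const int lo = std::max(0, pad - kh);
            const int hi = std::min(Ho, H + pad - kh);  // exclusive
            for (int ho = 0; ho < lo; ++ho) d[ho] = 0.0;
            if (hi > lo) memcpy(d + lo, s + (lo + kh - pad),
                                (size_t)(hi - lo) * sizeof(double));
            for (int ho = hi; ho < Ho; ++ho) d[ho] = 0.0;
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              const int h = ho * stride - pad + kh;
              d[ho] = (h >= 0 && h < H) ? s[h] : 0.0;
            }
          }
        }
      }
  }
}

// Scatter-add of `colsT` ((Ho*Wo) x K) back into one (H, W, C) slice.
static void col2imT(const arma::mat& colsT, int H, int W, int C,
                    int k, int stride, int pad, int Ho, int Wo,
                    double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const double* src = colsT.colptr(kh + k * kw + k * k * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + kw;
          if (w < 0 || w >= W) continue;
          const double* s = src + (size_t)Ho * wo;
          double* d = xc + (size_t)H * w;
          if (stride == 1) {
            const int lo = std::max(0, pad - kh);
            const int hi = std::min(Ho, H + pad - kh);
            for (int ho = lo; ho < hi; ++ho) d[ho + kh - pad] += s[ho];
          } else {
            for (int ho = 0; ho < Ho; ++ho) {
              const int h = ho * stride - pad + kh;
              if (h >= 0 && h < H) d[h] += s[ho];
            }
          }
        }
      }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericMatrix w,
                                 NumericVector b, int k, int stride, int pad) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int Cout = w.nrow();
  const int K = w.ncol();
  if (K != k * k * C) stop("weight/input channel mismatch in conv2d");
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d output would be empty");

  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat Wt(w.begin(), Cout, K, false);      // Cout x K
  arma::mat WtT = Wt.t();                       // K x Cout
  arma::rowvec bv(b.begin(), Cout, false);
  arma::mat colsT((size_t)Ho * Wo, K);

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    im2colT(xn, H, W, C, k, stride, pad, Ho, Wo, colsT);
    arma::mat Yt(out.begin() + (size_t)Ho * Wo * Cout * n,
                 (size_t)Ho * Wo, Cout, false, true);
    Yt = colsT * WtT;                           // (Ho*Wo) x Cout
    Yt.each_row() += bv;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericMatrix w, NumericVector dy,
                         int k, int stride, int pad, bool need_dx) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int Cout = w.nrow();
  const int K = w.ncol();
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);

  arma::mat Wt(w.begin(), Cout, K, false);
  arma::mat dWt(K, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  arma::mat colsT((size_t)Ho * Wo, K);

  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((size_t)H * W * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
  }

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)H * W * C * n;
    im2colT(xn, H, W, C, k, stride, pad, Ho, Wo, colsT);
    arma::mat dYt(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * Cout * n,
                  (size_t)Ho * Wo, Cout, false);
    dWt += colsT.t() * dYt;
    db += arma::sum(dYt, 0);
    if (need_dx) {
      arma::mat dcolsT = dYt * Wt;              // (Ho*Wo) x K
      double* dxn = dx.begin() + (size_t)H * W * C * n;
      col2imT(dcolsT, H, W, C, k, stride, pad, Ho, Wo, dxn);
    }
  }

  NumericMatrix dW(Cout, K);
  arma::mat dWv(dW.begin(), Cout, K, false);
  dWv = dWt.t();
  NumericVector dbv(Cout);
  std::copy(db.begin(), db.end(), dbv.begin());
  if (need_dx) return List::create(_["dx"] = dx, _["dw"] = dW, _["db"] = dbv);
  return List::create(_["dw"] = dW, _["db"] = dbv);
}

// 2x2 max pooling, stride 2; H and W must be even.
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool2 needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N);  // 0-based index into x

  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)H * W * (c + (size_t)C * n);
      const size_t ooff = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          size_t best = off + (2 * ho) + (size_t)H * (2 * wo);
          double bv = xp[best];
          const size_t cand[3] = {off + (2 * ho + 1) + (size_t)H * (2 * wo),
                                  off + (2 * ho) + (size_t)H * (2 * wo + 1),
                                  off + (2 * ho + 1) + (size_t)H * (2 * wo + 1)};
          for (int j = 0; j < 3; ++j)
            if (xp[cand[j]] > bv) { bv = xp[cand[j]]; best = cand[j]; }
          yp[ooff + ho + (size_t)Ho * wo] = bv;
          ip[ooff + ho + (size_t)Ho * wo] = (int)best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector dy, IntegerVector idx,
                                    IntegerVector in_dim) {
  NumericVector dx((size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3]);
  dx.attr("dim") = in_dim;
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  const R_xlen_t m = dy.size();
  for (R_xlen_t i = 0; i < m; ++i) dxp[ip[i]] += dyp[i];
  return dx;
}

// Transposed convolution, kernel 2, stride 2 (the U-Net up-sampling step).
// [[Rcpp::export]]
NumericVector cpp_upconv2_forward(NumericVector x, NumericMatrix w,
                                  NumericVector b) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int Cout = w.nrow();
  if (w.ncol() != 4 * C) stop("upconv2 weight/channel mismatch");
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  arma::mat Wt(w.begin(), Cout, 4 * C, false);
  for (int n = 0; n < N; ++n) {
    arma::mat Xm(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                 (size_t)H * W, C, false);
    double* on = out.begin() + (size_t)Ho * Wo * Cout * n;
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        arma::mat Wsub = Wt.cols((di + 2 * dj) * C, (di + 2 * dj) * C + C - 1);
        arma::mat Y = Xm * Wsub.t();            // (H*W) x Cout
        for (int co = 0; co < Cout; ++co) {
          double* oc = on + (size_t)Ho * Wo * co;
          const double* yc = Y.colptr(co);
          const double bias = b[co];
          for (int wcol = 0; wcol < W; ++wcol)
            for (int h = 0; h < H; ++h)
              oc[(2 * h + di) + (size_t)Ho * (2 * wcol + dj)] =
                yc[h + (size_t)H * wcol] + bias;
        }
      }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_upconv2_backward(NumericVector x, NumericMatrix w, NumericVector dy,
                          bool need_dx) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int Cout = w.nrow();
  const int Ho = 2 * H, Wo = 2 * W;
  arma::mat Wt(w.begin(), Cout, 4 * C, false);
  arma::mat dW(Cout, 4 * C, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);

  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((size_t)H * W * C * N);
    dx.attr("dim") = IntegerVector::create(H, W, C, N);
  }

  arma::mat dYsub((size_t)H * W, Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat Xm(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                 (size_t)H * W, C, false);
    const double* dyn = dy.begin() + (size_t)Ho * Wo * Cout * n;
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        for (int co = 0; co < Cout; ++co) {
          const double* dc = dyn + (size_t)Ho * Wo * co;
          double* tc = dYsub.colptr(co);
          for (int wcol = 0; wcol < W; ++wcol)
            for (int h = 0; h < H; ++h)
              tc[h + (size_t)H * wcol] =
                dc[(2 * h + di) + (size_t)Ho * (2 * wcol + dj)];
        }
        dW.cols((di + 2 * dj) * C, (di + 2 * dj) * C + C - 1) += dYsub.t() * Xm;
        db += arma::sum(dYsub, 0);
        if (need_dx) {
          arma::mat Wsub = Wt.cols((di + 2 * dj) * C, (di + 2 * dj) * C + C - 1);
          arma::mat dXm(dx.begin() + (size_t)H * W * C * n, (size_t)H * W, C,
                        false);
          dXm += dYsub * Wsub;
        }
      }
  }

  NumericMatrix dWout(Cout, 4 * C);
  std::copy(dW.begin(), dW.end(), dWout.begin());
  NumericVector dbv(Cout);
  std::copy(db.begin(), db.end(), dbv.begin());
  if (need_dx) return List::create(_["dx"] = dx, _["dw"] = dWout, _["db"] = dbv);
  return List::create(_["dw"] = dWout, _["db"] = dbv);
}

// Per-pixel median over the first counts[h, w] entries of acc[h, w, ] with
// the even-count convention median = mean of the two middle order statistics.
// [[Rcpp::export]]
NumericMatrix cpp_masked_median(NumericVector acc, IntegerMatrix counts) {
  IntegerVector d = acc.attr("dim");
  const int H = d[0], W = d[1], K = d[2];
  NumericMatrix out(H, W);
  std::vector<double> buf(K);
  const double* ap = acc.begin();
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      const int m = counts(h, w);
      if (m < 1) { out(h, w) = NA_REAL; continue; }
      for (int j = 0; j < m; ++j) buf[j] = ap[h + (size_t)H * w + (size_t)H * W * j];
      std::sort(buf.begin(), buf.begin() + m);
      out(h, w) = (m % 2) ? buf[m / 2] : 0.5 * (buf[m / 2 - 1] + buf[m / 2]);
    }
  return out;
}

// ---- batch-norm / ReLU helpers (hot path) -------------------------------

// Per-channel mean and biased variance of an (H, W, C, N) array.
// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const size_t hw = (size_t)H * W;
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double m = s / (hw * N);
    mu[c] = m;
    var[c] = s2 / (hw * N) - m * m;
  }
  return List::create(_["mu"] = mu, _["var"] = var);
}

// y = x * scale[channel] + shift[channel], preserving dims.
// [[Rcpp::export]]
NumericVector cpp_channel_affine(NumericVector x, NumericVector scale,
                                 NumericVector shift) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const size_t hw = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + hw * (c + (size_t)C * n);
      double* q = y.begin() + hw * (c + (size_t)C * n);
      const double a = scale[c], b = shift[c];
      for (size_t i = 0; i < hw; ++i) q[i] = p[i] * a + b;
    }
  return y;
}

// Batch-norm backward from the cached normalized input.
// [[Rcpp::export]]
List cpp_bn_backward(NumericVector xhat, NumericVector dy,
                     NumericVector gamma, NumericVector invstd) {
  int H, W, C, N;
  get_dims4(xhat, H, W, C, N);
  const size_t hw = (size_t)H * W;
  const double m = (double)hw * N;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sb = 0.0;
    for (int n = 0; n < N; ++n) {
      const size_t off = hw * (c + (size_t)C * n);
      const double* xh = xhat.begin() + off;
      const double* d = dy.begin() + off;
      for (size_t i = 0; i < hw; ++i) { sg += d[i] * xh[i]; sb += d[i]; }
    }
    dgamma[c] = sg; dbeta[c] = sb;
  }
  NumericVector dx(xhat.size());
  dx.attr("dim") = xhat.attr("dim");
  for (int c = 0; c < C; ++c) {
    const double gi = gamma[c] * invstd[c];
    const double tb = dbeta[c] / m, tg = dgamma[c] / m;
    for (int n = 0; n < N; ++n) {
      const size_t off = hw * (c + (size_t)C * n);
      const double* xh = xhat.begin() + off;
      const double* d = dy.begin() + off;
      double* o = dx.begin() + off;
      for (size_t i = 0; i < hw; ++i) o[i] = gi * (d[i] - tb - xh[i] * tg);
    }
  }
  return List::create(_["dx"] = dx, _["gamma"] = dgamma, _["beta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_relu_forward(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* p = x.begin();
  double* q = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) q[i] = p[i] > 0 ? p[i] : 0.0;
  return y;
}

// dx = dy where the forward output was positive (0 elsewhere).
// [[Rcpp::export]]
NumericVector cpp_relu_backward(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* d = dy.begin();
  const double* p = y.begin();
  double* q = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) q[i] = p[i] > 0 ? d[i] : 0.0;
  return dx;
}
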