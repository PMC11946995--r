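// Convolution and pooling kernels for the SE-ResNet. Feature maps are R
// arrays with dim (H, W, C, N); weights have dim (kh, kw, Cin, Cout) and
// are passed flattened to (kh*kw*Cin) x Cout. Convolutions are realized as
// im2col followed by a GEMM per sample, the standard CPU formulation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector make_num_array(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// uninitialized variant for outputs that are fully overwritten
static NumericVector make_num_array_noinit(int a, int b, int c, int d) {
  NumericVector v(no_init((R_xlen_t)a * b * c * d));
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector make_int_array(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// fill the im2col matrix (kh*kw*Cin) x (Ho*Wo) for one sample.
// row index order: dh fastest, then dw, then c  (matches R's flattening of
// a (kh, kw, Cin, Cout) weight array).
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        int r = dh + kh * (dw + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + dw;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + dh;
            double v = 0.0;
            if (hi >= 0 && hi < H && wi >= 0 && wi < W)
              v = xc[hi + (size_t)wi * H];
            col(r, ho + (size_t)Ho * wo) = v;
          }
        }
      }
    }
  }
}

// scatter-add of a column matrix back into an image (transpose of im2col)
static void col2im(const arma::mat& col, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, double* dx) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        int r = dh + kh * (dw + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + dw;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + dh;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)wi * H] += col(r, ho + (size_t)Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, IntegerVector xdim,
                             NumericMatrix wmat, NumericVector bias,
                             int kh, int kw, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int K = kh * kw * C;
  const int Cout = wmat.ncol();
  const int Ho = out_dim(H, kh, stride, pad);
  const int Wo = out_dim(W, kw, stride, pad);
  NumericVector y = make_num_array_noinit(Ho, Wo, Cout, N);
  arma::mat Wm(wmat.begin(), K, Cout, false);
  arma::vec b(bias.begin(), Cout, false);
  arma::mat col(K, (size_t)Ho * Wo);
  const size_t xs = (size_t)H * W * C;
  const size_t ys = (size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xs, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat yn(y.begin() + n * ys, (size_t)Ho * Wo, Cout, false, true);
    yn = col.t() * Wm;
    yn.each_row() += b.t();
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, IntegerVector xdim,
                    NumericMatrix wmat, NumericVector dy,
                    int kh, int kw, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int K = kh * kw * C;
  const int Cout = wmat.ncol();
  const int Ho = out_dim(H, kh, stride, pad);
  const int Wo = out_dim(W, kw, stride, pad);
  NumericVector dx = make_num_array(H, W, C, N);
  NumericMatrix dw(K, Cout);
  NumericVector db(Cout);
  arma::mat Wm(wmat.begin(), K, Cout, false);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat col(K, (size_t)Ho * Wo);
  const size_t xs = (size_t)H * W * C;
  const size_t ys = (size_t)Ho * Wo * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * xs, H, W, C, kh, kw, stride, pad, Ho, Wo, col);
    arma::mat dyn((double*)dy.begin() + n * ys, (size_t)Ho * Wo, Cout,
                  false, true);
    dWm += col * dyn;
    dbv += arma::sum(dyn, 0).t();
    arma::mat dcol = Wm * dyn.t(); // K x (Ho*Wo)
    col2im(dcol, H, W, C, kh, kw, stride, pad, Ho, Wo,
           dx.begin() + n * xs);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. Returns pooled map and flat argmax indices
// (1-based into the input array) for the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = make_num_array_noinit(Ho, Wo, C, N);
  IntegerVector idx = make_int_array(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300; size_t bi = 0;
          for (int dw = 0; dw < 2; ++dw) {
            for (int dh = 0; dh < 2; ++dh) {
              size_t k = base + (2 * ho + dh) + (size_t)(2 * wo + dw) * H;
              if (xp[k] > best) { best = xp[k]; bi = k; }
            }
          }
          // output element (ho, wo, c, n)
          o = ((size_t)n * C + c) * Ho * Wo + ho + (size_t)wo * Ho;
          yp[o] = best;
          ip[o] = (int)(bi + 1);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector idx,
                               IntegerVector xdim) {
  NumericVector dx = make_num_array(xdim[0], xdim[1], xdim[2], xdim[3]);
  double* dxp = dx.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dxp[idx[i] - 1] += dy[i];
  return dx;
}

// ---- batch-norm / SE / ReLU helpers ----------------------------------
// These exist to keep per-channel broadcasts out of R, where the repeated
// rep()/array() temporaries dominate the training profile.

// per-channel mean and population variance over (H, W, N)
// [[Rcpp::export]]
List channel_stats_cpp(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t hw = (size_t)H * W;
  NumericVector mu(C), va(C);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* p = xp + ((size_t)n * C + c) * hw;
      double s = 0, s2 = 0;
      for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      mu[c] += s; va[c] += s2;
    }
  }
  const double m = (double)hw * N;
  for (int c = 0; c < C; ++c) {
    mu[c] /= m;
    va[c] = va[c] / m - mu[c] * mu[c];
  }
  return List::create(_["mean"] = mu, _["var"] = va);
}

// y = gamma * (x - mu) * invstd + beta (optionally ReLU-gated); also
// returns xhat for backprop
// [[Rcpp::export]]
List bn_apply_cpp(NumericVector x, IntegerVector xdim, NumericVector mu,
                  NumericVector invstd, NumericVector gamma,
                  NumericVector beta, bool relu = false) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t hw = (size_t)H * W;
  NumericVector xhat = make_num_array_noinit(H, W, C, N);
  NumericVector y = make_num_array_noinit(H, W, C, N);
  const double* xp = x.begin();
  double* hp = xhat.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double m = mu[c], is = invstd[c], g = gamma[c], b = beta[c];
      for (size_t i = 0; i < hw; ++i) {
        const double xh = (xp[off + i] - m) * is;
        hp[off + i] = xh;
        double v = g * xh + b;
        if (relu && v < 0) v = 0;
        yp[off + i] = v;
      }
    }
  }
  return List::create(_["xhat"] = xhat, _["y"] = y);
}

// full batch-norm backward given dy and cached xhat/invstd
// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector dy, NumericVector xhat, IntegerVector xdim,
                NumericVector gamma, NumericVector invstd) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t hw = (size_t)H * W;
  const double m = (double)hw * N;
  NumericVector dx = make_num_array(H, W, C, N);
  NumericVector dgamma(C), dbeta(C), s1(C), s2(C);
  const double* dyp = dy.begin();
  const double* hp = xhat.begin();
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * hw;
      double a = 0, b = 0;
      for (size_t i = 0; i < hw; ++i) {
        a += dyp[off + i];
        b += dyp[off + i] * hp[off + i];
      }
      dbeta[c] += a; dgamma[c] += b;
    }
  }
  for (int c = 0; c < C; ++c) {
    s1[c] = dbeta[c] * gamma[c];   // sum of dxhat
    s2[c] = dgamma[c] * gamma[c];  // sum of dxhat * xhat
  }
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double g = gamma[c], is = invstd[c];
      const double k1 = s1[c] / m, k2 = s2[c] / m;
      for (size_t i = 0; i < hw; ++i)
        dxp[off + i] = is * (g * dyp[off + i] - k1 - hp[off + i] * k2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// y = u * s[c, n] (channel-wise rescale)
// [[Rcpp::export]]
NumericVector scale_channels_cpp(NumericVector u, IntegerVector xdim,
                                 NumericMatrix s) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t hw = (size_t)H * W;
  NumericVector y = make_num_array_noinit(H, W, C, N);
  const double* up = u.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double sc = s(c, n);
      for (size_t i = 0; i < hw; ++i) yp[off + i] = up[off + i] * sc;
    }
  return y;
}

// per-(channel, sample) spatial mean of a*b (b may be omitted): the
// squeeze / gap operation and the SE ds reduction
// [[Rcpp::export]]
NumericMatrix channel_gap_cpp(NumericVector a, IntegerVector xdim,
                              Nullable<NumericVector> b = R_NilValue) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t hw = (size_t)H * W;
  NumericMatrix out(C, N);
  const double* ap = a.begin();
  const double* bp = b.isNotNull() ? NumericVector(b).begin() : nullptr;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * hw;
      double s = 0;
      if (bp) for (size_t i = 0; i < hw; ++i) s += ap[off + i] * bp[off + i];
      else    for (size_t i = 0; i < hw; ++i) s += ap[off + i];
      out(c, n) = s / hw;
    }
  return out;
}

// y = x + v[c, n] (broadcast add of a per-(channel, sample) matrix)
// [[Rcpp::export]]
NumericVector add_channel_cpp(NumericVector x, IntegerVector xdim,
                              NumericMatrix v) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t hw = (size_t)H * W;
  NumericVector y = make_num_array_noinit(H, W, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * hw;
      const double a = v(c, n);
      for (size_t i = 0; i < hw; ++i) yp[off + i] = xp[off + i] + a;
    }
  return y;
}

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y = clone(x);
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < y.size(); ++i) if (yp[i] < 0) yp[i] = 0;
  return y;
}

// dy gated by (ref > 0)
// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector dy, NumericVector ref) {
  NumericVector dx = clone(dy);
  double* dp = dx.begin();
  const double* rp = ref.begin();
  for (R_xlen_t i = 0; i < dx.size(); ++i) if (rp[i] <= 0) dp[i] = 0;
  return dx;
}
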