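// Low-level tensor kernels for the conv-net engine.
// Layout convention everywhere: activations are (H, W, C, N) column-major
// (R array order); conv weights are (kh, kw, Cin, Cout); transposed-conv
// weights are (2, 2, Cin, Cout). Convolutions use "same" zero padding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H,W,C,N) array");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Fill the im2col matrix (HW x kh*kw*Cin) for sample n.
static void im2col(const double* x, int H, int W, int Cin, long samp_off,
                   int kh, int kw, arma::mat& col) {
  const int padh = (kh - 1) / 2, padw = (kw - 1) / 2;
  const long HW = (long)H * W;
  col.zeros();
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + samp_off + (long)c * HW;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int q = di + kh * (dj + kw * c);
        double* colq = col.colptr(q);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj - padw;
          if (js < 0 || js >= W) continue;
          int i0 = std::max(0, padh - di);
          int i1 = std::min(H, H + padh - di);
          const double* src = xc + (long)js * H + (i0 + di - padh);
          std::copy(src, src + (i1 - i0), colq + (long)j * H + i0);
        }
      }
    }
  }
}

// Scatter-add the columns matrix back into an image (inverse of im2col).
static void col2im(const arma::mat& col, int H, int W, int Cin, long samp_off,
                   int kh, int kw, double* dx) {
  const int padh = (kh - 1) / 2, padw = (kw - 1) / 2;
  const long HW = (long)H * W;
  for (int c = 0; c < Cin; ++c) {
    double* xc = dx + samp_off + (long)c * HW;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int q = di + kh * (dj + kw * c);
        const double* colq = col.colptr(q);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj - padw;
          if (js < 0 || js >= W) continue;
          int i0 = std::max(0, padh - di);
          int i1 = std::min(H, H + padh - di);
          double* dst = xc + (long)js * H + (i0 + di - padh);
          const double* src = colq + (long)j * H + i0;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, Cin, N;
  get_dims4(x, H, W, Cin, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d_fwd: channel mismatch");
  const long HW = (long)H * W;
  const int K = kh * kw * Cin;

  NumericVector y(HW * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::rowvec bv(b.begin(), Cout);
  arma::mat col(HW, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, Cin, (long)n * HW * Cin, kh, kw, col);
    arma::mat Y(y.begin() + (long)n * HW * Cout, HW, Cout, false, true);
    Y = col * Wm;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int H, W, Cin, N;
  get_dims4(x, H, W, Cin, N);
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const long HW = (long)H * W;
  const int K = kh * kw * Cin;

  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  NumericVector dw(w.size());
  dw.attr("dim") = w.attr("dim");
  NumericVector db(Cout);

  arma::mat Wm(w.begin(), K, Cout, false, true);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat col(HW, K), dcol(HW, K);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, Cin, (long)n * HW * Cin, kh, kw, col);
    arma::mat dY((double*)dy.begin() + (long)n * HW * Cout, HW, Cout, false, true);
    dWm += col.t() * dY;
    dbv += arma::sum(dY, 0).t();
    dcol = dY * Wm.t();
    col2im(dcol, H, W, Cin, (long)n * HW * Cin, kh, kw, dx.begin());
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("maxpool2_fwd: spatial dims must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((long)Ho * Wo * C * N);
  IntegerVector idx((long)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  long po = 0;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* xc = xp + cn * H * W;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i, ++po) {
        double best = -1e300; int bk = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            double v = xc[(2 * i + di) + (long)H * (2 * j + dj)];
            if (v > best) { best = v; bk = di + 2 * dj; }
          }
        yp[po] = best; ip[po] = bk;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector d = dy.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx((long)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dyp = dy.begin();
  const int* ip = idx.begin();
  double* dxp = dx.begin();
  long po = 0;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    double* dxc = dxp + cn * H * W;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i, ++po) {
        int di = ip[po] % 2, dj = ip[po] / 2;
        dxc[(2 * i + di) + (long)H * (2 * j + dj)] += dyp[po];
      }
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector convT2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int H, W, Cin, N;
  get_dims4(x, H, W, Cin, N);
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3];
  const long HW = (long)H * W;
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((long)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat X((double*)x.begin() + (long)n * HW * Cin, HW, Cin, false, true);
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        arma::mat Wsub(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Wsub(ci, co) = w[di + 2 * (dj + 2 * (ci + Cin * co))];
        arma::mat Ysub = X * Wsub;  // HW x Cout
        for (int co = 0; co < Cout; ++co) {
          double* yc = y.begin() + (long)n * Ho * Wo * Cout + (long)co * Ho * Wo;
          const double* ys = Ysub.colptr(co);
          const double bc = b[co];
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              yc[(2 * i + di) + (long)Ho * (2 * j + dj)] = ys[i + (long)H * j] + bc;
        }
      }
  }
  return y;
}

// [[Rcpp::export]]
List convT2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  int H, W, Cin, N;
  get_dims4(x, H, W, Cin, N);
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3];
  const long HW = (long)H * W;
  const int Ho = 2 * H, Wo = 2 * W;

  NumericVector dx(x.size());
  dx.attr("dim") = x.attr("dim");
  NumericVector dw(w.size());
  dw.attr("dim") = w.attr("dim");
  NumericVector db(Cout);

  arma::mat Ysub(HW, Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat X((double*)x.begin() + (long)n * HW * Cin, HW, Cin, false, true);
    arma::mat dX(dx.begin() + (long)n * HW * Cin, HW, Cin, false, true);
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        for (int co = 0; co < Cout; ++co) {
          const double* dyc = dy.begin() + (long)n * Ho * Wo * Cout + (long)co * Ho * Wo;
          double* ys = Ysub.colptr(co);
          double acc = 0.0;
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i) {
              double v = dyc[(2 * i + di) + (long)Ho * (2 * j + dj)];
              ys[i + (long)H * j] = v;
              acc += v;
            }
          db[co] += acc;
        }
        arma::mat Wsub(Cin, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            Wsub(ci, co) = w[di + 2 * (dj + 2 * (ci + Cin * co))];
        dX += Ysub * Wsub.t();
        arma::mat dWsub = X.t() * Ysub;  // Cin x Cout
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < Cin; ++ci)
            dw[di + 2 * (dj + 2 * (ci + Cin * co))] += dWsub(ci, co);
      }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---- batch-norm / relu helpers (hot path, avoid R-level broadcasting) -------

// per-channel mean and biased variance over (H,W,N)
// [[Rcpp::export]]
List channel_stats(NumericVector x) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const long HW = (long)H * W;
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + HW * (c + (long)C * n);
      for (long p = 0; p < HW; ++p) { s += xc[p]; s2 += xc[p] * xc[p]; }
    }
    const double m = s / (HW * N);
    mean[c] = m;
    double v = s2 / (HW * N) - m * m;
    var[c] = v > 0 ? v : 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// y = (x - mean) * inv * gamma + beta, per channel
// [[Rcpp::export]]
NumericVector bn_apply(NumericVector x, NumericVector mean, NumericVector inv,
                       NumericVector gamma, NumericVector beta) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const long HW = (long)H * W;
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double a = inv[c] * gamma[c];
      const double b0 = beta[c] - mean[c] * a;
      const double* xc = x.begin() + HW * (c + (long)C * n);
      double* yc = y.begin() + HW * (c + (long)C * n);
      for (long p = 0; p < HW; ++p) yc[p] = xc[p] * a + b0;
    }
  return y;
}

// full batch-norm backward; batch_mode=false treats mean/inv as constants
// [[Rcpp::export]]
List bn_bwd(NumericVector x, NumericVector dy, NumericVector mean,
            NumericVector inv, NumericVector gamma, bool batch_mode) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const long HW = (long)H * W;
  const double npx = (double)HW * N;
  NumericVector dx(x.size()), dgamma(C), dbeta(C);
  dx.attr("dim") = x.attr("dim");
  for (int c = 0; c < C; ++c) {
    double sdy = 0, sdyh = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + HW * (c + (long)C * n);
      const double* dc = dy.begin() + HW * (c + (long)C * n);
      for (long p = 0; p < HW; ++p) {
        sdy += dc[p];
        sdyh += dc[p] * (xc[p] - mean[c]) * inv[c];
      }
    }
    dgamma[c] = sdyh; dbeta[c] = sdy;
    const double gi = gamma[c] * inv[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + HW * (c + (long)C * n);
      const double* dc = dy.begin() + HW * (c + (long)C * n);
      double* dxc = dx.begin() + HW * (c + (long)C * n);
      if (batch_mode) {
        for (long p = 0; p < HW; ++p) {
          const double xhat = (xc[p] - mean[c]) * inv[c];
          dxc[p] = gi * (dc[p] - sdy / npx - xhat * sdyh / npx);
        }
      } else {
        for (long p = 0; p < HW; ++p) dxc[p] = gi * dc[p];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (long i = 0; i < (long)x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  for (long i = 0; i < (long)dy.size(); ++i) dx[i] = y[i] > 0 ? dy[i] : 0;
  return dx;
}
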