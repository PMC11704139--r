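// Minimal batched 2D convolution (cross-correlation) primitives used by the
// identification encoder and the proximal networks.  Layout follows R's
// column-major arrays: images are (H, W, C, N) flattened with slice index
// c + C*n; weights are passed as a (kh*kw*Cin) x Cout matrix whose row index
// is ki + kh*(kj + kw*c), matching as.vector() of a (kh, kw, Cin, Cout) array.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

static void im2col(const cube &x, int n, int C, int kh, int kw,
                   int stride, int pad, mat &col) {
  const int H = x.n_rows, W = x.n_cols;
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  col.zeros(kh * kw * C, Ho * Wo);
  for (int c = 0; c < C; ++c) {
    const mat &xc = x.slice(c + C * n);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int iw = wo * stride + kj - pad;
          if (iw < 0 || iw >= W) continue;
          double *dst = col.colptr(Ho * wo) + r;
          for (int ho = 0; ho < Ho; ++ho) {
            const int ih = ho * stride + ki - pad;
            if (ih < 0 || ih >= H) continue;
            dst[(size_t)ho * col.n_rows] = xc(ih, iw);
          }
        }
      }
    }
  }
}

static void col2im_add(const mat &col, int C, int H, int W, int kh, int kw,
                       int stride, int pad, cube &gx, int n) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  for (int c = 0; c < C; ++c) {
    mat &gc = gx.slice(c + C * n);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          const int iw = wo * stride + kj - pad;
          if (iw < 0 || iw >= W) continue;
          const double *src = col.colptr(Ho * wo) + r;
          for (int ho = 0; ho < Ho; ++ho) {
            const int ih = ho * stride + ki - pad;
            if (ih < 0 || ih >= H) continue;
            gc(ih, iw) += src[(size_t)ho * col.n_rows];
          }
        }
      }
    }
  }
}

// Forward: y[, , cout + Cout*n] = sum_c w[, c, cout] * x[, , c + C*n] + b[cout]
// [[Rcpp::export]]
arma::cube nn_conv_fwd(const arma::cube &x, int C, int N,
                       const arma::mat &wt, const arma::vec &b,
                       int kh, int kw, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = wt.n_cols;
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  cube y(Ho, Wo, (size_t)Cout * N);
  mat col;
  for (int n = 0; n < N; ++n) {
    im2col(x, n, C, kh, kw, stride, pad, col);
    mat yt = col.t() * wt;            // (Ho*Wo) x Cout
    yt.each_row() += b.t();
    for (int co = 0; co < Cout; ++co)
      y.slice(co + Cout * n) = reshape(yt.col(co), Ho, Wo);
  }
  return y;
}

// Backward: returns gradients w.r.t. input, weights and bias.
// [[Rcpp::export]]
Rcpp::List nn_conv_bwd(const arma::cube &x, const arma::cube &gy,
                       int C, int N, const arma::mat &wt,
                       int kh, int kw, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = wt.n_cols;
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  mat gwt(wt.n_rows, wt.n_cols, fill::zeros);
  vec gb(Cout, fill::zeros);
  cube gx(H, W, (size_t)C * N, fill::zeros);
  mat col, gt(Ho * Wo, Cout);
  for (int n = 0; n < N; ++n) {
    im2col(x, n, C, kh, kw, stride, pad, col);
    for (int co = 0; co < Cout; ++co)
      gt.col(co) = vectorise(gy.slice(co + Cout * n));
    gwt += col * gt;
    gb += sum(gt, 0).t();
    mat gcol = wt * gt.t();           // (kh*kw*C) x (Ho*Wo)
    col2im_add(gcol, C, H, W, kh, kw, stride, pad, gx, n);
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gwt,
                            Rcpp::Named("gb") = gb);
}

// Valid-region cross-correlation of a single-channel image with one window,
// used by the SSIM local statistics.
// [[Rcpp::export]]
arma::mat nn_xcorr_valid(const arma::mat &x, const arma::mat &w) {
  const int H = x.n_rows, W = x.n_cols;
  const int kh = w.n_rows, kw = w.n_cols;
  const int Ho = H - kh + 1, Wo = W - kw + 1;
  mat y(Ho, Wo);
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      y(ho, wo) = accu(w % x.submat(ho, wo, ho + kh - 1, wo + kw - 1));
  return y;
}

// Batch normalization over (H, W, N) per channel; x has C*N slices with
// slice index c + C*n.  Returns the normalized output plus what the
// backward pass needs; running statistics are updated in training mode.
// [[Rcpp::export]]
Rcpp::List nn_bn_fwd(const arma::cube &x, int C, int N,
                     const arma::vec &gamma, const arma::vec &beta,
                     const arma::vec &run_mean, const arma::vec &run_var,
                     bool training, double momentum, double eps) {
  const size_t HW = (size_t)x.n_rows * x.n_cols;
  vec mu(C), v(C);
  if (training) {
    mu.zeros(); v.zeros();
    for (int c = 0; c < C; ++c) {
      for (int n = 0; n < N; ++n) mu(c) += accu(x.slice(c + C * n));
      mu(c) /= (double)(HW * N);
      for (int n = 0; n < N; ++n) {
        const mat &s = x.slice(c + C * n);
        v(c) += accu(square(s - mu(c)));
      }
      v(c) /= (double)(HW * N);
    }
  } else {
    mu = run_mean; v = run_var;
  }
  vec inv_std = 1.0 / sqrt(v + eps);
  cube xhat(x.n_rows, x.n_cols, x.n_slices);
  cube y(x.n_rows, x.n_cols, x.n_slices);
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      xhat.slice(c + C * n) = (x.slice(c + C * n) - mu(c)) * inv_std(c);
      y.slice(c + C * n) = gamma(c) * xhat.slice(c + C * n) + beta(c);
    }
  vec new_mean = run_mean, new_var = run_var;
  if (training) {
    new_mean = (1.0 - momentum) * run_mean + momentum * mu;
    new_var = (1.0 - momentum) * run_var + momentum * v;
  }
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("inv_std") = inv_std,
                            Rcpp::Named("mean") = new_mean,
                            Rcpp::Named("var") = new_var);
}

// [[Rcpp::export]]
Rcpp::List nn_bn_bwd(const arma::cube &g, const arma::cube &xhat,
                     const arma::vec &inv_std, const arma::vec &gamma,
                     int C, int N, bool training) {
  const double M = (double)((size_t)g.n_rows * g.n_cols * N);
  vec ggamma(C, fill::zeros), gbeta(C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      ggamma(c) += accu(g.slice(c + C * n) % xhat.slice(c + C * n));
      gbeta(c) += accu(g.slice(c + C * n));
    }
  cube gx(g.n_rows, g.n_cols, g.n_slices);
  for (int c = 0; c < C; ++c) {
    const double gs = gamma(c) * inv_std(c);
    if (training) {
      const double mg = gbeta(c) / M;          // mean of upstream grad
      const double mgx = ggamma(c) / M;        // mean of grad * xhat
      for (int n = 0; n < N; ++n)
        gx.slice(c + C * n) =
          gs * (g.slice(c + C * n) - mg - xhat.slice(c + C * n) * mgx);
    } else {
      for (int n = 0; n < N; ++n)
        gx.slice(c + C * n) = gs * g.slice(c + C * n);
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("ggamma") = ggamma,
                            Rcpp::Named("gbeta") = gbeta);
}
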