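// Core dense tensor ops for the segmentation network: 2-D convolution
// forward/backward via blocked im2col/col2im + BLAS GEMM, and 2x2/stride-2
// max pooling. Arrays follow R's column-major layout with dims (H, W, C, N);
// kernels have dims (kh, kw, Cin, Cout). Transposed convolution is expressed
// in R on top of these primitives (its forward pass is the data-gradient of
// the matching strided convolution). im2col is blocked over output columns
// so the patch matrix stays cache-sized even at full image resolution, and
// 1x1 stride-1 convolutions skip im2col entirely (they are plain GEMMs on
// the channel dimension). The im2col/GEMM inner path runs in single
// precision (inputs, outputs and parameter state remain double); the ~1e-7
// relative rounding this introduces is far below the gradient noise of
// stochastic training.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int COL_BLOCK = 512;  // output columns per im2col block

// Fill col (K x nb) for output positions p0 .. p0+nb-1 of one image.
// Both the writes (column-contiguous) and the reads (kh-long runs of the
// input) are sequential.
static void im2col_block(const double* x, int H, int W, int C,
                         int kh, int kw, int stride, int pad,
                         int Ho, int p0, int nb, arma::fmat& col) {
  for (int pb = 0; pb < nb; ++pb) {
    const int p = p0 + pb;
    const int ho = p % Ho, wo = p / Ho;
    const int hi0 = ho * stride - pad, wi0 = wo * stride - pad;
    float* dst = col.colptr(pb);
    for (int c = 0; c < C; ++c) {
      const double* xc = x + (size_t)H * W * c;
      for (int kj = 0; kj < kw; ++kj) {
        const int wi = wi0 + kj;
        float* d = dst + kh * (kj + kw * c);
        if (wi < 0 || wi >= W) {
          for (int ki = 0; ki < kh; ++ki) d[ki] = 0.0f;
          continue;
        }
        const double* xcol = xc + (size_t)H * wi;
        for (int ki = 0; ki < kh; ++ki) {
          const int hi = hi0 + ki;
          d[ki] = (hi >= 0 && hi < H) ? (float)xcol[hi] : 0.0f;
        }
      }
    }
  }
}

// Scatter-accumulate col (K x nb) back into one image's gradient.
static void col2im_block(const arma::fmat& col, int H, int W, int C,
                         int kh, int kw, int stride, int pad,
                         int Ho, int p0, int nb, double* dx) {
  for (int pb = 0; pb < nb; ++pb) {
    const int p = p0 + pb;
    const int ho = p % Ho, wo = p / Ho;
    const int hi0 = ho * stride - pad, wi0 = wo * stride - pad;
    const float* src = col.colptr(pb);
    for (int c = 0; c < C; ++c) {
      double* xc = dx + (size_t)H * W * c;
      for (int kj = 0; kj < kw; ++kj) {
        const int wi = wi0 + kj;
        if (wi < 0 || wi >= W) continue;
        double* xcol = xc + (size_t)H * wi;
        const float* s = src + kh * (kj + kw * c);
        for (int ki = 0; ki < kh; ++ki) {
          const int hi = hi0 + ki;
          if (hi >= 0 && hi < H) xcol[hi] += s[ki];
        }
      }
    }
  }
}

static arma::fmat weight_matrix(const NumericVector& w, int K, int Cout) {
  // (Cout x K); R kernel index = r + K * co with r = ki + kh*(kj + kw*c)
  arma::fmat Wmat(Cout, K);
  for (int co = 0; co < Cout; ++co)
    for (int r = 0; r < K; ++r) Wmat(co, r) = (float)w[r + (size_t)K * co];
  return Wmat;
}

// (P x Cout) float copy of one image's output-gradient slab
static arma::fmat grad_matrix(const double* dy, int P, int Cout) {
  arma::fmat dY(P, Cout);
  for (int co = 0; co < Cout; ++co) {
    const double* s = dy + (size_t)P * co;
    float* d = dY.colptr(co);
    for (int p = 0; p < P; ++p) d[p] = (float)s[p];
  }
  return dY;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input channel mismatch");
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * C, P = Ho * Wo;
  NumericVector y((size_t)P * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::vec bv(b.begin(), Cout);

  if (kh == 1 && kw == 1 && stride == 1 && pad == 0) {
    // pure channel GEMM: (HW x C) * (C x Cout)
    arma::mat Wt(Cout, C);
    for (int co = 0; co < Cout; ++co)
      for (int c = 0; c < C; ++c) Wt(co, c) = w[c + (size_t)C * co];
    for (int n = 0; n < N; ++n) {
      arma::mat X(const_cast<double*>(&x[0]) + (size_t)P * C * n, P, C, false);
      arma::mat Y(&y[0] + (size_t)P * Cout * n, P, Cout, false, true);
      Y = X * Wt.t();
      Y.each_row() += bv.t();
    }
    return y;
  }

  arma::fmat Wmat = weight_matrix(w, K, Cout);
  arma::fmat col(K, COL_BLOCK);
  for (int n = 0; n < N; ++n) {
    const double* xp = &x[0] + (size_t)H * W * C * n;
    double* yp = &y[0] + (size_t)P * Cout * n;
    for (int p0 = 0; p0 < P; p0 += COL_BLOCK) {
      const int nb = std::min(COL_BLOCK, P - p0);
      im2col_block(xp, H, W, C, kh, kw, stride, pad, Ho, p0, nb, col);
      arma::fmat Y = Wmat * col.cols(0, nb - 1);  // Cout x nb
      for (int co = 0; co < Cout; ++co) {
        const double bc = b[co];
        double* yc = yp + (size_t)P * co + p0;
        for (int pb = 0; pb < nb; ++pb) yc[pb] = (double)Y(co, pb) + bc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_dx(NumericVector w, NumericVector dy,
                                int stride, int pad, int Hin, int Win) {
  IntegerVector wd = w.attr("dim"), dyd = dy.attr("dim");
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int Ho = dyd[0], Wo = dyd[1], N = dyd[3];
  if (dyd[2] != Cout) stop("conv2d_bwd_dx: channel mismatch");
  const int K = kh * kw * Cin, P = Ho * Wo;
  NumericVector dx((size_t)Hin * Win * Cin * N);
  dx.attr("dim") = IntegerVector::create(Hin, Win, Cin, N);

  if (kh == 1 && kw == 1 && stride == 1 && pad == 0) {
    arma::mat Wt(Cout, Cin);
    for (int co = 0; co < Cout; ++co)
      for (int c = 0; c < Cin; ++c) Wt(co, c) = w[c + (size_t)Cin * co];
    for (int n = 0; n < N; ++n) {
      arma::mat dY(const_cast<double*>(&dy[0]) + (size_t)P * Cout * n, P, Cout, false);
      arma::mat dX(&dx[0] + (size_t)P * Cin * n, P, Cin, false, true);
      dX = dY * Wt;
    }
    return dx;
  }

  arma::fmat Wmat = weight_matrix(w, K, Cout);
  for (int n = 0; n < N; ++n) {
    arma::fmat dY = grad_matrix(&dy[0] + (size_t)P * Cout * n, P, Cout);
    double* dxp = &dx[0] + (size_t)Hin * Win * Cin * n;
    for (int p0 = 0; p0 < P; p0 += COL_BLOCK) {
      const int nb = std::min(COL_BLOCK, P - p0);
      arma::fmat colg = Wmat.t() * dY.rows(p0, p0 + nb - 1).t();  // K x nb
      col2im_block(colg, Hin, Win, Cin, kh, kw, stride, pad, Ho, p0, nb, dxp);
    }
  }
  return dx;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd_dwdb(NumericVector x, NumericVector dy,
                         int kh, int kw, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), dyd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = dyd[0], Wo = dyd[1], Cout = dyd[2];
  if (dyd[3] != N) stop("conv2d_bwd_dwdb: batch mismatch");
  const int K = kh * kw * C, P = Ho * Wo;
  arma::mat dWmat(Cout, K, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  arma::fmat col(K, COL_BLOCK);
  for (int n = 0; n < N; ++n) {
    const double* xp = &x[0] + (size_t)H * W * C * n;
    arma::mat dYd(const_cast<double*>(&dy[0]) + (size_t)P * Cout * n, P, Cout, false);
    if (kh == 1 && kw == 1 && stride == 1 && pad == 0) {
      arma::mat X(const_cast<double*>(xp), P, C, false);
      dWmat += dYd.t() * X;  // note: K == C here
    } else {
      arma::fmat dY = grad_matrix(&dy[0] + (size_t)P * Cout * n, P, Cout);
      for (int p0 = 0; p0 < P; p0 += COL_BLOCK) {
        const int nb = std::min(COL_BLOCK, P - p0);
        im2col_block(xp, H, W, C, kh, kw, stride, pad, Ho, p0, nb, col);
        dWmat += arma::conv_to<arma::mat>::from(
            dY.rows(p0, p0 + nb - 1).t() * col.cols(0, nb - 1).t());
      }
    }
    db += arma::sum(dYd, 0);
  }
  NumericVector dw((size_t)K * Cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int r = 0; r < K; ++r) dw[r + (size_t)K * co] = dWmat(co, r);
  NumericVector dbv(Cout);
  for (int co = 0; co < Cout; ++co) dbv[co] = db(co);
  return List::create(_["dw"] = dw, _["db"] = dbv);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool: spatial dims must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);  // 0-based linear index into x
  y.attr("dim") = idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    const double* xp = &x[0] + (size_t)H * W * C * n;
    const size_t base = (size_t)H * W * C * n;
    for (int c = 0; c < C; ++c) {
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300;
          size_t bi = 0;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              const size_t ii = (2 * ho + di) + (size_t)H * ((2 * wo + dj) + (size_t)W * c);
              if (xp[ii] > best) { best = xp[ii]; bi = ii; }
            }
          }
          y[o] = best;
          idx[o] = (int)(base + bi);
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  size_t nx = 1;
  for (int i = 0; i < xdim.size(); ++i) nx *= (size_t)xdim[i];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// Batch normalization over (H, W, N) per channel, single-pass accumulation.
// Training mode uses batch statistics and returns updated running stats;
// inference uses the stored running statistics.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector rmean, NumericVector rvar, bool training,
                double eps) {
  IntegerVector xd = x.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  const double m = (double)HW * N;
  NumericVector y(x.size()), xhat(training ? x.size() : 0);
  y.attr("dim") = xd;
  if (training) xhat.attr("dim") = xd;
  NumericVector invstd(C), nrmean(C), nrvar(C);
  for (int c = 0; c < C; ++c) {
    double mean, var;
    if (training) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* xp = &x[0] + (size_t)HW * (c + (size_t)C * n);
        for (int i = 0; i < HW; ++i) { s += xp[i]; s2 += xp[i] * xp[i]; }
      }
      mean = s / m;
      var = s2 / m - mean * mean;
      if (var < 0) var = 0;
      nrmean[c] = 0.9 * rmean[c] + 0.1 * mean;
      nrvar[c] = 0.9 * rvar[c] + 0.1 * var;
    } else {
      mean = rmean[c]; var = rvar[c];
      nrmean[c] = rmean[c]; nrvar[c] = rvar[c];
    }
    const double is = 1.0 / std::sqrt(var + eps);
    invstd[c] = is;
    const double g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = (size_t)HW * (c + (size_t)C * n);
      const double* xp = &x[0] + off;
      double* yp = &y[0] + off;
      if (training) {
        double* hp = &xhat[0] + off;
        for (int i = 0; i < HW; ++i) {
          const double h = (xp[i] - mean) * is;
          hp[i] = h; yp[i] = g * h + b;
        }
      } else {
        for (int i = 0; i < HW; ++i) yp[i] = g * (xp[i] - mean) * is + b;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["running_mean"] = nrmean, _["running_var"] = nrvar);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector dy, NumericVector xhat, NumericVector invstd,
                NumericVector gamma) {
  IntegerVector xd = dy.attr("dim");
  const int HW = xd[0] * xd[1], C = xd[2], N = xd[3];
  const double m = (double)HW * N;
  NumericVector dx(dy.size()), dgamma(C), dbeta(C);
  dx.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0, db = 0, dg = 0;
    for (int n = 0; n < N; ++n) {
      const size_t off = (size_t)HW * (c + (size_t)C * n);
      const double* dp = &dy[0] + off;
      const double* hp = &xhat[0] + off;
      for (int i = 0; i < HW; ++i) {
        db += dp[i]; dg += dp[i] * hp[i];
      }
    }
    dbeta[c] = db; dgamma[c] = dg;
    const double g = gamma[c];
    s1 = g * db; s2 = g * dg;  // sums of dxhat and dxhat*xhat
    const double k = invstd[c] / m;
    for (int n = 0; n < N; ++n) {
      const size_t off = (size_t)HW * (c + (size_t)C * n);
      const double* dp = &dy[0] + off;
      const double* hp = &xhat[0] + off;
      double* xp = &dx[0] + off;
      for (int i = 0; i < HW; ++i) {
        xp[i] = k * (m * g * dp[i] - s1 - hp[i] * s2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = &x[0];
  double* yp = &y[0];
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* dp = &dy[0];
  const double* yp = &y[0];
  double* xp = &dx[0];
  for (R_xlen_t i = 0; i < dy.size(); ++i) xp[i] = yp[i] > 0 ? dp[i] : 0.0;
  return dx;
}
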