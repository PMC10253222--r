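// 3D convolution / pooling kernels for the residual regression networks.
// Tensors are R arrays in column-major order with dims (W, H, D, C, N);
// convolution is implemented as vol2col + GEMM (and the transpose for the
// backward pass), the standard lowering used by CPU deep-learning kernels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

static NumericVector make5d(int a, int b, int c, int d, int e) {
  NumericVector v((R_xlen_t)a * b * c * d * e);
  v.attr("dim") = IntegerVector::create(a, b, c, d, e);
  return v;
}

// Fill `col` (nout x k^3*C) for sample pointer `x` with dims (W,H,D,C).
static void vol2col(const double* x, int W, int H, int D, int C,
                    int k, int s, int p, arma::mat& col) {
  const int ow = out_dim(W, k, s, p), oh = out_dim(H, k, s, p),
            od = out_dim(D, k, s, p);
  int q = 0;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)c * W * H * D;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx, ++q) {
          double* dst = col.colptr(q);
          int r = 0;
          for (int oz = 0; oz < od; ++oz) {
            const int iz = oz * s - p + kz;
            const bool zok = iz >= 0 && iz < D;
            for (int oy = 0; oy < oh; ++oy) {
              const int iy = oy * s - p + ky;
              const bool yok = zok && iy >= 0 && iy < H;
              const double* row =
                  yok ? xc + ((std::size_t)iz * H + iy) * W : nullptr;
              for (int ox = 0; ox < ow; ++ox, ++r) {
                const int ix = ox * s - p + kx;
                dst[r] = (yok && ix >= 0 && ix < W) ? row[ix] : 0.0;
              }
            }
          }
        }
  }
}

// Scatter-add `col` gradients back into the input gradient for one sample.
static void col2vol(const arma::mat& col, double* dx, int W, int H, int D,
                    int C, int k, int s, int p) {
  const int ow = out_dim(W, k, s, p), oh = out_dim(H, k, s, p),
            od = out_dim(D, k, s, p);
  int q = 0;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (std::size_t)c * W * H * D;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx, ++q) {
          const double* src = col.colptr(q);
          int r = 0;
          for (int oz = 0; oz < od; ++oz) {
            const int iz = oz * s - p + kz;
            const bool zok = iz >= 0 && iz < D;
            for (int oy = 0; oy < oh; ++oy) {
              const int iy = oy * s - p + ky;
              const bool yok = zok && iy >= 0 && iy < H;
              double* row = yok ? xc + ((std::size_t)iz * H + iy) * W : nullptr;
              for (int ox = 0; ox < ow; ++ox, ++r) {
                const int ix = ox * s - p + kx;
                if (yok && ix >= 0 && ix < W) row[ix] += src[r];
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericMatrix w,
                             NumericVector b, int k, int s, int p) {
  IntegerVector xd = x.attr("dim");
  const int W = xd[0], H = xd[1], D = xd[2], C = xd[3], N = xd[4];
  const int ow = out_dim(W, k, s, p), oh = out_dim(H, k, s, p),
            od = out_dim(D, k, s, p);
  const int cout = w.ncol(), nout = ow * oh * od;
  if (w.nrow() != k * k * k * C) stop("weight/input channel mismatch");
  NumericVector out = make5d(ow, oh, od, cout, N);
  arma::mat Wm(w.begin(), w.nrow(), cout, false);
  arma::rowvec bv(b.begin(), cout);
  const std::size_t in_stride = (std::size_t)W * H * D * C;
  const std::size_t out_stride = (std::size_t)nout * cout;
  const bool pointwise = (k == 1 && s == 1 && p == 0);
  arma::mat col;
  if (!pointwise) col.set_size(nout, k * k * k * C);
  for (int n = 0; n < N; ++n) {
    arma::mat Y(out.begin() + n * out_stride, nout, cout, false, true);
    if (pointwise) {
      // a 1x1x1 stride-1 convolution is a plain channel mixing: the
      // sample is already an (nout x C) matrix in memory
      const arma::mat X(const_cast<double*>(x.begin()) + n * in_stride,
                        nout, C, false);
      Y = X * Wm;
    } else {
      vol2col(x.begin() + n * in_stride, W, H, D, C, k, s, p, col);
      Y = col * Wm;
    }
    Y.each_row() += bv;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericMatrix w, NumericVector dout,
                    int k, int s, int p) {
  IntegerVector xd = x.attr("dim");
  const int W = xd[0], H = xd[1], D = xd[2], C = xd[3], N = xd[4];
  const int ow = out_dim(W, k, s, p), oh = out_dim(H, k, s, p),
            od = out_dim(D, k, s, p);
  const int cout = w.ncol(), nout = ow * oh * od;
  NumericVector dx = make5d(W, H, D, C, N);
  arma::mat Wm(w.begin(), w.nrow(), cout, false);
  arma::mat dW(w.nrow(), cout, arma::fill::zeros);
  arma::rowvec db(cout, arma::fill::zeros);
  const bool pointwise = (k == 1 && s == 1 && p == 0);
  arma::mat col;
  if (!pointwise) col.set_size(nout, k * k * k * C);
  const std::size_t in_stride = (std::size_t)W * H * D * C;
  const std::size_t out_stride = (std::size_t)nout * cout;
  for (int n = 0; n < N; ++n) {
    arma::mat dY(const_cast<double*>(dout.begin()) + n * out_stride,
                 nout, cout, false);
    db += arma::sum(dY, 0);
    if (pointwise) {
      const arma::mat X(const_cast<double*>(x.begin()) + n * in_stride,
                        nout, C, false);
      arma::mat dX(dx.begin() + n * in_stride, nout, C, false, true);
      dW += X.t() * dY;
      dX = dY * Wm.t();
    } else {
      vol2col(x.begin() + n * in_stride, W, H, D, C, k, s, p, col);
      dW += col.t() * dY;
      arma::mat dcol = dY * Wm.t();
      col2vol(dcol, dx.begin() + n * in_stride, W, H, D, C, k, s, p);
    }
  }
  NumericMatrix dWr(w.nrow(), cout);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  NumericVector dbr(cout);
  std::copy(db.begin(), db.end(), dbr.begin());
  return List::create(_["dx"] = dx, _["dW"] = dWr, _["db"] = dbr);
}

// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x, int k, int s, int p) {
  IntegerVector xd = x.attr("dim");
  const int W = xd[0], H = xd[1], D = xd[2], C = xd[3], N = xd[4];
  const int ow = out_dim(W, k, s, p), oh = out_dim(H, k, s, p),
            od = out_dim(D, k, s, p);
  NumericVector out = make5d(ow, oh, od, C, N);
  IntegerVector idx(out.size());  // 0-based linear index into x
  const double* xp = x.begin();
  double* op = out.begin();
  int* ip = idx.begin();
  std::size_t r = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t base = ((std::size_t)n * C + c) * W * H * D;
      for (int oz = 0; oz < od; ++oz)
        for (int oy = 0; oy < oh; ++oy)
          for (int ox = 0; ox < ow; ++ox, ++r) {
            double best = -HUGE_VAL;
            std::size_t bi = 0;
            for (int kz = 0; kz < k; ++kz) {
              const int iz = oz * s - p + kz;
              if (iz < 0 || iz >= D) continue;
              for (int ky = 0; ky < k; ++ky) {
                const int iy = oy * s - p + ky;
                if (iy < 0 || iy >= H) continue;
                for (int kx = 0; kx < k; ++kx) {
                  const int ix = ox * s - p + kx;
                  if (ix < 0 || ix >= W) continue;
                  const std::size_t li =
                      base + ((std::size_t)iz * H + iy) * W + ix;
                  if (xp[li] > best) { best = xp[li]; bi = li; }
                }
              }
            }
            op[r] = best;
            ip[r] = (int)bi;
          }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(NumericVector dout, IntegerVector idx,
                                IntegerVector xdim) {
  NumericVector dx = make5d(xdim[0], xdim[1], xdim[2], xdim[3], xdim[4]);
  const double* dp = dout.begin();
  double* xp = dx.begin();
  const int* ip = idx.begin();
  for (R_xlen_t i = 0; i < dout.size(); ++i) xp[ip[i]] += dp[i];
  return dx;
}

// ---- per-channel helpers for batch normalization ----
// x has dims (W, H, D, C, N); channel c occupies contiguous runs of
// S = W*H*D values, repeated for each sample.

// [[Rcpp::export]]
List cpp_channel_moments(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const std::size_t S = (std::size_t)xd[0] * xd[1] * xd[2];
  const int C = xd[3], N = xd[4];
  NumericVector sum(C), sumsq(C);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double s = 0, q = 0;
      for (std::size_t i = 0; i < S; ++i, ++xp) {
        s += *xp;
        q += *xp * *xp;
      }
      sum[c] += s;
      sumsq[c] += q;
    }
  return List::create(_["sum"] = sum, _["sumsq"] = sumsq);
}

// y = a[c] * x + b[c]
// [[Rcpp::export]]
NumericVector cpp_channel_affine(NumericVector x, NumericVector a,
                                 NumericVector b) {
  IntegerVector xd = x.attr("dim");
  const std::size_t S = (std::size_t)xd[0] * xd[1] * xd[2];
  const int C = xd[3], N = xd[4];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c];
      for (std::size_t i = 0; i < S; ++i) *yp++ = ac * *xp++ + bc;
    }
  return y;
}

// y = a[c] * u + b[c] * v + d[c]
// [[Rcpp::export]]
NumericVector cpp_channel_affine2(NumericVector u, NumericVector v,
                                  NumericVector a, NumericVector b,
                                  NumericVector d) {
  IntegerVector xd = u.attr("dim");
  const std::size_t S = (std::size_t)xd[0] * xd[1] * xd[2];
  const int C = xd[3], N = xd[4];
  NumericVector y(u.size());
  y.attr("dim") = xd;
  const double* up = u.begin();
  const double* vp = v.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double ac = a[c], bc = b[c], dc = d[c];
      for (std::size_t i = 0; i < S; ++i) *yp++ = ac * *up++ + bc * *vp++ + dc;
    }
  return y;
}

// per-channel sum(a * b) and sum(a)
// [[Rcpp::export]]
List cpp_channel_dots(NumericVector a, NumericVector b) {
  IntegerVector xd = a.attr("dim");
  const std::size_t S = (std::size_t)xd[0] * xd[1] * xd[2];
  const int C = xd[3], N = xd[4];
  NumericVector dot(C), suma(C);
  const double* ap = a.begin();
  const double* bp = b.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double d = 0, s = 0;
      for (std::size_t i = 0; i < S; ++i, ++ap, ++bp) {
        d += *ap * *bp;
        s += *ap;
      }
      dot[c] += d;
      suma[c] += s;
    }
  return List::create(_["dot"] = dot, _["sum"] = suma);
}
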