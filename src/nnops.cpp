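#include <Rcpp.h>
using namespace Rcpp;

// Tensors are R arrays with dim (D, H, W, C, N), column-major, depth fastest.
// im2col rows are ordered (kd fastest, kh, kw, channel) so that an R weight
// array of dim (kd, kh, kw, C_in, C_out) flattens to a conforming K x C_out
// matrix; columns are ordered (od, oh, ow, n).

static inline int out_len(int D, int k, int stride, int pad) {
  return (D + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col3d_cpp(NumericVector x, IntegerVector xdim,
                           IntegerVector k, int stride, int pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  const int kd = k[0], kh = k[1], kw = k[2];
  const int Od = out_len(D, kd, stride, pad);
  const int Oh = out_len(H, kh, stride, pad);
  const int Ow = out_len(W, kw, stride, pad);
  const int K = kd * kh * kw * C;
  const R_xlen_t ncol = (R_xlen_t)Od * Oh * Ow * N;
  NumericMatrix M(K, ncol);
  const double* xp = x.begin();
  double* mp = M.begin();
  const R_xlen_t strideC = (R_xlen_t)D * H * W;      // channel stride in x
  const R_xlen_t strideN = strideC * C;              // sample stride in x
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < Ow; ++ow) {
      const int w0 = ow * stride - pad;
      for (int oh = 0; oh < Oh; ++oh) {
        const int h0 = oh * stride - pad;
        for (int od = 0; od < Od; ++od) {
          const int d0 = od * stride - pad;
          const R_xlen_t col = od + (R_xlen_t)Od * (oh + (R_xlen_t)Oh * (ow + (R_xlen_t)Ow * n));
          double* colp = mp + col * K;
          int r = 0;
          for (int c = 0; c < C; ++c) {
            const double* xc = xp + n * strideN + c * strideC;
            for (int cc = 0; cc < kw; ++cc) {
              const int wi = w0 + cc;
              const bool wok = (wi >= 0 && wi < W);
              for (int b = 0; b < kh; ++b) {
                const int hi = h0 + b;
                const bool hok = wok && (hi >= 0 && hi < H);
                const R_xlen_t base = (R_xlen_t)D * (hi + (R_xlen_t)H * wi);
                for (int a = 0; a < kd; ++a, ++r) {
                  const int di = d0 + a;
                  colp[r] = (hok && di >= 0 && di < D) ? xc[base + di] : 0.0;
                }
              }
            }
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericVector col2im3d_cpp(NumericMatrix M, IntegerVector xdim,
                           IntegerVector k, int stride, int pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  const int kd = k[0], kh = k[1], kw = k[2];
  const int Od = out_len(D, kd, stride, pad);
  const int Oh = out_len(H, kh, stride, pad);
  const int Ow = out_len(W, kw, stride, pad);
  const int K = kd * kh * kw * C;
  NumericVector x((R_xlen_t)D * H * W * C * N);
  double* xp = x.begin();
  const double* mp = M.begin();
  const R_xlen_t strideC = (R_xlen_t)D * H * W;
  const R_xlen_t strideN = strideC * C;
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < Ow; ++ow) {
      const int w0 = ow * stride - pad;
      for (int oh = 0; oh < Oh; ++oh) {
        const int h0 = oh * stride - pad;
        for (int od = 0; od < Od; ++od) {
          const int d0 = od * stride - pad;
          const R_xlen_t col = od + (R_xlen_t)Od * (oh + (R_xlen_t)Oh * (ow + (R_xlen_t)Ow * n));
          const double* colp = mp + col * K;
          int r = 0;
          for (int c = 0; c < C; ++c) {
            double* xc = xp + n * strideN + c * strideC;
            for (int cc = 0; cc < kw; ++cc) {
              const int wi = w0 + cc;
              const bool wok = (wi >= 0 && wi < W);
              for (int b = 0; b < kh; ++b) {
                const int hi = h0 + b;
                const bool hok = wok && (hi >= 0 && hi < H);
                const R_xlen_t base = (R_xlen_t)D * (hi + (R_xlen_t)H * wi);
                for (int a = 0; a < kd; ++a, ++r) {
                  const int di = d0 + a;
                  if (hok && di >= 0 && di < D) xc[base + di] += colp[r];
                }
              }
            }
          }
        }
      }
    }
  }
  x.attr("dim") = xdim;
  return x;
}

// Precomputed gather map for one sample's (D,H,W,C) block: entry j = r + K*col
// holds the 0-based source index of M(r, col), or -1 for zero padding. The
// map is constant for fixed (xdim, k, stride, pad) and is cached R-side, so
// per-iteration im2col/col2im reduce to flat gathers/scatters.
// [[Rcpp::export]]
IntegerVector im2col_idx_cpp(IntegerVector xdim, IntegerVector k,
                             int stride, int pad) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int kd = k[0], kh = k[1], kw = k[2];
  const int Od = out_len(D, kd, stride, pad);
  const int Oh = out_len(H, kh, stride, pad);
  const int Ow = out_len(W, kw, stride, pad);
  const int K = kd * kh * kw * C;
  const R_xlen_t ncol = (R_xlen_t)Od * Oh * Ow;
  IntegerVector idx(K * ncol);
  int* ip = idx.begin();
  const R_xlen_t strideC = (R_xlen_t)D * H * W;
  for (int ow = 0; ow < Ow; ++ow) {
    const int w0 = ow * stride - pad;
    for (int oh = 0; oh < Oh; ++oh) {
      const int h0 = oh * stride - pad;
      for (int od = 0; od < Od; ++od) {
        const int d0 = od * stride - pad;
        const R_xlen_t col = od + (R_xlen_t)Od * (oh + (R_xlen_t)Oh * ow);
        int* colp = ip + col * K;
        int r = 0;
        for (int c = 0; c < C; ++c) {
          for (int cc = 0; cc < kw; ++cc) {
            const int wi = w0 + cc;
            const bool wok = (wi >= 0 && wi < W);
            for (int b = 0; b < kh; ++b) {
              const int hi = h0 + b;
              const bool hok = wok && (hi >= 0 && hi < H);
              const R_xlen_t base = c * strideC + (R_xlen_t)D * (hi + (R_xlen_t)H * wi);
              for (int a = 0; a < kd; ++a, ++r) {
                const int di = d0 + a;
                colp[r] = (hok && di >= 0 && di < D) ? (int)(base + di) : -1;
              }
            }
          }
        }
      }
    }
  }
  return idx;
}

// [[Rcpp::export]]
NumericMatrix gather_cols_cpp(NumericVector x, IntegerVector idx,
                              IntegerVector xdim, int K) {
  const int N = xdim[4];
  const R_xlen_t strideN = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  const R_xlen_t per = idx.size();
  const R_xlen_t colsPer = per / K;
  NumericMatrix M(K, colsPer * N);
  const double* xp = x.begin();
  const int* ip = idx.begin();
  double* mp = M.begin();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + n * strideN;
    double* mn = mp + (R_xlen_t)n * per;
    for (R_xlen_t j = 0; j < per; ++j) {
      const int ix = ip[j];
      mn[j] = ix >= 0 ? xn[ix] : 0.0;
    }
  }
  return M;
}

// [[Rcpp::export]]
NumericVector scatter_cols_cpp(NumericMatrix M, IntegerVector idx,
                               IntegerVector xdim, int K) {
  const int N = xdim[4];
  const R_xlen_t strideN = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector x(strideN * N);
  const R_xlen_t per = idx.size();
  double* xp = x.begin();
  const int* ip = idx.begin();
  const double* mp = M.begin();
  for (int n = 0; n < N; ++n) {
    double* xn = xp + n * strideN;
    const double* mn = mp + (R_xlen_t)n * per;
    for (R_xlen_t j = 0; j < per; ++j) {
      const int ix = ip[j];
      if (ix >= 0) xn[ix] += mn[j];
    }
  }
  x.attr("dim") = xdim;
  return x;
}

// [[Rcpp::export]]
List maxpool3d_fwd_cpp(NumericVector x, IntegerVector xdim, int pool) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], N = xdim[4];
  const int Od = D / pool, Oh = H / pool, Ow = W / pool;
  const R_xlen_t ylen = (R_xlen_t)Od * Oh * Ow * C * N;
  NumericVector y(ylen);
  IntegerVector idx(ylen);  // 1-based flat index into x of each max
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  R_xlen_t j = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t off = (R_xlen_t)D * H * W * (c + (R_xlen_t)C * n);
      for (int ow = 0; ow < Ow; ++ow) {
        for (int oh = 0; oh < Oh; ++oh) {
          for (int od = 0; od < Od; ++od, ++j) {
            double best = R_NegInf;
            R_xlen_t bestix = 0;
            for (int cc = 0; cc < pool; ++cc) {
              const int wi = ow * pool + cc;
              for (int b = 0; b < pool; ++b) {
                const int hi = oh * pool + b;
                for (int a = 0; a < pool; ++a) {
                  const int di = od * pool + a;
                  const R_xlen_t ix = off + di + (R_xlen_t)D * (hi + (R_xlen_t)H * wi);
                  if (xp[ix] > best) { best = xp[ix]; bestix = ix; }
                }
              }
            }
            yp[j] = best;
            ip[j] = (int)(bestix + 1);
          }
        }
      }
    }
  }
  // y needs reordering: loop filled (od,oh,ow) fastest within (c,n) which
  // matches dim (Od,Oh,Ow,C,N) column-major exactly.
  y.attr("dim") = IntegerVector::create(Od, Oh, Ow, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd_cpp(NumericVector gy, IntegerVector idx,
                                IntegerVector xdim) {
  const R_xlen_t xlen = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3] * xdim[4];
  NumericVector gx(xlen);
  double* gp = gx.begin();
  const double* gyp = gy.begin();
  const int* ip = idx.begin();
  const R_xlen_t m = gy.size();
  for (R_xlen_t j = 0; j < m; ++j) gp[ip[j] - 1] += gyp[j];
  gx.attr("dim") = xdim;
  return gx;
}
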