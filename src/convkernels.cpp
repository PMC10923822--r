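// Low-level image-to-column kernels backing the convolution, transposed
// convolution and max-pooling layers. Tensors are (H, W, C) R arrays
// (column-major). The patch matrix uses the transposed layout
//   colT(i + out_h*j, ki + k*kj + k*k*c)
// so each (ki, kj, c) offset occupies one contiguous column, which makes
// both the gather and the scatter sequential in memory and lets the caller
// run the convolution as a single GEMM: Y = colT %*% W. Rcpp containers are
// used directly (they alias R memory) so no tensor is ever copied across
// the R/C++ boundary.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

static inline void get_dims3(const NumericVector& x, int& H, int& W,
                             int& C) {
  IntegerVector d = x.attr("dim");
  if (d.size() == 2) { H = d[0]; W = d[1]; C = 1; }
  else { H = d[0]; W = d[1]; C = d[2]; }
}

// Gather: source cube (H, W, C) -> (out_h*out_w) x (k*k*C). Output position
// (i, j) reads source pixel (i*stride + ki - pad, j*stride + kj - pad);
// out-of-range reads are zero.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericVector& x, int k, int stride, int pad,
                         int out_h, int out_w) {
  int H, W, C;
  get_dims3(x, H, W, C);
  const double* px = x.begin();
  const R_xlen_t n_pos = (R_xlen_t)out_h * out_w;
  NumericVector out(no_init(n_pos * k * k * C));
  double* po = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* slice = px + (R_xlen_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* dst = po + n_pos * (ki + k * kj + (R_xlen_t)k * k * c);
        int i0 = 0;
        while (i0 * stride + ki - pad < 0) ++i0;
        for (int j = 0; j < out_w; ++j) {
          const int sj = j * stride + kj - pad;
          double* col = dst + (R_xlen_t)out_h * j;
          if (sj < 0 || sj >= W) {
            std::memset(col, 0, sizeof(double) * out_h);
            continue;
          }
          const double* src = slice + (R_xlen_t)H * sj;
          if (i0 > 0) std::memset(col, 0, sizeof(double) * i0);
          if (stride == 1) {
            const int i1 = std::min(out_h, H - ki + pad);
            if (i1 > i0)
              std::memcpy(col + i0, src + i0 + ki - pad,
                          sizeof(double) * (i1 - i0));
            if (i1 < out_h)
              std::memset(col + i1, 0, sizeof(double) * (out_h - i1));
          } else {
            int i = i0;
            for (; i < out_h; ++i) {
              const int si = i * stride + ki - pad;
              if (si >= H) break;
              col[i] = src[si];
            }
            if (i < out_h)
              std::memset(col + i, 0, sizeof(double) * (out_h - i));
          }
        }
      }
    }
  }
  out.attr("dim") = Dimension(n_pos, k * k * C);
  return NumericMatrix(out);
}

// Scatter (adjoint of cpp_im2col): accumulate patch-matrix entries back
// into an (H, W, C) array using the same geometry.
// [[Rcpp::export]]
NumericVector cpp_col2im(const NumericMatrix& colT, int k, int stride,
                         int pad, int out_h, int out_w, int H, int W,
                         int C) {
  NumericVector x(no_init((R_xlen_t)H * W * C));
  std::memset(x.begin(), 0, sizeof(double) * x.size());
  double* px = x.begin();
  const double* po = colT.begin();
  const R_xlen_t n_pos = (R_xlen_t)out_h * out_w;
  for (int c = 0; c < C; ++c) {
    double* slice = px + (R_xlen_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* src0 = po + n_pos * (ki + k * kj +
                                           (R_xlen_t)k * k * c);
        int i0 = 0;
        while (i0 * stride + ki - pad < 0) ++i0;
        for (int j = 0; j < out_w; ++j) {
          const int sj = j * stride + kj - pad;
          if (sj < 0 || sj >= W) continue;
          const double* in = src0 + (R_xlen_t)out_h * j;
          double* dst = slice + (R_xlen_t)H * sj;
          if (stride == 1) {
            const int i1 = std::min(out_h, H - ki + pad);
            for (int i = i0; i < i1; ++i) dst[i + ki - pad] += in[i];
          } else {
            for (int i = i0; i < out_h; ++i) {
              const int si = i * stride + ki - pad;
              if (si >= H) break;
              dst[si] += in[i];
            }
          }
        }
      }
    }
  }
  x.attr("dim") = Dimension(H, W, C);
  return x;
}

// 2x2 stride-2 max pooling with 'valid' windows (last row/col dropped for
// odd sizes, so 299 -> 149). Returns the pooled array and the 1-based
// linear argmax index into the input array for each output element.
// [[Rcpp::export]]
List cpp_maxpool(const NumericVector& x) {
  int H, W, C;
  get_dims3(x, H, W, C);
  const int oh = H / 2, ow = W / 2;
  const double* px = x.begin();
  NumericVector y(no_init((R_xlen_t)oh * ow * C));
  IntegerVector idx(no_init((R_xlen_t)oh * ow * C));
  double* py = y.begin();
  int* pi = idx.begin();
  R_xlen_t t = 0;
  for (int c = 0; c < C; ++c) {
    const double* slice = px + (R_xlen_t)H * W * c;
    const R_xlen_t off = (R_xlen_t)H * W * c;
    for (int j = 0; j < ow; ++j) {
      const double* c0 = slice + (R_xlen_t)H * (2 * j);
      const double* c1 = slice + (R_xlen_t)H * (2 * j + 1);
      for (int i = 0; i < oh; ++i) {
        const int si = 2 * i;
        double best = c0[si];
        R_xlen_t bidx = off + (R_xlen_t)H * (2 * j) + si;
        if (c0[si + 1] > best) { best = c0[si + 1]; bidx += 1; }
        if (c1[si] > best) {
          best = c1[si]; bidx = off + (R_xlen_t)H * (2 * j + 1) + si;
        }
        if (c1[si + 1] > best) {
          best = c1[si + 1]; bidx = off + (R_xlen_t)H * (2 * j + 1) + si + 1;
        }
        py[t] = best;
        pi[t] = (int)(bidx + 1);
        ++t;
      }
    }
  }
  y.attr("dim") = Dimension(oh, ow, C);
  return List::create(Named("y") = y, Named("idx") = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(const NumericVector& dy,
                             const IntegerVector& idx, int H, int W) {
  int oh, ow, C;
  get_dims3(dy, oh, ow, C);
  NumericVector dx(no_init((R_xlen_t)H * W * C));
  std::memset(dx.begin(), 0, sizeof(double) * dx.size());
  double* pd = dx.begin();
  const double* ps = dy.begin();
  const int* pi = idx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t t = 0; t < n; ++t) pd[pi[t] - 1] += ps[t];
  dx.attr("dim") = Dimension(H, W, C);
  return dx;
}

// ---- fused convolution kernels ------------------------------------------
// These build the patch matrix in a reused C++ scratch buffer (no R
// allocation, no GC pressure) and call BLAS dgemm directly, so a
// convolution costs one gather plus one GEMM.

#include <R_ext/BLAS.h>
#include <vector>

static std::vector<double> g_buf1, g_buf2;

static void im2col_buf(const double* px, int H, int W, int C, int k,
                       int stride, int pad, int out_h, int out_w,
                       double* po) {
  const R_xlen_t n_pos = (R_xlen_t)out_h * out_w;
  for (int c = 0; c < C; ++c) {
    const double* slice = px + (R_xlen_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* dst = po + n_pos * (ki + k * kj + (R_xlen_t)k * k * c);
        int i0 = 0;
        while (i0 * stride + ki - pad < 0) ++i0;
        for (int j = 0; j < out_w; ++j) {
          const int sj = j * stride + kj - pad;
          double* col = dst + (R_xlen_t)out_h * j;
          if (sj < 0 || sj >= W) {
            std::memset(col, 0, sizeof(double) * out_h);
            continue;
          }
          const double* src = slice + (R_xlen_t)H * sj;
          if (i0 > 0) std::memset(col, 0, sizeof(double) * i0);
          if (stride == 1) {
            const int i1 = std::min(out_h, H - ki + pad);
            if (i1 > i0)
              std::memcpy(col + i0, src + i0 + ki - pad,
                          sizeof(double) * (i1 - i0));
            if (i1 < out_h)
              std::memset(col + i1, 0, sizeof(double) * (out_h - i1));
          } else {
            int i = i0;
            for (; i < out_h; ++i) {
              const int si = i * stride + ki - pad;
              if (si >= H) break;
              col[i] = src[si];
            }
            if (i < out_h)
              std::memset(col + i, 0, sizeof(double) * (out_h - i));
          }
        }
      }
    }
  }
}

static void col2im_buf(const double* po, int k, int stride, int pad,
                       int out_h, int out_w, int H, int W, int C,
                       double* px) {
  std::memset(px, 0, sizeof(double) * (R_xlen_t)H * W * C);
  const R_xlen_t n_pos = (R_xlen_t)out_h * out_w;
  for (int c = 0; c < C; ++c) {
    double* slice = px + (R_xlen_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* src0 = po + n_pos * (ki + k * kj +
                                           (R_xlen_t)k * k * c);
        int i0 = 0;
        while (i0 * stride + ki - pad < 0) ++i0;
        for (int j = 0; j < out_w; ++j) {
          const int sj = j * stride + kj - pad;
          if (sj < 0 || sj >= W) continue;
          const double* in = src0 + (R_xlen_t)out_h * j;
          double* dst = slice + (R_xlen_t)H * sj;
          if (stride == 1) {
            const int i1 = std::min(out_h, H - ki + pad);
            for (int i = i0; i < i1; ++i) dst[i + ki - pad] += in[i];
          } else {
            for (int i = i0; i < out_h; ++i) {
              const int si = i * stride + ki - pad;
              if (si >= H) break;
              dst[si] += in[i];
            }
          }
        }
      }
    }
  }
}

static void dgemm_(char ta, char tb, int m, int n, int kk, double alpha,
                   const double* A, int lda, const double* B, int ldb,
                   double beta, double* C, int ldc) {
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &kk, &alpha, A, &lda, B, &ldb, &beta,
                  C, &ldc FCONE FCONE);
}

// Convolution forward: y = im2col(x) %*% W + b. W is (k*k*C) x F.
// [[Rcpp::export]]
NumericVector cpp_conv_fw(const NumericVector& x, const NumericMatrix& W,
                          const NumericVector& b, int k, int stride,
                          int pad, int out_h, int out_w) {
  int H, Wd, C;
  get_dims3(x, H, Wd, C);
  const int F = W.ncol();
  const R_xlen_t n_pos = (R_xlen_t)out_h * out_w;
  g_buf1.resize(n_pos * k * k * C);
  im2col_buf(x.begin(), H, Wd, C, k, stride, pad, out_h, out_w,
             g_buf1.data());
  NumericVector y(no_init(n_pos * F));
  dgemm_('N', 'N', (int)n_pos, F, k * k * C, 1.0, g_buf1.data(),
         (int)n_pos, W.begin(), k * k * C, 0.0, y.begin(), (int)n_pos);
  double* py = y.begin();
  for (int f = 0; f < F; ++f) {
    const double bf = b[f];
    double* col = py + n_pos * f;
    for (R_xlen_t i = 0; i < n_pos; ++i) col[i] += bf;
  }
  y.attr("dim") = Dimension(out_h, out_w, F);
  return y;
}

// Convolution backward: returns dx, dW (k*k*C x F) and db.
// [[Rcpp::export]]
List cpp_conv_bw(const NumericVector& x, const NumericMatrix& W,
                 const NumericVector& dy, int k, int stride, int pad,
                 int out_h, int out_w) {
  int H, Wd, C;
  get_dims3(x, H, Wd, C);
  const int F = W.ncol();
  const R_xlen_t n_pos = (R_xlen_t)out_h * out_w;
  const int kkC = k * k * C;
  g_buf1.resize(n_pos * kkC);
  im2col_buf(x.begin(), H, Wd, C, k, stride, pad, out_h, out_w,
             g_buf1.data());
  NumericMatrix dW(kkC, F);
  dgemm_('T', 'N', kkC, F, (int)n_pos, 1.0, g_buf1.data(), (int)n_pos,
         dy.begin(), (int)n_pos, 0.0, dW.begin(), kkC);
  NumericVector db(F);
  for (int f = 0; f < F; ++f) {
    const double* col = dy.begin() + n_pos * f;
    double s = 0;
    for (R_xlen_t i = 0; i < n_pos; ++i) s += col[i];
    db[f] = s;
  }
  g_buf2.resize(n_pos * kkC);
  dgemm_('N', 'T', (int)n_pos, kkC, F, 1.0, dy.begin(), (int)n_pos,
         W.begin(), kkC, 0.0, g_buf2.data(), (int)n_pos);
  NumericVector dx(no_init((R_xlen_t)H * Wd * C));
  col2im_buf(g_buf2.data(), k, stride, pad, out_h, out_w, H, Wd, C,
             dx.begin());
  dx.attr("dim") = Dimension(H, Wd, C);
  return List::create(Named("dx") = dx, Named("dW") = dW,
                      Named("db") = db);
}

// Transposed convolution forward (stride 2): the adjoint scatter of a
// stride-2 gather. V is (k*k*F) x C_in; output is (out_h, out_w, F).
// [[Rcpp::export]]
NumericVector cpp_convt_fw(const NumericVector& x, const NumericMatrix& V,
                           const NumericVector& b, int k, int out_h,
                           int out_w) {
  int H, W, C;
  get_dims3(x, H, W, C);
  const int kkF = V.nrow();
  const int F = kkF / (k * k);
  const R_xlen_t n_pos = (R_xlen_t)H * W;
  g_buf1.resize(n_pos * kkF);
  // dcolT = x_mat (N x C) %*% V^T -> N x kkF
  dgemm_('N', 'T', (int)n_pos, kkF, C, 1.0, x.begin(), (int)n_pos,
         V.begin(), kkF, 0.0, g_buf1.data(), (int)n_pos);
  NumericVector y(no_init((R_xlen_t)out_h * out_w * F));
  col2im_buf(g_buf1.data(), k, 2, 0, H, W, out_h, out_w, F, y.begin());
  double* py = y.begin();
  const R_xlen_t plane = (R_xlen_t)out_h * out_w;
  for (int f = 0; f < F; ++f) {
    const double bf = b[f];
    double* col = py + plane * f;
    for (R_xlen_t i = 0; i < plane; ++i) col[i] += bf;
  }
  y.attr("dim") = Dimension(out_h, out_w, F);
  return y;
}

// Transposed convolution backward: returns dx, dV and db.
// [[Rcpp::export]]
List cpp_convt_bw(const NumericVector& x, const NumericMatrix& V,
                  const NumericVector& dy, int k) {
  int H, W, C;
  get_dims3(x, H, W, C);
  int oh, ow, F;
  get_dims3(dy, oh, ow, F);
  const int kkF = k * k * F;
  const R_xlen_t n_pos = (R_xlen_t)H * W;
  g_buf1.resize(n_pos * kkF);
  im2col_buf(dy.begin(), oh, ow, F, k, 2, 0, H, W, g_buf1.data());
  NumericMatrix dV(kkF, C);
  dgemm_('T', 'N', kkF, C, (int)n_pos, 1.0, g_buf1.data(), (int)n_pos,
         x.begin(), (int)n_pos, 0.0, dV.begin(), kkF);
  NumericVector db(F);
  const R_xlen_t plane = (R_xlen_t)oh * ow;
  for (int f = 0; f < F; ++f) {
    const double* col = dy.begin() + plane * f;
    double s = 0;
    for (R_xlen_t i = 0; i < plane; ++i) s += col[i];
    db[f] = s;
  }
  NumericVector dx(no_init(n_pos * C));
  dgemm_('N', 'N', (int)n_pos, C, kkF, 1.0, g_buf1.data(), (int)n_pos,
         V.begin(), kkF, 0.0, dx.begin(), (int)n_pos);
  dx.attr("dim") = Dimension(H, W, C);
  return List::create(Named("dx") = dx, Named("dV") = dV,
                      Named("db") = db);
}

// ---- fused elementwise/statistics helpers --------------------------------
// Per-channel affine transforms, batch-norm reductions and CBAM descriptor
// passes, each a single sweep over the tensor with no R intermediates.

// per-channel sum and sum of squares
// [[Rcpp::export]]
List cpp_channel_stats(const NumericVector& x) {
  int H, W, C;
  get_dims3(x, H, W, C);
  const R_xlen_t np = (R_xlen_t)H * W;
  NumericVector s(C), sq(C);
  for (int c = 0; c < C; ++c) {
    const double* p = x.begin() + np * c;
    double a = 0, b = 0;
    for (R_xlen_t i = 0; i < np; ++i) { a += p[i]; b += p[i] * p[i]; }
    s[c] = a; sq[c] = b;
  }
  return List::create(Named("sum") = s, Named("sqsum") = sq);
}

// y = x * a[c] + b[c] per channel (fused batch-norm / gating transform)
// [[Rcpp::export]]
NumericVector cpp_channel_affine(const NumericVector& x,
                                 const NumericVector& a,
                                 const NumericVector& b) {
  int H, W, C;
  get_dims3(x, H, W, C);
  const R_xlen_t np = (R_xlen_t)H * W;
  NumericVector y(no_init(np * C));
  for (int c = 0; c < C; ++c) {
    const double* p = x.begin() + np * c;
    double* q = y.begin() + np * c;
    const double ac = a[c], bc = b[c];
    for (R_xlen_t i = 0; i < np; ++i) q[i] = p[i] * ac + bc;
  }
  y.attr("dim") = Dimension(H, W, C);
  return y;
}

// per-channel sums of dy and of dy * xhat, with xhat = (x - mu) * inv_std
// [[Rcpp::export]]
List cpp_bn_bw_sums(const NumericVector& x, const NumericVector& dy,
                    const NumericVector& mu, const NumericVector& inv_std) {
  int H, W, C;
  get_dims3(x, H, W, C);
  const R_xlen_t np = (R_xlen_t)H * W;
  NumericVector s1(C), s2(C);
  for (int c = 0; c < C; ++c) {
    const double* px = x.begin() + np * c;
    const double* pd = dy.begin() + np * c;
    const double m = mu[c], is = inv_std[c];
    double a = 0, b = 0;
    for (R_xlen_t i = 0; i < np; ++i) {
      a += pd[i];
      b += pd[i] * (px[i] - m) * is;
    }
    s1[c] = a; s2[c] = b;
  }
  return List::create(Named("sum_dy") = s1, Named("sum_dy_xhat") = s2);
}

// dx = (gamma * inv_std / N) * (N * dy - s1 - xhat * s2)
// [[Rcpp::export]]
NumericVector cpp_bn_bw_dx(const NumericVector& x, const NumericVector& dy,
                           const NumericVector& mu,
                           const NumericVector& inv_std,
                           const NumericVector& gamma,
                           const NumericVector& s1, const NumericVector& s2,
                           double N) {
  int H, W, C;
  get_dims3(x, H, W, C);
  const R_xlen_t np = (R_xlen_t)H * W;
  NumericVector dx(no_init(np * C));
  for (int c = 0; c < C; ++c) {
    const double* px = x.begin() + np * c;
    const double* pd = dy.begin() + np * c;
    double* q = dx.begin() + np * c;
    const double m = mu[c], is = inv_std[c];
    const double f = gamma[c] * is / N, a1 = s1[c], a2 = s2[c];
    for (R_xlen_t i = 0; i < np; ++i)
      q[i] = f * (N * pd[i] - a1 - (px[i] - m) * is * a2);
  }
  dx.attr("dim") = Dimension(H, W, C);
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_relu_fw(const NumericVector& x) {
  NumericVector y(no_init(x.size()));
  const double* p = x.begin();
  double* q = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) q[i] = p[i] > 0 ? p[i] : 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bw(const NumericVector& y, const NumericVector& dy) {
  NumericVector dx(no_init(dy.size()));
  const double* py = y.begin();
  const double* pd = dy.begin();
  double* q = dx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) q[i] = py[i] > 0 ? pd[i] : 0;
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// channel descriptors: per-channel mean, max and 1-based argmax pixel
// [[Rcpp::export]]
List cpp_chan_descr(const NumericVector& x) {
  int H, W, C;
  get_dims3(x, H, W, C);
  const R_xlen_t np = (R_xlen_t)H * W;
  NumericVector va(C), vm(C);
  IntegerVector carg(C);
  for (int c = 0; c < C; ++c) {
    const double* p = x.begin() + np * c;
    double s = 0, best = p[0];
    R_xlen_t bi = 0;
    for (R_xlen_t i = 0; i < np; ++i) {
      s += p[i];
      if (p[i] > best) { best = p[i]; bi = i; }
    }
    va[c] = s / np; vm[c] = best; carg[c] = (int)(bi + 1);
  }
  return List::create(Named("va") = va, Named("vm") = vm,
                      Named("carg") = carg);
}

// spatial descriptors of a channel-gated tensor: per-pixel channel mean,
// max and 1-based argmax channel
// [[Rcpp::export]]
List cpp_spatial_descr(const NumericVector& x) {
  int H, W, C;
  get_dims3(x, H, W, C);
  const R_xlen_t np = (R_xlen_t)H * W;
  NumericVector savg(np), smax(no_init(np));
  IntegerVector sarg(no_init(np));
  const double* p0 = x.begin();
  for (R_xlen_t i = 0; i < np; ++i) { smax[i] = p0[i]; sarg[i] = 1; }
  double* pa = savg.begin();
  double* pm = smax.begin();
  int* pg = sarg.begin();
  for (int c = 0; c < C; ++c) {
    const double* p = x.begin() + np * c;
    for (R_xlen_t i = 0; i < np; ++i) {
      pa[i] += p[i];
      if (p[i] > pm[i]) { pm[i] = p[i]; pg[i] = c + 1; }
    }
  }
  for (R_xlen_t i = 0; i < np; ++i) pa[i] /= C;
  return List::create(Named("savg") = savg, Named("smax") = smax,
                      Named("sarg") = sarg);
}

// y = x * S (per-pixel gate broadcast across channels)
// [[Rcpp::export]]
NumericVector cpp_scale_spatial(const NumericVector& x,
                                const NumericVector& S) {
  int H, W, C;
  get_dims3(x, H, W, C);
  const R_xlen_t np = (R_xlen_t)H * W;
  NumericVector y(no_init(np * C));
  for (int c = 0; c < C; ++c) {
    const double* p = x.begin() + np * c;
    double* q = y.begin() + np * c;
    const double* ps = S.begin();
    for (R_xlen_t i = 0; i < np; ++i) q[i] = p[i] * ps[i];
  }
  y.attr("dim") = Dimension(H, W, C);
  return y;
}

// per-pixel dot product across channels: out[i] = sum_c a[i,c] * b[i,c]
// [[Rcpp::export]]
NumericVector cpp_pixel_dot(const NumericVector& a,
                            const NumericVector& b) {
  int H, W, C;
  get_dims3(a, H, W, C);
  const R_xlen_t np = (R_xlen_t)H * W;
  NumericVector out(np);
  double* q = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* pa = a.begin() + np * c;
    const double* pb = b.begin() + np * c;
    for (R_xlen_t i = 0; i < np; ++i) q[i] += pa[i] * pb[i];
  }
  return out;
}

// per-channel dot product: out[c] = sum_i a[i,c] * b[i,c]
// [[Rcpp::export]]
NumericVector cpp_channel_dot(const NumericVector& a,
                              const NumericVector& b) {
  int H, W, C;
  get_dims3(a, H, W, C);
  const R_xlen_t np = (R_xlen_t)H * W;
  NumericVector out(C);
  for (int c = 0; c < C; ++c) {
    const double* pa = a.begin() + np * c;
    const double* pb = b.begin() + np * c;
    double s = 0;
    for (R_xlen_t i = 0; i < np; ++i) s += pa[i] * pb[i];
    out[c] = s;
  }
  return out;
}

// spatial-attention input gradient: dx = dxm1 + davg/C (all channels),
// plus dmax scattered into each pixel's argmax channel
// [[Rcpp::export]]
NumericVector cpp_cbam_spatial_bw(const NumericVector& dxm1,
                                  const NumericVector& davg,
                                  const NumericVector& dmax,
                                  const IntegerVector& sarg) {
  int H, W, C;
  get_dims3(dxm1, H, W, C);
  const R_xlen_t np = (R_xlen_t)H * W;
  NumericVector dx(no_init(np * C));
  for (int c = 0; c < C; ++c) {
    const double* p = dxm1.begin() + np * c;
    double* q = dx.begin() + np * c;
    const double* pa = davg.begin();
    for (R_xlen_t i = 0; i < np; ++i) q[i] = p[i] + pa[i] / C;
  }
  const double* pm = dmax.begin();
  const int* pg = sarg.begin();
  for (R_xlen_t i = 0; i < np; ++i)
    dx[np * (pg[i] - 1) + i] += pm[i];
  dx.attr("dim") = Dimension(H, W, C);
  return dx;
}
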