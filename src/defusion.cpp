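// Low-level numerical kernels: 3x3 stride-1 convolution (forward/backward,
// im2col + BLAS) and separable image filtering. Everything operates on a
// single sample; batching is looped one level up in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col for a 3x3 window with zero padding 1.
// Column index r = di + 3*dj + 9*c matches the R weight layout
// dim = c(3, 3, Cin, Cout) flattened over its first three dimensions.
static arma::mat im2col3(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(H * W, 9 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int r = di + 3 * dj + 9 * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - 1;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - 1;
            if (si < 0 || si >= H) continue;
            cols(i + H * j, r) = x(si, sj, c);
          }
        }
      }
    }
  }
  return cols;
}

// y = conv3x3(x, W) + b, zero padding 1, stride 1.
// [[Rcpp::export]]
arma::cube cpp_conv3_fwd(const arma::cube& x, const arma::mat& Wm,
                         const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = Wm.n_cols;
  arma::mat y = im2col3(x) * Wm;
  y.each_row() += b.t();
  arma::cube out(H, W, Cout);
  for (int o = 0; o < Cout; ++o)
    out.slice(o) = arma::reshape(y.col(o), H, W);
  return out;
}

// Gradients of the same convolution: gx, gW, gb given upstream gy.
// [[Rcpp::export]]
List cpp_conv3_bwd(const arma::cube& x, const arma::mat& Wm,
                   const arma::cube& gy) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  arma::mat gy_mat(H * W, Cout);
  for (int o = 0; o < Cout; ++o)
    gy_mat.col(o) = arma::vectorise(gy.slice(o));
  arma::mat cols = im2col3(x);
  arma::mat gW = cols.t() * gy_mat;
  arma::vec gb = arma::sum(gy_mat, 0).t();
  arma::mat gcols = gy_mat * Wm.t();
  arma::cube gx(H, W, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int r = di + 3 * dj + 9 * c;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - 1;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - 1;
            if (si < 0 || si >= H) continue;
            gx(si, sj, c) += gcols(i + H * j, r);
          }
        }
      }
    }
  }
  return List::create(Named("gx") = gx, Named("gW") = gW, Named("gb") = gb);
}

// Batched variants: activations are (H*W*N) x C matrices, sample-major in
// blocks of H*W rows (column-major spatial flatten within each block).
static arma::mat im2col3_batch(const arma::mat& x, int H, int W, int N) {
  const int C = x.n_cols, P = H * W;
  arma::mat cols(P * N, 9 * C, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const int off = n * P;
    for (int c = 0; c < C; ++c) {
      for (int dj = 0; dj < 3; ++dj) {
        for (int di = 0; di < 3; ++di) {
          const int r = di + 3 * dj + 9 * c;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dj - 1;
            if (sj < 0 || sj >= W) continue;
            const int i0 = (di - 1 < 0) ? 1 : 0;
            const int i1 = (di - 1 > 0) ? H - 1 : H;
            double* dst = cols.colptr(r) + off + H * j;
            const double* src = x.colptr(c) + off + H * sj + (di - 1);
            for (int i = i0; i < i1; ++i) dst[i] = src[i];
          }
        }
      }
    }
  }
  return cols;
}

// Forward returns the im2col matrix alongside y so the backward pass can
// reuse it instead of rebuilding it.
// [[Rcpp::export]]
List cpp_conv3_fwd_batch(const arma::mat& x, int H, int W, int N,
                         const arma::mat& Wm, const arma::vec& b,
                         bool keep_cols) {
  arma::mat cols = im2col3_batch(x, H, W, N);
  arma::mat y = cols * Wm;
  y.each_row() += b.t();
  if (keep_cols)
    return List::create(Named("y") = y, Named("cols") = cols);
  return List::create(Named("y") = y);
}

// [[Rcpp::export]]
List cpp_conv3_bwd_batch(const arma::mat& cols, int H, int W, int N,
                         const arma::mat& Wm, const arma::mat& gy,
                         bool need_gx) {
  const int Cin = Wm.n_rows / 9, P = H * W;
  arma::mat gW = cols.t() * gy;
  arma::vec gb = arma::sum(gy, 0).t();
  if (!need_gx)
    return List::create(Named("gx") = R_NilValue, Named("gW") = gW,
                        Named("gb") = gb);
  arma::mat gcols = gy * Wm.t();
  arma::mat gx(P * N, Cin, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const int off = n * P;
    for (int c = 0; c < Cin; ++c) {
      for (int dj = 0; dj < 3; ++dj) {
        for (int di = 0; di < 3; ++di) {
          const int r = di + 3 * dj + 9 * c;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dj - 1;
            if (sj < 0 || sj >= W) continue;
            const int i0 = (di - 1 < 0) ? 1 : 0;
            const int i1 = (di - 1 > 0) ? H - 1 : H;
            double* dst = gx.colptr(c) + off + H * sj + (di - 1);
            const double* src = gcols.colptr(r) + off + H * j;
            for (int i = i0; i < i1; ++i) dst[i] += src[i];
          }
        }
      }
    }
  }
  return List::create(Named("gx") = gx, Named("gW") = gW, Named("gb") = gb);
}

// Batch-norm forward (training mode): per-column standardization.
// [[Rcpp::export]]
List cpp_bn_fwd_train(const arma::mat& z, const arma::vec& gamma,
                      const arma::vec& beta, double eps) {
  arma::rowvec mu = arma::mean(z, 0);
  arma::mat xhat = z;
  xhat.each_row() -= mu;
  arma::rowvec va = arma::mean(arma::square(xhat), 0);
  arma::rowvec inv = 1.0 / arma::sqrt(va + eps);
  xhat.each_row() %= inv;
  arma::mat y = xhat;
  y.each_row() %= gamma.t();
  y.each_row() += beta.t();
  return List::create(Named("y") = y, Named("xhat") = xhat,
                      Named("mu") = mu.t(), Named("va") = va.t());
}

// Batch-norm forward (eval mode): running statistics.
// [[Rcpp::export]]
arma::mat cpp_bn_fwd_eval(const arma::mat& z, const arma::vec& gamma,
                          const arma::vec& beta, const arma::vec& rm,
                          const arma::vec& rv, double eps) {
  arma::mat y = z;
  y.each_row() -= rm.t();
  y.each_row() %= (gamma / arma::sqrt(rv + eps)).t();
  y.each_row() += beta.t();
  return y;
}

// Batch-norm backward through the batch statistics.
// [[Rcpp::export]]
List cpp_bn_bwd(const arma::mat& gy, const arma::mat& xhat,
                const arma::vec& va, const arma::vec& gamma, double eps) {
  arma::rowvec ggamma = arma::sum(gy % xhat, 0);
  arma::rowvec gbeta = arma::sum(gy, 0);
  arma::mat gxhat = gy;
  gxhat.each_row() %= gamma.t();
  arma::rowvec m1 = arma::mean(gxhat, 0);
  arma::rowvec m2 = arma::mean(gxhat % xhat, 0);
  arma::mat gx = xhat;
  gx.each_row() %= m2;
  gx = gxhat - gx;
  gx.each_row() -= m1;
  gx.each_row() %= (1.0 / arma::sqrt(va.t() + eps));
  return List::create(Named("gx") = gx, Named("ggamma") = ggamma.t(),
                      Named("gbeta") = gbeta.t());
}

static inline int reflect_idx(int i, int n) {
  // symmetric boundary without edge repetition: -1 -> 1, n -> n-2
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// 1-D correlation along columns of x with kernel k.
// mode: 0 = same size, zero padding; 1 = same size, reflect padding;
//       2 = valid (n - K + 1); 3 = full adjoint of valid, out(q) = sum_u
//       k(u) x(q - u) with zero padding (size n + K - 1).
static arma::mat corr1_cols(const arma::mat& x, const arma::vec& k, int mode) {
  const int n = x.n_rows, m = x.n_cols, K = k.n_elem, c = (K - 1) / 2;
  int no = (mode == 2) ? n - K + 1 : (mode == 3 ? n + K - 1 : n);
  arma::mat out(no, m, arma::fill::zeros);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < no; ++i) {
      double s = 0.0;
      for (int u = 0; u < K; ++u) {
        int si;
        if (mode == 2) si = i + u;
        else if (mode == 3) si = i - u;
        else si = i + u - c;
        if (mode == 1) si = reflect_idx(si, n);
        if (si < 0 || si >= n) continue;
        s += k(u) * x(si, j);
      }
      out(i, j) = s;
    }
  }
  return out;
}

// Separable 2-D filter: kernel k applied along rows then columns.
// [[Rcpp::export]]
arma::mat cpp_sepfilter(const arma::mat& x, const arma::vec& k, int mode) {
  arma::mat t = corr1_cols(x, k, mode);
  return corr1_cols(t.t(), k, mode).t();
}
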