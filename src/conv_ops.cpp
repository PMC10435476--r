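// Low-level single-sample convolution kernels for the GAN layers.
// Tensors are arma::cube with dimensions (H, W, C); weights are flat
// matrices of shape (k*k*C_in, C_out) with column index c*k*k + kj*k + ki,
// matching the im2col layout below. Batch size is 1 throughout (the
// training convention for instance-normalized translation networks).

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static cube pad_zero(const cube& x, int p) {
  if (p == 0) return x;
  cube xp(x.n_rows + 2 * p, x.n_cols + 2 * p, x.n_slices, fill::zeros);
  xp.subcube(p, p, 0, p + x.n_rows - 1, p + x.n_cols - 1, x.n_slices - 1) = x;
  return xp;
}

// windows of a padded cube as rows; row index r = oj*OH + oi
static mat im2col(const cube& x, int k, int s, int OH, int OW) {
  const int C = x.n_slices;
  const size_t Hp = x.n_rows;
  mat M(OH * (size_t)OW, (size_t)k * k * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.slice_memptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* mcol = M.colptr(c * k * k + kj * k + ki);
        for (int oj = 0; oj < OW; ++oj) {
          const double* src = xc + (oj * s + kj) * Hp + ki;
          double* dst = mcol + oj * (size_t)OH;
          if (s == 1) {
            std::memcpy(dst, src, OH * sizeof(double));
          } else {
            for (int oi = 0; oi < OH; ++oi) dst[oi] = src[oi * s];
          }
        }
      }
    }
  }
  return M;
}

// adjoint of im2col: scatter-add window rows back into a (Hp, Wp, C) cube
static cube col2im(const mat& M, int k, int s, int OH, int OW,
                   int Hp, int Wp, int C) {
  cube x(Hp, Wp, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* xc = x.slice_memptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* mcol = M.colptr(c * k * k + kj * k + ki);
        for (int oj = 0; oj < OW; ++oj) {
          double* dst = xc + (oj * s + kj) * (size_t)Hp + ki;
          const double* src = mcol + oj * (size_t)OH;
          for (int oi = 0; oi < OH; ++oi) dst[oi * s] += src[oi];
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int k, int stride, int pad) {
  cube xp = pad_zero(x, pad);
  const int OH = (xp.n_rows - k) / stride + 1;
  const int OW = (xp.n_cols - k) / stride + 1;
  mat Y = im2col(xp, k, stride, OH, OW) * W;
  Y.each_row() += b.t();
  cube y(OH, OW, W.n_cols);
  for (uword co = 0; co < W.n_cols; ++co)
    y.slice(co) = reshape(Y.col(co), OH, OW);
  return y;
}

// Fused backward: accumulates dW, db and the padded input gradient in one
// sweep over kernel offsets, avoiding the large im2col temporaries that
// make full-resolution layers memory-bound.
// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& x, const arma::mat& W,
                          const arma::cube& dy, int k, int stride, int pad) {
  cube xp = pad_zero(x, pad);
  const int OH = dy.n_rows, OW = dy.n_cols;
  const int C = x.n_slices, Cout = dy.n_slices;
  const size_t Hp = xp.n_rows;
  mat dW(W.n_rows, Cout, fill::zeros);
  vec db(Cout, fill::zeros);
  cube dxp(xp.n_rows, xp.n_cols, C, fill::zeros);
  for (int co = 0; co < Cout; ++co) {
    const double* dyc = dy.slice_memptr(co);
    db(co) = accu(dy.slice(co));
    for (int c = 0; c < C; ++c) {
      const double* xc = xp.slice_memptr(c);
      double* dxc = dxp.slice_memptr(c);
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const int col = c * k * k + kj * k + ki;
          const double w = W(col, co);
          double acc = 0.0;
          for (int oj = 0; oj < OW; ++oj) {
            const double* xrow = xc + (oj * stride + kj) * Hp + ki;
            double* dxrow = dxc + (oj * stride + kj) * Hp + ki;
            const double* dyrow = dyc + oj * (size_t)OH;
            if (stride == 1) {
              for (int oi = 0; oi < OH; ++oi) {
                acc += xrow[oi] * dyrow[oi];
                dxrow[oi] += w * dyrow[oi];
              }
            } else {
              for (int oi = 0; oi < OH; ++oi) {
                acc += xrow[oi * stride] * dyrow[oi];
                dxrow[oi * stride] += w * dyrow[oi];
              }
            }
          }
          dW(col, co) += acc;
        }
      }
    }
  }
  cube dx = (pad == 0) ? dxp
    : cube(dxp.subcube(pad, pad, 0, pad + x.n_rows - 1,
                       pad + x.n_cols - 1, x.n_slices - 1));
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Transposed convolution. Weights: (k*k*C_out, C_in). Output size
// (H-1)*stride - 2*pad + k + outpad per spatial dim.
// [[Rcpp::export]]
arma::cube cpp_convt2d_fwd(const arma::cube& x, const arma::mat& W,
                           const arma::vec& b, int k, int stride, int pad,
                           int outpad) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_rows / (k * k);
  const int Hfull = (H - 1) * stride + k;
  const int Wfull = (Wd - 1) * stride + k;
  const int OH = (H - 1) * stride - 2 * pad + k + outpad;
  const int OW = (Wd - 1) * stride - 2 * pad + k + outpad;
  mat X(H * (size_t)Wd, Cin);
  for (int c = 0; c < Cin; ++c)
    X.col(c) = vectorise(x.slice(c));
  cube yfull = col2im(X * W.t(), k, stride, H, Wd, Hfull, Wfull, Cout);
  cube y(OH, OW, Cout);
  for (int c = 0; c < Cout; ++c)
    y.slice(c) = yfull.slice(c).submat(pad, pad, pad + OH - 1, pad + OW - 1)
               + b(c);
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_convt2d_bwd(const arma::cube& x, const arma::mat& W,
                           const arma::cube& dy, int k, int stride, int pad,
                           int outpad) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices;
  const int Hfull = (H - 1) * stride + k;
  const int Wfull = (Wd - 1) * stride + k;
  cube dyfull(Hfull, Wfull, Cout, fill::zeros);
  dyfull.subcube(pad, pad, 0, pad + dy.n_rows - 1, pad + dy.n_cols - 1,
                 Cout - 1) = dy;
  mat dcols = im2col(dyfull, k, stride, H, Wd);  // (H*Wd, k*k*Cout)
  mat dX = dcols * W;                            // (H*Wd, Cin)
  mat X(H * (size_t)Wd, Cin);
  for (int c = 0; c < Cin; ++c)
    X.col(c) = vectorise(x.slice(c));
  mat dW = dcols.t() * X;
  vec db(Cout);
  cube dx(H, Wd, Cin);
  for (int c = 0; c < Cout; ++c)
    db(c) = accu(dy.slice(c));
  for (int c = 0; c < Cin; ++c)
    dx.slice(c) = reshape(dX.col(c), H, Wd);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// All k x k windows (stride 1, valid) of a 2D image as rows; used by the
// sliding-window SSIM statistics.
// [[Rcpp::export]]
arma::mat cpp_windows(const arma::mat& a, int k) {
  const int OH = a.n_rows - k + 1;
  const int OW = a.n_cols - k + 1;
  cube x(a.n_rows, a.n_cols, 1);
  x.slice(0) = a;
  return im2col(x, k, 1, OH, OW);
}
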