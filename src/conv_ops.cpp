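#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Low-level kernels for the U-Net: same-padding stride-1 convolution via
// im2col + GEMM, 2x2 max pooling with argmax bookkeeping, and factor-2
// bilinear upsampling with its exact transpose for backprop.
//
// Array convention everywhere: H x W x C cubes, column-major (R layout).
// im2col column ordering: c * K*K + ky * K + kx (offsets 0..K-1); weight
// matrices passed from R must use the same (K*K*Cin) x Cout layout.

static arma::mat im2col(const arma::cube& x, int K) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, P = K / 2;
  arma::mat M(H * (size_t)W, (size_t)K * K * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int ky = 0; ky < K; ++ky)
      for (int kx = 0; kx < K; ++kx) {
        const size_t col = (size_t)c * K * K + ky * K + kx;
        for (int j = 0; j < W; ++j) {
          const int js = j + kx - P;
          if (js < 0 || js >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int is = i + ky - P;
            if (is < 0 || is >= H) continue;
            M((size_t)j * H + i, col) = x(is, js, c);
          }
        }
      }
  return M;
}

static arma::cube col2im(const arma::mat& M, int H, int W, int C, int K) {
  const int P = K / 2;
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int ky = 0; ky < K; ++ky)
      for (int kx = 0; kx < K; ++kx) {
        const size_t col = (size_t)c * K * K + ky * K + kx;
        for (int j = 0; j < W; ++j) {
          const int js = j + kx - P;
          if (js < 0 || js >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int is = i + ky - P;
            if (is < 0 || is >= H) continue;
            gx(is, js, c) += M((size_t)j * H + i, col);
          }
        }
      }
  return gx;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fw(const arma::cube& x, const arma::mat& Wm,
                         const arma::vec& b, int K) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = Wm.n_cols;
  arma::mat Y;
  if (K == 1) {
    arma::mat X((double*)x.memptr(), (size_t)H * W, x.n_slices);
    Y = X * Wm;
  } else {
    Y = im2col(x, K) * Wm;
  }
  Y.each_row() += b.t();
  arma::cube out(H, W, Cout);
  std::memcpy(out.memptr(), Y.memptr(), Y.n_elem * sizeof(double));
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(const arma::cube& x, const arma::mat& Wm,
                   const arma::cube& gy, int K) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  arma::mat Gy((double*)gy.memptr(), (size_t)H * W, Cout);
  arma::mat gW;
  arma::cube gx(H, W, Cin);
  if (K == 1) {
    arma::mat X((double*)x.memptr(), (size_t)H * W, Cin);
    gW = X.t() * Gy;
    arma::mat Gx = Gy * Wm.t();
    std::memcpy(gx.memptr(), Gx.memptr(), Gx.n_elem * sizeof(double));
  } else {
    arma::mat M = im2col(x, K);
    gW = M.t() * Gy;
    arma::mat gM = Gy * Wm.t();
    gx = col2im(gM, H, W, Cin, K);
  }
  arma::vec gb = arma::sum(Gy, 0).t();
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);  // absolute linear index into x
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = -1e300;
        size_t bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int ii = 2 * i + di, jj = 2 * j + dj;
            const double v = x(ii, jj, c);
            if (v > best) {
              best = v;
              bi = (size_t)c * H * W + (size_t)jj * H + ii;
            }
          }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bw(const arma::cube& gy, const arma::ucube& idx,
                           int H, int W) {
  const int C = gy.n_slices;
  arma::cube gx(H, W, C, arma::fill::zeros);
  const arma::uword* p = idx.memptr();
  const double* g = gy.memptr();
  for (size_t k = 0; k < gy.n_elem; ++k) gx(p[k]) += g[k];
  return gx;
}

// Half-pixel-center bilinear interpolation, fixed factor 2.
static void up2_axis(int n_out, int n_in, arma::ivec& i0, arma::ivec& i1,
                     arma::vec& w1) {
  i0.set_size(n_out); i1.set_size(n_out); w1.set_size(n_out);
  for (int i = 0; i < n_out; ++i) {
    double u = (i + 0.5) / 2.0 - 0.5;
    if (u < 0) u = 0;
    if (u > n_in - 1) u = n_in - 1;
    int a = (int)std::floor(u);
    if (a > n_in - 2) a = n_in - 2;
    if (a < 0) a = 0;
    i0[i] = a;
    i1[i] = (n_in > 1) ? a + 1 : a;
    w1[i] = u - a;
  }
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = 2 * H, Wo = 2 * W;
  arma::ivec r0, r1, c0, c1;
  arma::vec rw, cw;
  up2_axis(Ho, H, r0, r1, rw);
  up2_axis(Wo, W, c0, c1, cw);
  arma::cube y(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j) {
      const double wj = cw[j];
      for (int i = 0; i < Ho; ++i) {
        const double wi = rw[i];
        y(i, j, c) =
            (1 - wi) * (1 - wj) * x(r0[i], c0[j], c) +
            wi * (1 - wj) * x(r1[i], c0[j], c) +
            (1 - wi) * wj * x(r0[i], c1[j], c) +
            wi * wj * x(r1[i], c1[j], c);
      }
    }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bw(const arma::cube& gy, int H, int W) {
  const int C = gy.n_slices;
  const int Ho = gy.n_rows, Wo = gy.n_cols;
  arma::ivec r0, r1, c0, c1;
  arma::vec rw, cw;
  up2_axis(Ho, H, r0, r1, rw);
  up2_axis(Wo, W, c0, c1, cw);
  arma::cube gx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j) {
      const double wj = cw[j];
      for (int i = 0; i < Ho; ++i) {
        const double wi = rw[i];
        const double g = gy(i, j, c);
        gx(r0[i], c0[j], c) += (1 - wi) * (1 - wj) * g;
        gx(r1[i], c0[j], c) += wi * (1 - wj) * g;
        gx(r0[i], c1[j], c) += (1 - wi) * wj * g;
        gx(r1[i], c1[j], c) += wi * wj * g;
      }
    }
  return gx;
}
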