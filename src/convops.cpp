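// Low-level kernels for the autograd engine.
//
// Tensor layout convention throughout the package: numeric arrays with
// dim = c(H, W, C, N) (column-major, row index fastest).  im2col produces a
// (k*k*C) x (L*N) matrix whose column order is (ho fastest, then wo, then n)
// and whose row order is (di fastest, then dj, then c), so that a weight
// matrix of shape (Cout, k*k*Cin) left-multiplies it directly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".im2col_batch")]]
arma::mat im2col_batch(const arma::vec& x, int H, int W, int C, int N,
                       int k, int stride, int pad) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  const int L = Ho * Wo;
  arma::mat cols(k * k * C, (size_t)L * N, arma::fill::zeros);
  const double* xp = x.memptr();
  for (int n = 0; n < N; ++n) {
    const double* xn = xp + (size_t)n * H * W * C;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t col = (size_t)n * L + (size_t)wo * Ho + ho;
        double* cp = cols.colptr(col);
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double* xc = xn + (size_t)c * H * W;
          for (int dj = 0; dj < k; ++dj) {
            const int w = w0 + dj;
            const bool wok = (w >= 0 && w < W);
            for (int di = 0; di < k; ++di) {
              const int h = h0 + di;
              if (wok && h >= 0 && h < H)
                cp[c * k * k + dj * k + di] = xc[(size_t)w * H + h];
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export(name = ".col2im_batch")]]
arma::vec col2im_batch(const arma::mat& cols, int H, int W, int C, int N,
                       int k, int stride, int pad) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  const int L = Ho * Wo;
  arma::vec x((size_t)H * W * C * N, arma::fill::zeros);
  double* xp = x.memptr();
  for (int n = 0; n < N; ++n) {
    double* xn = xp + (size_t)n * H * W * C;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t col = (size_t)n * L + (size_t)wo * Ho + ho;
        const double* cp = cols.colptr(col);
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          double* xc = xn + (size_t)c * H * W;
          for (int dj = 0; dj < k; ++dj) {
            const int w = w0 + dj;
            if (w < 0 || w >= W) continue;
            for (int di = 0; di < k; ++di) {
              const int h = h0 + di;
              if (h >= 0 && h < H)
                xc[(size_t)w * H + h] += cp[c * k * k + dj * k + di];
            }
          }
        }
      }
    }
  }
  return x;
}

// 2x2 stride-2 max pooling with argmax bookkeeping (H, W even).
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(const arma::vec& x, int H, int W, int C, int N) {
  const int Ho = H / 2, Wo = W / 2;
  arma::vec out((size_t)Ho * Wo * C * N);
  arma::ivec arg((size_t)Ho * Wo * C * N);
  const double* xp = x.memptr();
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          size_t i00 = base + (size_t)(2 * wo) * H + 2 * ho;
          size_t idx[4] = { i00, i00 + 1, i00 + (size_t)H, i00 + (size_t)H + 1 };
          int best = 0;
          double bv = xp[idx[0]];
          for (int t = 1; t < 4; ++t)
            if (xp[idx[t]] > bv) { bv = xp[idx[t]]; best = t; }
          out[o] = bv;
          arg[o] = (long long)idx[best];
          ++o;
        }
    }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
arma::vec maxpool2_bwd(const arma::vec& grad, const arma::ivec& argmax,
                       size_t len_in) {
  arma::vec gx(len_in, arma::fill::zeros);
  for (size_t i = 0; i < grad.n_elem; ++i) gx[(size_t)argmax[i]] += grad[i];
  return gx;
}

// Fused convolution forward: im2col + grouped GEMM + reshape to (Ho,Wo,C,N).
// [[Rcpp::export(name = ".conv_fwd")]]
List conv_fwd(const arma::vec& x, int H, int W, int C, int N,
              const arma::mat& wm, const Rcpp::Nullable<Rcpp::NumericVector>& bias,
              int k, int stride, int pad, int groups) {
  arma::mat cols = im2col_batch(x, H, W, C, N, k, stride, pad);
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  const int L = Ho * Wo;
  const int Cout = wm.n_rows;
  const int cg = C / groups, og = Cout / groups;
  arma::mat out(Cout, (size_t)L * N);
  for (int g = 0; g < groups; ++g) {
    out.rows(g * og, (g + 1) * og - 1) =
      wm.rows(g * og, (g + 1) * og - 1) *
      cols.rows((size_t)g * cg * k * k, (size_t)(g + 1) * cg * k * k - 1);
  }
  if (bias.isNotNull()) {
    Rcpp::NumericVector b(bias);
    for (size_t j = 0; j < out.n_cols; ++j)
      for (int c = 0; c < Cout; ++c) out(c, j) += b[c];
  }
  arma::vec y((size_t)Ho * Wo * Cout * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c)
      for (size_t l = 0; l < (size_t)L; ++l)
        y[l + (size_t)L * c + (size_t)L * Cout * n] = out(c, (size_t)n * L + l);
  return List::create(_["y"] = y, _["cols"] = cols);
}

// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(const arma::vec& grad, const arma::mat& cols, const arma::mat& wm,
              int H, int W, int C, int N, int k, int stride, int pad,
              int groups, bool has_bias) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  const int L = Ho * Wo;
  const int Cout = wm.n_rows;
  const int cg = C / groups, og = Cout / groups;
  arma::mat G(Cout, (size_t)L * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c)
      for (size_t l = 0; l < (size_t)L; ++l)
        G(c, (size_t)n * L + l) = grad[l + (size_t)L * c + (size_t)L * Cout * n];
  arma::mat gw(Cout, wm.n_cols);
  arma::mat gcols(cols.n_rows, cols.n_cols);
  for (int g = 0; g < groups; ++g) {
    const arma::mat Gg = G.rows(g * og, (g + 1) * og - 1);
    gw.rows(g * og, (g + 1) * og - 1) =
      Gg * cols.rows((size_t)g * cg * k * k, (size_t)(g + 1) * cg * k * k - 1).t();
    gcols.rows((size_t)g * cg * k * k, (size_t)(g + 1) * cg * k * k - 1) =
      wm.rows(g * og, (g + 1) * og - 1).t() * Gg;
  }
  arma::vec gx = col2im_batch(gcols, H, W, C, N, k, stride, pad);
  List res = List::create(_["gx"] = gx, _["gw"] = gw);
  if (has_bias) res["gb"] = Rcpp::wrap(arma::vec(arma::sum(G, 1)));
  return res;
}
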