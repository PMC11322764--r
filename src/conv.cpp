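#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Same-padded 2-D cross-correlation primitives over channel-blocked
// matrices. An n x (m*l) matrix is read as l channels of an n x m image
// (column blocks of width m). Kernels are passed as a (k*k) x l matrix
// whose column c is vec(K_c), entry p + (q-1)*k holding K_c[p, q]; the
// correlation is out[i, j] = sum_{p,q} X[i + p - cen, j + q - cen] * K[p, q]
// with zero padding and cen = (k + 1) / 2. Loops are blocked by output
// column with a local accumulator so every matrix is streamed once.

// [[Rcpp::export(name = ".im2col_channels")]]
NumericMatrix im2col_channels(const NumericMatrix& Y, int m, int l, int k) {
  const int n = Y.nrow();
  if ((R_xlen_t)m * l != (R_xlen_t)Y.ncol()) {
    stop("column count does not match m * l");
  }
  const int cen = (k + 1) / 2;
  const int kk = k * k;
  NumericMatrix out((R_xlen_t)n * m, (R_xlen_t)kk * l);
  for (int c = 0; c < l; ++c) {
    for (int q = 1; q <= k; ++q) {
      for (int p = 1; p <= k; ++p) {
        const int col = c * kk + (q - 1) * k + (p - 1);
        const int di = p - cen;
        const int dj = q - cen;
        double* ocol0 = &out(0, col);
        const int i0 = std::max(0, -di);
        const int i1 = std::min(n, n - di);
        for (int j = 0; j < m; ++j) {
          const int jj = j + dj;
          if (jj < 0 || jj >= m) continue;
          const double* ycol = &Y(0, c * m + jj);
          double* ocol = ocol0 + (R_xlen_t)j * n;
          for (int i = i0; i < i1; ++i) ocol[i] = ycol[i + di];
        }
      }
    }
  }
  return out;
}

// out (n x m) = sum over channels c of corr(Y_c, K_c)
// [[Rcpp::export(name = ".conv_mc")]]
NumericMatrix conv_mc(const NumericMatrix& Y, int m, int l, int k,
                      const NumericMatrix& Kmat) {
  const int n = Y.nrow();
  const int cen = (k + 1) / 2;
  NumericMatrix out(n, m);
  std::vector<double> acc(n);
  for (int j = 0; j < m; ++j) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int c = 0; c < l; ++c) {
      for (int q = 1; q <= k; ++q) {
        const int jj = j + q - cen;
        if (jj < 0 || jj >= m) continue;
        const double* ycol = &Y(0, c * m + jj);
        for (int p = 1; p <= k; ++p) {
          const double w = Kmat((q - 1) * k + (p - 1), c);
          if (w == 0) continue;
          const int di = p - cen;
          const int i0 = std::max(0, -di);
          const int i1 = std::min(n, n - di);
          for (int i = i0; i < i1; ++i) acc[i] += w * ycol[i + di];
        }
      }
    }
    std::copy(acc.begin(), acc.end(), &out(0, j));
  }
  return out;
}

// out (n x (m*l)): channel c = corr(G, K_c), G a single n x m channel
// [[Rcpp::export(name = ".conv_bc")]]
NumericMatrix conv_bc(const NumericMatrix& G, int k,
                      const NumericMatrix& Kmat) {
  const int n = G.nrow();
  const int m = G.ncol();
  const int l = Kmat.ncol();
  const int cen = (k + 1) / 2;
  NumericMatrix out(n, (R_xlen_t)m * l);
  std::vector<double> acc(n);
  for (int c = 0; c < l; ++c) {
    for (int j = 0; j < m; ++j) {
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int q = 1; q <= k; ++q) {
        const int jj = j + q - cen;
        if (jj < 0 || jj >= m) continue;
        const double* gcol = &G(0, jj);
        for (int p = 1; p <= k; ++p) {
          const double w = Kmat((q - 1) * k + (p - 1), c);
          if (w == 0) continue;
          const int di = p - cen;
          const int i0 = std::max(0, -di);
          const int i1 = std::min(n, n - di);
          for (int i = i0; i < i1; ++i) acc[i] += w * gcol[i + di];
        }
      }
      std::copy(acc.begin(), acc.end(), &out(0, (R_xlen_t)c * m + j));
    }
  }
  return out;
}

// out (k*k x l): [p + (q-1)k, c] = sum_{i,j} G[i, j] * Y_c[i+di, j+dj]
// (the kernel gradient sums of a same-padded correlation)
// [[Rcpp::export(name = ".kernel_sums")]]
NumericMatrix kernel_sums(const NumericMatrix& Y, int m, int l,
                          const NumericMatrix& G, int k) {
  const int n = Y.nrow();
  const int cen = (k + 1) / 2;
  const int kk = k * k;
  NumericMatrix out(kk, l);
  std::vector<double> acc((size_t)kk);
  for (int c = 0; c < l; ++c) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int j = 0; j < m; ++j) {
      const double* gcol = &G(0, j);
      for (int q = 1; q <= k; ++q) {
        const int jj = j + q - cen;
        if (jj < 0 || jj >= m) continue;
        const double* ycol = &Y(0, c * m + jj);
        for (int p = 1; p <= k; ++p) {
          const int di = p - cen;
          const int i0 = std::max(0, -di);
          const int i1 = std::min(n, n - di);
          double s = 0;
          for (int i = i0; i < i1; ++i) s += gcol[i] * ycol[i + di];
          acc[(q - 1) * k + (p - 1)] += s;
        }
      }
    }
    for (int t = 0; t < kk; ++t) out(t, c) = acc[t];
  }
  return out;
}

// fused elementwise helpers for the training loops ---------------------------

// 1 / (1 + exp(-x)), one pass
// [[Rcpp::export(name = ".sigmoid_mat")]]
NumericMatrix sigmoid_mat(const NumericMatrix& X) {
  NumericMatrix out(X.nrow(), X.ncol());
  const R_xlen_t nn = (R_xlen_t)X.nrow() * X.ncol();
  const double* x = X.begin();
  double* o = out.begin();
  for (R_xlen_t i = 0; i < nn; ++i) o[i] = 1.0 / (1.0 + std::exp(-x[i]));
  return out;
}

// g * s * (1 - s): gradient through a sigmoid with activations s
// [[Rcpp::export(name = ".sig_grad")]]
NumericMatrix sig_grad(const NumericMatrix& G, const NumericMatrix& S) {
  NumericMatrix out(G.nrow(), G.ncol());
  const R_xlen_t nn = (R_xlen_t)G.nrow() * G.ncol();
  const double* g = G.begin();
  const double* s = S.begin();
  double* o = out.begin();
  for (R_xlen_t i = 0; i < nn; ++i) o[i] = g[i] * s[i] * (1.0 - s[i]);
  return out;
}

// g * (pre > 0): gradient through a ReLU with pre-activations pre
// [[Rcpp::export(name = ".relu_grad")]]
NumericMatrix relu_grad(const NumericMatrix& G, const NumericMatrix& Pre) {
  NumericMatrix out(G.nrow(), G.ncol());
  const R_xlen_t nn = (R_xlen_t)G.nrow() * G.ncol();
  const double* g = G.begin();
  const double* p = Pre.begin();
  double* o = out.begin();
  for (R_xlen_t i = 0; i < nn; ++i) o[i] = p[i] > 0 ? g[i] : 0.0;
  return out;
}

// one fused Adam update; returns the new parameter vector and updated
// moment estimates (bias corrections bc1 = 1-beta1^t, bc2 = 1-beta2^t)
// [[Rcpp::export(name = ".adam_fused")]]
List adam_fused(const NumericVector& p, const NumericVector& g,
                const NumericVector& m, const NumericVector& v,
                double lr, double beta1, double beta2, double eps,
                double bc1, double bc2) {
  const R_xlen_t nn = p.size();
  NumericVector pn(nn), mn(nn), vn(nn);
  for (R_xlen_t i = 0; i < nn; ++i) {
    const double mi = beta1 * m[i] + (1.0 - beta1) * g[i];
    const double vi = beta2 * v[i] + (1.0 - beta2) * g[i] * g[i];
    mn[i] = mi;
    vn[i] = vi;
    pn[i] = p[i] - lr * (mi / bc1) / (std::sqrt(vi / bc2) + eps);
  }
  return List::create(_["p"] = pn, _["m"] = mn, _["v"] = vn);
}

// max(x, 0), one pass
// [[Rcpp::export(name = ".relu_mat")]]
NumericMatrix relu_mat(const NumericMatrix& X) {
  NumericMatrix out(X.nrow(), X.ncol());
  const R_xlen_t nn = (R_xlen_t)X.nrow() * X.ncol();
  const double* x = X.begin();
  double* o = out.begin();
  for (R_xlen_t i = 0; i < nn; ++i) o[i] = x[i] > 0 ? x[i] : 0.0;
  return out;
}
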