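// Hot kernels of the neural-network engine. All matrices follow the engine's
// layout: convolutional feature maps are (N*L, C) with sample index n
// fastest, position l next. The matrix products themselves stay in R (BLAS);
// these kernels only do the data movement and elementwise passes that
// dominate in pure R.
#include <Rcpp.h>
using namespace Rcpp;

// patch matrix for 'same' zero-padded 1-D convolution, kernel K (odd)
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& A, int N, int L, int C, int K) {
  int pad = (K - 1) / 2;
  NumericMatrix M(N * L, K * C);
  for (int o = 0; o < K; ++o) {
    int shift = o - pad;
    for (int c = 0; c < C; ++c) {
      const double* src = &A(0, c);
      double* dst = &M(0, o * C + c);
      for (int l = 0; l < L; ++l) {
        int l2 = l + shift;
        if (l2 < 0 || l2 >= L) continue;
        std::copy(src + (size_t)l2 * N, src + (size_t)(l2 + 1) * N,
                  dst + (size_t)l * N);
      }
    }
  }
  return M;
}

// adjoint of cpp_im2col
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dM, int N, int L, int C, int K) {
  int pad = (K - 1) / 2;
  NumericMatrix dA(N * L, C);
  for (int o = 0; o < K; ++o) {
    int shift = o - pad;
    for (int c = 0; c < C; ++c) {
      const double* src = &dM(0, o * C + c);
      double* dst = &dA(0, c);
      for (int l = 0; l < L; ++l) {
        int l2 = l + shift;
        if (l2 < 0 || l2 >= L) continue;
        const double* s = src + (size_t)l * N;
        double* d = dst + (size_t)l2 * N;
        for (int n = 0; n < N; ++n) d[n] += s[n];
      }
    }
  }
  return dA;
}

// max-pool of 2 along l; mask records whether the first element won
// [[Rcpp::export]]
List cpp_pool_fwd(const NumericMatrix& X, int N, int L) {
  int Lo = L / 2, C = X.ncol();
  NumericMatrix Y(N * Lo, C);
  LogicalMatrix mask(N * Lo, C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    double* y = &Y(0, c);
    int* m = &mask(0, c);
    for (int lo = 0; lo < Lo; ++lo) {
      const double* a = x + (size_t)(2 * lo) * N;
      const double* b = a + N;
      double* yy = y + (size_t)lo * N;
      int* mm = m + (size_t)lo * N;
      for (int n = 0; n < N; ++n) {
        bool first = a[n] >= b[n];
        yy[n] = first ? a[n] : b[n];
        mm[n] = first;
      }
    }
  }
  return List::create(_["Y"] = Y, _["mask"] = mask);
}

// [[Rcpp::export]]
NumericMatrix cpp_pool_bwd(const NumericMatrix& dY, const LogicalMatrix& mask,
                           int N, int L) {
  int Lo = L / 2, C = dY.ncol();
  NumericMatrix dX(N * L, C);
  for (int c = 0; c < C; ++c) {
    const double* dy = &dY(0, c);
    const int* m = &mask(0, c);
    double* dx = &dX(0, c);
    for (int lo = 0; lo < Lo; ++lo) {
      const double* s = dy + (size_t)lo * N;
      const int* mm = m + (size_t)lo * N;
      double* d1 = dx + (size_t)(2 * lo) * N;
      double* d2 = d1 + N;
      for (int n = 0; n < N; ++n) {
        if (mm[n]) d1[n] = s[n]; else d2[n] = s[n];
      }
    }
  }
  return dX;
}

// batch norm forward: per-column standardization with affine, one pass.
// Returns xh (standardized), Y, mu, var (population).
// [[Rcpp::export]]
List cpp_bn_fwd(const NumericMatrix& X, const NumericVector& g,
                const NumericVector& b, double eps) {
  int n = X.nrow(), C = X.ncol();
  NumericMatrix xh(n, C), Y(n, C);
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    const double* x = &X(0, c);
    double s = 0, s2 = 0;
    for (int i = 0; i < n; ++i) { s += x[i]; s2 += x[i] * x[i]; }
    double m = s / n;
    double v = s2 / n - m * m;
    if (v < 0) v = 0;
    mu[c] = m; var[c] = v;
    double inv = 1.0 / std::sqrt(v + eps);
    double gc = g[c], bc = b[c];
    double* ph = &xh(0, c);
    double* py = &Y(0, c);
    for (int i = 0; i < n; ++i) {
      ph[i] = (x[i] - m) * inv;
      py[i] = ph[i] * gc + bc;
    }
  }
  return List::create(_["xh"] = xh, _["Y"] = Y, _["mu"] = mu, _["var"] = var);
}

// apply stored (running) statistics: eval mode
// [[Rcpp::export]]
List cpp_bn_apply(const NumericMatrix& X, const NumericVector& mu,
                  const NumericVector& var, const NumericVector& g,
                  const NumericVector& b, double eps) {
  int n = X.nrow(), C = X.ncol();
  NumericMatrix xh(n, C), Y(n, C);
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(var[c] + eps);
    double m = mu[c], gc = g[c], bc = b[c];
    const double* x = &X(0, c);
    double* ph = &xh(0, c);
    double* py = &Y(0, c);
    for (int i = 0; i < n; ++i) {
      ph[i] = (x[i] - m) * inv;
      py[i] = ph[i] * gc + bc;
    }
  }
  return List::create(_["xh"] = xh, _["Y"] = Y);
}

// batch norm backward (training mode); ginv = g / sqrt(var + eps)
// [[Rcpp::export]]
List cpp_bn_bwd(const NumericMatrix& dY, const NumericMatrix& xh,
                const NumericVector& ginv) {
  int n = dY.nrow(), C = dY.ncol();
  NumericMatrix dX(n, C);
  NumericVector dg(C), db(C);
  for (int c = 0; c < C; ++c) {
    const double* dy = &dY(0, c);
    const double* h = &xh(0, c);
    double s1 = 0, s2 = 0;
    for (int i = 0; i < n; ++i) { s1 += dy[i]; s2 += dy[i] * h[i]; }
    dg[c] = s2; db[c] = s1;
    double m1 = s1 / n, m2 = s2 / n, gi = ginv[c];
    double* dx = &dX(0, c);
    for (int i = 0; i < n; ++i) dx[i] = (dy[i] - m1 - h[i] * m2) * gi;
  }
  return List::create(_["dX"] = dX, _["dg"] = dg, _["db"] = db);
}

// [[Rcpp::export]]
NumericMatrix cpp_relu(const NumericMatrix& X) {
  NumericMatrix Y(X.nrow(), X.ncol());
  size_t n = (size_t)X.nrow() * X.ncol();
  const double* x = X.begin();
  double* y = Y.begin();
  for (size_t i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : 0;
  return Y;
}

// gradient through relu using the forward output (Y > 0 iff X > 0)
// [[Rcpp::export]]
NumericMatrix cpp_relu_bwd(const NumericMatrix& dY, const NumericMatrix& Y) {
  NumericMatrix dX(dY.nrow(), dY.ncol());
  size_t n = (size_t)dY.nrow() * dY.ncol();
  const double* dy = dY.begin();
  const double* y = Y.begin();
  double* dx = dX.begin();
  for (size_t i = 0; i < n; ++i) dx[i] = y[i] > 0 ? dy[i] : 0;
  return dX;
}
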