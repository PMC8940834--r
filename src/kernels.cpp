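// Performance kernels for the convolutional-network engine: im2col/col2im
// data movement, fused column-wise scaling (batch normalisation), activation
// functions and the in-place Adam update. All heavy linear algebra stays in
// R/BLAS; these kernels only avoid the allocation churn of the equivalent
// vectorised R.

#include <Rcpp.h>
using namespace Rcpp;

// Xcol[r, k*cin + c] = Xpad[gather[r, k] - 1, c]
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& Xpad, const IntegerMatrix& gather,
                         int cin) {
  const int nr = gather.nrow(), K = gather.ncol();
  NumericMatrix out(nr, K * cin);
  for (int k = 0; k < K; ++k) {
    const int* gi = &gather(0, k);
    for (int c = 0; c < cin; ++c) {
      const double* src = &Xpad(0, c);
      double* dst = &out(0, (R_xlen_t)k * cin + c);
      for (int r = 0; r < nr; ++r) dst[r] = src[gi[r] - 1];
    }
  }
  return out;
}

// out[gather[r, k] - 1, c] += dXcol[r, k*cin + c]  (adjoint of cpp_im2col)
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dXcol,
                         const IntegerMatrix& gather, int npad, int cin) {
  const int nr = gather.nrow(), K = gather.ncol();
  NumericMatrix out(npad, cin);
  for (int k = 0; k < K; ++k) {
    const int* gi = &gather(0, k);
    for (int c = 0; c < cin; ++c) {
      double* dst = &out(0, c);
      const double* src = &dXcol(0, (R_xlen_t)k * cin + c);
      for (int r = 0; r < nr; ++r) dst[gi[r] - 1] += src[r];
    }
  }
  return out;
}

// out[rows[i] - 1, c] = X[i, c] on an nout-row zero matrix (zero padding)
// [[Rcpp::export]]
NumericMatrix cpp_scatter_rows(const NumericMatrix& X, const IntegerVector& rows,
                               int nout) {
  const int nr = X.nrow(), nc = X.ncol();
  NumericMatrix out(nout, nc);
  for (int c = 0; c < nc; ++c) {
    double* dst = &out(0, c);
    const double* src = &X(0, c);
    for (int i = 0; i < nr; ++i) dst[rows[i] - 1] = src[i];
  }
  return out;
}

// out[i, c] = X[rows[i] - 1, c] (padding removal)
// [[Rcpp::export]]
NumericMatrix cpp_gather_rows(const NumericMatrix& X, const IntegerVector& rows) {
  const int nr = rows.size(), nc = X.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    double* dst = &out(0, c);
    const double* src = &X(0, c);
    for (int i = 0; i < nr; ++i) dst[i] = src[rows[i] - 1];
  }
  return out;
}

// Y[, c] += b[c], in place
// [[Rcpp::export]]
void cpp_add_bias(NumericMatrix Y, const NumericVector& b) {
  const int nr = Y.nrow(), nc = Y.ncol();
  for (int c = 0; c < nc; ++c) {
    double* y = &Y(0, c);
    const double bc = b[c];
    for (int r = 0; r < nr; ++r) y[r] += bc;
  }
}

// out[, c] = (X[, c] - mu[c]) * inv[c]
// [[Rcpp::export]]
NumericMatrix cpp_col_center_scale(const NumericMatrix& X,
                                   const NumericVector& mu,
                                   const NumericVector& inv) {
  const int nr = X.nrow(), nc = X.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    const double* x = &X(0, c);
    double* y = &out(0, c);
    const double m = mu[c], s = inv[c];
    for (int r = 0; r < nr; ++r) y[r] = (x[r] - m) * s;
  }
  return out;
}

// out[, c] = X[, c] * a[c] + b[c]
// [[Rcpp::export]]
NumericMatrix cpp_col_scale_shift(const NumericMatrix& X,
                                  const NumericVector& a,
                                  const NumericVector& b) {
  const int nr = X.nrow(), nc = X.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    const double* x = &X(0, c);
    double* y = &out(0, c);
    const double ac = a[c], bc = b[c];
    for (int r = 0; r < nr; ++r) y[r] = x[r] * ac + bc;
  }
  return out;
}

// dX[, c] = (dxhat[, c] - s1[c] - xhat[, c] * s2[c]) * inv[c]
// (batch-norm backward; s1, s2 are the column means of dxhat and dxhat*xhat)
// [[Rcpp::export]]
NumericMatrix cpp_bn_backward(const NumericMatrix& dxhat,
                              const NumericMatrix& xhat,
                              const NumericVector& s1, const NumericVector& s2,
                              const NumericVector& inv) {
  const int nr = dxhat.nrow(), nc = dxhat.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    const double* dh = &dxhat(0, c);
    const double* xh = &xhat(0, c);
    double* y = &out(0, c);
    const double a = s1[c], b = s2[c], s = inv[c];
    for (int r = 0; r < nr; ++r) y[r] = (dh[r] - a - xh[r] * b) * s;
  }
  return out;
}

// leaky ReLU forward (slope 0 gives plain ReLU)
// [[Rcpp::export]]
NumericMatrix cpp_lrelu(const NumericMatrix& X, double slope) {
  const R_xlen_t n = X.size();
  NumericMatrix out(X.nrow(), X.ncol());
  const double* x = X.begin();
  double* y = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : slope * x[i];
  return out;
}

// leaky ReLU backward from the forward output (sign of y matches sign of x)
// [[Rcpp::export]]
NumericMatrix cpp_lrelu_grad(const NumericMatrix& dY, const NumericMatrix& Y,
                             double slope) {
  const R_xlen_t n = dY.size();
  NumericMatrix out(dY.nrow(), dY.ncol());
  const double* d = dY.begin();
  const double* y = Y.begin();
  double* g = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) g[i] = y[i] > 0 ? d[i] : slope * d[i];
  return out;
}

// In-place Adam update with bias correction at step t.
// [[Rcpp::export]]
void cpp_adam(NumericVector p, const NumericVector& g, NumericVector m,
              NumericVector v, double lr, double b1, double b2, double eps,
              int t) {
  const double c1 = 1.0 - std::pow(b1, (double)t);
  const double c2 = 1.0 - std::pow(b2, (double)t);
  const R_xlen_t n = p.size();
  double* pp = p.begin();
  const double* gp = g.begin();
  double* mp = m.begin();
  double* vp = v.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    mp[i] = b1 * mp[i] + (1.0 - b1) * gp[i];
    vp[i] = b2 * vp[i] + (1.0 - b2) * gp[i] * gp[i];
    pp[i] -= lr * (mp[i] / c1) / (std::sqrt(vp[i] / c2) + eps);
  }
}

// C = t(A) %*% B for small k = nrow(A) (gradient outer products): A is
// k x M, B is k x N. BLAS dgemm handles this shape poorly; the hand loop
// streams the M x N output once.
// [[Rcpp::export]]
NumericMatrix cpp_crossprod_smallk(const NumericMatrix& A,
                                   const NumericMatrix& B) {
  const int k = A.nrow(), M = A.ncol(), N = B.ncol();
  NumericMatrix C(M, N);
  for (int j = 0; j < N; ++j) {
    const double* bj = &B(0, j);
    double* cj = &C(0, j);
    const double* a = A.begin(); // A column i at a + i * k
    for (int i = 0; i < M; ++i) {
      const double* ai = a + (size_t)i * k;
      double acc = 0.0;
      for (int r = 0; r < k; ++r) acc += ai[r] * bj[r];
      cj[i] = acc;
    }
  }
  return C;
}

// C = X %*% t(W) for small m = nrow(X): X is m x K, W is N x K. Streams W
// once while the m x N accumulator stays cache-resident.
// [[Rcpp::export]]
NumericMatrix cpp_tcrossprod_smallm(const NumericMatrix& X,
                                    const NumericMatrix& W) {
  const int m = X.nrow(), K = X.ncol(), N = W.nrow();
  NumericMatrix C(m, N);
  for (int k = 0; k < K; ++k) {
    const double* wk = &W(0, k);
    const double* xk = &X(0, k);
    double* c = C.begin();
    for (int j = 0; j < N; ++j) {
      const double w = wk[j];
      double* cj = c + (size_t)j * m;
      for (int i = 0; i < m; ++i) cj[i] += xk[i] * w;
    }
  }
  return C;
}

// Adam with single-precision moment state held in R integer vectors
// (bit-cast to float), halving optimiser-state memory traffic.
// [[Rcpp::export]]
void cpp_adam_f(NumericVector p, const NumericVector& g, IntegerVector m,
                IntegerVector v, double lr, double b1, double b2, double eps,
                int t) {
  const double c1 = 1.0 - std::pow(b1, (double)t);
  const double c2 = 1.0 - std::pow(b2, (double)t);
  const R_xlen_t n = p.size();
  double* pp = p.begin();
  const double* gp = g.begin();
  float* mp = reinterpret_cast<float*>(m.begin());
  float* vp = reinterpret_cast<float*>(v.begin());
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = gp[i];
    const double mi = b1 * (double)mp[i] + (1.0 - b1) * gi;
    const double vi = b2 * (double)vp[i] + (1.0 - b2) * gi * gi;
    mp[i] = (float)mi;
    vp[i] = (float)vi;
    pp[i] -= lr * (mi / c1) / (std::sqrt(vi / c2) + eps);
  }
}
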