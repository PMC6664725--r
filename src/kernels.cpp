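// Hot loops of the CNN engine: im2col gather/scatter, max pooling with
// argmax bookkeeping, and the fused Adam update. Everything else stays in
// R where BLAS does the heavy lifting. Loops work on hoisted raw pointers
// so the optimizer keeps them in registers.

#include <Rcpp.h>
using namespace Rcpp;

// Gather columns of Xp (Cin x LpB) into the im2col matrix (Cin*k x LoutB).
// colidx is k x LoutB of 1-based column indices into Xp.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& Xp, const IntegerMatrix& colidx) {
  const int Cin = Xp.nrow();
  const int k = colidx.nrow();
  const int n = colidx.ncol();
  NumericMatrix M(Cin * k, n);
  const double* xp = REAL(Xp);
  const int* ci = INTEGER(colidx);
  double* out = REAL(M);
  for (int j = 0; j < n; ++j) {
    const int* cij = ci + (size_t)j * k;
    double* oj = out + (size_t)j * Cin * k;
    for (int ki = 0; ki < k; ++ki) {
      const double* src = xp + (size_t)(cij[ki] - 1) * Cin;
      std::copy(src, src + Cin, oj + (size_t)ki * Cin);
    }
  }
  return M;
}

// Scatter-add the im2col gradient dM (Cin*k x LoutB) back onto the padded
// input gradient (Cin x LpB).
// [[Rcpp::export]]
NumericMatrix cpp_col2im_add(const NumericMatrix& dM,
                             const IntegerMatrix& colidx,
                             int Cin, int LpB) {
  const int k = colidx.nrow();
  const int n = colidx.ncol();
  NumericMatrix dXp(Cin, LpB);
  const double* dm = REAL(dM);
  const int* ci = INTEGER(colidx);
  double* out = REAL(dXp);
  for (int j = 0; j < n; ++j) {
    const int* cij = ci + (size_t)j * k;
    const double* src = dm + (size_t)j * Cin * k;
    for (int ki = 0; ki < k; ++ki) {
      double* oj = out + (size_t)(cij[ki] - 1) * Cin;
      const double* s = src + (size_t)ki * Cin;
      for (int c = 0; c < Cin; ++c) oj[c] += s[c];
    }
  }
  return dXp;
}

// Max pooling over windows of width w, stride s along the length axis of a
// (C, L, B) array given as a C x (L*B) matrix. Returns the pooled matrix
// C x (Lout*B) and the 1-based source column of each maximum (first
// maximum wins on ties). Windows may overhang the end of a sample.
// [[Rcpp::export]]
List cpp_maxpool(const NumericMatrix& X, int L, int B, int w, int s,
                 int Lout) {
  const int C = X.nrow();
  NumericMatrix Y(C, (size_t)Lout * B);
  IntegerMatrix arg(C, (size_t)Lout * B);
  const double* x = REAL(X);
  double* y0 = REAL(Y);
  int* a0 = INTEGER(arg);
  for (int b = 0; b < B; ++b) {
    const int in0 = b * L;
    for (int t = 0; t < Lout; ++t) {
      const int start = t * s;
      const int end = std::min(start + w, L);
      double* y = y0 + (size_t)(b * Lout + t) * C;
      int* a = a0 + (size_t)(b * Lout + t) * C;
      const double* x0 = x + (size_t)(in0 + start) * C;
      for (int c = 0; c < C; ++c) { y[c] = x0[c]; a[c] = in0 + start + 1; }
      for (int p = start + 1; p < end; ++p) {
        const double* xp = x + (size_t)(in0 + p) * C;
        for (int c = 0; c < C; ++c) {
          if (xp[c] > y[c]) { y[c] = xp[c]; a[c] = in0 + p + 1; }
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["argmax"] = arg);
}

// Route the pooled gradient back to the argmax positions.
// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(const NumericMatrix& dY,
                              const IntegerMatrix& argmax,
                              int ncol_in) {
  const int C = dY.nrow();
  const int n = dY.ncol();
  NumericMatrix dX(C, ncol_in);
  const double* g0 = REAL(dY);
  const int* a0 = INTEGER(argmax);
  double* out = REAL(dX);
  for (int j = 0; j < n; ++j) {
    const double* g = g0 + (size_t)j * C;
    const int* a = a0 + (size_t)j * C;
    for (int c = 0; c < C; ++c) out[(size_t)(a[c] - 1) * C + c] += g[c];
  }
  return dX;
}

// Fused Adam update. m and v are updated in place (they are owned solely
// by the optimizer state); the updated parameter vector is returned as a
// fresh allocation so parameter snapshots held elsewhere stay intact.
// [[Rcpp::export]]
NumericVector cpp_adam(const NumericVector& p, NumericVector m,
                       NumericVector v, const NumericVector& g,
                       double lr_t, double eps_t, double beta1,
                       double beta2) {
  const R_xlen_t n = p.size();
  NumericVector out(n);
  out.attr("dim") = p.attr("dim");
  const double* pp = REAL(p);
  const double* gp = REAL(g);
  double* mp = REAL(m);
  double* vp = REAL(v);
  double* op = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = gp[i];
    const double mi = beta1 * mp[i] + (1.0 - beta1) * gi;
    const double vi = beta2 * vp[i] + (1.0 - beta2) * gi * gi;
    mp[i] = mi;
    vp[i] = vi;
    op[i] = pp[i] - lr_t * mi / (std::sqrt(vi) + eps_t);
  }
  return out;
}
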