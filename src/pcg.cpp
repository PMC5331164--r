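#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Jacobi-preconditioned conjugate gradients on an SPD matrix in CSC form
// (dgCMatrix slots), run entirely in C++ to keep the per-iteration cost at
// the memory bandwidth of the matvec. Deterministic: no threading.
// [[Rcpp::export]]
List pcg_csc(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
             NumericVector b, NumericVector diag_A,
             NumericVector x0, double tol, int max_iter) {
  const R_xlen_t n = b.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> r(n), z(n), p(n), Apv(n);
  const int* ap = INTEGER(Ap);
  const int* ai = INTEGER(Ai);
  const double* ax = REAL(Ax);
  const double* bp = REAL(b);
  const double* dp = REAL(diag_A);

  // r = b - A x0 (skip the matvec if x0 is zero)
  bool x0zero = true;
  for (R_xlen_t i = 0; i < n; ++i) if (x[i] != 0.0) { x0zero = false; break; }
  if (x0zero) {
    for (R_xlen_t i = 0; i < n; ++i) r[i] = bp[i];
  } else {
    std::fill(Apv.begin(), Apv.end(), 0.0);
    for (R_xlen_t j = 0; j < n; ++j) {
      double xj = x[j];
      if (xj == 0.0) continue;
      for (int q = ap[j]; q < ap[j + 1]; ++q) Apv[ai[q]] += ax[q] * xj;
    }
    for (R_xlen_t i = 0; i < n; ++i) r[i] = bp[i] - Apv[i];
  }

  double bn = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) bn += bp[i] * bp[i];
  bn = std::sqrt(bn);
  if (bn == 0.0) bn = 1.0;

  double rz = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    z[i] = r[i] / dp[i];
    p[i] = z[i];
    rz += r[i] * z[i];
  }

  int it = 0;
  double rn = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) rn += r[i] * r[i];
  rn = std::sqrt(rn);

  while (rn > tol * bn && it < max_iter) {
    ++it;
    std::fill(Apv.begin(), Apv.end(), 0.0);
    for (R_xlen_t j = 0; j < n; ++j) {
      double pj = p[j];
      if (pj == 0.0) continue;
      const int lo = ap[j], hi = ap[j + 1];
      for (int q = lo; q < hi; ++q) Apv[ai[q]] += ax[q] * pj;
    }
    double pAp = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) pAp += p[i] * Apv[i];
    double alpha = rz / pAp;
    for (R_xlen_t i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Apv[i];
    }
    double rz2 = 0.0;
    rn = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      z[i] = r[i] / dp[i];
      rz2 += r[i] * z[i];
      rn += r[i] * r[i];
    }
    rn = std::sqrt(rn);
    double beta = rz2 / rz;
    for (R_xlen_t i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
    rz = rz2;
  }

  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["iterations"] = it,
                      _["relres"] = rn / bn);
}
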