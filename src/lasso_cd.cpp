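#include <Rcpp.h>
using namespace Rcpp;

// Per-pixel sparsity-penalized unmixing by cyclic coordinate descent.
//
// Solves, independently for every column y of Y (M x N):
//   min_c  || y - A^T c ||_2^2 + lam * || c ||_1    [ c >= 0 if nonneg ]
// where A is the K x M reference-spectra matrix (one spectrum per row).
// Descent starts from c = 0 (or a warm start) with fixed cyclic component
// order, which together with convexity makes the output deterministic.
// The coordinate update for the objective above (note: no 1/2 factor on the
// residual term) soft-thresholds at lam / 2:
//   c_k <- max(0, z_k - lam/2) / G_kk,  z_k = a_k.y - sum_{j != k} G_kj c_j
// using precomputed Gram quantities G = A A^T and b = A Y ("covariance
// updates"), so a full sweep costs O(K^2) per pixel regardless of M.
// Rows of A need not be unit norm: after channel restriction the library
// keeps its full-spectrum normalization, so G_kk < 1 is expected there.
//
// Convergence: sweep until the largest single-coordinate change is below
// tol * max(1, ||c||_inf), or max_iters sweeps.
// [[Rcpp::export]]
NumericMatrix lasso_cd_cpp(const NumericMatrix& A, const NumericMatrix& Y,
                           double lam, bool nonneg, int max_iters, double tol,
                           Nullable<NumericMatrix> warm = R_NilValue) {
  const int K = A.nrow(), M = A.ncol(), N = Y.ncol();
  if (Y.nrow() != M) stop("lasso_cd_cpp: Y rows must match A columns");
  NumericMatrix C(K, N);
  std::vector<double> G(K * K);
  for (int k = 0; k < K; ++k)
    for (int j = k; j < K; ++j) {
      double acc = 0.0;
      for (int m = 0; m < M; ++m) acc += A(k, m) * A(j, m);
      G[k * K + j] = G[j * K + k] = acc;
    }
  for (int k = 0; k < K; ++k)
    if (G[k * K + k] <= 0.0) stop("lasso_cd_cpp: zero reference spectrum");
  const double thr = lam / 2.0;
  bool have_warm = warm.isNotNull();
  NumericMatrix W;
  if (have_warm) {
    W = NumericMatrix(warm);
    if (W.nrow() != K || W.ncol() != N)
      stop("lasso_cd_cpp: warm start has wrong shape");
  }
  std::vector<double> b(K), c(K);
  for (int n = 0; n < N; ++n) {
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      for (int m = 0; m < M; ++m) acc += A(k, m) * Y(m, n);
      b[k] = acc;
      c[k] = have_warm ? W(k, n) : 0.0;
    }
    for (int it = 0; it < max_iters; ++it) {
      double max_delta = 0.0, cmax = 1.0;
      for (int k = 0; k < K; ++k) {
        double z = b[k];
        const double* Gk = &G[k * K];
        for (int j = 0; j < K; ++j) if (j != k) z -= Gk[j] * c[j];
        double cnew;
        if (nonneg) {
          cnew = (z - thr) / Gk[k];
          if (cnew < 0.0) cnew = 0.0;
        } else {
          double az = std::abs(z) - thr;
          cnew = az > 0.0 ? ((z > 0.0 ? az : -az) / Gk[k]) : 0.0;
        }
        double d = cnew - c[k];
        c[k] = cnew;
        if (std::abs(d) > max_delta) max_delta = std::abs(d);
        if (std::abs(cnew) > cmax) cmax = std::abs(cnew);
      }
      if (max_delta <= tol * cmax) break;
    }
    for (int k = 0; k < K; ++k) C(k, n) = c[k];
  }
  return C;
}
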