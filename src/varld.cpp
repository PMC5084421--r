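// VarLD raw scores: for each sliding window, the SNP-correlation matrices of
// two populations are compared as the summed absolute difference between
// their rank-matched eigenvalues. Zero-variance SNPs within a window keep a
// unit diagonal and zero off-diagonal correlation, so each eigenvalue list
// sums to the window size (the matrix trace).

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Scaled window columns -> eigenvalues (ascending, length w) of the window
// correlation matrix, in `ev`. Columns are centered and scaled to unit norm
// (zero-variance columns become zero but keep a unit diagonal in the
// correlation matrix, i.e. contribute an isolated eigenvalue of 1). When
// the haplotype count n is below the window size the nonzero spectrum is
// computed from the n x n Gram matrix Z Z^T, which has the same nonzero
// eigenvalues as Z^T Z.
static void window_eigvals(const IntegerMatrix& haps, int start, int w,
                           std::vector<double>& Z, std::vector<double>& C,
                           std::vector<double>& work, std::vector<double>& ev) {
  const int n = haps.nrow();
  int n_zero = 0;
  for (int j = 0; j < w; ++j) {
    double mean = 0.0;
    for (int i = 0; i < n; ++i) mean += haps(i, start + j);
    mean /= n;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      const double d = haps(i, start + j) - mean;
      Z[(size_t)j * n + i] = d;
      ss += d * d;
    }
    if (ss > 0) {
      const double inv = 1.0 / std::sqrt(ss);
      for (int i = 0; i < n; ++i) Z[(size_t)j * n + i] *= inv;
    } else {
      for (int i = 0; i < n; ++i) Z[(size_t)j * n + i] = 0.0;
      ++n_zero;
    }
  }
  const double one = 1.0, zero = 0.0;
  int info = 0, lwork = (int)work.size();
  if (n < w) {
    // Gram-matrix route: eigenvalues of Z Z^T (n x n) plus w - n zeros,
    // with one eigenvalue of 1 per zero-variance column
    F77_CALL(dsyrk)("U", "N", &n, &w, &one, Z.data(), &n, &zero, C.data(), &n
                    FCONE FCONE);
    std::vector<double> evg(n);
    F77_CALL(dsyev)("N", "U", &n, C.data(), &n, evg.data(), work.data(), &lwork,
                    &info FCONE FCONE);
    if (info != 0) stop("dsyev failed in VarLD window (info=%d)", info);
    // the nonzero-column block has rank <= min(n, w - n_zero): keep the
    // largest such eigenvalues of the Gram matrix (the rest are zeros)
    const int m = std::min(n, w - n_zero);
    std::fill(ev.begin(), ev.begin() + w, 0.0);
    for (int j = 0; j < m; ++j) ev[j] = evg[n - m + j];
    for (int j = 0; j < n_zero; ++j) ev[m + j] = 1.0;
    std::sort(ev.begin(), ev.begin() + w);
  } else {
    F77_CALL(dsyrk)("U", "T", &w, &n, &one, Z.data(), &n, &zero, C.data(), &w
                    FCONE FCONE);
    for (int j = 0; j < w; ++j) C[(size_t)j * w + j] = 1.0;  // unit diagonal
    F77_CALL(dsyev)("N", "U", &w, C.data(), &w, ev.data(), work.data(), &lwork,
                    &info FCONE FCONE);
    if (info != 0) stop("dsyev failed in VarLD window (info=%d)", info);
  }
}

// [[Rcpp::export]]
NumericVector cpp_varld_raw(IntegerMatrix hapsA, IntegerMatrix hapsB,
                            IntegerVector centers0, int window) {
  const int half = window / 2;
  std::vector<double> ZA((size_t)hapsA.nrow() * window),
      ZB((size_t)hapsB.nrow() * window), C((size_t)window * window),
      work(10 * window), evA(window), evB(window);
  NumericVector out(centers0.size());
  for (int k = 0; k < centers0.size(); ++k) {
    const int start = centers0[k] - half;
    window_eigvals(hapsA, start, window, ZA, C, work, evA);
    window_eigvals(hapsB, start, window, ZB, C, work, evB);
    double raw = 0.0;
    for (int j = 0; j < window; ++j) raw += std::fabs(evA[j] - evB[j]);
    out[k] = raw;
  }
  return out;
}
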