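#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger (algorithm 1) estimator of the
// multiinformation (total correlation) of the d columns of `x`, in nats:
//   I = psi(k) + (d-1) psi(N) - < sum_j psi(n_j + 1) >
// where n_j counts marginal neighbours strictly inside the max-norm distance
// to the k-th joint neighbour. d = 2 gives mutual information, d = 3 the
// 3-way total correlation. Ties are resolved by the strict inequality; no
// jitter is applied, so the estimate is deterministic in its input.
static double ksg_multiinfo(const double* x, int n, int d, int k) {
  std::vector<double> dd(n - 1);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int l = 0; l < n; ++l) {
      if (l == i) continue;
      double mx = 0.0;
      for (int j = 0; j < d; ++j) {
        double a = std::fabs(x[j * n + l] - x[j * n + i]);
        if (a > mx) mx = a;
      }
      dd[m++] = mx;
    }
    std::nth_element(dd.begin(), dd.begin() + (k - 1), dd.end());
    double eps = dd[k - 1];
    for (int j = 0; j < d; ++j) {
      int c = 0;
      const double* col = x + j * n;
      double xi = col[i];
      for (int l = 0; l < n; ++l) {
        if (l != i && std::fabs(col[l] - xi) < eps) ++c;
      }
      acc += R::digamma(c + 1.0);
    }
  }
  return R::digamma((double)k) + (d - 1.0) * R::digamma((double)n) - acc / n;
}

// [[Rcpp::export(name = ".ksg_multiinfo_cpp")]]
double ksg_multiinfo_cpp(NumericMatrix x, int k) {
  if (k < 1 || k >= x.nrow()) stop("k must satisfy 1 <= k < number of samples");
  return ksg_multiinfo(REAL(x), x.nrow(), x.ncol(), k);
}

// All-pairs mutual information of the columns of `ts` (samples x regions),
// lexicographic (i < j) order.
// [[Rcpp::export(name = ".ksg_all_pairs_cpp")]]
NumericVector ksg_all_pairs_cpp(NumericMatrix ts, int k) {
  int n = ts.nrow(), r = ts.ncol();
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < number of samples");
  NumericVector out((double)r * (r - 1) / 2);
  std::vector<double> buf(2 * (size_t)n);
  const double* src = REAL(ts);
  int idx = 0;
  for (int i = 0; i < r; ++i) {
    for (int j = i + 1; j < r; ++j) {
      std::copy(src + (size_t)i * n, src + (size_t)(i + 1) * n, buf.begin());
      std::copy(src + (size_t)j * n, src + (size_t)(j + 1) * n, buf.begin() + n);
      out[idx++] = ksg_multiinfo(buf.data(), n, 2, k);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// All-triplets total correlation, lexicographic (i < j < l) order.
// [[Rcpp::export(name = ".ksg_all_triplets_cpp")]]
NumericVector ksg_all_triplets_cpp(NumericMatrix ts, int k) {
  int n = ts.nrow(), r = ts.ncol();
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < number of samples");
  double len = (double)r * (r - 1) * (r - 2) / 6;
  NumericVector out(len);
  std::vector<double> buf(3 * (size_t)n);
  const double* src = REAL(ts);
  R_xlen_t idx = 0;
  for (int i = 0; i < r; ++i) {
    std::copy(src + (size_t)i * n, src + (size_t)(i + 1) * n, buf.begin());
    for (int j = i + 1; j < r; ++j) {
      std::copy(src + (size_t)j * n, src + (size_t)(j + 1) * n, buf.begin() + n);
      for (int l = j + 1; l < r; ++l) {
        std::copy(src + (size_t)l * n, src + (size_t)(l + 1) * n,
                  buf.begin() + 2 * (size_t)n);
        out[idx++] = ksg_multiinfo(buf.data(), n, 3, k);
      }
      Rcpp::checkUserInterrupt();
    }
  }
  return out;
}
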