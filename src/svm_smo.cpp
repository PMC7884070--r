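#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dual solver for the binary C-SVC:
//   min_a  0.5 a'Qa - e'a   s.t.  y'a = 0,  0 <= a_i <= C,
// with Q_ij = y_i y_j K_ij, solved by SMO with maximal-violating-pair
// working-set selection (the same problem libsvm solves; the unregularized
// bias is recovered from the KKT conditions). Sized for the small problems
// that arise in leave-one-run-out decoding (n <= a few hundred trials).
// The kernel matrix is an input so that cross-validation folds, whose
// features do not change under label permutation, can precompute it once.

static void smo_solve(const double* K, const int* y, int n, double cost,
                      double eps, int max_iter, double* a, double* b_out,
                      int* iter_out) {
  std::vector<double> G(n, -1.0);
  for (int k = 0; k < n; ++k) a[k] = 0.0;
  int iter = 0;
  double m = 0.0, M = 0.0;
  while (iter < max_iter) {
    m = -HUGE_VAL; M = HUGE_VAL;
    int ii = -1, jj = -1;
    for (int k = 0; k < n; ++k) {
      const int yk = y[k];
      const double v = -yk * G[k];
      const bool up  = (yk > 0) ? (a[k] < cost) : (a[k] > 0);
      const bool low = (yk > 0) ? (a[k] > 0)    : (a[k] < cost);
      if (up && v > m)  { m = v; ii = k; }
      if (low && v < M) { M = v; jj = k; }
    }
    if (ii < 0 || jj < 0 || m - M < eps) break;

    // feasible direction: da_i = y_i s, da_j = -y_j s, s > 0
    const double* Ki = K + (size_t)ii * n;
    const double* Kj = K + (size_t)jj * n;
    const double eta = Ki[ii] + Kj[jj] - 2.0 * Ki[jj];
    const double smax_i = (y[ii] > 0) ? cost - a[ii] : a[ii];
    const double smax_j = (y[jj] > 0) ? a[jj] : cost - a[jj];
    double s = (eta > 1e-12) ? (m - M) / eta : HUGE_VAL;
    if (s > smax_i) s = smax_i;
    if (s > smax_j) s = smax_j;
    if (s <= 0.0) break;

    a[ii] += (y[ii] > 0) ? s : -s;
    a[jj] += (y[jj] > 0) ? -s : s;
    for (int k = 0; k < n; ++k) G[k] += y[k] * s * (Ki[k] - Kj[k]);
    ++iter;
  }

  // bias from KKT: free SVs satisfy y_i (f(x_i) + b) = 1 => b = -y_i G_i
  double bsum = 0.0; int nfree = 0;
  const double tol = 1e-8 * cost;
  for (int k = 0; k < n; ++k) {
    if (a[k] > tol && a[k] < cost - tol) { bsum += -y[k] * G[k]; ++nfree; }
  }
  *b_out = (nfree > 0) ? bsum / nfree : (m + M) / 2.0;
  *iter_out = iter;
}

// [[Rcpp::export]]
List svm_gram_fit(const NumericMatrix& K, const IntegerVector& y,
                  double cost, double eps, int max_iter) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("K must be n x n matching y");
  NumericVector a(n);
  double b; int iter;
  smo_solve(REAL(K), INTEGER(y), n, cost, eps, max_iter,
            REAL(a), &b, &iter);
  return List::create(_["alpha"] = a, _["b"] = b, _["iterations"] = iter,
                      _["converged"] = iter < max_iter);
}

// [[Rcpp::export]]
List svm_linear_fit(const NumericMatrix& X, const IntegerVector& y,
                    double cost, double eps, int max_iter) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length of y must match rows of X");
  const double* xp = REAL(X);

  // linear-kernel Gram, accumulated feature-by-feature (column-major)
  std::vector<double> K((size_t)n * n, 0.0);
  for (int f = 0; f < p; ++f) {
    const double* c = xp + (size_t)f * n;
    for (int i = 0; i < n; ++i) {
      const double ci = c[i];
      double* Ki = &K[(size_t)i * n];
      for (int j = i; j < n; ++j) Ki[j] += ci * c[j];
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < i; ++j) K[(size_t)i * n + j] = K[(size_t)j * n + i];

  NumericVector a(n);
  double b; int iter;
  smo_solve(K.data(), INTEGER(y), n, cost, eps, max_iter,
            REAL(a), &b, &iter);

  NumericVector w(p);
  for (int k = 0; k < n; ++k) {
    if (a[k] > 0.0) {
      const double ck = a[k] * y[k];
      for (int f = 0; f < p; ++f) w[f] += ck * xp[k + (size_t)f * n];
    }
  }
  return List::create(_["w"] = w, _["b"] = b, _["alpha"] = a,
                      _["iterations"] = iter,
                      _["converged"] = iter < max_iter);
}
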