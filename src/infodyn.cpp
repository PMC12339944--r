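#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;

// Chebyshev (max-norm) distance between rows i and j of a column-major matrix.
static inline double cheb_dist(const double *x, int n, int d, int i, int j) {
  double m = 0.0;
  for (int c = 0; c < d; ++c) {
    double diff = std::fabs(x[i + (size_t)c * n] - x[j + (size_t)c * n]);
    if (diff > m) m = diff;
  }
  return m;
}

// Distance to the k-th nearest neighbour of every row (self excluded).
// [[Rcpp::export]]
NumericVector knn_cheb_dist(NumericMatrix X, int k) {
  int n = X.nrow(), d = X.ncol();
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n");
  NumericVector out(n);
  std::vector<double> buf((size_t)n - 1);
  const double *px = REAL(X);
  for (int i = 0; i < n; ++i) {
    size_t m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      buf[m++] = cheb_dist(px, n, d, i, j);
    }
    std::nth_element(buf.begin(), buf.begin() + (k - 1), buf.end());
    out[i] = buf[k - 1];
  }
  return out;
}

// Number of rows j != i with d(i, j) < eps[i] (strict) or <= eps[i].
// [[Rcpp::export]]
IntegerVector count_within_cheb(NumericMatrix X, NumericVector eps, bool strict) {
  int n = X.nrow(), d = X.ncol();
  if (eps.size() != n) stop("eps must have one entry per row of X");
  IntegerVector out(n);
  const double *px = REAL(X);
  for (int i = 0; i < n; ++i) {
    double e = eps[i];
    int cnt = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      bool within = true;
      double m = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = std::fabs(px[i + (size_t)c * n] - px[j + (size_t)c * n]);
        if (diff > m) m = diff;
        if (strict ? (m >= e) : (m > e)) { within = false; break; }
      }
      if (within) ++cnt;
    }
    out[i] = cnt;
  }
  return out;
}

// Number of sample rows within `radius` (max-norm) of each query row.
// Coincident points count; no self-exclusion (queries need not be samples).
// [[Rcpp::export]]
IntegerVector range_count_cheb(NumericMatrix X, NumericMatrix Q, double radius,
                               bool strict) {
  int n = X.nrow(), d = X.ncol(), m = Q.nrow();
  if (Q.ncol() != d) stop("X and Q must have the same number of columns");
  IntegerVector out(m);
  const double *px = REAL(X);
  const double *pq = REAL(Q);
  for (int i = 0; i < m; ++i) {
    int cnt = 0;
    for (int j = 0; j < n; ++j) {
      bool within = true;
      double mx = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = std::fabs(pq[i + (size_t)c * m] - px[j + (size_t)c * n]);
        if (diff > mx) mx = diff;
        if (strict ? (mx >= radius) : (mx > radius)) { within = false; break; }
      }
      if (within) ++cnt;
    }
    out[i] = cnt;
  }
  return out;
}

// Product-Gaussian KDE with shared per-axis bandwidth h, evaluated at Q.
// [[Rcpp::export]]
NumericVector gauss_kde_cpp(NumericMatrix X, NumericMatrix Q, double h) {
  int n = X.nrow(), d = X.ncol(), m = Q.nrow();
  if (Q.ncol() != d) stop("X and Q must have the same number of columns");
  if (h <= 0) stop("bandwidth must be positive");
  NumericVector out(m);
  const double *px = REAL(X);
  const double *pq = REAL(Q);
  double inv2h2 = 1.0 / (2.0 * h * h);
  double norm = 1.0 / ((double)n * std::pow(h * std::sqrt(TWO_PI), d));
  for (int i = 0; i < m; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      double ssq = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = pq[i + (size_t)c * m] - px[j + (size_t)c * n];
        ssq += diff * diff;
      }
      double e = ssq * inv2h2;
      if (e < 36.0) s += std::exp(-e);  // exp(-36) ~ 2e-16: below double noise
    }
    out[i] = s * norm;
  }
  return out;
}

// Ring of M coupled maps: x^m <- f(eps * x^{m-1} + (1 - eps) * x^m).
// map: 0 = tent on [0, 1], 1 = Ulam f(x) = 2 - x^2 on [-2, 2].
// Returns the T states after the transient, one row per time step.
// [[Rcpp::export]]
NumericMatrix simulate_lattice_cpp(int M, int T, double eps, int transient,
                                   int map, NumericVector init) {
  if (init.size() != M) stop("init must have length M");
  NumericMatrix out(T, M);
  std::vector<double> x(init.begin(), init.end()), y((size_t)M);
  int total = T + transient;
  for (int t = 0; t < total; ++t) {
    for (int m = 0; m < M; ++m) {
      int left = (m == 0) ? (M - 1) : (m - 1);
      double a = eps * x[left] + (1.0 - eps) * x[m];
      double v;
      if (map == 0) {
        v = (a < 0.5) ? 2.0 * a : 2.0 - 2.0 * a;
        if (v < 0.0) v = 0.0;
        if (v > 1.0) v = 1.0;
      } else {
        v = 2.0 - a * a;
        if (v < -2.0) v = -2.0;
        if (v > 2.0) v = 2.0;
      }
      y[m] = v;
    }
    x.swap(y);
    if (t >= transient)
      for (int m = 0; m < M; ++m) out(t - transient, m) = x[m];
  }
  return out;
}
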