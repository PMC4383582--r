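#include <Rcpp.h>
#include <vector>
#include <cstddef>
using namespace Rcpp;

// Sequential minimal optimization for the C-SVM dual on a precomputed Gram
// matrix, restricted to the rows/columns listed in `idx`:
//
//   min_a  1/2 a' Q a - 1'a,   Q = (y y') .* K,   y'a = 0,  0 <= a <= C.
//
// Working-set selection is the maximal-violating-pair rule; the solver stops
// when the duality-gap surrogate m(a) - M(a) drops below eps.  With p >> n
// features the Gram form keeps the cost O(n^2) per iteration sweep, which is
// what makes whole-cohort leave-one-out and permutation loops affordable.

struct SmoFit {
  std::vector<double> alpha;
  double b;
  bool converged;
  long iter;
};

static SmoFit smo_core(const double* K, int N,
                       const std::vector<int>& idx,
                       const std::vector<int>& y,
                       double C, double eps, long max_iter) {
  const int n = (int)idx.size();
  SmoFit out;
  out.alpha.assign(n, 0.0);
  std::vector<double>& a = out.alpha;
  std::vector<double> g(n, -1.0);  // gradient of the dual objective

  long it = 0;
  bool conv = false;
  double m = 0.0, M = 0.0;
  for (it = 0; it < max_iter; ++it) {
    // first index: maximal violator in I_up
    int i = -1;
    m = -1e300; M = 1e300;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * g[t];
      const bool up  = (y[t] == 1) ? (a[t] < C) : (a[t] > 0.0);
      const bool low = (y[t] == 1) ? (a[t] > 0.0) : (a[t] < C);
      if (up  && v > m) { m = v; i = t; }
      if (low && v < M) { M = v; }
    }
    if (i < 0 || m - M < eps) { conv = true; break; }
    const double* Ki = K + (std::size_t)N * idx[i];
    const double Kii = Ki[idx[i]];
    // second index: maximal second-order gain among violated partners
    int j = -1; double best = -1.0, quad_best = 1.0;
    for (int t = 0; t < n; ++t) {
      const bool low = (y[t] == 1) ? (a[t] > 0.0) : (a[t] < C);
      if (!low) continue;
      const double v = -y[t] * g[t];
      const double diff = m - v;
      if (diff <= 0.0) continue;
      double quad = Kii + K[(std::size_t)N * idx[t] + idx[t]] -
        2.0 * Ki[idx[t]];
      if (quad < 1e-12) quad = 1e-12;
      const double gain = diff * diff / quad;
      if (gain > best) { best = gain; j = t; quad_best = quad; }
    }
    if (j < 0) { conv = true; break; }

    const double* Kj = K + (std::size_t)N * idx[j];
    const double quad = quad_best;
    // step along u with u_i = y_i, u_j = -y_j keeps y'a = 0; optimum >= 0
    double d = (m - (-y[j] * g[j])) / quad;
    const double cap_i = (y[i] == 1) ? (C - a[i]) : a[i];
    const double cap_j = (y[j] == 1) ? a[j] : (C - a[j]);
    if (d > cap_i) d = cap_i;
    if (d > cap_j) d = cap_j;
    a[i] += y[i] * d;
    a[j] -= y[j] * d;
    for (int t = 0; t < n; ++t) {
      const double kti = K[(std::size_t)N * idx[i] + idx[t]];
      const double ktj = K[(std::size_t)N * idx[j] + idx[t]];
      g[t] += d * y[t] * (kti - ktj);
    }
  }
  out.converged = conv;
  out.iter = it;

  // bias: for a free support vector -y_t g_t equals b exactly; average over
  // free SVs, falling back to the midpoint of the feasible interval [M, m]
  double amax = 0.0;
  for (int t = 0; t < n; ++t) if (a[t] > amax) amax = a[t];
  const double lo = 1e-10 * amax, hi = C * (1.0 - 1e-9);
  double sum = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (a[t] > lo && a[t] < hi) { sum += -y[t] * g[t]; ++nfree; }
  }
  out.b = (nfree > 0) ? (sum / nfree) : ((m + M) / 2.0);
  return out;
}

// decision value for row `row` of K given a fit over `idx`
static double decide(const double* K, int N, int row,
                     const std::vector<int>& idx, const std::vector<int>& y,
                     const std::vector<double>& a, double b) {
  double f = b;
  for (int t = 0; t < (int)idx.size(); ++t)
    f += a[t] * y[t] * K[(std::size_t)N * idx[t] + row];
  return f;
}

// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, IntegerVector y, double C,
               double eps = 1e-6, double max_iter = 1e7) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("Gram matrix must be square");
  if (y.size() != n) stop("label length must match Gram dimension");
  std::vector<int> idx(n), yy(n);
  for (int t = 0; t < n; ++t) { idx[t] = t; yy[t] = y[t]; }
  SmoFit fit = smo_core(REAL(K), n, idx, yy, C, eps, (long)max_iter);
  NumericVector alpha(fit.alpha.begin(), fit.alpha.end());
  NumericVector f(n);
  for (int t = 0; t < n; ++t)
    f[t] = decide(REAL(K), n, t, idx, yy, fit.alpha, fit.b);
  return List::create(_["alpha"] = alpha, _["b"] = fit.b,
                      _["decision"] = f,
                      _["converged"] = fit.converged,
                      _["iterations"] = (double)fit.iter);
}

// Leave-one-out decision scores over a fixed Gram matrix.  When `shortcut`
// is true, a held-out subject that is not a support vector of the full-data
// model and sits strictly outside the margin keeps the full-model score:
// removing a non-support point leaves the hard-margin solution unchanged.
// [[Rcpp::export(name = ".loo_scores_gram")]]
List loo_scores_gram(NumericMatrix K, IntegerVector y, double C,
                     double eps = 1e-6, double kkt_tol = 1e-4,
                     bool shortcut = true, double max_iter = 1e7) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("dimension mismatch");
  const double* Kp = REAL(K);
  std::vector<int> all(n), yy(n);
  for (int t = 0; t < n; ++t) { all[t] = t; yy[t] = y[t]; }

  SmoFit full = smo_core(Kp, n, all, yy, C, eps, (long)max_iter);
  if (!full.converged) {
    NumericVector alpha0(full.alpha.begin(), full.alpha.end());
    return List::create(_["score"] = NumericVector(n),
                        _["refit"] = LogicalVector(n),
                        _["alpha_full"] = alpha0, _["b_full"] = full.b,
                        _["converged"] = false);
  }
  double amax = 0.0;
  for (int t = 0; t < n; ++t) if (full.alpha[t] > amax) amax = full.alpha[t];
  const double sv_tol = 1e-6 * amax;

  NumericVector score(n);
  LogicalVector refit(n);
  bool all_conv = full.converged;
  std::vector<int> sub(n - 1), ysub(n - 1);
  for (int i = 0; i < n; ++i) {
    const double f_full = decide(Kp, n, i, all, yy, full.alpha, full.b);
    if (shortcut && full.alpha[i] <= sv_tol &&
        yy[i] * f_full > 1.0 + kkt_tol) {
      score[i] = f_full;
      refit[i] = false;
      continue;
    }
    int k = 0;
    for (int t = 0; t < n; ++t)
      if (t != i) { sub[k] = t; ysub[k] = yy[t]; ++k; }
    SmoFit fit = smo_core(Kp, n, sub, ysub, C, eps, (long)max_iter);
    all_conv = all_conv && fit.converged;
    score[i] = decide(Kp, n, i, sub, ysub, fit.alpha, fit.b);
    refit[i] = true;
    // a fold that exhausts the iteration budget signals an ill-conditioned
    // problem; stop early so the caller can switch solver
    if (!fit.converged) break;
  }
  NumericVector alpha(full.alpha.begin(), full.alpha.end());
  return List::create(_["score"] = score, _["refit"] = refit,
                      _["alpha_full"] = alpha, _["b_full"] = full.b,
                      _["converged"] = all_conv);
}
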