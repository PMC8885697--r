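#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pair-counting Kendall tau-b with tie correction:
//   tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2)),
// n0 = n(n-1)/2, n1/n2 = tied pairs in x/y. O(n^2); n here is small (<= a few hundred).
static double tau_b_core(const double* x, const double* y, int n, bool* ok) {
  double C = 0, D = 0, Tx = 0, Ty = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx == 0 && dy == 0) { Tx += 1; Ty += 1; }
      else if (dx == 0) Tx += 1;
      else if (dy == 0) Ty += 1;
      else if (dx * dy > 0) C += 1;
      else D += 1;
    }
  }
  double n0 = n * (n - 1.0) / 2.0;
  double den = std::sqrt((n0 - Tx) * (n0 - Ty));
  if (den <= 0) { *ok = false; return NA_REAL; }
  *ok = true;
  return (C - D) / den;
}

// [[Rcpp::export]]
double cpp_kendall_tau_b(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n != y.size()) stop("x and y must have equal length");
  bool ok;
  double t = tau_b_core(REAL(x), REAL(y), n, &ok);
  if (!ok) stop("kendall tau-b is undefined: a variable is constant (all pairs tied)");
  return t;
}

// Double (nested) bootstrap for Kendall tau-b on paired data.
// Outer loop: n_outer pair resamples, statistic recorded.
// Inner loop: for each outer resample, n_inner second-level resamples; the inner
// empirical CDF evaluated at the original estimate t0 gives the u-value used for
// coverage calibration (prepivoting). Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
List cpp_double_boot_tau(NumericVector x, NumericVector y, int n_outer, int n_inner) {
  int n = x.size();
  if (n != y.size()) stop("x and y must have equal length");
  bool ok;
  double t0 = tau_b_core(REAL(x), REAL(y), n, &ok);
  if (!ok) stop("kendall tau-b is undefined on the input data");

  NumericVector t_boot(n_outer);
  NumericVector u(n_outer);
  std::vector<double> xb(n), yb(n), xbb(n), ybb(n);
  RNGScope scope;

  for (int b = 0; b < n_outer; ++b) {
    for (int i = 0; i < n; ++i) {
      int idx = (int)(unif_rand() * n);
      if (idx == n) idx = n - 1;
      xb[i] = x[idx]; yb[i] = y[idx];
    }
    t_boot[b] = tau_b_core(xb.data(), yb.data(), n, &ok);
    if (!ok) t_boot[b] = NA_REAL;

    if (n_inner > 0) {
      // inner CDF of inner resample statistics at t0
      double below = 0, at = 0; int valid = 0;
      for (int c = 0; c < n_inner; ++c) {
        for (int i = 0; i < n; ++i) {
          int idx = (int)(unif_rand() * n);
          if (idx == n) idx = n - 1;
          xbb[i] = xb[idx]; ybb[i] = yb[idx];
        }
        double t2 = tau_b_core(xbb.data(), ybb.data(), n, &ok);
        if (!ok) continue;
        ++valid;
        if (t2 < t0) below += 1;
        else if (t2 == t0) at += 1;
      }
      u[b] = valid > 0 ? (below + 0.5 * at) / valid : NA_REAL;
    } else {
      u[b] = NA_REAL;
    }
  }

  // jackknife for the acceleration constant
  NumericVector t_jack(n);
  std::vector<double> xj(n - 1), yj(n - 1);
  for (int i = 0; i < n; ++i) {
    int k = 0;
    for (int j = 0; j < n; ++j) if (j != i) { xj[k] = x[j]; yj[k] = y[j]; ++k; }
    t_jack[i] = tau_b_core(xj.data(), yj.data(), n - 1, &ok);
    if (!ok) t_jack[i] = NA_REAL;
  }

  return List::create(_["t0"] = t0, _["t_boot"] = t_boot, _["u"] = u,
                      _["t_jack"] = t_jack);
}
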