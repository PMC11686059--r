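#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sequential minimal optimisation for the box-constrained dual
//
//   min_a  1/2 a' Q a + p' a   s.t.  y' a = 0,  0 <= a_i <= C_i
//
// with y_i in {+1, -1}. Working-set selection is the maximal violating
// pair; stopping rule m(a) - M(a) < eps. Covers both the soft-margin
// classifier (p = -1, Q = yy' .* K) and epsilon-insensitive regression
// via the standard doubled formulation. Problems here are small (a few
// hundred samples), so Q is taken dense and the full gradient is kept.

static const double TAU = 1e-12;

// [[Rcpp::export]]
List smo_solve_cpp(const NumericMatrix& Q, const NumericVector& p,
                   const IntegerVector& y, const NumericVector& C,
                   double eps = 1e-3, int max_iter = 1000000) {
  const int l = Q.nrow();
  std::vector<double> alpha(l, 0.0), G(p.begin(), p.end());

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // select maximal violating pair
    int i = -1, j = -1;
    double m = -HUGE_VAL, M = HUGE_VAL;
    for (int t = 0; t < l; ++t) {
      const double v = -y[t] * G[t];
      const bool up  = (y[t] == 1) ? (alpha[t] < C[t]) : (alpha[t] > 0);
      const bool low = (y[t] == 1) ? (alpha[t] > 0)    : (alpha[t] < C[t]);
      if (up && v > m) { m = v; i = t; }
      if (low && v < M) { M = v; j = t; }
    }
    if (i < 0 || j < 0 || m - M < eps) break;

    const double Ci = C[i], Cj = C[j];
    double quad = Q(i, i) + Q(j, j) - 2.0 * y[i] * y[j] * Q(i, j);
    if (quad <= 0) quad = TAU;
    const double old_ai = alpha[i], old_aj = alpha[j];

    if (y[i] != y[j]) {
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; } }
      else          { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; } }
      if (diff > Ci - Cj) {
        if (alpha[i] > Ci) { alpha[i] = Ci; alpha[j] = Ci - diff; }
      } else {
        if (alpha[j] > Cj) { alpha[j] = Cj; alpha[i] = Cj + diff; }
      }
    } else {
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > Ci) { if (alpha[i] > Ci) { alpha[i] = Ci; alpha[j] = sum - Ci; } }
      else          { if (alpha[j] < 0)  { alpha[j] = 0;  alpha[i] = sum; } }
      if (sum > Cj) { if (alpha[j] > Cj) { alpha[j] = Cj; alpha[i] = sum - Cj; } }
      else          { if (alpha[i] < 0)  { alpha[i] = 0;  alpha[j] = sum; } }
    }

    const double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    for (int t = 0; t < l; ++t)
      G[t] += Q(t, i) * dai + Q(t, j) * daj;
  }

  // offset rho: average of y_t G_t over free points, else midpoint
  double ub = HUGE_VAL, lb = -HUGE_VAL, sum_free = 0.0;
  int nfree = 0;
  for (int t = 0; t < l; ++t) {
    const double yG = y[t] * G[t];
    if (alpha[t] >= C[t] - 1e-12) {
      if (y[t] < 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 1e-12) {
      if (y[t] > 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else { ++nfree; sum_free += yG; }
  }
  const double rho = nfree > 0 ? sum_free / nfree : (ub + lb) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["rho"] = rho, _["iterations"] = iter,
                      _["converged"] = iter < max_iter);
}
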