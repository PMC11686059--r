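#include <Rcpp.h>
using namespace Rcpp;

// T is the element-wise signed cube root of the weight matrix (zero
// diagonal); by multiplicativity of the real cube root,
// T_ij * T_ik * T_jk = cbrt(S_ij * S_ik * S_jk).

// [[Rcpp::export]]
double brute_force_energy_cpp(const NumericMatrix& T) {
  const int n = T.nrow();
  long double acc = 0.0L;
  for (int i = 0; i < n - 2; ++i)
    for (int j = i + 1; j < n - 1; ++j) {
      const double tij = T(i, j);
      for (int k = j + 1; k < n; ++k)
        acc += tij * T(i, k) * T(j, k);
    }
  const long double ntri = (long double)n * (n - 1) * (n - 2) / 6.0L;
  return (double)(-acc / ntri);
}

// [[Rcpp::export]]
List triangle_census_cpp(const NumericMatrix& T) {
  const int n = T.nrow();
  long long nb = 0, ni = 0;
  long double ib = 0.0L, ii = 0.0L;
  for (int i = 0; i < n - 2; ++i)
    for (int j = i + 1; j < n - 1; ++j) {
      const double tij = T(i, j);
      for (int k = j + 1; k < n; ++k) {
        const double p = tij * T(i, k) * T(j, k);
        if (p > 0) { ++nb; ib += p; }
        else if (p < 0) { ++ni; ii -= p; }
        // p == 0: a zero edge, counted as neither balanced nor imbalanced
      }
    }
  return List::create(_["n_balanced"] = (double)nb,
                      _["n_imbalanced"] = (double)ni,
                      _["intensity_balanced"] = (double)ib,
                      _["intensity_imbalanced"] = (double)ii);
}
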