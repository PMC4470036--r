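#include <Rcpp.h>
using namespace Rcpp;

// Maximum standardized arc statistic over a lag grid.
//
// S: cumulative sums with leading zero (length m + 1).
// lags: arc lengths d to scan (1 <= d < m).
// For each lag d and start i (0-based), the arc covers values
// (i, i + d] and its statistic is
//   |S[i+d] - S[i] - d * mean| / sqrt(d * (m - d) / m),
// the likelihood-ratio statistic for a mean shift on the arc against the
// rest of the segment (variance held global, which permutation testing
// makes exact). Returns the maximum and its (i, d).
// [[Rcpp::export]]
List arc_max_stat(NumericVector S, IntegerVector lags) {
  const int m = S.size() - 1;
  const double mu = S[m] / m;
  double best = -1.0;
  int best_i = 0, best_d = 1;
  for (int k = 0; k < lags.size(); ++k) {
    const int d = lags[k];
    if (d < 1 || d >= m) continue;
    const double w = 1.0 / sqrt((double)d * (m - d) / m);
    const double drift = d * mu;
    for (int i = 0; i + d <= m; ++i) {
      double u = S[i + d] - S[i] - drift;
      if (u < 0) u = -u;
      u *= w;
      if (u > best) { best = u; best_i = i; best_d = d; }
    }
  }
  return List::create(_["stat"] = best, _["i"] = best_i, _["d"] = best_d);
}

// Permutation loop for the arc statistic with early stopping: counts
// permutations whose maximum reaches `target`; stops once `limit`
// exceedances make significance impossible. Returns the exceedance count
// and the number of permutations actually run.
// [[Rcpp::export]]
List arc_perm_count(NumericVector y, IntegerVector lags, double target,
                    int n_perm, int limit) {
  const int m = y.size();
  NumericVector S(m + 1);
  int exceed = 0, used = 0;
  NumericVector yp = clone(y);
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates using R's RNG for reproducibility under set.seed()
    for (int j = m - 1; j > 0; --j) {
      int k = (int)(unif_rand() * (j + 1));
      double tmp = yp[j]; yp[j] = yp[k]; yp[k] = tmp;
    }
    S[0] = 0.0;
    for (int j = 0; j < m; ++j) S[j + 1] = S[j] + yp[j];
    const double mu = S[m] / m;
    double best = -1.0;
    for (int k = 0; k < lags.size(); ++k) {
      const int d = lags[k];
      if (d < 1 || d >= m) continue;
      const double w = 1.0 / sqrt((double)d * (m - d) / m);
      const double drift = d * mu;
      for (int i = 0; i + d <= m; ++i) {
        double u = S[i + d] - S[i] - drift;
        if (u < 0) u = -u;
        u *= w;
        if (u > best) best = u;
        if (best >= target) break;
      }
      if (best >= target) break;
    }
    ++used;
    if (best >= target) {
      if (++exceed >= limit) break;
    }
  }
  return List::create(_["exceed"] = exceed, _["used"] = used);
}
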