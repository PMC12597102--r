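#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Max-|t| scan over all candidate arcs (i, j], 0 <= i < j <= n, of a signal.
// The statistic is the mean difference between the arc and its complement,
// standardised by sqrt(k * (n - k)); under within-segment permutation this is
// a monotone transform of the two-sample t statistic (total sum and sum of
// squares are permutation-invariant), so the permutation p-value is
// identical. Both resulting pieces must hold at least min_width markers.
// Ties broken leftmost (smallest arc start, then smallest arc end).

static double arc_scan(const std::vector<double> &S, int n, int min_width,
                       int *best_i, int *best_j, double stop_at) {
  const double T = S[n];
  double best = -1.0;
  int bi = -1, bj = -1;
  for (int k = min_width; k <= n - min_width; ++k) {
    const double ck = (double)k * T / n;
    const double inv = 1.0 / std::sqrt((double)k * (n - k));
    for (int i = 0; i + k <= n; ++i) {
      double v = std::fabs(S[i + k] - S[i] - ck) * inv;
      if (v > best) {
        best = v; bi = i; bj = i + k;
        if (stop_at > 0 && best >= stop_at) {
          if (best_i) { *best_i = bi; *best_j = bj; }
          return best;
        }
      }
    }
  }
  if (best_i) { *best_i = bi; *best_j = bj; }
  return best;
}

// [[Rcpp::export(name = ".cbs_max_arc")]]
List cbs_max_arc(NumericVector x, int min_width) {
  int n = x.size();
  if (n < 2 * min_width)
    return List::create(_["stat"] = NA_REAL, _["i"] = NA_INTEGER,
                        _["j"] = NA_INTEGER);
  std::vector<double> S(n + 1, 0.0);
  for (int i = 0; i < n; ++i) S[i + 1] = S[i] + x[i];
  int bi, bj;
  double best = arc_scan(S, n, min_width, &bi, &bj, -1.0);
  // 1-based: arc spans markers (bi+1)..bj
  return List::create(_["stat"] = best, _["i"] = bi, _["j"] = bj);
}

// Count permutations whose max arc statistic reaches obs. Permutations use
// R's RNG (reproducible under set.seed). Stops early once count exceeds
// max_exceed (the p-value is then already >= alpha).
// [[Rcpp::export(name = ".cbs_perm_count")]]
int cbs_perm_count(NumericVector x, int min_width, double obs, int nperm,
                   int max_exceed) {
  int n = x.size();
  std::vector<double> z(x.begin(), x.end());
  std::vector<double> S(n + 1, 0.0);
  int count = 0;
  for (int p = 0; p < nperm; ++p) {
    // Fisher-Yates with R uniforms
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(z[i], z[j]);
    }
    for (int i = 0; i < n; ++i) S[i + 1] = S[i] + z[i];
    double m = arc_scan(S, n, min_width, nullptr, nullptr, obs);
    if (m >= obs) {
      if (++count > max_exceed) return count;
    }
    if (p % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return count;
}
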