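#include <Rcpp.h>
using namespace Rcpp;

// Max two-sample mean-shift statistic over boundary pairs (i, j], the
// circular-binary-segmentation split statistic on an ordered signal.
// For arc (i, j] of length k in a region of n points with prefix sums P,
//   Z(i, j) = (mean_arc - mean_rest) / (sd * sqrt(1/k + 1/(n-k)))
//           = (P[j] - P[i] - k * mean) * sqrt(n / (k * (n - k))) / sd.
// sd (whole-region, denominator n-1) is permutation-invariant, so the
// permutation test can compare the unscaled maxima.

static double scan_max(const std::vector<double>& P, int n, double mean,
                       int* best_i, int* best_j, double stop_at) {
  double best = -1.0;
  for (int k = 1; k < n; ++k) {
    const double w = std::sqrt((double)n / ((double)k * (double)(n - k)));
    const double km = k * mean;
    for (int i = 0; i + k <= n; ++i) {
      double u = std::fabs(P[i + k] - P[i] - km) * w;
      if (u > best) {
        best = u;
        if (best_i) { *best_i = i; *best_j = i + k; }
        if (stop_at > 0 && best >= stop_at) return best;
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
List cbs_scan(NumericVector x) {
  const int n = x.size();
  if (n < 2) return List::create(_["stat"] = 0.0, _["i"] = 0, _["j"] = 0);
  std::vector<double> P(n + 1, 0.0);
  for (int i = 0; i < n; ++i) P[i + 1] = P[i] + x[i];
  const double mean = P[n] / n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (x[i] - mean) * (x[i] - mean);
  const double sd = std::sqrt(ss / (n - 1));
  int bi = 0, bj = 0;
  double u = scan_max(P, n, mean, &bi, &bj, -1.0);
  const double stat = (sd > 0) ? u / sd : 0.0;
  return List::create(_["stat"] = stat, _["i"] = bi, _["j"] = bj);
}

// Permutation p-value for the best split of x. Uses R's RNG (seed with
// set.seed). Early exits: a permutation scan stops once it exceeds the
// observed maximum, and the permutation loop stops once enough
// exceedances have accrued that p cannot fall below alpha.
// [[Rcpp::export]]
List cbs_split_pvalue(NumericVector x, int n_permutations, double alpha) {
  const int n = x.size();
  if (n < 2) {
    return List::create(_["stat"] = 0.0, _["i"] = 0, _["j"] = 0,
                        _["p"] = 1.0, _["n_perm_used"] = 0);
  }
  std::vector<double> P(n + 1, 0.0);
  for (int i = 0; i < n; ++i) P[i + 1] = P[i] + x[i];
  const double mean = P[n] / n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) ss += (x[i] - mean) * (x[i] - mean);
  const double sd = std::sqrt(ss / (n - 1));
  int bi = 0, bj = 0;
  const double obs = scan_max(P, n, mean, &bi, &bj, -1.0);
  if (sd == 0.0 || obs <= 0.0) {
    return List::create(_["stat"] = 0.0, _["i"] = bi, _["j"] = bj,
                        _["p"] = 1.0, _["n_perm_used"] = 0);
  }

  RNGScope scope;
  std::vector<double> y(x.begin(), x.end());
  const int max_exceed = (int)std::floor(alpha * (n_permutations + 1));
  int exceed = 0, b = 0;
  for (b = 0; b < n_permutations; ++b) {
    // Fisher-Yates with R's uniform RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(y[i], y[j]);
    }
    std::vector<double> Q(n + 1, 0.0);
    for (int i = 0; i < n; ++i) Q[i + 1] = Q[i] + y[i];
    double u = scan_max(Q, n, mean, nullptr, nullptr, obs);
    if (u >= obs) {
      ++exceed;
      if (exceed > max_exceed) { ++b; break; }
    }
  }
  const double p = (exceed + 1.0) / (b + 1.0);
  return List::create(_["stat"] = obs / sd, _["i"] = bi, _["j"] = bj,
                      _["p"] = p, _["n_perm_used"] = b);
}
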