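#include <Rcpp.h>
using namespace Rcpp;

// Count permutation exceedances for the two-sample mean-difference test.
//
// values: per-sample values; is_a: group membership (1 = group A).
// For each of n_reps replicates, group labels are shuffled uniformly
// (partial Fisher-Yates draw of n_a indices using R's RNG) and the
// statistic |mean(A) - mean(B)| recomputed. Returns the number of
// replicates whose statistic is >= the observed statistic; ties count
// as exceedances (a small relative epsilon guards float round-off).
// [[Rcpp::export]]
int perm_exceed_count(NumericVector values, LogicalVector is_a, int n_reps) {
  int n = values.size();
  int n_a = 0;
  double total = 0.0, sum_a = 0.0;
  for (int i = 0; i < n; ++i) {
    total += values[i];
    if (is_a[i]) { sum_a += values[i]; ++n_a; }
  }
  int n_b = n - n_a;
  if (n_a == 0 || n_b == 0)
    stop("both groups must be non-empty");
  double stat_obs = std::fabs(sum_a / n_a - (total - sum_a) / n_b);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) scale = std::max(scale, std::fabs(values[i]));
  double eps = 1e-12 * std::max(1.0, scale);

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<double> v(values.begin(), values.end());

  int exceed = 0;
  for (int r = 0; r < n_reps; ++r) {
    double s = 0.0;
    // partial Fisher-Yates: after the loop, idx[0..n_a-1] is a uniform
    // random n_a-subset; leaving idx shuffled between replicates keeps
    // each replicate's draw uniform.
    for (int i = 0; i < n_a; ++i) {
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1; // guard unif_rand() == 1.0 edge
      std::swap(idx[i], idx[j]);
      s += v[idx[i]];
    }
    double stat = std::fabs(s / n_a - (total - s) / n_b);
    if (stat >= stat_obs - eps) ++exceed;
  }
  return exceed;
}
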