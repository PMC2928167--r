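#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo null for the two-group mean-difference statistic.
// Pools the values, draws `m` random partitions into groups of size n and
// c = N - n (without replacement, via partial Fisher-Yates over indices,
// using R's RNG so set.seed() governs reproducibility), and records
// v = mean(simulated group 2) - mean(simulated group 1) for each draw.
// Returns the population mean and sd of the draws, and optionally the draws.
// [[Rcpp::export]]
List mc_null_distribution(NumericVector x, int n, int m,
                          bool retain_draws = false) {
  const int N = x.size();
  const int c = N - n;
  if (n < 1 || c < 1) stop("both groups must be non-empty");
  if (m < 1) stop("m must be >= 1");
  const double S = Rcpp::sum(x);
  std::vector<double> pool(x.begin(), x.end());
  std::vector<int> idx(N);
  NumericVector draws(retain_draws ? m : 0);
  double acc = 0.0, acc2 = 0.0;
  for (int it = 0; it < m; ++it) {
    for (int i = 0; i < N; ++i) idx[i] = i;
    double s1 = 0.0;
    for (int i = 0; i < n; ++i) {
      int j = i + static_cast<int>(unif_rand() * (N - i));
      if (j >= N) j = N - 1;
      std::swap(idx[i], idx[j]);
      s1 += pool[idx[i]];
    }
    const double v = (S - s1) / c - s1 / n;
    acc += v;
    acc2 += v * v;
    if (retain_draws) draws[it] = v;
  }
  const double mu = acc / m;
  double var = acc2 / m - mu * mu;
  if (var < 0) var = 0;
  return List::create(_["mu"] = mu, _["sigma"] = std::sqrt(var),
                      _["draws"] = draws);
}
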