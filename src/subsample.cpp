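#include <Rcpp.h>
using namespace Rcpp;

// Subset-mean resampling core. For each of n_combos combinations and each
// subject (row of y), draws n distinct day indices uniformly without
// replacement (partial Fisher-Yates driven by R's RNG, so results are
// reproducible under set.seed) and averages those days.
//
// Returns an m x n_combos matrix of subsample means.
// [[Rcpp::export(name = ".subsample_means_cpp")]]
NumericMatrix subsample_means_cpp(NumericMatrix y, int n, int n_combos) {
  const int m = y.nrow(), N = y.ncol();
  if (n < 1 || n > N) stop("subset size out of range");
  NumericMatrix out(m, n_combos);
  std::vector<int> idx(N);
  RNGScope scope;
  for (int c = 0; c < n_combos; ++c) {
    for (int i = 0; i < m; ++i) {
      for (int k = 0; k < N; ++k) idx[k] = k;
      double s = 0.0;
      for (int j = 0; j < n; ++j) {
        int pick = j + (int)(unif_rand() * (N - j));
        if (pick >= N) pick = N - 1;  // guard against unif_rand() == 1
        std::swap(idx[j], idx[pick]);
        s += y(i, idx[j]);
      }
      out(i, c) = s / n;
    }
  }
  return out;
}
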