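#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Quantile-regression-forest kernels.
//
// Trees arrive as terminal-node assignments (train and query rows) plus
// bootstrap inbag counts. Leaves therefore "store" the raw training targets
// of their inbag members. Quantiles use the left-continuous inverse of the
// weighted empirical CDF, inf{y : F(y) >= q}, both per tree and for the
// ensemble (Meinshausen weights: average over trees of
// inbag_count / leaf_size for co-leaf training points).

// [[Rcpp::export]]
List qrf_quantiles_cpp(IntegerMatrix trainLeaf, IntegerMatrix testLeaf,
                       IntegerMatrix inbag, NumericVector y,
                       NumericVector levels, bool perTree) {
  const int n = trainLeaf.nrow();
  const int T = trainLeaf.ncol();
  const int m = testLeaf.nrow();
  const int L = levels.size();
  const double tol = 1e-9;

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return y[a] < y[b]; });

  // Per tree: leaf id -> inbag member indices (sorted by target value),
  // and total inbag count per leaf.
  std::vector< std::unordered_map<int, std::vector<int> > > members(T);
  std::vector< std::unordered_map<int, double> > leafSum(T);
  for (int t = 0; t < T; ++t) {
    for (int j = 0; j < n; ++j) {
      const int c = inbag(j, t);
      if (c > 0) {
        members[t][trainLeaf(j, t)].push_back(j);
        leafSum[t][trainLeaf(j, t)] += c;
      }
    }
    for (auto &kv : members[t]) {
      std::sort(kv.second.begin(), kv.second.end(),
                [&](int a, int b) { return y[a] < y[b]; });
    }
  }

  NumericMatrix Q(m, L);
  NumericVector treeQ;
  if (perTree) treeQ = NumericVector(Dimension(m, T, L));

  std::vector<double> w(n);
  for (int i = 0; i < m; ++i) {
    std::fill(w.begin(), w.end(), 0.0);
    for (int t = 0; t < T; ++t) {
      const int leaf = testLeaf(i, t);
      auto it = members[t].find(leaf);
      if (it == members[t].end()) continue;
      const double ls = leafSum[t][leaf];
      for (int j : it->second) w[j] += inbag(j, t) / (ls * T);
      if (perTree) {
        for (int l = 0; l < L; ++l) {
          const double target = levels[l] * ls;
          double cum = 0.0;
          double val = y[it->second.back()];
          for (int j : it->second) {
            cum += inbag(j, t);
            if (cum >= target - tol) { val = y[j]; break; }
          }
          treeQ[i + (size_t)m * t + (size_t)m * T * l] = val;
        }
      }
    }
    double tot = 0.0;
    for (int j = 0; j < n; ++j) tot += w[j];
    for (int l = 0; l < L; ++l) {
      const double target = levels[l] * tot;
      double cum = 0.0;
      double val = y[ord[n - 1]];
      for (int jj = 0; jj < n; ++jj) {
        const int j = ord[jj];
        cum += w[j];
        if (cum >= target - tol) { val = y[j]; break; }
      }
      Q(i, l) = val;
    }
  }
  return List::create(Named("quantiles") = Q,
                      Named("per_tree") = perTree ? (SEXP)treeQ : R_NilValue);
}
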