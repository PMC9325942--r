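#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Minimal CART random forest (classification, Gini impurity).
// Self-contained because the target environment ships no tree learner.
// Determinism: all randomness comes from a user seed through a local
// xorshift generator, so results do not depend on the compiler's
// std::uniform_int_distribution.

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  // integer in [0, n)
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // x[f] <= thr goes left
  std::vector<int> left, right;  // child node ids, -1 for leaf
  std::vector<double> probs;     // nnode * K, class proportions
};

double gini_from_counts(const std::vector<double>& cnt, double n) {
  if (n <= 0) return 0.0;
  double s = 0.0;
  for (double c : cnt) s += (c / n) * (c / n);
  return 1.0 - s;
}

struct Grower {
  const NumericMatrix& X;
  const IntegerVector& y; // 0..K-1
  int K, mtry, min_split, max_depth;
  Rng& rng;
  Tree tree;

  Grower(const NumericMatrix& X_, const IntegerVector& y_, int K_, int mtry_,
         int min_split_, int max_depth_, Rng& rng_)
      : X(X_), y(y_), K(K_), mtry(mtry_), min_split(min_split_),
        max_depth(max_depth_), rng(rng_) {}

  int make_leaf(const std::vector<int>& idx) {
    std::vector<double> cnt(K, 0.0);
    for (int i : idx) cnt[y[i]] += 1.0;
    int id = static_cast<int>(tree.feature.size());
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    double n = static_cast<double>(idx.size());
    for (int k = 0; k < K; ++k) tree.probs.push_back(cnt[k] / n);
    return id;
  }

  int grow(std::vector<int>& idx, int depth) {
    int n = static_cast<int>(idx.size());
    std::vector<double> cnt(K, 0.0);
    for (int i : idx) cnt[y[i]] += 1.0;
    bool pure = false;
    for (int k = 0; k < K; ++k)
      if (cnt[k] == static_cast<double>(n)) pure = true;
    if (pure || n < min_split || depth >= max_depth) return make_leaf(idx);

    // sample mtry distinct candidate features (partial Fisher-Yates)
    int S = X.ncol();
    std::vector<int> feats(S);
    for (int j = 0; j < S; ++j) feats[j] = j;
    int m = std::min(mtry, S);
    for (int j = 0; j < m; ++j) std::swap(feats[j], feats[j + rng.below(S - j)]);

    double parent_imp = gini_from_counts(cnt, n);
    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;

    std::vector<std::pair<double, int> > vals(n);
    for (int jj = 0; jj < m; ++jj) {
      int f = feats[jj];
      for (int i = 0; i < n; ++i) vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      std::vector<double> lc(K, 0.0);
      double nl = 0.0;
      for (int i = 0; i + 1 < n; ++i) {
        lc[vals[i].second] += 1.0;
        nl += 1.0;
        if (vals[i].first == vals[i + 1].first) continue;
        double nr = n - nl;
        std::vector<double> rc(K);
        for (int k = 0; k < K; ++k) rc[k] = cnt[k] - lc[k];
        double child = (nl / n) * gini_from_counts(lc, nl) +
                       (nr / n) * gini_from_counts(rc, nr);
        double gain = parent_imp - child;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = vals[i].first + 0.5 * (vals[i + 1].first - vals[i].first);
        }
      }
    }
    if (best_f < 0) return make_leaf(idx);

    std::vector<int> li, ri;
    li.reserve(n);
    ri.reserve(n);
    for (int i : idx)
      (X(i, best_f) <= best_thr ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) return make_leaf(idx);

    int id = static_cast<int>(tree.feature.size());
    tree.feature.push_back(best_f);
    tree.threshold.push_back(best_thr);
    tree.left.push_back(-2);  // placeholder
    tree.right.push_back(-2);
    for (int k = 0; k < K; ++k) tree.probs.push_back(0.0);
    int lid = grow(li, depth + 1);
    int rid = grow(ri, depth + 1);
    tree.left[id] = lid;
    tree.right[id] = rid;
    return id;
  }
};

} // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int nclass, int ntree,
                int mtry, int min_split, int max_depth, double seed) {
  int n = X.nrow();
  Rng rng(static_cast<uint64_t>(seed));
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> boot(n);
    for (int i = 0; i < n; ++i) boot[i] = rng.below(n);
    Grower g(X, y, nclass, mtry, min_split, max_depth, rng);
    g.grow(boot, 0);
    int nn = static_cast<int>(g.tree.feature.size());
    NumericMatrix probs(nn, nclass);
    for (int i = 0; i < nn; ++i)
      for (int k = 0; k < nclass; ++k) probs(i, k) = g.tree.probs[i * nclass + k];
    trees[t] = List::create(
        Named("feature") = IntegerVector(g.tree.feature.begin(), g.tree.feature.end()),
        Named("threshold") = NumericVector(g.tree.threshold.begin(), g.tree.threshold.end()),
        Named("left") = IntegerVector(g.tree.left.begin(), g.tree.left.end()),
        Named("right") = IntegerVector(g.tree.right.begin(), g.tree.right.end()),
        Named("probs") = probs);
  }
  return trees;
}

// [[Rcpp::export]]
NumericMatrix rf_predict_cpp(List trees, NumericMatrix X, int nclass) {
  int n = X.nrow();
  int T = trees.size();
  NumericMatrix out(n, nclass);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    NumericMatrix probs = tr["probs"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
      for (int k = 0; k < nclass; ++k) out(i, k) += probs(node, k);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < nclass; ++k) out(i, k) /= T;
  return out;
}
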