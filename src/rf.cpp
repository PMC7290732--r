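// Minimal random-forest classifier for two classes, built for the
// iterative marker-selection procedure: bootstrap sampling, random feature
// subsets at each node (mtry), CART splits by Gini impurity, and either
// mean-decrease-in-Gini or out-of-bag permutation importance.  Sample
// sizes here are tiny (a handful of replicates), so trees are grown to
// purity with no depth cap.
//
// Randomness uses a self-contained xorshift generator seeded from R, so
// results are bit-reproducible across platforms and independent of R's
// RNG state.
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  // uniform integer in [0, n)
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Node {
  int feature = -1;        // -1 for leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  int pred = 0;            // leaf class
};

double gini(int n1, int n) {
  if (n == 0) return 0.0;
  double p = static_cast<double>(n1) / n;
  return 2.0 * p * (1.0 - p);
}

struct Tree {
  std::vector<Node> nodes;

  int predict(const NumericMatrix& X, int row,
              const int* perm = nullptr, int perm_feat = -1) const {
    int cur = 0;
    while (nodes[cur].feature >= 0) {
      int f = nodes[cur].feature;
      int r = (perm && f == perm_feat) ? perm[row] : row;
      cur = (X(r, f) <= nodes[cur].threshold) ? nodes[cur].left
                                              : nodes[cur].right;
    }
    return nodes[cur].pred;
  }
};

// grow one node recursively; idx holds in-bag row indices (with repeats)
int grow(const NumericMatrix& X, const IntegerVector& y,
         std::vector<int>& idx, int mtry, XorShift& rng,
         Tree& tree, std::vector<double>& imp) {
  int n = idx.size();
  int n1 = 0;
  for (int i : idx) n1 += y[i];
  int me = tree.nodes.size();
  tree.nodes.push_back(Node());
  tree.nodes[me].pred = (2 * n1 > n) ? 1 : (2 * n1 < n ? 0 : rng.below(2));
  if (n1 == 0 || n1 == n || n < 2) return me;

  int p = X.ncol();
  double parent_score = gini(n1, n) * n;
  double best_gain = 1e-12;  // require strictly positive impurity decrease
  int best_f = -1; double best_thr = 0.0;

  // sample mtry distinct features (partial Fisher-Yates over a scratch list)
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    int pick = j + rng.below(p - j);
    std::swap(feats[j], feats[pick]);
    int f = feats[j];
    // candidate thresholds: midpoints between sorted distinct values
    std::vector<std::pair<double, int>> v(n);
    for (int i = 0; i < n; ++i) v[i] = {X(idx[i], f), y[idx[i]]};
    std::sort(v.begin(), v.end());
    int ln = 0, ln1 = 0;
    for (int i = 0; i + 1 < n; ++i) {
      ln += 1; ln1 += v[i].second;
      if (v[i].first == v[i + 1].first) continue;
      int rn = n - ln, rn1 = n1 - ln1;
      double child = gini(ln1, ln) * ln + gini(rn1, rn) * rn;
      double gain = parent_score - child;
      if (gain > best_gain) {
        best_gain = gain; best_f = f;
        best_thr = 0.5 * (v[i].first + v[i + 1].first);
      }
    }
  }
  if (best_f < 0) return me;  // no informative split among sampled features

  imp[best_f] += best_gain;   // mean-decrease-in-Gini accumulator
  std::vector<int> li, ri;
  for (int i : idx) {
    if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
  }
  tree.nodes[me].feature = best_f;
  tree.nodes[me].threshold = best_thr;
  int l = grow(X, y, li, mtry, rng, tree, imp);
  int r = grow(X, y, ri, mtry, rng, tree, imp);
  tree.nodes[me].left = l;
  tree.nodes[me].right = r;
  return me;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_rf_importance(NumericMatrix X, IntegerVector y,
                                int ntree, int mtry, double seed,
                                std::string type) {
  int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("X and y dimensions disagree");
  bool permutation = (type == "permutation");
  XorShift rng(static_cast<uint64_t>(seed) * 0x2545F4914F6CDD1DULL + 1ULL);
  NumericVector imp(p);
  std::vector<double> gini_imp(p, 0.0);
  std::vector<int> perm(n);

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> bag(n);
    std::vector<bool> inbag(n, false);
    for (int i = 0; i < n; ++i) { bag[i] = rng.below(n); inbag[bag[i]] = true; }
    Tree tree;
    grow(X, y, bag, mtry, rng, tree, gini_imp);
    if (!permutation) continue;

    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i);
    if (oob.empty()) continue;
    int correct = 0;
    for (int i : oob) correct += (tree.predict(X, i) == y[i]);
    double acc = static_cast<double>(correct) / oob.size();
    // permute each feature among OOB rows and measure the accuracy drop
    for (int f = 0; f < p; ++f) {
      for (int i = 0; i < n; ++i) perm[i] = i;
      for (size_t i = oob.size(); i > 1; --i) {
        size_t j = rng.below(static_cast<int>(i));
        std::swap(perm[oob[i - 1]], perm[oob[j]]);
      }
      int c2 = 0;
      for (int i : oob) c2 += (tree.predict(X, i, perm.data(), f) == y[i]);
      imp[f] += acc - static_cast<double>(c2) / oob.size();
    }
  }
  if (!permutation) {
    for (int f = 0; f < p; ++f) imp[f] = gini_imp[f] / ntree;
  } else {
    for (int f = 0; f < p; ++f) imp[f] /= ntree;
  }
  return imp;
}
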