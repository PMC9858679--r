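// Compact CART classification ensemble: exhaustive best-split trees
// (decision tree / random forest) and random-threshold trees (extra trees).
// Class probabilities are leaf class proportions averaged over trees.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<std::vector<double>> prob; // leaf class distribution
};

struct Grower {
  const NumericMatrix &X;
  const IntegerVector &y;
  int n_classes, mtry, max_depth, min_split;
  bool random_splits;
  std::mt19937 &rng;

  Grower(const NumericMatrix &X, const IntegerVector &y, int n_classes,
         int mtry, int max_depth, int min_split, bool random_splits,
         std::mt19937 &rng)
      : X(X), y(y), n_classes(n_classes), mtry(mtry), max_depth(max_depth),
        min_split(min_split), random_splits(random_splits), rng(rng) {}

  static double gini_from_counts(const std::vector<double> &cnt, double n) {
    if (n <= 0.0) return 0.0;
    double s = 0.0;
    for (double c : cnt) s += c * c;
    return 1.0 - s / (n * n);
  }

  // weighted child impurity for an exhaustive scan over one feature;
  // returns best score and threshold (midpoint), or false if unsplittable
  bool best_split_feature(const std::vector<int> &idx, int f, double &score,
                          double &thr) const {
    size_t n = idx.size();
    std::vector<std::pair<double, int>> v(n);
    for (size_t i = 0; i < n; ++i) v[i] = {X(idx[i], f), y[idx[i]]};
    std::sort(v.begin(), v.end());
    if (v.front().first == v.back().first) return false;

    std::vector<double> left_cnt(n_classes, 0.0), right_cnt(n_classes, 0.0);
    for (size_t i = 0; i < n; ++i) right_cnt[v[i].second] += 1.0;
    bool found = false;
    for (size_t i = 0; i + 1 < n; ++i) {
      left_cnt[v[i].second] += 1.0;
      right_cnt[v[i].second] -= 1.0;
      if (v[i].first == v[i + 1].first) continue;
      double nl = double(i + 1), nr = double(n - i - 1);
      double s = nl * gini_from_counts(left_cnt, nl) +
                 nr * gini_from_counts(right_cnt, nr);
      if (!found || s < score) {
        found = true;
        score = s;
        thr = v[i].first + 0.5 * (v[i + 1].first - v[i].first);
      }
    }
    return found;
  }

  // extra-trees candidate: one uniform random threshold on feature f
  bool random_split_feature(const std::vector<int> &idx, int f, double &score,
                            double &thr) {
    double lo = X(idx[0], f), hi = lo;
    for (int i : idx) {
      double v = X(i, f);
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
    if (lo == hi) return false;
    std::uniform_real_distribution<double> U(lo, hi);
    double t = U(rng);
    if (t >= hi) t = std::nextafter(hi, lo); // keep both sides non-empty
    std::vector<double> left_cnt(n_classes, 0.0), right_cnt(n_classes, 0.0);
    double nl = 0.0, nr = 0.0;
    for (int i : idx) {
      if (X(i, f) <= t) { left_cnt[y[i]] += 1.0; nl += 1.0; }
      else              { right_cnt[y[i]] += 1.0; nr += 1.0; }
    }
    if (nl == 0.0 || nr == 0.0) return false;
    score = nl * gini_from_counts(left_cnt, nl) +
            nr * gini_from_counts(right_cnt, nr);
    thr = t;
    return true;
  }

  bool find_split(const std::vector<int> &idx, const std::vector<int> &feats,
                  int &best_f, double &best_thr) {
    bool found = false;
    double best_score = 0.0;
    for (int f : feats) {
      double score, thr;
      bool ok = random_splits ? random_split_feature(idx, f, score, thr)
                              : best_split_feature(idx, f, score, thr);
      if (ok && (!found || score < best_score)) {
        found = true;
        best_score = score;
        best_f = f;
        best_thr = thr;
      }
    }
    return found;
  }

  int make_leaf(Tree &t, const std::vector<int> &idx) {
    std::vector<double> cnt(n_classes, 0.0);
    for (int i : idx) cnt[y[i]] += 1.0;
    double n = double(idx.size());
    for (double &c : cnt) c /= n;
    t.feature.push_back(-1);
    t.threshold.push_back(0.0);
    t.left.push_back(-1);
    t.right.push_back(-1);
    t.prob.push_back(cnt);
    return int(t.feature.size()) - 1;
  }

  bool pure(const std::vector<int> &idx) const {
    int c0 = y[idx[0]];
    for (int i : idx)
      if (y[i] != c0) return false;
    return true;
  }

  int grow(Tree &t, const std::vector<int> &idx, int depth) {
    int p = X.ncol();
    if (depth >= max_depth || int(idx.size()) < min_split || pure(idx))
      return make_leaf(t, idx);

    // sample mtry candidate features (partial Fisher-Yates)
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> U(j, p - 1);
      std::swap(feats[j], feats[U(rng)]);
    }
    std::vector<int> cand(feats.begin(), feats.begin() + m);

    int f;
    double thr;
    bool ok = find_split(idx, cand, f, thr);
    if (!ok && m < p) {
      // all sampled candidates constant: fall back to the full feature set
      ok = find_split(idx, feats, f, thr);
    }
    if (!ok) return make_leaf(t, idx);

    std::vector<int> li, ri;
    for (int i : idx) (X(i, f) <= thr ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) return make_leaf(t, idx);

    int node = int(t.feature.size());
    t.feature.push_back(f);
    t.threshold.push_back(thr);
    t.left.push_back(-1);
    t.right.push_back(-1);
    t.prob.push_back(std::vector<double>());
    int l = grow(t, li, depth + 1);
    int r = grow(t, ri, depth + 1);
    t.left[node] = l;
    t.right[node] = r;
    return node;
  }
};

List tree_to_list(const Tree &t, int n_classes) {
  int n = int(t.feature.size());
  IntegerVector feature(n), left(n), right(n);
  NumericVector threshold(n);
  NumericMatrix prob(n, n_classes);
  for (int i = 0; i < n; ++i) {
    feature[i] = t.feature[i];
    threshold[i] = t.threshold[i];
    left[i] = t.left[i];
    right[i] = t.right[i];
    if (t.feature[i] == -1)
      for (int k = 0; k < n_classes; ++k) prob(i, k) = t.prob[i][k];
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right, _["prob"] = prob);
}

} // namespace

// [[Rcpp::export]]
List cpp_forest_fit(NumericMatrix X, IntegerVector y, int n_classes,
                    int n_trees, int mtry, int max_depth, int min_split,
                    bool bootstrap, bool random_splits, int seed) {
  int n = X.nrow();
  if (y.size() != n) stop("X/y length mismatch");
  for (int i = 0; i < n; ++i)
    if (y[i] < 0 || y[i] >= n_classes) stop("class code out of range");
  std::mt19937 rng(static_cast<uint32_t>(seed));
  List trees(n_trees);
  for (int tix = 0; tix < n_trees; ++tix) {
    std::vector<int> idx;
    idx.reserve(n);
    if (bootstrap) {
      std::uniform_int_distribution<int> U(0, n - 1);
      for (int i = 0; i < n; ++i) idx.push_back(U(rng));
    } else {
      for (int i = 0; i < n; ++i) idx.push_back(i);
    }
    Tree t;
    Grower g(X, y, n_classes, mtry, max_depth, min_split, random_splits, rng);
    g.grow(t, idx, 0);
    trees[tix] = tree_to_list(t, n_classes);
  }
  return trees;
}

// [[Rcpp::export]]
NumericMatrix cpp_forest_predict(List trees, NumericMatrix X, int n_classes) {
  int n = X.nrow(), T = trees.size();
  NumericMatrix out(n, n_classes);
  for (int tix = 0; tix < T; ++tix) {
    List t = trees[tix];
    IntegerVector feature = t["feature"], left = t["left"], right = t["right"];
    NumericVector threshold = t["threshold"];
    NumericMatrix prob = t["prob"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] != -1)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      for (int k = 0; k < n_classes; ++k) out(i, k) += prob(node, k);
    }
  }
  if (T > 0)
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < n_classes; ++k) out(i, k) /= double(T);
  return out;
}
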