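// Random forest for small-sample binary classification: Gini-impurity CART
// trees on bootstrap samples with per-node feature subsampling. Uses R's RNG
// so results are reproducible under set.seed(). Trees are returned as flat
// numeric matrices (one row per node) so models are plain R objects.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // split: x[feature] <= threshold -> left
  int left, right;  // child indices, -1 for leaf
  double prob1;     // leaf probability of class 1
};

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, max_depth, min_node;
  std::vector<Node> nodes;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
          int max_depth_, int min_node_)
      : X(X_), y(y_), mtry(mtry_), max_depth(max_depth_),
        min_node(min_node_) {}

  int build(std::vector<int>& idx, int depth) {
    int n = idx.size();
    int n1 = 0;
    for (int i : idx) n1 += y[i];
    int id = nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, (double)n1 / n});
    if (depth >= max_depth || n < min_node || n1 == 0 || n1 == n)
      return id;

    int p = X.ncol();
    // sample mtry distinct features (partial Fisher-Yates with R RNG)
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int k = j + (int)(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(feats[j], feats[k]);
    }

    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    double parent_gini = 2.0 * n1 * (n - n1) / ((double)n * n);
    std::vector<std::pair<double, int> > vals(n);
    for (int j = 0; j < m; ++j) {
      int f = feats[j];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      int left1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        left1 += vals[i].second;
        if (vals[i + 1].first <= vals[i].first) continue;  // tie on value
        int nl = i + 1, nr = n - nl;
        int right1 = n1 - left1;
        double gl = 2.0 * left1 * (nl - left1) / ((double)nl * nl);
        double gr = 2.0 * right1 * (nr - right1) / ((double)nr * nr);
        double gain = parent_gini - (nl * gl + nr * gr) / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return id;

    std::vector<int> li, ri;
    for (int i : idx)
      (X(i, best_f) <= best_thr ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) return id;
    nodes[id].feature = best_f;
    nodes[id].threshold = best_thr;
    int l = build(li, depth + 1);
    int r = build(ri, depth + 1);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }
};

double tree_predict(const NumericMatrix& tree, const NumericMatrix& X,
                    int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = (X(row, f) <= tree(node, 1)) ? (int)tree(node, 2)
                                        : (int)tree(node, 3);
  }
  return tree(node, 4);
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int max_depth,
                int mtry, int min_node) {
  int n = X.nrow();
  RNGScope scope;
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      idx[i] = k;
    }
    Builder b(X, y, mtry, max_depth, min_node);
    b.build(idx, 0);
    NumericMatrix tm(b.nodes.size(), 5);
    for (size_t i = 0; i < b.nodes.size(); ++i) {
      tm(i, 0) = b.nodes[i].feature;
      tm(i, 1) = b.nodes[i].threshold;
      tm(i, 2) = b.nodes[i].left;
      tm(i, 3) = b.nodes[i].right;
      tm(i, 4) = b.nodes[i].prob1;
    }
    trees[t] = tm;
  }
  return trees;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), nt = trees.size();
  NumericVector out(n);
  for (int t = 0; t < nt; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += tree_predict(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= nt;
  return out;
}
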