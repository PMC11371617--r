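// Seed-deterministic regression forest used by the missForest-style
// imputer.  Variance-reduction (sum-of-squares) splits; ties resolve to the
// lowest feature index, then the lowest threshold; bootstrap rows and
// feature subsets come from one std::mt19937 stream so results are
// bit-identical across runs and platforms.
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;        // -1 marks a leaf
  double threshold = 0.0;  // go left if x <= threshold
  double value = 0.0;      // leaf prediction
  int left = -1, right = -1;
};

struct Tree {
  std::vector<Node> nodes;
};

double node_mean(const std::vector<int>& rows, const NumericVector& y) {
  double s = 0.0;
  for (int r : rows) s += y[r];
  return s / rows.size();
}

// best split on one feature by scanning sorted values with prefix sums;
// returns gain (SSE reduction); threshold is the midpoint between distinct
// neighbours, first-best wins so equal-gain thresholds take the lowest.
bool best_split_feature(const NumericMatrix& X, const NumericVector& y,
                        const std::vector<int>& rows, int j, int min_leaf,
                        double& gain, double& thr) {
  const int n = (int)rows.size();
  std::vector<int> ord(rows);
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return X(a, j) < X(b, j);
  });
  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + y[ord[i]];
    cs2[i + 1] = cs2[i] + y[ord[i]] * y[ord[i]];
  }
  const double tot = cs[n], tot2 = cs2[n];
  const double sse_all = tot2 - tot * tot / n;
  gain = 0.0;
  bool found = false;
  for (int i = min_leaf; i <= n - min_leaf; ++i) {
    if (X(ord[i - 1], j) >= X(ord[i], j)) continue;  // not a boundary
    const double sl = cs[i], sl2 = cs2[i];
    const double sr = tot - sl, sr2 = tot2 - sl2;
    const double sse = (sl2 - sl * sl / i) + (sr2 - sr * sr / (n - i));
    const double g = sse_all - sse;
    if (g > gain + 1e-12) {
      gain = g;
      thr = 0.5 * (X(ord[i - 1], j) + X(ord[i], j));
      found = true;
    }
  }
  return found;
}

int grow(Tree& tree, const NumericMatrix& X, const NumericVector& y,
         std::vector<int>& rows, int mtry, int min_leaf,
         std::mt19937& rng) {
  const int p = X.ncol();
  Node node;
  node.value = node_mean(rows, y);
  const int id = (int)tree.nodes.size();
  tree.nodes.push_back(node);
  if ((int)rows.size() < 2 * min_leaf) return id;

  // sample mtry features without replacement, then visit in ascending
  // index order so equal gains resolve to the lowest feature index
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int i = 0; i < mtry && i < p; ++i) {
    std::uniform_int_distribution<int> u(i, p - 1);
    std::swap(feats[i], feats[u(rng)]);
  }
  feats.resize(std::min(mtry, p));
  std::sort(feats.begin(), feats.end());

  double best_gain = 0.0, best_thr = 0.0;
  int best_feat = -1;
  for (int j : feats) {
    double g, t;
    if (best_split_feature(X, y, rows, j, min_leaf, g, t) &&
        g > best_gain + 1e-12) {
      best_gain = g; best_thr = t; best_feat = j;
    }
  }
  if (best_feat < 0) return id;

  std::vector<int> lrows, rrows;
  for (int r : rows) {
    (X(r, best_feat) <= best_thr ? lrows : rrows).push_back(r);
  }
  tree.nodes[id].feature = best_feat;
  tree.nodes[id].threshold = best_thr;
  const int l = grow(tree, X, y, lrows, mtry, min_leaf, rng);
  const int r = grow(tree, X, y, rrows, mtry, min_leaf, rng);
  tree.nodes[id].left = l;
  tree.nodes[id].right = r;
  return id;
}

double predict_tree(const Tree& tree, const NumericMatrix& X, int row) {
  int id = 0;
  while (tree.nodes[id].feature >= 0) {
    id = (X(row, tree.nodes[id].feature) <= tree.nodes[id].threshold)
             ? tree.nodes[id].left
             : tree.nodes[id].right;
  }
  return tree.nodes[id].value;
}

}  // namespace

// [[Rcpp::export]]
NumericVector rf_fit_predict(NumericMatrix Xtr, NumericVector ytr,
                             NumericMatrix Xte, int n_trees, int mtry,
                             int min_leaf, int seed) {
  const int n = Xtr.nrow(), m = Xte.nrow();
  if (n_trees < 1) stop("n_trees must be >= 1");
  if (Xtr.ncol() != Xte.ncol()) stop("train/test width mismatch");
  std::mt19937 rng((unsigned)seed);
  NumericVector pred(m, 0.0);
  std::uniform_int_distribution<int> boot(0, n - 1);
  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = boot(rng);
    std::sort(rows.begin(), rows.end());  // row-index tie determinism
    Tree tree;
    grow(tree, Xtr, ytr, rows, mtry, min_leaf, rng);
    for (int i = 0; i < m; ++i) pred[i] += predict_tree(tree, Xte, i);
  }
  for (int i = 0; i < m; ++i) pred[i] /= n_trees;
  return pred;
}
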