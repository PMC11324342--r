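// Gradient-boosted decision trees for binary classification.
//
// Exact greedy split search with second-order (Newton) boosting on the
// logistic loss. Regularisation follows the conventional defaults of
// gradient-boosting libraries: L2 penalty lambda = 1 on leaf weights,
// no split penalty (gamma = 0), minimum child hessian weight 1.
// Deterministic: ties in split gain break on the lower feature index,
// then the lower threshold; row subsampling uses a seeded Mersenne
// Twister, so results are reproducible across platforms.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

constexpr double kLambda = 1.0;          // L2 on leaf weights
constexpr double kMinChildWeight = 1.0;  // min hessian sum per child

struct Node {
  int feature = -1;       // -1 for leaves
  double threshold = 0.0; // go left if x <= threshold
  int left = -1, right = -1;
  double value = 0.0;     // leaf weight (already scaled by eta)
};

struct SplitResult {
  double gain = 0.0;
  int feature = -1;
  double threshold = 0.0;
};

inline double sigmoid(double m) { return 1.0 / (1.0 + std::exp(-m)); }

inline double leaf_objective(double g, double h) {
  return (g * g) / (h + kLambda);
}

// Best exact split over all features for the rows in `rows`.
// `order` holds, per feature, all row indices sorted by feature value.
// `in_node` marks rows of the current node.
SplitResult best_split(const NumericMatrix& X,
                       const std::vector<std::vector<int>>& order,
                       const std::vector<char>& in_node,
                       const std::vector<double>& grad,
                       const std::vector<double>& hess,
                       double g_total, double h_total) {
  const int p = X.ncol();
  const int n = X.nrow();
  const double* xp = &X[0];  // column-major
  SplitResult best;
  const double parent_obj = leaf_objective(g_total, h_total);
  for (int j = 0; j < p; ++j) {
    const std::vector<int>& ord = order[j];
    const double* col = xp + static_cast<size_t>(j) * n;
    double gl = 0.0, hl = 0.0;
    double prev_val = 0.0;
    bool have_prev = false;
    for (size_t k = 0; k < ord.size(); ++k) {
      const int i = ord[k];
      if (!in_node[i]) continue;
      const double v = col[i];
      if (have_prev && v > prev_val) {
        // candidate split between prev_val and v
        const double gr = g_total - gl, hr = h_total - hl;
        if (hl >= kMinChildWeight && hr >= kMinChildWeight) {
          const double gain =
              0.5 * (leaf_objective(gl, hl) + leaf_objective(gr, hr) -
                     parent_obj);
          if (gain > best.gain + 1e-12) {
            best.gain = gain;
            best.feature = j;
            best.threshold = 0.5 * (prev_val + v);
          }
        }
      }
      gl += grad[i];
      hl += hess[i];
      prev_val = v;
      have_prev = true;
    }
  }
  return best;
}

// Recursively grow one tree; returns the index of the created node.
int grow(const NumericMatrix& X,
         const std::vector<std::vector<int>>& order,
         std::vector<char>& in_node, const std::vector<int>& rows,
         const std::vector<double>& grad, const std::vector<double>& hess,
         int depth, int max_depth, double eta,
         std::vector<Node>& nodes, std::vector<double>& importance) {
  double g = 0.0, h = 0.0;
  for (int i : rows) { g += grad[i]; h += hess[i]; }

  Node node;
  const int idx = static_cast<int>(nodes.size());
  nodes.push_back(node);

  SplitResult split;
  // a split needs min_child_weight of hessian on both sides
  if (depth < max_depth && rows.size() >= 2 && h >= 2 * kMinChildWeight) {
    for (int i : rows) in_node[i] = 1;
    split = best_split(X, order, in_node, grad, hess, g, h);
    for (int i : rows) in_node[i] = 0;
  }
  if (split.feature < 0 || split.gain <= 0.0) {
    nodes[idx].value = -eta * g / (h + kLambda);
    return idx;
  }
  importance[split.feature] += split.gain;

  std::vector<int> left_rows, right_rows;
  for (int i : rows) {
    if (X(i, split.feature) <= split.threshold) left_rows.push_back(i);
    else right_rows.push_back(i);
  }
  const int l = grow(X, order, in_node, left_rows, grad, hess, depth + 1,
                     max_depth, eta, nodes, importance);
  const int r = grow(X, order, in_node, right_rows, grad, hess, depth + 1,
                     max_depth, eta, nodes, importance);
  nodes[idx].feature = split.feature;
  nodes[idx].threshold = split.threshold;
  nodes[idx].left = l;
  nodes[idx].right = r;
  return idx;
}

inline double tree_value(const std::vector<Node>& nodes,
                         const NumericMatrix& X, int row) {
  int idx = 0;
  while (nodes[idx].feature >= 0) {
    idx = (X(row, nodes[idx].feature) <= nodes[idx].threshold)
              ? nodes[idx].left
              : nodes[idx].right;
  }
  return nodes[idx].value;
}

NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix m(static_cast<int>(nodes.size()), 5);
  for (size_t k = 0; k < nodes.size(); ++k) {
    m(k, 0) = nodes[k].feature;
    m(k, 1) = nodes[k].threshold;
    m(k, 2) = nodes[k].left;
    m(k, 3) = nodes[k].right;
    m(k, 4) = nodes[k].value;
  }
  return m;
}

std::vector<Node> unpack_tree(const NumericMatrix& m) {
  std::vector<Node> nodes(m.nrow());
  for (int k = 0; k < m.nrow(); ++k) {
    nodes[k].feature = static_cast<int>(m(k, 0));
    nodes[k].threshold = m(k, 1);
    nodes[k].left = static_cast<int>(m(k, 2));
    nodes[k].right = static_cast<int>(m(k, 3));
    nodes[k].value = m(k, 4);
  }
  return nodes;
}

}  // namespace

// [[Rcpp::export(name = ".gbm_train_cpp")]]
List gbm_train_cpp(NumericMatrix X, NumericVector y, int nrounds,
                   double eta, int max_depth, double subsample, int seed,
                   Nullable<NumericMatrix> Xval = R_NilValue,
                   Nullable<NumericVector> yval = R_NilValue) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("label length must match rows");

  // presort rows by every feature once
  std::vector<std::vector<int>> order(p);
  for (int j = 0; j < p; ++j) {
    order[j].resize(n);
    for (int i = 0; i < n; ++i) order[j][i] = i;
    const int jc = j;
    std::stable_sort(order[j].begin(), order[j].end(),
                     [&X, jc](int a, int b) { return X(a, jc) < X(b, jc); });
  }

  const bool has_val = Xval.isNotNull() && yval.isNotNull();
  NumericMatrix Xv;
  NumericVector yv;
  int nv = 0;
  if (has_val) {
    Xv = NumericMatrix(Xval);
    yv = NumericVector(yval);
    nv = Xv.nrow();
  }

  std::vector<double> margin(n, 0.0), grad(n), hess(n);
  std::vector<double> val_margin(nv, 0.0);
  NumericVector val_logloss(has_val ? nrounds : 0);
  std::vector<double> importance(p, 0.0);
  std::vector<char> in_node(n, 0);
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<int> all_rows(n), pool(n);
  for (int i = 0; i < n; ++i) all_rows[i] = i;

  List trees(nrounds);
  const int n_sub = std::max(2, static_cast<int>(std::lround(subsample * n)));

  for (int t = 0; t < nrounds; ++t) {
    for (int i = 0; i < n; ++i) {
      const double pr = sigmoid(margin[i]);
      grad[i] = pr - y[i];
      hess[i] = std::max(pr * (1.0 - pr), 1e-16);
    }
    std::vector<int> rows;
    if (subsample < 1.0) {
      pool = all_rows;
      std::shuffle(pool.begin(), pool.end(), rng);
      rows.assign(pool.begin(), pool.begin() + std::min(n_sub, n));
      std::sort(rows.begin(), rows.end());
    } else {
      rows = all_rows;
    }

    std::vector<Node> nodes;
    grow(X, order, in_node, rows, grad, hess, 0, max_depth, eta, nodes,
         importance);
    trees[t] = pack_tree(nodes);

    for (int i = 0; i < n; ++i) margin[i] += tree_value(nodes, X, i);
    if (has_val) {
      double ll = 0.0;
      for (int i = 0; i < nv; ++i) {
        val_margin[i] += tree_value(nodes, Xv, i);
        const double pr =
            std::min(1.0 - 1e-15, std::max(1e-15, sigmoid(val_margin[i])));
        ll += yv[i] > 0.5 ? -std::log(pr) : -std::log(1.0 - pr);
      }
      val_logloss[t] = ll / std::max(1, nv);
    }
  }

  NumericVector pred(n);
  for (int i = 0; i < n; ++i) pred[i] = sigmoid(margin[i]);
  return List::create(
      Named("trees") = trees, Named("importance") = wrap(importance),
      Named("train_pred") = pred,
      Named("val_logloss") = has_val ? val_logloss : NumericVector(0));
}

// [[Rcpp::export(name = ".gbm_predict_cpp")]]
NumericVector gbm_predict_cpp(List trees, NumericMatrix X, int nrounds) {
  const int n = X.nrow();
  const int use = (nrounds > 0 && nrounds < trees.size())
                      ? nrounds
                      : static_cast<int>(trees.size());
  NumericVector out(n);
  std::vector<double> margin(n, 0.0);
  for (int t = 0; t < use; ++t) {
    std::vector<Node> nodes = unpack_tree(trees[t]);
    for (int i = 0; i < n; ++i) margin[i] += tree_value(nodes, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] = sigmoid(margin[i]);
  return out;
}
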