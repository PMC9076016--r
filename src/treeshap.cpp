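// Tree-path Shapley attributions for random-forest regressors.
//
// Implements the polynomial-time path-dependent algorithm for exact
// Shapley values of a tree ensemble, where the value of a coalition is
// the expected tree output when the coalition's features are fixed to
// the instance and the rest follow cover-weighted paths. Covers are the
// per-node training-sample counts computed by forest_cover(); children
// covers sum exactly to their parent's, which makes the attributions
// satisfy additivity to floating precision:
//   sum_j phi_ij + base = f(x_i)  for every instance i.
//
// Trees are passed as numeric matrices with columns
//   0: left child (0-based, -1 for terminal)
//   1: right child
//   2: split feature (0-based, -1 for terminal)
//   3: split threshold (x <= threshold goes left)
//   4: terminal value
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct PathElement {
  int feature_index;
  double zero_fraction;  // fraction of paths flowing through when feature is unknown
  double one_fraction;   // 1 if the instance goes this way, else 0
  double pweight;
};

void extend_path(PathElement *unique_path, int unique_depth,
                 double zero_fraction, double one_fraction,
                 int feature_index) {
  unique_path[unique_depth].feature_index = feature_index;
  unique_path[unique_depth].zero_fraction = zero_fraction;
  unique_path[unique_depth].one_fraction = one_fraction;
  unique_path[unique_depth].pweight = (unique_depth == 0 ? 1.0 : 0.0);
  for (int i = unique_depth - 1; i >= 0; --i) {
    unique_path[i + 1].pweight += one_fraction * unique_path[i].pweight *
                                  (i + 1) / static_cast<double>(unique_depth + 1);
    unique_path[i].pweight = zero_fraction * unique_path[i].pweight *
                             (unique_depth - i) / static_cast<double>(unique_depth + 1);
  }
}

void unwind_path(PathElement *unique_path, int unique_depth, int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = unique_path[i].pweight;
      unique_path[i].pweight = next_one_portion * (unique_depth + 1) /
                               static_cast<double>((i + 1) * one_fraction);
      next_one_portion = tmp - unique_path[i].pweight * zero_fraction *
                         (unique_depth - i) / static_cast<double>(unique_depth + 1);
    } else {
      unique_path[i].pweight = (unique_path[i].pweight * (unique_depth + 1)) /
                               static_cast<double>(zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    unique_path[i].feature_index = unique_path[i + 1].feature_index;
    unique_path[i].zero_fraction = unique_path[i + 1].zero_fraction;
    unique_path[i].one_fraction = unique_path[i + 1].one_fraction;
  }
}

double unwound_path_sum(const PathElement *unique_path, int unique_depth,
                        int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  double total = 0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (unique_depth + 1) /
                         static_cast<double>((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = unique_path[i].pweight - tmp * zero_fraction *
                         (unique_depth - i) / static_cast<double>(unique_depth + 1);
    } else {
      total += (unique_path[i].pweight / zero_fraction) /
               ((unique_depth - i) / static_cast<double>(unique_depth + 1));
    }
  }
  return total;
}

struct TreeView {
  const double *left, *right, *feature, *threshold, *value;
  const double *cover;
  int n_nodes;
};

void tree_shap_recursive(const TreeView &t, const double *x, double *phi,
                         int node, int unique_depth,
                         PathElement *parent_unique_path,
                         double parent_zero_fraction,
                         double parent_one_fraction,
                         int parent_feature_index) {
  PathElement *unique_path = parent_unique_path + unique_depth + 1;
  std::copy(parent_unique_path, parent_unique_path + unique_depth + 1,
            unique_path);
  extend_path(unique_path, unique_depth, parent_zero_fraction,
              parent_one_fraction, parent_feature_index);

  const int feat = static_cast<int>(t.feature[node]);
  if (feat < 0) {  // terminal
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(unique_path, unique_depth, i);
      const PathElement &el = unique_path[i];
      phi[el.feature_index] += w * (el.one_fraction - el.zero_fraction) *
                               t.value[node];
    }
    return;
  }

  const int left = static_cast<int>(t.left[node]);
  const int right = static_cast<int>(t.right[node]);
  const bool go_left = x[feat] <= t.threshold[node];
  const int hot = go_left ? left : right;
  const int cold = go_left ? right : left;
  const double w = t.cover[node];
  const double hot_zero_fraction = t.cover[hot] / w;
  const double cold_zero_fraction = t.cover[cold] / w;
  double incoming_zero_fraction = 1.0;
  double incoming_one_fraction = 1.0;

  // if this feature was split on upstream, undo that path element first
  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index)
    if (unique_path[path_index].feature_index == feat) break;
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = unique_path[path_index].zero_fraction;
    incoming_one_fraction = unique_path[path_index].one_fraction;
    unwind_path(unique_path, unique_depth, path_index);
    unique_depth -= 1;
  }

  tree_shap_recursive(t, x, phi, hot, unique_depth + 1, unique_path,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, feat);
  tree_shap_recursive(t, x, phi, cold, unique_depth + 1, unique_path,
                      cold_zero_fraction * incoming_zero_fraction, 0.0, feat);
}

TreeView make_view(const NumericMatrix &m, const NumericVector &cover) {
  TreeView t;
  t.n_nodes = m.nrow();
  t.left = &m(0, 0);
  t.right = &m(0, 1);
  t.feature = &m(0, 2);
  t.threshold = &m(0, 3);
  t.value = &m(0, 4);
  t.cover = cover.begin();
  return t;
}

int tree_depth(const NumericMatrix &m, int node) {
  const int feat = static_cast<int>(m(node, 2));
  if (feat < 0) return 1;
  return 1 + std::max(tree_depth(m, static_cast<int>(m(node, 0))),
                      tree_depth(m, static_cast<int>(m(node, 1))));
}

int descend(const NumericMatrix &m, const double *x) {
  int node = 0;
  while (static_cast<int>(m(node, 2)) >= 0) {
    const int feat = static_cast<int>(m(node, 2));
    node = (x[feat] <= m(node, 3)) ? static_cast<int>(m(node, 0))
                                   : static_cast<int>(m(node, 1));
  }
  return node;
}

}  // namespace

// [[Rcpp::export(name = ".forest_cover")]]
List forest_cover(List trees, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  List out(trees.size());
  std::vector<double> row(p);
  for (int ti = 0; ti < trees.size(); ++ti) {
    NumericMatrix m = trees[ti];
    NumericVector cover(m.nrow());
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < p; ++j) row[j] = X(i, j);
      int node = 0;
      cover[node] += 1;
      while (static_cast<int>(m(node, 2)) >= 0) {
        const int feat = static_cast<int>(m(node, 2));
        node = (row[feat] <= m(node, 3)) ? static_cast<int>(m(node, 0))
                                         : static_cast<int>(m(node, 1));
        cover[node] += 1;
      }
    }
    out[ti] = cover;
  }
  return out;
}

// [[Rcpp::export(name = ".forest_predict")]]
NumericVector forest_predict(List trees, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector pred(n);
  std::vector<double> row(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) row[j] = X(i, j);
    double acc = 0;
    for (int ti = 0; ti < trees.size(); ++ti) {
      NumericMatrix m = trees[ti];
      acc += m(descend(m, row.data()), 4);
    }
    pred[i] = acc / trees.size();
  }
  return pred;
}

// [[Rcpp::export(name = ".forest_shap")]]
List forest_shap(List trees, List covers, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  const int n_trees = trees.size();
  NumericMatrix phi(n, p);
  double base = 0;

  // per-tree base value: cover-weighted mean of the leaves
  for (int ti = 0; ti < n_trees; ++ti) {
    NumericMatrix m = trees[ti];
    NumericVector cover = covers[ti];
    double b = 0, tot = cover[0];
    for (int v = 0; v < m.nrow(); ++v)
      if (static_cast<int>(m(v, 2)) < 0) b += cover[v] * m(v, 4);
    base += b / tot;
  }
  base /= n_trees;

  std::vector<double> row(p);
  for (int ti = 0; ti < n_trees; ++ti) {
    NumericMatrix m = trees[ti];
    NumericVector cover = covers[ti];
    TreeView t = make_view(m, cover);
    const int depth = tree_depth(m, 0);
    std::vector<PathElement> path((depth + 2) * (depth + 3) / 2);
    std::vector<double> phi_row(p);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < p; ++j) row[j] = X(i, j);
      std::fill(phi_row.begin(), phi_row.end(), 0.0);
      tree_shap_recursive(t, row.data(), phi_row.data(), 0, 0, path.data(),
                          1.0, 1.0, -1);
      for (int j = 0; j < p; ++j) phi(i, j) += phi_row[j];
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) phi(i, j) /= n_trees;
  return List::create(Named("phi") = phi, Named("base") = base);
}
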