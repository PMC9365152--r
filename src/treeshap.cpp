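// Exact tree-path-dependent SHAP attributions for ranger regression forests.
// Node covers are obtained by passing a reference matrix (the training
// windows) down each tree, so parent covers equal the sum of child covers
// and the local-accuracy identity holds exactly per tree.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(PathElement *unique_path, int unique_depth,
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

static void unwind_path(PathElement *unique_path, int unique_depth,
                        int path_index) {
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

static double unwound_path_sum(const PathElement *unique_path,
                               int unique_depth, int path_index) {
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
        ((unique_depth - i) / static_cast<double>(unique_depth + 1));
    } else {
      total += (unique_path[i].pweight / zero_fraction) /
        ((unique_depth - i) / static_cast<double>(unique_depth + 1));
    }
  }
  return total;
}

struct TreeArrays {
  const int *left;
  const int *right;
  const int *feat;   // -1 for leaf
  const double *thresh;
  const double *value;  // leaf prediction
  const double *cover;
};

static void tree_shap_recursive(const TreeArrays &tree, const double *x,
                                double *phi, int node_index, int unique_depth,
                                PathElement *parent_unique_path,
                                double parent_zero_fraction,
                                double parent_one_fraction,
                                int parent_feature_index) {
  PathElement *unique_path = parent_unique_path + unique_depth + 1;
  std::copy(parent_unique_path, parent_unique_path + unique_depth + 1,
            unique_path);
  extend_path(unique_path, unique_depth, parent_zero_fraction,
              parent_one_fraction, parent_feature_index);

  const int split_feature = tree.feat[node_index];
  if (split_feature < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(unique_path, unique_depth, i);
      const PathElement &el = unique_path[i];
      phi[el.feature_index] +=
        w * (el.one_fraction - el.zero_fraction) * tree.value[node_index];
    }
    return;
  }

  const int left = tree.left[node_index];
  const int right = tree.right[node_index];
  const int hot = (x[split_feature] <= tree.thresh[node_index]) ? left : right;
  const int cold = (hot == left) ? right : left;
  const double w_node = tree.cover[node_index];
  const double hot_zero_fraction = tree.cover[hot] / w_node;
  const double cold_zero_fraction = tree.cover[cold] / w_node;
  double incoming_zero_fraction = 1;
  double incoming_one_fraction = 1;

  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index) {
    if (unique_path[path_index].feature_index == split_feature) break;
  }
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = unique_path[path_index].zero_fraction;
    incoming_one_fraction = unique_path[path_index].one_fraction;
    unwind_path(unique_path, unique_depth, path_index);
    unique_depth -= 1;
  }

  tree_shap_recursive(tree, x, phi, hot, unique_depth + 1, unique_path,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, split_feature);
  tree_shap_recursive(tree, x, phi, cold, unique_depth + 1, unique_path,
                      cold_zero_fraction * incoming_zero_fraction, 0,
                      split_feature);
}

static int tree_max_depth(const IntegerVector &left, const IntegerVector &right,
                          int node, int depth) {
  if (left[node] < 0) return depth;
  return std::max(tree_max_depth(left, right, left[node], depth + 1),
                  tree_max_depth(left, right, right[node], depth + 1));
}

// [[Rcpp::export(name = ".treeshap_forest")]]
List treeshap_forest(List trees, NumericMatrix X, NumericMatrix X_explain) {
  const int n_ref = X.nrow();
  const int n = X_explain.nrow();
  const int p = X_explain.ncol();
  const int n_trees = trees.size();
  NumericMatrix phi(n, p);
  double base_value = 0;

  std::vector<double> xrow(p);
  for (int t = 0; t < n_trees; ++t) {
    List tr = trees[t];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    IntegerVector feat = tr["feature"];
    NumericVector thresh = tr["threshold"];
    NumericVector value = tr["value"];
    const int n_nodes = left.size();

    // covers from the reference matrix
    std::vector<double> cover(n_nodes, 0.0);
    for (int i = 0; i < n_ref; ++i) {
      int node = 0;
      cover[0] += 1;
      while (feat[node] >= 0) {
        node = (X(i, feat[node]) <= thresh[node]) ? left[node] : right[node];
        cover[node] += 1;
      }
    }
    for (int v = 0; v < n_nodes; ++v) {
      if (feat[v] >= 0 && (cover[left[v]] <= 0 || cover[right[v]] <= 0)) {
        stop("reference matrix leaves an internal node child empty");
      }
    }

    // base value: cover-weighted mean of leaf values
    double base_t = 0;
    for (int v = 0; v < n_nodes; ++v) {
      if (feat[v] < 0) base_t += cover[v] * value[v];
    }
    base_value += base_t / cover[0] / n_trees;

    TreeArrays ta;
    ta.left = INTEGER(left);
    ta.right = INTEGER(right);
    ta.feat = INTEGER(feat);
    ta.thresh = REAL(thresh);
    ta.value = REAL(value);
    ta.cover = cover.data();

    const int maxd = tree_max_depth(left, right, 0, 0);
    std::vector<PathElement> arena((maxd + 3) * (maxd + 4) / 2 + 2);
    std::vector<double> phi_row(p);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < p; ++j) xrow[j] = X_explain(i, j);
      std::fill(phi_row.begin(), phi_row.end(), 0.0);
      tree_shap_recursive(ta, xrow.data(), phi_row.data(), 0, 0, arena.data(),
                          1, 1, -1);
      for (int j = 0; j < p; ++j) phi(i, j) += phi_row[j] / n_trees;
    }
  }
  return List::create(Named("phi") = phi, Named("base_value") = base_value);
}

// Per-row single-tree prediction used for validating split-rule orientation.
// [[Rcpp::export(name = ".tree_predict")]]
NumericVector tree_predict(List tr, NumericMatrix X) {
  IntegerVector left = tr["left"];
  IntegerVector right = tr["right"];
  IntegerVector feat = tr["feature"];
  NumericVector thresh = tr["threshold"];
  NumericVector value = tr["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feat[node] >= 0) {
      node = (X(i, feat[node]) <= thresh[node]) ? left[node] : right[node];
    }
    out[i] = value[node];
  }
  return out;
}
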