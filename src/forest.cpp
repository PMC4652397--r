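#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Flattened-array CART forest for binary classification with class-balanced
// (or plain) bootstrap sampling and pooled out-of-bag voting.
//
// Covariate matrix X is numeric; categorical columns hold integer level
// codes 1..K (K <= 52 so a level subset fits exactly in a double bitmask).
// Class codes: 0 = low, 1 = high. All randomness comes from R's RNG stream
// (unif_rand), so results are reproducible under set.seed().

namespace {

inline bool mask_has_level(double mask, int lev) {
  return ((unsigned long long)mask >> lev) & 1ULL;
}

struct TreeBuilder {
  const NumericMatrix& X;
  const LogicalVector& is_cat;
  const IntegerVector& y;
  int mtry, min_leaf;
  // flattened node arrays (appended across trees by the caller)
  std::vector<int>& feature;      // -1 for leaf
  std::vector<double>& value;     // threshold (continuous) or level bitmask (categorical)
  std::vector<int>& left;
  std::vector<int>& right;
  std::vector<int>& pred;         // leaf class, -1 for internal
  std::vector<int> feat_pool;

  TreeBuilder(const NumericMatrix& X_, const LogicalVector& cat_,
              const IntegerVector& y_, int mtry_, int min_leaf_,
              std::vector<int>& f, std::vector<double>& v,
              std::vector<int>& l, std::vector<int>& r, std::vector<int>& p)
      : X(X_), is_cat(cat_), y(y_), mtry(mtry_), min_leaf(min_leaf_),
        feature(f), value(v), left(l), right(r), pred(p) {
    feat_pool.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) feat_pool[j] = j;
  }

  int new_node() {
    feature.push_back(-1);
    value.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    pred.push_back(-1);
    return (int)feature.size() - 1;
  }

  static double gini_impurity(double n0, double n1) {
    double n = n0 + n1;
    if (n <= 0.0) return 0.0;
    double p1 = n1 / n;
    return 2.0 * p1 * (1.0 - p1);
  }

  // Recursively grow; idx holds in-bag sample row indices for this node.
  int grow(std::vector<int>& idx) {
    int node = new_node();
    int n = (int)idx.size();
    int n1 = 0;
    for (int i : idx) n1 += y[i];
    int n0 = n - n1;

    if (n0 == 0 || n1 == 0 || n < 2 * min_leaf || n < 2) {
      pred[node] = (n1 >= n0) ? 1 : 0;  // tie -> high
      return node;
    }

    // sample mtry candidate features without replacement (partial Fisher-Yates)
    int d = (int)feat_pool.size();
    int m = std::min(mtry, d);
    for (int k = 0; k < m; ++k) {
      int j = k + (int)(unif_rand() * (d - k));
      if (j >= d) j = d - 1;
      std::swap(feat_pool[k], feat_pool[j]);
    }

    double parent_gini = gini_impurity(n0, n1);
    double best_dec = 0.0;
    int best_feat = -1;
    bool best_is_cat = false;
    double best_val = 0.0;

    std::vector<std::pair<double, int> > vals;  // (covariate value, class)
    vals.reserve(n);

    for (int k = 0; k < m; ++k) {
      int f = feat_pool[k];
      if (is_cat[f]) {
        // per-level class counts; order levels by class-1 proportion
        // (optimal ordering for binary Gini), then scan prefix splits
        double c0[64] = {0}, c1[64] = {0};
        int maxlev = 0;
        for (int i : idx) {
          int lev = (int)X(i, f);
          if (lev > maxlev) maxlev = lev;
          if (y[i]) c1[lev] += 1; else c0[lev] += 1;
        }
        std::vector<std::pair<double, int> > levs;
        for (int lev = 1; lev <= maxlev; ++lev) {
          double tot = c0[lev] + c1[lev];
          if (tot > 0) levs.push_back(std::make_pair(c1[lev] / tot, lev));
        }
        if (levs.size() < 2) continue;
        std::sort(levs.begin(), levs.end());
        double l0 = 0, l1 = 0;
        double mask = 0.0;
        for (size_t s = 0; s + 1 < levs.size(); ++s) {
          int lev = levs[s].second;
          l0 += c0[lev];
          l1 += c1[lev];
          mask += (double)(1ULL << lev);  // set bit `lev`
          double nl = l0 + l1, nr = n - nl;
          if (nl < min_leaf || nr < min_leaf) continue;
          double dec = parent_gini -
                       (nl / n) * gini_impurity(l0, l1) -
                       (nr / n) * gini_impurity(n0 - l0, n1 - l1);
          if (dec > best_dec + 1e-12) {
            best_dec = dec;
            best_feat = f;
            best_is_cat = true;
            best_val = mask;
          }
        }
      } else {
        vals.clear();
        for (int i : idx) vals.push_back(std::make_pair(X(i, f), y[i]));
        std::sort(vals.begin(), vals.end());
        double l0 = 0, l1 = 0;
        for (int s = 0; s + 1 < n; ++s) {
          if (vals[s].second) l1 += 1; else l0 += 1;
          if (vals[s].first == vals[s + 1].first) continue;
          double nl = s + 1.0, nr = n - nl;
          if (nl < min_leaf || nr < min_leaf) continue;
          double dec = parent_gini -
                       (nl / n) * gini_impurity(l0, l1) -
                       (nr / n) * gini_impurity(n0 - l0, n1 - l1);
          if (dec > best_dec + 1e-12) {
            best_dec = dec;
            best_feat = f;
            best_is_cat = false;
            best_val = 0.5 * (vals[s].first + vals[s + 1].first);
          }
        }
      }
    }

    if (best_feat < 0) {
      pred[node] = (n1 >= n0) ? 1 : 0;
      return node;
    }

    std::vector<int> lidx, ridx;
    for (int i : idx) {
      bool go_left;
      if (best_is_cat) {
        go_left = mask_has_level(best_val, (int)X(i, best_feat));
      } else {
        go_left = X(i, best_feat) <= best_val;
      }
      if (go_left) lidx.push_back(i); else ridx.push_back(i);
    }
    if (lidx.empty() || ridx.empty()) {  // numerically degenerate split
      pred[node] = (n1 >= n0) ? 1 : 0;
      return node;
    }

    feature[node] = best_feat;
    value[node] = best_val;
    std::vector<int>().swap(idx);  // free before recursing
    int l = grow(lidx);
    int r = grow(ridx);
    left[node] = l;
    right[node] = r;
    return node;
  }
};

inline int drop_down(const std::vector<int>& feature, const std::vector<double>& value,
                     const std::vector<int>& left, const std::vector<int>& right,
                     const std::vector<int>& pred, const LogicalVector& is_cat,
                     int root, const NumericMatrix& X, int row) {
  int node = root;
  while (feature[node] >= 0) {
    int f = feature[node];
    bool go_left;
    if (is_cat[f]) {
      go_left = mask_has_level(value[node], (int)X(row, f));
    } else {
      go_left = X(row, f) <= value[node];
    }
    node = go_left ? left[node] : right[node];
  }
  return pred[node];
}

inline int draw_from(const std::vector<int>& pool) {
  int j = (int)(unif_rand() * pool.size());
  if (j >= (int)pool.size()) j = (int)pool.size() - 1;
  return pool[j];
}

}  // namespace

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, LogicalVector is_cat, IntegerVector y,
                     int n_trees, int mtry, int min_leaf, bool balanced) {
  int n = X.nrow();
  std::vector<int> cls0, cls1;
  for (int i = 0; i < n; ++i) (y[i] ? cls1 : cls0).push_back(i);
  if (cls0.empty() || cls1.empty())
    stop("both classes must be present in the training data");

  int n_min = (int)std::min(cls0.size(), cls1.size());

  std::vector<int> feature, left, right, pred, tree_start;
  std::vector<double> value;
  IntegerMatrix oob_votes(n, 2);
  IntegerMatrix inbag_counts(n_trees, 2);
  std::vector<char> inbag(n);

  RNGScope rng;
  TreeBuilder tb(X, is_cat, y, mtry, min_leaf, feature, value, left, right, pred);

  for (int t = 0; t < n_trees; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    std::vector<int> idx;
    if (balanced) {
      idx.reserve(2 * n_min);
      for (int k = 0; k < n_min; ++k) idx.push_back(draw_from(cls0));
      for (int k = 0; k < n_min; ++k) idx.push_back(draw_from(cls1));
    } else {
      idx.reserve(n);
      std::vector<int> all(n);
      for (int i = 0; i < n; ++i) all[i] = i;
      for (int k = 0; k < n; ++k) idx.push_back(draw_from(all));
    }
    int ib1 = 0;
    for (int i : idx) {
      inbag[i] = 1;
      ib1 += y[i];
    }
    inbag_counts(t, 0) = (int)idx.size() - ib1;
    inbag_counts(t, 1) = ib1;

    tree_start.push_back((int)feature.size());
    int root = tb.grow(idx);

    for (int i = 0; i < n; ++i) {
      if (!inbag[i]) {
        int c = drop_down(feature, value, left, right, pred, is_cat, root, X, i);
        oob_votes(i, c) += 1;
      }
    }
  }

  return List::create(
      _["feature"] = wrap(feature), _["value"] = wrap(value),
      _["left"] = wrap(left), _["right"] = wrap(right),
      _["pred"] = wrap(pred), _["tree_start"] = wrap(tree_start),
      _["oob_votes"] = oob_votes, _["inbag_counts"] = inbag_counts);
}

// [[Rcpp::export]]
IntegerMatrix cpp_predict_forest(IntegerVector feature, NumericVector value,
                                 IntegerVector left, IntegerVector right,
                                 IntegerVector pred, IntegerVector tree_start,
                                 NumericMatrix X, LogicalVector is_cat) {
  int n = X.nrow(), T = tree_start.size();
  std::vector<int> f(feature.begin(), feature.end());
  std::vector<double> v(value.begin(), value.end());
  std::vector<int> l(left.begin(), left.end());
  std::vector<int> r(right.begin(), right.end());
  std::vector<int> p(pred.begin(), pred.end());
  IntegerMatrix votes(n, 2);
  for (int t = 0; t < T; ++t) {
    int root = tree_start[t];
    for (int i = 0; i < n; ++i) {
      int c = drop_down(f, v, l, r, p, is_cat, root, X, i);
      votes(i, c) += 1;
    }
  }
  return votes;
}
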