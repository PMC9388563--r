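// CART-style tree learner shared by the three tree-ensemble classifier
// families (extremely randomised trees, gradient boosting, AdaBoost).
// Trees are stored flat: feature[i] == -1 marks a leaf with prediction
// value[i]; internal nodes send x[feature] <= threshold to left[i].
#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct FlatTree {
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;

  int new_node() {
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(0.0);
    return (int)feature.size() - 1;
  }
};

struct SplitParams {
  int max_depth;       // 0 = unlimited
  int min_leaf;        // minimum samples per leaf
  int mtry;            // features considered per split
  bool random_splits;  // extra-trees: one uniform threshold per feature
  bool classification; // gini vs variance impurity
};

// weighted impurity of the samples in idx: gini for classification
// (y in {0,1}), variance for regression
double node_impurity(const std::vector<int>& idx, const NumericVector& y,
                     const NumericVector& w, bool classification,
                     double& wsum, double& mean_out) {
  double sw = 0.0, swy = 0.0;
  for (int i : idx) { sw += w[i]; swy += w[i] * y[i]; }
  wsum = sw;
  if (sw <= 0.0) { mean_out = 0.0; return 0.0; }
  double m = swy / sw;
  mean_out = m;
  if (classification) {
    return 2.0 * m * (1.0 - m); // gini for two classes
  }
  double ss = 0.0;
  for (int i : idx) ss += w[i] * (y[i] - m) * (y[i] - m);
  return ss / sw;
}

struct BestSplit {
  int feature = -1;
  double threshold = 0.0;
  double decrease = -1.0; // weighted impurity decrease, > 0 required
};

// impurity of a weighted (sw, swy[, sww-like]) aggregate; for regression we
// need sum w*y^2 too, so pass it in
double agg_impurity(double sw, double swy, double swy2, bool classification) {
  if (sw <= 0.0) return 0.0;
  double m = swy / sw;
  if (classification) return 2.0 * m * (1.0 - m);
  return swy2 / sw - m * m;
}

void consider_threshold(const NumericMatrix& X, const NumericVector& y,
                        const NumericVector& w, const std::vector<int>& idx,
                        int f, double thr, double parent_imp, double parent_w,
                        int min_leaf, bool classification, BestSplit& best) {
  double swl = 0, swyl = 0, swy2l = 0, swr = 0, swyr = 0, swy2r = 0;
  int nl = 0, nr = 0;
  for (int i : idx) {
    double yi = y[i], wi = w[i];
    if (X(i, f) <= thr) {
      swl += wi; swyl += wi * yi; swy2l += wi * yi * yi; ++nl;
    } else {
      swr += wi; swyr += wi * yi; swy2r += wi * yi * yi; ++nr;
    }
  }
  if (nl < min_leaf || nr < min_leaf) return;
  double impl = agg_impurity(swl, swyl, swy2l, classification);
  double impr = agg_impurity(swr, swyr, swy2r, classification);
  double child = (swl * impl + swr * impr) / parent_w;
  double dec = parent_w * (parent_imp - child);
  if (dec > best.decrease) {
    best.feature = f; best.threshold = thr; best.decrease = dec;
  }
}

// exhaustive best split on one feature via a sort + sweep
void best_split_exhaustive(const NumericMatrix& X, const NumericVector& y,
                           const NumericVector& w, const std::vector<int>& idx,
                           int f, double parent_imp, double parent_w,
                           int min_leaf, bool classification, BestSplit& best) {
  const int n = (int)idx.size();
  std::vector<int> ord(idx);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return X(a, f) < X(b, f); });
  double swl = 0, swyl = 0, swy2l = 0;
  double swT = 0, swyT = 0, swy2T = 0;
  for (int i : ord) {
    swT += w[i]; swyT += w[i] * y[i]; swy2T += w[i] * y[i] * y[i];
  }
  for (int k = 0; k < n - 1; ++k) {
    int i = ord[k];
    swl += w[i]; swyl += w[i] * y[i]; swy2l += w[i] * y[i] * y[i];
    double xk = X(i, f), xk1 = X(ord[k + 1], f);
    if (xk1 <= xk) continue; // tie, not a valid cut
    int nl = k + 1, nr = n - nl;
    if (nl < min_leaf || nr < min_leaf) continue;
    double swr = swT - swl, swyr = swyT - swyl, swy2r = swy2T - swy2l;
    double impl = agg_impurity(swl, swyl, swy2l, classification);
    double impr = agg_impurity(swr, swyr, swy2r, classification);
    double child = (swl * impl + swr * impr) / parent_w;
    double dec = parent_w * (parent_imp - child);
    if (dec > best.decrease) {
      best.feature = f;
      best.threshold = 0.5 * (xk + xk1);
      best.decrease = dec;
    }
  }
}

void grow(const NumericMatrix& X, const NumericVector& y,
          const NumericVector& w, std::vector<int>& idx, int depth,
          const SplitParams& par, std::mt19937& rng, FlatTree& tree, int node,
          std::vector<double>& importance, double total_w) {
  double wsum, mean;
  double imp = node_impurity(idx, y, w, par.classification, wsum, mean);
  tree.value[node] = mean;
  const int n = (int)idx.size(), p = X.ncol();
  bool stop = (par.max_depth > 0 && depth >= par.max_depth) ||
              n < 2 * par.min_leaf || imp <= 1e-12 || wsum <= 0.0;
  if (stop) return;

  // sample mtry distinct features (partial Fisher-Yates)
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int k = std::min(par.mtry, p);
  for (int j = 0; j < k; ++j) {
    std::uniform_int_distribution<int> U(j, p - 1);
    std::swap(feats[j], feats[U(rng)]);
  }

  BestSplit best;
  for (int j = 0; j < k; ++j) {
    int f = feats[j];
    if (par.random_splits) {
      double lo = R_PosInf, hi = R_NegInf;
      for (int i : idx) {
        double v = X(i, f);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      if (!(hi > lo)) continue;
      std::uniform_real_distribution<double> U(lo, hi);
      consider_threshold(X, y, w, idx, f, U(rng), imp, wsum, par.min_leaf,
                         par.classification, best);
    } else {
      best_split_exhaustive(X, y, w, idx, f, imp, wsum, par.min_leaf,
                            par.classification, best);
    }
  }
  if (best.feature < 0 || best.decrease <= 1e-12) return;

  importance[best.feature] += best.decrease / total_w;
  std::vector<int> lidx, ridx;
  for (int i : idx) {
    if (X(i, best.feature) <= best.threshold) lidx.push_back(i);
    else ridx.push_back(i);
  }
  int L = tree.new_node(), R = tree.new_node();
  tree.feature[node] = best.feature;
  tree.threshold[node] = best.threshold;
  tree.left[node] = L;
  tree.right[node] = R;
  grow(X, y, w, lidx, depth + 1, par, rng, tree, L, importance, total_w);
  grow(X, y, w, ridx, depth + 1, par, rng, tree, R, importance, total_w);
}

FlatTree fit_tree(const NumericMatrix& X, const NumericVector& y,
                  const NumericVector& w, const std::vector<int>& idx0,
                  const SplitParams& par, std::mt19937& rng,
                  std::vector<double>& importance) {
  FlatTree tree;
  int root = tree.new_node();
  std::vector<int> idx(idx0);
  double total_w = 0.0;
  for (int i : idx) total_w += w[i];
  if (total_w <= 0.0) total_w = 1.0;
  grow(X, y, w, idx, 0, par, rng, tree, root, importance, total_w);
  return tree;
}

double tree_predict_one(const FlatTree& t, const NumericMatrix& X, int i) {
  int node = 0;
  while (t.feature[node] >= 0)
    node = (X(i, t.feature[node]) <= t.threshold[node]) ? t.left[node]
                                                        : t.right[node];
  return t.value[node];
}

int leaf_of(const FlatTree& t, const NumericMatrix& X, int i) {
  int node = 0;
  while (t.feature[node] >= 0)
    node = (X(i, t.feature[node]) <= t.threshold[node]) ? t.left[node]
                                                        : t.right[node];
  return node;
}

List tree_to_list(const FlatTree& t) {
  return List::create(_["feature"] = wrap(t.feature),
                      _["threshold"] = wrap(t.threshold),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["value"] = wrap(t.value));
}

FlatTree tree_from_list(const List& l) {
  FlatTree t;
  t.feature = as<std::vector<int>>(l["feature"]);
  t.threshold = as<std::vector<double>>(l["threshold"]);
  t.left = as<std::vector<int>>(l["left"]);
  t.right = as<std::vector<int>>(l["right"]);
  t.value = as<std::vector<double>>(l["value"]);
  return t;
}

NumericVector normalise(std::vector<double> v) {
  double s = 0.0;
  for (double x : v) s += x;
  NumericVector out(v.size());
  for (size_t j = 0; j < v.size(); ++j) out[j] = s > 0 ? v[j] / s : 0.0;
  return out;
}

} // namespace

// [[Rcpp::export(name = ".cpp_extra_trees")]]
List cpp_extra_trees(NumericMatrix X, NumericVector y, int n_trees,
                     int max_depth, int min_leaf, int mtry, int seed) {
  const int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed);
  NumericVector w(n, 1.0);
  SplitParams par{max_depth, min_leaf, mtry, true, true};
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<double> imp(p, 0.0);
  List trees(n_trees);
  for (int m = 0; m < n_trees; ++m) {
    FlatTree t = fit_tree(X, y, w, idx, par, rng, imp);
    trees[m] = tree_to_list(t);
  }
  for (double& v : imp) v /= n_trees;
  return List::create(_["trees"] = trees, _["importance"] = normalise(imp));
}

// [[Rcpp::export(name = ".cpp_forest_predict")]]
NumericVector cpp_forest_predict(List trees, NumericMatrix X) {
  const int n = X.nrow(), M = trees.size();
  NumericVector out(n, 0.0);
  for (int m = 0; m < M; ++m) {
    FlatTree t = tree_from_list(trees[m]);
    for (int i = 0; i < n; ++i) out[i] += tree_predict_one(t, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= M;
  return out;
}

// Binomial-deviance gradient boosting with Newton leaf updates
// [[Rcpp::export(name = ".cpp_gbm")]]
List cpp_gbm(NumericMatrix X, NumericVector y, int n_trees, int max_depth,
             double learning_rate, int min_leaf, int seed) {
  const int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
  double F0 = std::log(ybar / (1.0 - ybar));
  std::vector<double> F(n, F0);
  NumericVector w(n, 1.0);
  SplitParams par{max_depth, min_leaf, p, false, false};
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<double> imp(p, 0.0);
  List trees(n_trees);
  NumericVector resid(n);
  for (int m = 0; m < n_trees; ++m) {
    std::vector<double> prob(n);
    for (int i = 0; i < n; ++i) {
      prob[i] = 1.0 / (1.0 + std::exp(-F[i]));
      resid[i] = y[i] - prob[i];
    }
    FlatTree t = fit_tree(X, resid, w, idx, par, rng, imp);
    // Newton step per leaf: gamma = sum(resid) / sum(p(1-p))
    std::vector<double> num(t.value.size(), 0.0), den(t.value.size(), 0.0);
    for (int i = 0; i < n; ++i) {
      int lf = leaf_of(t, X, i);
      num[lf] += resid[i];
      den[lf] += prob[i] * (1.0 - prob[i]);
    }
    for (size_t nd = 0; nd < t.value.size(); ++nd)
      if (t.feature[nd] < 0)
        t.value[nd] = den[nd] > 1e-10 ? num[nd] / den[nd] : 0.0;
    for (int i = 0; i < n; ++i)
      F[i] += learning_rate * tree_predict_one(t, X, i);
    trees[m] = tree_to_list(t);
  }
  return List::create(_["trees"] = trees, _["F0"] = F0,
                      _["learning_rate"] = learning_rate,
                      _["importance"] = normalise(imp));
}

// [[Rcpp::export(name = ".cpp_gbm_predict")]]
NumericVector cpp_gbm_predict(List model, NumericMatrix X) {
  List trees = model["trees"];
  double F0 = model["F0"], lr = model["learning_rate"];
  const int n = X.nrow(), M = trees.size();
  NumericVector out(n, F0);
  for (int m = 0; m < M; ++m) {
    FlatTree t = tree_from_list(trees[m]);
    for (int i = 0; i < n; ++i) out[i] += lr * tree_predict_one(t, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-out[i]));
  return out;
}

// Discrete AdaBoost (SAMME) on weighted exhaustive trees
// [[Rcpp::export(name = ".cpp_adaboost")]]
List cpp_adaboost(NumericMatrix X, NumericVector y, int n_trees, int max_depth,
                  double learning_rate, int min_leaf, int seed) {
  const int n = X.nrow(), p = X.ncol();
  std::mt19937 rng((unsigned)seed);
  NumericVector w(n, 1.0 / n);
  SplitParams par{max_depth, min_leaf, p, false, true};
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<double> imp_total(p, 0.0);
  std::vector<double> alphas;
  List trees(n_trees);
  int m_used = 0;
  for (int m = 0; m < n_trees; ++m) {
    std::vector<double> imp_m(p, 0.0);
    FlatTree t = fit_tree(X, y, w, idx, par, rng, imp_m);
    double err = 0.0, wsum = 0.0;
    std::vector<int> miss(n);
    for (int i = 0; i < n; ++i) {
      int pred = tree_predict_one(t, X, i) > 0.5 ? 1 : 0;
      miss[i] = (pred != (int)y[i]);
      if (miss[i]) err += w[i];
      wsum += w[i];
    }
    err /= wsum;
    if (err <= 1e-10) { // perfect learner dominates
      trees[m] = tree_to_list(t);
      alphas.push_back(learning_rate * std::log(1e10));
      double s = 0; for (double v : imp_m) s += v;
      if (s > 0) for (int j = 0; j < p; ++j)
        imp_total[j] += alphas.back() * imp_m[j] / s;
      ++m_used;
      break;
    }
    if (err >= 0.5) break; // no better than chance: stop
    double alpha = learning_rate * std::log((1.0 - err) / err);
    trees[m] = tree_to_list(t);
    alphas.push_back(alpha);
    double s = 0; for (double v : imp_m) s += v;
    if (s > 0) for (int j = 0; j < p; ++j) imp_total[j] += alpha * imp_m[j] / s;
    ++m_used;
    double wnew = 0.0;
    for (int i = 0; i < n; ++i) {
      if (miss[i]) w[i] *= std::exp(alpha);
      wnew += w[i];
    }
    for (int i = 0; i < n; ++i) w[i] /= wnew;
  }
  List used(m_used);
  for (int m = 0; m < m_used; ++m) used[m] = trees[m];
  return List::create(_["trees"] = used, _["alpha"] = wrap(alphas),
                      _["importance"] = normalise(imp_total));
}

// [[Rcpp::export(name = ".cpp_adaboost_predict")]]
NumericVector cpp_adaboost_predict(List model, NumericMatrix X) {
  List trees = model["trees"];
  NumericVector alpha = model["alpha"];
  const int n = X.nrow(), M = trees.size();
  NumericVector f(n, 0.0);
  double asum = 0.0;
  for (int m = 0; m < M; ++m) {
    FlatTree t = tree_from_list(trees[m]);
    double a = alpha[m];
    asum += a;
    for (int i = 0; i < n; ++i) {
      int pred = tree_predict_one(t, X, i) > 0.5 ? 1 : 0;
      f[i] += a * (2 * pred - 1);
    }
  }
  // normalised margin mapped to [0, 1]; monotone in the decision function
  for (int i = 0; i < n; ++i)
    f[i] = asum > 0 ? 0.5 * (f[i] / asum + 1.0) : 0.5;
  return f;
}

// Brute-force O(n*m) nearest-neighbour distances, the oracle route for the
// accelerated spatial metrics
// [[Rcpp::export(name = ".cpp_min_dist")]]
NumericVector cpp_min_dist(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  NumericVector out(n, R_PosInf);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double dx = a(i, 0) - b(j, 0), dy = a(i, 1) - b(j, 1);
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
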