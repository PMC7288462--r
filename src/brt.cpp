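// Core of the boosted-regression-trees learner: depth-limited least-squares
// regression trees fitted to loss gradients, with bagging, categorical
// splits by the ordered-mean heuristic, and staged prediction/deviance for
// cross-validated tree selection.  Uses R's RNG so results are reproducible
// under set.seed().
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// node layout (complete binary tree, nodes_per_tree = 2^(depth+1)-1):
// col 0 var   (-1 leaf, else 0-based feature)
// col 1 split (numeric threshold; go left if x < split)
// col 2 mask  (categorical: bit l set => level l goes left)
// col 3 value (leaf prediction, shrinkage already applied)
// col 4 improve (SSE reduction of the split)
// col 5 is_cat

static const int NCOL = 6;

static inline bool mask_bit(double mask, int level) {
  return ((unsigned long long)mask >> level) & 1ULL;
}

struct SplitResult {
  int var = -1;
  double split = 0.0, mask = 0.0, gain = 0.0;
  bool is_cat = false;
  bool found = false;
};

static SplitResult best_split(const NumericMatrix& X, const IntegerVector& is_cat,
                              const std::vector<double>& r,
                              const std::vector<int>& rows, int min_node) {
  SplitResult best;
  int n = rows.size();
  double sum = 0.0;
  for (int i : rows) sum += r[i];
  double base = sum * sum / n;
  int p = X.ncol();
  std::vector<std::pair<double,double>> v;  // (x, resid)
  for (int j = 0; j < p; ++j) {
    if (!is_cat[j]) {
      v.clear(); v.reserve(n);
      for (int i : rows) v.push_back(std::make_pair(X(i, j), r[i]));
      std::sort(v.begin(), v.end());
      double sl = 0.0; int nl = 0;
      for (int k = 0; k < n - 1; ++k) {
        sl += v[k].second; ++nl;
        if (v[k].first == v[k + 1].first) continue;
        int nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        double sr = sum - sl;
        double gain = sl * sl / nl + sr * sr / nr - base;
        if (gain > best.gain + 1e-12) {
          best.gain = gain; best.var = j; best.is_cat = false;
          best.split = 0.5 * (v[k].first + v[k + 1].first);
          best.found = true;
        }
      }
    } else {
      // level means, ordered-mean scan
      int L = 0;
      for (int i : rows) L = std::max(L, (int)X(i, j) + 1);
      if (L < 2 || L > 32) continue;
      std::vector<double> s(L, 0.0); std::vector<int> cnt(L, 0);
      for (int i : rows) { int l = (int)X(i, j); s[l] += r[i]; cnt[l]++; }
      std::vector<int> lev;
      for (int l = 0; l < L; ++l) if (cnt[l] > 0) lev.push_back(l);
      if ((int)lev.size() < 2) continue;
      std::sort(lev.begin(), lev.end(), [&](int a, int b) {
        return s[a] / cnt[a] < s[b] / cnt[b];
      });
      double sl = 0.0; int nl = 0; double mask = 0.0;
      for (size_t k = 0; k + 1 < lev.size(); ++k) {
        sl += s[lev[k]]; nl += cnt[lev[k]];
        mask += (double)(1ULL << lev[k]);
        int nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        double sr = sum - sl;
        double gain = sl * sl / nl + sr * sr / nr - base;
        if (gain > best.gain + 1e-12) {
          best.gain = gain; best.var = j; best.is_cat = true;
          best.mask = mask; best.found = true;
        }
      }
    }
  }
  return best;
}

static void fit_node(NumericMatrix& nodes, int tree_row0, int node,
                     const NumericMatrix& X, const IntegerVector& is_cat,
                     const std::vector<double>& r,
                     const std::vector<int>& rows,
                     int depth_left, int min_node, double lr,
                     int nodes_per_tree) {
  int row = tree_row0 + node;
  double sum = 0.0;
  for (int i : rows) sum += r[i];
  double mean = rows.empty() ? 0.0 : sum / rows.size();
  // default: leaf
  nodes(row, 0) = -1; nodes(row, 3) = lr * mean;
  if (depth_left <= 0 || (int)rows.size() < 2 * min_node) return;
  SplitResult sp = best_split(X, is_cat, r, rows, min_node);
  if (!sp.found || sp.gain <= 0) return;
  std::vector<int> left, right;
  for (int i : rows) {
    bool go_left;
    if (sp.is_cat) {
      go_left = mask_bit(sp.mask, (int)X(i, sp.var));
    } else {
      go_left = X(i, sp.var) < sp.split;
    }
    (go_left ? left : right).push_back(i);
  }
  if (left.empty() || right.empty()) return;
  nodes(row, 0) = sp.var;
  nodes(row, 1) = sp.split;
  nodes(row, 2) = sp.mask;
  nodes(row, 4) = sp.gain;
  nodes(row, 5) = sp.is_cat ? 1.0 : 0.0;
  fit_node(nodes, tree_row0, 2 * node + 1, X, is_cat, r, left,
           depth_left - 1, min_node, lr, nodes_per_tree);
  fit_node(nodes, tree_row0, 2 * node + 2, X, is_cat, r, right,
           depth_left - 1, min_node, lr, nodes_per_tree);
}

static double tree_predict(const NumericMatrix& nodes, int tree_row0,
                           const NumericMatrix& X, int i) {
  int node = 0;
  for (;;) {
    int row = tree_row0 + node;
    int var = (int)nodes(row, 0);
    if (var < 0) return nodes(row, 3);
    bool go_left;
    if (nodes(row, 5) == 1.0) {
      go_left = mask_bit(nodes(row, 2), (int)X(i, var));
    } else {
      go_left = X(i, var) < nodes(row, 1);
    }
    node = go_left ? 2 * node + 1 : 2 * node + 2;
  }
}

static inline double clamp_f(double f) {
  return f > 19.0 ? 19.0 : (f < -19.0 ? -19.0 : f);
}

// deviance of current scores
static double deviance(const std::vector<double>& F, const IntegerVector& y,
                       int n, int K) {
  double dev = 0.0;
  if (K == 1) {
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-clamp_f(F[i])));
      p = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
      dev += y[i] == 1 ? -2.0 * std::log(p) : -2.0 * std::log(1.0 - p);
    }
  } else {
    for (int i = 0; i < n; ++i) {
      double mx = -1e300;
      for (int k = 0; k < K; ++k) mx = std::max(mx, F[i + k * (size_t)n]);
      double z = 0.0;
      for (int k = 0; k < K; ++k) z += std::exp(F[i + k * (size_t)n] - mx);
      double lp = F[i + y[i] * (size_t)n] - mx - std::log(z);
      dev += -2.0 * lp;
    }
  }
  return dev / n;
}

// [[Rcpp::export]]
List cpp_boost(NumericMatrix X, IntegerVector is_cat, IntegerVector y,
               int K, int n_trees, double lr, int depth, double bag_frac,
               int min_node) {
  int n = X.nrow();
  int nodes_per_tree = (1 << (depth + 1)) - 1;
  NumericMatrix nodes(n_trees * K * nodes_per_tree, NCOL);
  NumericVector init(K);
  std::vector<double> F((size_t)n * K, 0.0);
  if (K == 1) {
    double ybar = 0.0;
    for (int i = 0; i < n; ++i) ybar += y[i];
    ybar /= n;
    ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
    init[0] = std::log(ybar / (1.0 - ybar));
    for (int i = 0; i < n; ++i) F[i] = init[0];
  } else {
    std::vector<double> cnt(K, 0.0);
    for (int i = 0; i < n; ++i) cnt[y[i]]++;
    for (int k = 0; k < K; ++k) {
      init[k] = std::log(std::max(cnt[k], 0.5) / n);
      for (int i = 0; i < n; ++i) F[i + k * (size_t)n] = init[k];
    }
  }
  NumericVector train_dev(n_trees);
  int bag_n = std::max(2 * min_node, (int)std::floor(bag_frac * n));
  bag_n = std::min(bag_n, n);
  std::vector<int> perm(n);
  std::vector<double> resid(n), prob(K);
  for (int t = 0; t < n_trees; ++t) {
    // bag: partial Fisher-Yates draw without replacement using R's RNG
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = 0; i < bag_n; ++i) {
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(perm[i], perm[j]);
    }
    std::vector<int> bag(perm.begin(), perm.begin() + bag_n);
    for (int k = 0; k < K; ++k) {
      // negative gradient y_k - p_k on all rows
      if (K == 1) {
        for (int i = 0; i < n; ++i) {
          double p = 1.0 / (1.0 + std::exp(-clamp_f(F[i])));
          resid[i] = y[i] - p;
        }
      } else {
        for (int i = 0; i < n; ++i) {
          double mx = -1e300;
          for (int kk = 0; kk < K; ++kk) mx = std::max(mx, F[i + kk * (size_t)n]);
          double z = 0.0;
          for (int kk = 0; kk < K; ++kk) z += std::exp(F[i + kk * (size_t)n] - mx);
          double p = std::exp(F[i + k * (size_t)n] - mx) / z;
          resid[i] = (y[i] == k ? 1.0 : 0.0) - p;
        }
      }
      int tree_row0 = (t * K + k) * nodes_per_tree;
      fit_node(nodes, tree_row0, 0, X, is_cat, resid, bag, depth, min_node,
               lr, nodes_per_tree);
      for (int i = 0; i < n; ++i)
        F[i + k * (size_t)n] += tree_predict(nodes, tree_row0, X, i);
    }
    train_dev[t] = deviance(F, y, n, K);
  }
  return List::create(_["nodes"] = nodes, _["init"] = init,
                      _["train_deviance"] = train_dev,
                      _["nodes_per_tree"] = nodes_per_tree);
}

// [[Rcpp::export]]
NumericMatrix cpp_predict_raw(NumericMatrix nodes, NumericVector init, int K,
                              int nodes_per_tree, NumericMatrix X,
                              int n_stages) {
  int n = X.nrow();
  NumericMatrix F(n, K);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < n; ++i) F(i, k) = init[k];
  for (int t = 0; t < n_stages; ++t)
    for (int k = 0; k < K; ++k) {
      int tree_row0 = (t * K + k) * nodes_per_tree;
      for (int i = 0; i < n; ++i)
        F(i, k) += tree_predict(nodes, tree_row0, X, i);
    }
  return F;
}

// [[Rcpp::export]]
NumericVector cpp_staged_deviance(NumericMatrix nodes, NumericVector init,
                                  int K, int nodes_per_tree, NumericMatrix X,
                                  IntegerVector y, int n_stages) {
  int n = X.nrow();
  std::vector<double> F((size_t)n * K);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < n; ++i) F[i + k * (size_t)n] = init[k];
  NumericVector dev(n_stages);
  for (int t = 0; t < n_stages; ++t) {
    for (int k = 0; k < K; ++k) {
      int tree_row0 = (t * K + k) * nodes_per_tree;
      for (int i = 0; i < n; ++i)
        F[i + k * (size_t)n] += tree_predict(nodes, tree_row0, X, i);
    }
    dev[t] = deviance(F, y, n, K);
  }
  return dev;
}

// single least-squares regression tree on a response vector (no shrinkage)
// [[Rcpp::export]]
List cpp_fit_tree(NumericMatrix X, IntegerVector is_cat, NumericVector r,
                  int depth, int min_node) {
  int n = X.nrow();
  int nodes_per_tree = (1 << (depth + 1)) - 1;
  NumericMatrix nodes(nodes_per_tree, NCOL);
  std::vector<double> rv(r.begin(), r.end());
  std::vector<int> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;
  fit_node(nodes, 0, 0, X, is_cat, rv, rows, depth, min_node, 1.0,
           nodes_per_tree);
  NumericVector pred(n);
  for (int i = 0; i < n; ++i) pred[i] = tree_predict(nodes, 0, X, i);
  return List::create(_["nodes"] = nodes, _["pred"] = pred,
                      _["nodes_per_tree"] = nodes_per_tree);
}
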