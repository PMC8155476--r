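// Native CART / random-forest core.
//
// Trees are grown by exhaustive greedy search over (feature, midpoint
// threshold) pairs maximizing the Gini impurity decrease
//   dG = G(parent) - p_l G(left) - p_r G(right),
// optionally over a random feature subset per node (drawn from R's RNG so
// set.seed() governs reproducibility).  Nodes store per-class sample
// counts, impurity and the raw dG of their split, which is what both the
// impurity-based importance and the tree-conditional Shapley expectation
// need.  Ties in dG are broken by the lowest feature index, then the
// lowest threshold.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct NodeStore {
  std::vector<int> feature, left, right, n;
  std::vector<double> threshold, impurity, delta;
  std::vector<std::vector<int> > counts;
  int n_classes;
};

double gini(const std::vector<int>& cnt, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (size_t k = 0; k < cnt.size(); ++k) {
    double p = double(cnt[k]) / n;
    g -= p * p;
  }
  return g;
}

// Draw `m` distinct feature indices from 0..k-1 via partial Fisher-Yates
// on R's RNG, returned in ascending order.
std::vector<int> sample_features(int k, int m) {
  std::vector<int> pool(k);
  for (int i = 0; i < k; ++i) pool[i] = i;
  for (int i = 0; i < m; ++i) {
    int j = i + int(unif_rand() * (k - i));
    if (j >= k) j = k - 1;
    std::swap(pool[i], pool[j]);
  }
  pool.resize(m);
  std::sort(pool.begin(), pool.end());
  return pool;
}

int build_node(const NumericMatrix& X, const IntegerVector& y,
               std::vector<int>& idx, int lo, int hi, int depth,
               int max_depth, int min_leaf, int mtry, NodeStore& ns) {
  int n = hi - lo;
  int l = ns.n_classes;
  std::vector<int> cnt(l, 0);
  for (int i = lo; i < hi; ++i) cnt[y[idx[i]]]++;
  double g = gini(cnt, n);

  int me = ns.feature.size();
  ns.feature.push_back(-1);
  ns.threshold.push_back(NA_REAL);
  ns.left.push_back(-1);
  ns.right.push_back(-1);
  ns.n.push_back(n);
  ns.impurity.push_back(g);
  ns.delta.push_back(0.0);
  ns.counts.push_back(cnt);

  bool pure = false;
  for (int k = 0; k < l; ++k) {
    if (cnt[k] == n) pure = true;
  }
  if (pure || n < 2 * min_leaf || n < 2 ||
      (max_depth > 0 && depth >= max_depth)) {
    return me;
  }

  int k_feat = X.ncol();
  std::vector<int> cand = sample_features(k_feat, std::min(mtry, k_feat));

  double best_dg = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;
  std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
  std::vector<int> best_ord;
  std::vector<int> lcnt(l);

  for (size_t c = 0; c < cand.size(); ++c) {
    int f = cand[c];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      double va = X(a, f), vb = X(b, f);
      if (va != vb) return va < vb;
      return a < b;
    });
    std::fill(lcnt.begin(), lcnt.end(), 0);
    for (int i = 0; i < n - 1; ++i) {
      lcnt[y[ord[i]]]++;
      double v = X(ord[i], f), vn = X(ord[i + 1], f);
      if (v == vn) continue;
      int nl = i + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      double gl = 1.0, gr = 1.0;
      for (int kk = 0; kk < l; ++kk) {
        double pl = double(lcnt[kk]) / nl;
        double pr = double(cnt[kk] - lcnt[kk]) / nr;
        gl -= pl * pl;
        gr -= pr * pr;
      }
      double dg = g - (double(nl) / n) * gl - (double(nr) / n) * gr;
      if (dg > best_dg + 1e-15) {
        best_dg = dg;
        best_f = f;
        best_thr = (v + vn) / 2.0;
        best_ord = ord;
        // remember the split position via nl encoded below
      }
    }
  }

  if (best_f < 0) return me;

  // partition idx[lo:hi) by the chosen split
  std::vector<int> li, ri;
  li.reserve(n);
  ri.reserve(n);
  for (int i = lo; i < hi; ++i) {
    if (X(idx[i], best_f) <= best_thr) li.push_back(idx[i]);
    else ri.push_back(idx[i]);
  }
  std::copy(li.begin(), li.end(), idx.begin() + lo);
  std::copy(ri.begin(), ri.end(), idx.begin() + lo + li.size());
  int mid = lo + li.size();

  ns.feature[me] = best_f;
  ns.threshold[me] = best_thr;
  ns.delta[me] = best_dg;
  int lc = build_node(X, y, idx, lo, mid, depth + 1, max_depth, min_leaf,
                      mtry, ns);
  ns.left[me] = lc;
  int rc = build_node(X, y, idx, mid, hi, depth + 1, max_depth, min_leaf,
                      mtry, ns);
  ns.right[me] = rc;
  return me;
}

// Flattened read-only view of a fitted tree for traversal.
struct FlatTree {
  IntegerVector feature, left, right, n;
  NumericVector threshold;
  NumericMatrix prob;
};

FlatTree flatten(const List& tree) {
  FlatTree t;
  t.feature = tree["feature"];
  t.left = tree["left"];
  t.right = tree["right"];
  t.n = tree["n"];
  t.threshold = tree["threshold"];
  t.prob = as<NumericMatrix>(tree["prob"]);
  return t;
}

int descend(const FlatTree& t, const NumericMatrix& X, int row) {
  int node = 0;
  while (t.feature[node] >= 0) {
    node = (X(row, t.feature[node]) <= t.threshold[node]) ? t.left[node]
                                                          : t.right[node];
  }
  return node;
}

// Tree-conditional expectation: features in S follow x's branch, features
// outside S average the children weighted by their training-sample
// fractions.
void tree_expected(const FlatTree& t, const double* x, const bool* in_s,
                   int node, double w, double* acc, int l) {
  if (t.feature[node] < 0) {
    for (int k = 0; k < l; ++k) acc[k] += w * t.prob(node, k);
    return;
  }
  int f = t.feature[node];
  if (in_s[f]) {
    int child = (x[f] <= t.threshold[node]) ? t.left[node] : t.right[node];
    tree_expected(t, x, in_s, child, w, acc, l);
  } else {
    double nn = t.n[node];
    tree_expected(t, x, in_s, t.left[node], w * t.n[t.left[node]] / nn,
                  acc, l);
    tree_expected(t, x, in_s, t.right[node], w * t.n[t.right[node]] / nn,
                  acc, l);
  }
}

void forest_coalition(const std::vector<FlatTree>& ts, const double* x,
                      const bool* in_s, double* out, int l) {
  for (int k = 0; k < l; ++k) out[k] = 0.0;
  std::vector<double> acc(l);
  for (size_t t = 0; t < ts.size(); ++t) {
    std::fill(acc.begin(), acc.end(), 0.0);
    tree_expected(ts[t], x, in_s, 0, 1.0, acc.data(), l);
    for (int k = 0; k < l; ++k) out[k] += acc[k];
  }
  for (int k = 0; k < l; ++k) out[k] /= ts.size();
}

std::vector<FlatTree> flatten_forest(const List& trees) {
  std::vector<FlatTree> ts;
  ts.reserve(trees.size());
  for (int i = 0; i < trees.size(); ++i) {
    ts.push_back(flatten(as<List>(trees[i])));
  }
  return ts;
}

}  // namespace

// [[Rcpp::export]]
List cpp_fit_tree(NumericMatrix X, IntegerVector y, int n_classes,
                  IntegerVector rows, int max_depth, int min_leaf,
                  int mtry) {
  NodeStore ns;
  ns.n_classes = n_classes;
  std::vector<int> idx(rows.begin(), rows.end());
  build_node(X, y, idx, 0, idx.size(), 0, max_depth, min_leaf, mtry, ns);

  int m = ns.feature.size();
  IntegerMatrix counts(m, n_classes);
  NumericMatrix prob(m, n_classes);
  for (int i = 0; i < m; ++i) {
    for (int k = 0; k < n_classes; ++k) {
      counts(i, k) = ns.counts[i][k];
      prob(i, k) = double(ns.counts[i][k]) / ns.n[i];
    }
  }
  return List::create(
      _["feature"] = wrap(ns.feature), _["threshold"] = wrap(ns.threshold),
      _["left"] = wrap(ns.left), _["right"] = wrap(ns.right),
      _["n"] = wrap(ns.n), _["counts"] = counts,
      _["impurity"] = wrap(ns.impurity), _["delta"] = wrap(ns.delta),
      _["prob"] = prob);
}

// [[Rcpp::export]]
NumericMatrix cpp_tree_proba(List tree, NumericMatrix X) {
  FlatTree t = flatten(tree);
  int l = t.prob.ncol();
  NumericMatrix out(X.nrow(), l);
  for (int i = 0; i < X.nrow(); ++i) {
    int leaf = descend(t, X, i);
    for (int k = 0; k < l; ++k) out(i, k) = t.prob(leaf, k);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_forest_proba(List trees, NumericMatrix X, int n_classes) {
  std::vector<FlatTree> ts = flatten_forest(trees);
  NumericMatrix out(X.nrow(), n_classes);
  for (int i = 0; i < X.nrow(); ++i) {
    for (size_t t = 0; t < ts.size(); ++t) {
      int leaf = descend(ts[t], X, i);
      for (int k = 0; k < n_classes; ++k) {
        out(i, k) += ts[t].prob(leaf, k);
      }
    }
    for (int k = 0; k < n_classes; ++k) out(i, k) /= ts.size();
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_tree_expected(List tree, NumericVector x,
                                LogicalVector in_s) {
  FlatTree t = flatten(tree);
  int l = t.prob.ncol();
  NumericVector out(l);
  std::vector<char> mask(in_s.size());
  for (int j = 0; j < in_s.size(); ++j) mask[j] = in_s[j];
  tree_expected(t, x.begin(), reinterpret_cast<bool*>(mask.data()), 0, 1.0,
                out.begin(), l);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_forest_coalition(List trees, NumericVector x,
                                   LogicalVector in_s, int n_classes) {
  std::vector<FlatTree> ts = flatten_forest(trees);
  std::vector<char> mask(in_s.size());
  for (int j = 0; j < in_s.size(); ++j) mask[j] = in_s[j];
  NumericMatrix out(1, n_classes);
  std::vector<double> v(n_classes);
  forest_coalition(ts, x.begin(), reinterpret_cast<bool*>(mask.data()),
                   v.data(), n_classes);
  for (int k = 0; k < n_classes; ++k) out(0, k) = v[k];
  return out;
}

// Exact Shapley attribution of the tree-conditional coalition value by
// full subset enumeration (2^M coalition evaluations).
// [[Rcpp::export]]
List cpp_tree_shap_exact(List trees, NumericVector x, int n_classes) {
  int M = x.size();
  if (M > 20) stop("subset enumeration capped at 20 features");
  std::vector<FlatTree> ts = flatten_forest(trees);
  int nsub = 1 << M;

  // Shapley kernel weights w[s] = s! (M - s - 1)! / M!
  std::vector<double> w(M);
  for (int s = 0; s < M; ++s) {
    double lw = 0.0;
    for (int i = 2; i <= s; ++i) lw += std::log((double)i);
    for (int i = 2; i <= M - s - 1; ++i) lw += std::log((double)i);
    for (int i = 2; i <= M; ++i) lw -= std::log((double)i);
    w[s] = std::exp(lw);
  }

  std::vector<double> vals((size_t)nsub * n_classes);
  std::vector<char> mask(M);
  for (int sub = 0; sub < nsub; ++sub) {
    for (int j = 0; j < M; ++j) mask[j] = (sub >> j) & 1;
    forest_coalition(ts, x.begin(), reinterpret_cast<bool*>(mask.data()),
                     &vals[(size_t)sub * n_classes], n_classes);
  }

  NumericMatrix phi(M, n_classes);
  for (int sub = 0; sub < nsub; ++sub) {
    int s = 0;
    for (int j = 0; j < M; ++j) s += (sub >> j) & 1;
    for (int j = 0; j < M; ++j) {
      if ((sub >> j) & 1) continue;
      int with = sub | (1 << j);
      for (int k = 0; k < n_classes; ++k) {
        phi(j, k) += w[s] * (vals[(size_t)with * n_classes + k] -
                             vals[(size_t)sub * n_classes + k]);
      }
    }
  }
  NumericVector base(n_classes), fx(n_classes);
  for (int k = 0; k < n_classes; ++k) {
    base[k] = vals[k];
    fx[k] = vals[(size_t)(nsub - 1) * n_classes + k];
  }
  return List::create(_["phi"] = phi, _["base"] = base, _["fx"] = fx);
}

// Permutation-sampling (Castro-style) Shapley attribution of the
// tree-conditional coalition value, for a batch of instances.  Uses R's
// RNG for the permutations.
// [[Rcpp::export]]
List cpp_tree_shap_sampled(List trees, NumericMatrix X, int n_classes,
                           int n_perm) {
  std::vector<FlatTree> ts = flatten_forest(trees);
  int M = X.ncol(), n = X.nrow();
  NumericVector phi(Dimension(n, M, n_classes));
  NumericMatrix base(n, n_classes), fx(n, n_classes);

  std::vector<char> mask(M);
  std::vector<double> v_prev(n_classes), v_new(n_classes), x(M);
  std::vector<int> perm(M);

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < M; ++j) x[j] = X(i, j);
    std::fill(mask.begin(), mask.end(), 0);
    forest_coalition(ts, x.data(), reinterpret_cast<bool*>(mask.data()),
                     v_prev.data(), n_classes);
    for (int k = 0; k < n_classes; ++k) base(i, k) = v_prev[k];
    std::fill(mask.begin(), mask.end(), 1);
    forest_coalition(ts, x.data(), reinterpret_cast<bool*>(mask.data()),
                     v_new.data(), n_classes);
    for (int k = 0; k < n_classes; ++k) fx(i, k) = v_new[k];

    for (int p = 0; p < n_perm; ++p) {
      for (int j = 0; j < M; ++j) perm[j] = j;
      for (int j = 0; j < M; ++j) {
        int jj = j + int(unif_rand() * (M - j));
        if (jj >= M) jj = M - 1;
        std::swap(perm[j], perm[jj]);
      }
      std::fill(mask.begin(), mask.end(), 0);
      forest_coalition(ts, x.data(), reinterpret_cast<bool*>(mask.data()),
                       v_prev.data(), n_classes);
      for (int j = 0; j < M; ++j) {
        mask[perm[j]] = 1;
        forest_coalition(ts, x.data(), reinterpret_cast<bool*>(mask.data()),
                         v_new.data(), n_classes);
        for (int k = 0; k < n_classes; ++k) {
          phi[i + (size_t)n * perm[j] + (size_t)n * M * k] +=
              (v_new[k] - v_prev[k]) / n_perm;
        }
        std::copy(v_new.begin(), v_new.end(), v_prev.begin());
      }
    }
  }
  return List::create(_["phi"] = phi, _["base"] = base, _["fx"] = fx);
}
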