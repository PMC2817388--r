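// Random-forest core: unpruned Gini trees on bootstrap samples of a binary
// design matrix, with out-of-bag error and permutation importance.
// Per-tree RNG streams (std::mt19937 seeded from R) keep forests
// reproducible and make B extensible without reshuffling earlier trees.

#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> var, left, right, pred;  // var = -1 marks a leaf
};

int add_node(Tree &t) {
  t.var.push_back(-1);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.pred.push_back(0);
  return (int)t.var.size() - 1;
}

// Grow one node (preorder: node, left = value 1, right = value 0).
// Matches the R grower: phi = i0 - (nl/n) il - (nr/n) ir, candidates
// searched in ascending column order, strict phi > 0, child-size floor.
int grow_node(Tree &t, const IntegerMatrix &X, const IntegerVector &y,
              std::vector<int> &rows, int lo, int hi, int mtry, int min_node,
              std::mt19937 &rng, std::vector<int> &varpool,
              std::vector<double> &gini_imp) {
  const int id = add_node(t);
  const int n = hi - lo;
  int n1 = 0;
  for (int k = lo; k < hi; ++k) n1 += y[rows[k]];
  t.pred[id] = (n1 > n - n1) ? 1 : 0;
  if (n < 2) return id;
  const double p0 = (double)n1 / n;
  const double i0 = 2.0 * p0 * (1.0 - p0);
  if (i0 <= 0.0) return id;

  const int p = X.ncol();
  const int m = mtry < p ? mtry : p;
  // partial Fisher-Yates, then ascending order for the lowest-index tie-break
  for (int k = 0; k < m; ++k) {
    std::uniform_int_distribution<int> pick(k, p - 1);
    std::swap(varpool[k], varpool[pick(rng)]);
  }
  std::vector<int> cand(varpool.begin(), varpool.begin() + m);
  std::sort(cand.begin(), cand.end());

  int best_var = -1;
  double best_phi = 0.0;
  for (int c = 0; c < m; ++c) {
    const int j = cand[c];
    int nl = 0, n1l = 0;
    for (int k = lo; k < hi; ++k) {
      const int r = rows[k];
      if (X(r, j) == 1) {
        ++nl;
        n1l += y[r];
      }
    }
    const int nr = n - nl, n1r = n1 - n1l;
    if (nl < min_node || nr < min_node) continue;
    const double pl = (double)n1l / nl, pr = (double)n1r / nr;
    const double il = 2.0 * pl * (1.0 - pl), ir = 2.0 * pr * (1.0 - pr);
    const double phi = i0 - ((double)nl / n) * il - ((double)nr / n) * ir;
    if (phi > best_phi) {
      best_phi = phi;
      best_var = j;
    }
  }
  if (best_var < 0) return id;

  gini_imp[best_var] += n * best_phi;
  // in-place partition keeping relative order irrelevant for statistics
  int mid = lo;
  for (int k = lo; k < hi; ++k)
    if (X(rows[k], best_var) == 1) std::swap(rows[k], rows[mid++]);
  t.var[id] = best_var;
  t.left[id] = grow_node(t, X, y, rows, lo, mid, mtry, min_node, rng, varpool, gini_imp);
  t.right[id] = grow_node(t, X, y, rows, mid, hi, mtry, min_node, rng, varpool, gini_imp);
  return id;
}

int predict_row(const Tree &t, const IntegerMatrix &X, int row,
                int perm_var = -1, int perm_val = 0) {
  int node = 0;
  while (t.var[node] >= 0) {
    const int j = t.var[node];
    const int v = (j == perm_var) ? perm_val : X(row, j);
    node = (v == 1) ? t.left[node] : t.right[node];
  }
  return t.pred[node];
}

Tree tree_from_list(const List &tl) {
  Tree t;
  t.var = as<std::vector<int>>(tl["var"]);
  t.left = as<std::vector<int>>(tl["left"]);
  t.right = as<std::vector<int>>(tl["right"]);
  t.pred = as<std::vector<int>>(tl["pred"]);
  return t;
}

}  // namespace

// [[Rcpp::export]]
List rf_grow_cpp(IntegerMatrix X, IntegerVector y, int B, int mtry,
                 int min_node, IntegerVector tree_seeds) {
  const int n = X.nrow(), p = X.ncol();
  List trees(B);
  IntegerMatrix inbag(n, B);
  NumericMatrix gini(p, B);
  for (int b = 0; b < B; ++b) {
    std::mt19937 rng((unsigned)tree_seeds[b]);
    std::uniform_int_distribution<int> draw(0, n - 1);
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) {
      const int r = draw(rng);
      rows[i] = r;
      ++inbag(r, b);
    }
    std::vector<int> varpool(p);
    for (int j = 0; j < p; ++j) varpool[j] = j;
    std::vector<double> gi(p, 0.0);
    Tree t;
    grow_node(t, X, y, rows, 0, n, mtry, min_node, rng, varpool, gi);
    for (int j = 0; j < p; ++j) gini(j, b) = gi[j];
    trees[b] = List::create(_["var"] = wrap(t.var), _["left"] = wrap(t.left),
                            _["right"] = wrap(t.right), _["pred"] = wrap(t.pred));
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag, _["gini"] = gini);
}

// [[Rcpp::export]]
List rf_oob_cpp(List trees, IntegerMatrix inbag, IntegerMatrix X,
                IntegerVector y) {
  const int n = X.nrow(), B = trees.size();
  NumericVector per_tree(B);
  IntegerMatrix votes(n, 2);
  for (int b = 0; b < B; ++b) {
    Tree t = tree_from_list(trees[b]);
    int wrong = 0, m = 0;
    for (int i = 0; i < n; ++i) {
      if (inbag(i, b) > 0) continue;
      const int pr = predict_row(t, X, i);
      ++votes(i, pr);
      wrong += (pr != y[i]);
      ++m;
    }
    per_tree[b] = m > 0 ? (double)wrong / m : NA_REAL;
  }
  return List::create(_["per_tree"] = per_tree, _["votes"] = votes);
}

// [[Rcpp::export]]
List rf_perm_cpp(List trees, IntegerMatrix inbag, IntegerMatrix X,
                 IntegerVector y, IntegerVector perm_seeds) {
  const int n = X.nrow(), p = X.ncol(), B = trees.size();
  NumericMatrix delta(B, p);
  NumericVector oob_err(B);
  for (int b = 0; b < B; ++b) {
    Tree t = tree_from_list(trees[b]);
    std::vector<int> oob;
    for (int i = 0; i < n; ++i)
      if (inbag(i, b) == 0) oob.push_back(i);
    const int m = (int)oob.size();
    if (m == 0) {
      oob_err[b] = NA_REAL;
      continue;
    }
    int wrong = 0;
    for (int k = 0; k < m; ++k)
      wrong += (predict_row(t, X, oob[k]) != y[oob[k]]);
    const double base = (double)wrong / m;
    oob_err[b] = base;

    std::vector<bool> used(p, false);
    for (size_t u = 0; u < t.var.size(); ++u)
      if (t.var[u] >= 0) used[t.var[u]] = true;

    std::mt19937 rng((unsigned)perm_seeds[b]);
    std::vector<int> xj(m);
    for (int j = 0; j < p; ++j) {
      if (!used[j]) continue;  // permuting an unused variable cannot matter
      for (int k = 0; k < m; ++k) xj[k] = X(oob[k], j);
      std::shuffle(xj.begin(), xj.end(), rng);
      int w = 0;
      for (int k = 0; k < m; ++k)
        w += (predict_row(t, X, oob[k], j, xj[k]) != y[oob[k]]);
      delta(b, j) = (double)w / m - base;
    }
  }
  return List::create(_["delta"] = delta, _["oob_err"] = oob_err);
}

// [[Rcpp::export]]
IntegerMatrix rf_predict_cpp(List trees, IntegerMatrix X) {
  const int n = X.nrow(), B = trees.size();
  IntegerMatrix votes(n, 2);
  for (int b = 0; b < B; ++b) {
    Tree t = tree_from_list(trees[b]);
    for (int i = 0; i < n; ++i) ++votes(i, predict_row(t, X, i));
  }
  return votes;
}
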