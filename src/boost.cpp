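// Stochastic gradient-boosted regression trees for a Bernoulli outcome:
// best-first tree growth with squared-error split improvements, Newton leaf
// values, shrinkage, bagging without replacement and validation-based
// stopping. Missing predictor cells (NaN) are excluded from a split's
// improvement computation and routed to the child with more observed rows.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct Node {
  int var = -1;            // split variable (0-based), -1 for a leaf
  double thresh = 0.0;     // split threshold (midpoint)
  int left = -1, right = -1;
  double value = 0.0;      // leaf value
  double improvement = 0.0;
  bool na_left = true;     // route missing values to the left child?
  std::vector<int> rows;   // training rows in this node (during growth)
};

struct SplitResult {
  double improvement = 0.0;
  int var = -1;
  double thresh = 0.0;
  bool valid = false;
};

// Best split of a node: scan variables in ascending index, thresholds in
// ascending order, keep strictly better improvements (so ties resolve to the
// lowest variable index, then the smallest threshold).
static SplitResult best_split(const NumericMatrix& X, const std::vector<double>& r,
                              const std::vector<int>& rows, int min_node_size) {
  SplitResult best;
  const int p = X.ncol();
  std::vector<std::pair<double, double>> xv;  // (x value, residual)
  for (int v = 0; v < p; ++v) {
    xv.clear();
    for (int idx : rows) {
      double x = X(idx, v);
      if (!ISNAN(x)) xv.push_back({x, r[idx]});
    }
    const int nS = (int)xv.size();
    if (nS < 2 * min_node_size) continue;
    std::sort(xv.begin(), xv.end(),
              [](const std::pair<double, double>& a,
                 const std::pair<double, double>& b) { return a.first < b.first; });
    double sumS = 0.0;
    for (auto& q : xv) sumS += q.second;
    const double baseline = sumS * sumS / nS;
    double sumL = 0.0;
    for (int i = 0; i + 1 < nS; ++i) {
      sumL += xv[i].second;
      if (xv[i].first == xv[i + 1].first) continue;  // not between distinct values
      const int nL = i + 1, nR = nS - nL;
      if (nL < min_node_size || nR < min_node_size) continue;
      const double sumR = sumS - sumL;
      const double imp = sumL * sumL / nL + sumR * sumR / nR - baseline;
      if (imp > best.improvement + 1e-12 ||
          (imp > 0 && !best.valid)) {
        best.improvement = imp;
        best.var = v;
        best.thresh = (xv[i].first + xv[i + 1].first) / 2.0;
        best.valid = true;
      }
    }
  }
  return best;
}

// Grow a regression tree by best-first expansion: repeatedly split the leaf
// whose best split most reduces the residual sum of squares.
static std::vector<Node> grow_tree(const NumericMatrix& X,
                                   const std::vector<double>& r,
                                   const std::vector<int>& rows,
                                   int max_leaves, int min_node_size) {
  std::vector<Node> nodes;
  Node root;
  root.rows = rows;
  nodes.push_back(root);
  int n_leaves = 1;
  std::vector<SplitResult> cand(1, best_split(X, r, rows, min_node_size));

  while (n_leaves < max_leaves) {
    int pick = -1;
    double best_imp = 0.0;
    for (size_t i = 0; i < nodes.size(); ++i) {
      if (nodes[i].var != -1) continue;           // internal
      if (!cand[i].valid) continue;
      if (cand[i].improvement > best_imp + 1e-12) {
        best_imp = cand[i].improvement;
        pick = (int)i;
      }
    }
    if (pick < 0) break;

    const SplitResult sp = cand[pick];
    std::vector<int> lrows, rrows, narows;
    for (int idx : nodes[pick].rows) {
      double x = X(idx, sp.var);
      if (ISNAN(x)) narows.push_back(idx);
      else if (x <= sp.thresh) lrows.push_back(idx);
      else rrows.push_back(idx);
    }
    const bool na_left = lrows.size() >= rrows.size();
    if (!narows.empty()) {
      std::vector<int>& tgt = na_left ? lrows : rrows;
      tgt.insert(tgt.end(), narows.begin(), narows.end());
    }
    const int left_id = (int)nodes.size();
    const int right_id = left_id + 1;
    Node lc, rc;
    lc.rows = lrows;
    rc.rows = rrows;
    nodes.push_back(lc);
    nodes.push_back(rc);
    nodes[pick].var = sp.var;
    nodes[pick].thresh = sp.thresh;
    nodes[pick].improvement = sp.improvement;
    nodes[pick].na_left = na_left;
    nodes[pick].left = left_id;
    nodes[pick].right = right_id;
    nodes[pick].rows.clear();
    cand.push_back(best_split(X, r, nodes[left_id].rows, min_node_size));
    cand.push_back(best_split(X, r, nodes[right_id].rows, min_node_size));
    ++n_leaves;
  }
  // leaf values: mean residual
  for (auto& nd : nodes) {
    if (nd.var != -1) continue;
    double s = 0.0;
    for (int idx : nd.rows) s += r[idx];
    nd.value = nd.rows.empty() ? 0.0 : s / nd.rows.size();
  }
  return nodes;
}

static int leaf_of(const std::vector<Node>& nodes, const NumericMatrix& X, int row) {
  int cur = 0;
  while (nodes[cur].var != -1) {
    double x = X(row, nodes[cur].var);
    bool go_left = ISNAN(x) ? nodes[cur].na_left : (x <= nodes[cur].thresh);
    cur = go_left ? nodes[cur].left : nodes[cur].right;
  }
  return cur;
}

static List tree_to_list(const std::vector<Node>& nodes) {
  const int k = (int)nodes.size();
  IntegerVector var(k), left(k), right(k), n_rows(k);
  NumericVector thresh(k), value(k), improvement(k);
  LogicalVector na_left(k);
  for (int i = 0; i < k; ++i) {
    var[i] = nodes[i].var >= 0 ? nodes[i].var + 1 : NA_INTEGER;  // 1-based
    thresh[i] = nodes[i].thresh;
    left[i] = nodes[i].left >= 0 ? nodes[i].left + 1 : NA_INTEGER;
    right[i] = nodes[i].right >= 0 ? nodes[i].right + 1 : NA_INTEGER;
    value[i] = nodes[i].value;
    improvement[i] = nodes[i].improvement;
    na_left[i] = nodes[i].na_left;
    n_rows[i] = (int)nodes[i].rows.size();
  }
  return List::create(_["var"] = var, _["thresh"] = thresh, _["left"] = left,
                      _["right"] = right, _["value"] = value,
                      _["improvement"] = improvement, _["na_left"] = na_left,
                      _["n_rows"] = n_rows);
}

static std::vector<Node> tree_from_list(const List& tr) {
  IntegerVector var = tr["var"], left = tr["left"], right = tr["right"];
  NumericVector thresh = tr["thresh"], value = tr["value"];
  LogicalVector na_left = tr["na_left"];
  std::vector<Node> nodes(var.size());
  for (int i = 0; i < var.size(); ++i) {
    nodes[i].var = var[i] == NA_INTEGER ? -1 : var[i] - 1;
    nodes[i].thresh = thresh[i];
    nodes[i].left = left[i] == NA_INTEGER ? -1 : left[i] - 1;
    nodes[i].right = right[i] == NA_INTEGER ? -1 : right[i] - 1;
    nodes[i].value = value[i];
    nodes[i].na_left = na_left[i];
  }
  return nodes;
}

// [[Rcpp::export(name = ".cpp_grow_tree")]]
List cpp_grow_tree(NumericMatrix X, NumericVector r, int max_leaves,
                   int min_node_size) {
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  std::vector<double> rr(r.begin(), r.end());
  return tree_to_list(grow_tree(X, rr, rows, max_leaves, min_node_size));
}

// [[Rcpp::export(name = ".cpp_tree_predict")]]
NumericVector cpp_tree_predict(List tree, NumericMatrix X) {
  std::vector<Node> nodes = tree_from_list(tree);
  NumericVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) out[i] = nodes[leaf_of(nodes, X, i)].value;
  return out;
}

// Partial Fisher-Yates draw of k of n indices without replacement, using R's
// RNG so results are reproducible under set.seed().
static std::vector<int> sample_without_replacement(int n, int k) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(idx[i], idx[j]);
  }
  return std::vector<int>(idx.begin(), idx.begin() + k);
}

// [[Rcpp::export(name = ".cpp_boost_fit")]]
List cpp_boost_fit(NumericMatrix X, NumericVector y, IntegerVector train_idx,
                   IntegerVector valid_idx, double lambda, double bag_fraction,
                   int max_leaves, int min_node_size, int max_iter,
                   int patience, bool record_bags) {
  RNGScope rng;
  const int n = X.nrow();
  std::vector<int> tr(train_idx.begin(), train_idx.end());
  std::vector<int> va(valid_idx.begin(), valid_idx.end());
  for (int& i : tr) --i;  // to 0-based
  for (int& i : va) --i;
  const int n_train = (int)tr.size();
  double ybar = 0.0;
  for (int i : tr) ybar += y[i];
  ybar /= n_train;
  if (ybar <= 0.0 || ybar >= 1.0)
    stop("both outcome classes must be present in the training portion");
  const double F0 = std::log(ybar / (1.0 - ybar));
  std::vector<double> F(n, F0);

  const int bag_size = (int)std::ceil(bag_fraction * n_train);
  if (bag_size < 1) stop("configuration error: empty bag");

  auto valid_ll = [&]() {
    if (va.empty()) return 0.0;
    double ll = 0.0;
    for (int i : va) {
      double p = 1.0 / (1.0 + std::exp(-F[i]));
      p = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
      ll += y[i] * std::log(p) + (1.0 - y[i]) * std::log(1.0 - p);
    }
    return ll;
  };

  const bool has_valid = !va.empty();
  double best_ll = valid_ll();
  const double ll0 = best_ll;
  int best_iter = 0;
  int bad = 0;
  List trees(max_iter);
  List bags(record_bags ? max_iter : 0);
  NumericVector ll_trace(max_iter);
  std::vector<double> r(n, 0.0), pvec(n, 0.0);
  std::vector<char> in_bag(n, 0);
  int n_iter = 0;

  for (int it = 0; it < max_iter; ++it) {
    for (int i : tr) {
      pvec[i] = 1.0 / (1.0 + std::exp(-F[i]));
      r[i] = y[i] - pvec[i];
    }
    std::vector<int> bag_local = sample_without_replacement(n_train, bag_size);
    std::vector<int> bag(bag_size);
    for (int b = 0; b < bag_size; ++b) bag[b] = tr[bag_local[b]];
    if (record_bags) {
      IntegerVector bv(bag_size);
      for (int b = 0; b < bag_size; ++b) bv[b] = bag[b] + 1;
      bags[it] = bv;
    }

    std::vector<Node> nodes = grow_tree(X, r, bag, max_leaves, min_node_size);
    // Newton leaf values from the bag rows in each leaf
    for (auto& nd : nodes) {
      if (nd.var != -1) continue;
      double num = 0.0, den = 0.0;
      for (int idx : nd.rows) {
        num += r[idx];
        den += pvec[idx] * (1.0 - pvec[idx]);
      }
      nd.value = num / std::max(den, 1e-8);
    }
    for (int i = 0; i < n; ++i)
      F[i] += lambda * nodes[leaf_of(nodes, X, i)].value;

    trees[it] = tree_to_list(nodes);
    n_iter = it + 1;
    if (has_valid) {
      double ll = valid_ll();
      ll_trace[it] = ll;
      if (ll > best_ll) {
        best_ll = ll;
        best_iter = it + 1;
        bad = 0;
      } else {
        ++bad;
        if (bad > patience) break;
      }
    } else {
      ll_trace[it] = NA_REAL;
      best_iter = it + 1;
    }
  }

  List kept(n_iter);
  NumericVector ll_out(n_iter);
  for (int i = 0; i < n_iter; ++i) { kept[i] = trees[i]; ll_out[i] = ll_trace[i]; }
  List bags_out(record_bags ? n_iter : 0);
  if (record_bags) for (int i = 0; i < n_iter; ++i) bags_out[i] = bags[i];
  return List::create(_["F0"] = F0, _["trees"] = kept,
                      _["best_iteration"] = best_iter,
                      _["valid_loglik"] = ll_out,
                      _["valid_loglik_start"] = has_valid ? ll0 : NA_REAL,
                      _["n_iterations"] = n_iter,
                      _["bags"] = bags_out);
}
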