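// Graph-topology kernels: least-squares gradients, steepest ascent with
// shortcutting, flood-fill family clustering, deterministic maximum
// spanning trees and critical-tree pruning. All indices at this layer are
// 0-based; R wrappers convert.
#include <RcppArmadillo.h>
#include <queue>
#include <stack>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Least-squares gradient from neighborhood differences: at each node solve
// M g = b with M = sum (y-x)(y-x)^T, b = sum (y-x)(f(y)-f(x)). Where M is
// rank-deficient the minimum-norm solution restricted to the spanned
// subspace is returned and the node is flagged singular.
// [[Rcpp::export]]
List cpp_ls_gradient(const arma::mat& points, const IntegerVector& adj_ptr,
                     const IntegerVector& adj_idx, const NumericVector& values) {
  const int n = points.n_rows, d = points.n_cols;
  arma::mat g(n, d, arma::fill::zeros);
  LogicalVector singular(n);
  arma::mat M(d, d);
  arma::vec b(d), dy(d);
  for (int i = 0; i < n; ++i) {
    M.zeros(); b.zeros();
    for (int p = adj_ptr[i]; p < adj_ptr[i + 1]; ++p) {
      const int j = adj_idx[p];
      for (int k = 0; k < d; ++k) dy(k) = points(j, k) - points(i, k);
      M += dy * dy.t();
      b += dy * (values[j] - values[i]);
    }
    arma::vec eval; arma::mat evec;
    arma::eig_sym(eval, evec, M);
    const double tol = std::max(eval.max(), 0.0) * 1e-10;
    arma::vec sol(d, arma::fill::zeros);
    int rank = 0;
    for (int k = 0; k < d; ++k) {
      if (eval(k) > tol && eval(k) > 0) {
        sol += evec.col(k) * (arma::dot(evec.col(k), b) / eval(k));
        ++rank;
      }
    }
    singular[i] = (rank < d);
    for (int k = 0; k < d; ++k) g(i, k) = sol(k);
  }
  return List::create(_["vectors"] = g, _["singular_mask"] = singular);
}

// Strict graph local maxima: f(x) > f(y) for every neighbor y.
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(const IntegerVector& adj_ptr,
                               const IntegerVector& adj_idx,
                               const NumericVector& values) {
  const int n = adj_ptr.size() - 1;
  std::vector<int> out;
  for (int i = 0; i < n; ++i) {
    bool is_max = adj_ptr[i + 1] > adj_ptr[i];
    for (int p = adj_ptr[i]; p < adj_ptr[i + 1] && is_max; ++p)
      if (values[adj_idx[p]] >= values[i]) is_max = false;
    if (is_max) out.push_back(i);
  }
  return wrap(out);
}

// Steepest-ascent step: neighbor maximizing [f(y)-f(x)]/|y-x|; slope ties
// break to the lower index. Returns -1 at an ascent-terminal node. Plateau
// moves (slope == 0) are taken only toward a lower index, which makes the
// walk strictly decreasing in (slope>0 steps interleaved with index-
// decreasing plateau steps) and hence finite.
static int ascent_step(int i, const arma::mat& points, const IntegerVector& adj_ptr,
                       const IntegerVector& adj_idx, const NumericVector& values) {
  const int d = points.n_cols;
  double best = -1e300; int best_j = -1;
  for (int p = adj_ptr[i]; p < adj_ptr[i + 1]; ++p) {
    const int j = adj_idx[p];
    double dist2 = 0;
    for (int k = 0; k < d; ++k) {
      const double t = points(j, k) - points(i, k);
      dist2 += t * t;
    }
    const double slope = (values[j] - values[i]) / std::sqrt(dist2);
    // neighbors are visited in increasing index order, so strict '>' breaks
    // slope ties toward the lower index
    if (slope > best) { best = slope; best_j = j; }
  }
  if (best_j < 0) return -1;
  if (best > 0) return best_j;
  if (best == 0 && best_j < i && values[best_j] == values[i]) return best_j;
  return -1;
}

// Basin assignment by on-graph steepest ascent. Each unassigned node starts
// a path; paths adopt the attractor of the first already-assigned node they
// touch (shortcut), which never changes the result because ascent is
// deterministic. shortcut=false re-traces every path fully (oracle mode).
// [[Rcpp::export]]
IntegerVector cpp_assign_basins(const arma::mat& points, const IntegerVector& adj_ptr,
                                const IntegerVector& adj_idx, const NumericVector& values,
                                bool shortcut) {
  const int n = points.n_rows;
  IntegerVector attractor(n, -1);
  std::vector<int> path;
  for (int s = 0; s < n; ++s) {
    if (attractor[s] >= 0) continue;
    path.clear();
    int x = s;
    int dest = -1;
    for (;;) {
      if (shortcut && attractor[x] >= 0) { dest = attractor[x]; break; }
      path.push_back(x);
      const int y = ascent_step(x, points, adj_ptr, adj_idx, values);
      if (y < 0) { dest = x; break; }
      x = y;
    }
    if (shortcut) {
      for (int p : path) attractor[p] = dest;
    } else {
      attractor[s] = dest;  // full re-trace per seed
    }
  }
  return attractor;
}

// Flood fill around each local maximum m over nodes with deviation
// d(m, y) = (f(m) - f(y)) / (f(m) - fmin) < t, then transitive merge of
// overlapping fills (union-find). Returns the family id per maximum and
// the covered node set per fill.
// [[Rcpp::export]]
List cpp_flood_families(const IntegerVector& adj_ptr, const IntegerVector& adj_idx,
                        const NumericVector& values, const IntegerVector& maxima,
                        double t, double fmin) {
  const int n = adj_ptr.size() - 1, m = maxima.size();
  std::vector<int> parent(m);
  for (int i = 0; i < m; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) a = parent[a] = parent[parent[a]];
    return a;
  };
  std::vector<int> owner(n, -1);           // first fill to claim a node
  std::vector<std::vector<int>> fills(m);
  std::vector<char> in_fill(n, 0);
  for (int fi = 0; fi < m; ++fi) {
    const int root = maxima[fi];
    const double fx = values[root];
    const double scale = fx - fmin;
    std::fill(in_fill.begin(), in_fill.end(), 0);
    std::queue<int> q;
    q.push(root); in_fill[root] = 1;
    while (!q.empty()) {
      const int x = q.front(); q.pop();
      fills[fi].push_back(x);
      if (owner[x] < 0) owner[x] = fi;
      else {
        const int a = find(owner[x]), b2 = find(fi);
        if (a != b2) parent[std::max(a, b2)] = std::min(a, b2);
      }
      for (int p = adj_ptr[x]; p < adj_ptr[x + 1]; ++p) {
        const int y = adj_idx[p];
        if (in_fill[y]) continue;
        const double dev = scale > 0 ? (fx - values[y]) / scale : 0.0;
        if (dev < t) { in_fill[y] = 1; q.push(y); }
      }
    }
  }
  IntegerVector fam(m);
  for (int i = 0; i < m; ++i) fam[i] = find(i);
  List fl(m);
  for (int i = 0; i < m; ++i) fl[i] = wrap(fills[i]);
  return List::create(_["family_root"] = fam, _["fills"] = fl);
}

// Kruskal maximum spanning forest with fully deterministic tie-breaking:
// edges sorted by (-weight, i, j). Returns 0-based indices of kept edges.
// [[Rcpp::export]]
List cpp_max_spanning_tree(const IntegerMatrix& edges, const NumericVector& weights,
                           int n) {
  const int m = edges.nrow();
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (weights[a] != weights[b]) return weights[a] > weights[b];
    if (edges(a, 0) != edges(b, 0)) return edges(a, 0) < edges(b, 0);
    return edges(a, 1) < edges(b, 1);
  });
  std::vector<int> parent(n), rank_(n, 0);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) a = parent[a] = parent[parent[a]];
    return a;
  };
  std::vector<int> keep;
  keep.reserve(n - 1);
  int ncomp = n;
  for (int oi : ord) {
    const int a = find(edges(oi, 0)), b = find(edges(oi, 1));
    if (a == b) continue;
    if (rank_[a] < rank_[b]) parent[a] = b;
    else if (rank_[a] > rank_[b]) parent[b] = a;
    else { parent[b] = a; ++rank_[a]; }
    keep.push_back(oi);
    --ncomp;
  }
  return List::create(_["edge_idx"] = wrap(keep), _["n_components"] = ncomp);
}

// Iterative removal of leaf nodes that are not local maxima. Returns the
// mask of surviving nodes.
// [[Rcpp::export]]
LogicalVector cpp_prune_leaves(int n, const IntegerMatrix& edges,
                               const LogicalVector& is_max) {
  std::vector<std::vector<int>> adj(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    adj[edges(e, 0)].push_back(edges(e, 1));
    adj[edges(e, 1)].push_back(edges(e, 0));
  }
  std::vector<int> deg(n);
  for (int i = 0; i < n; ++i) deg[i] = adj[i].size();
  std::queue<int> q;
  std::vector<char> removed(n, 0);
  for (int i = 0; i < n; ++i)
    if (deg[i] <= 1 && !is_max[i]) q.push(i);
  while (!q.empty()) {
    const int x = q.front(); q.pop();
    if (removed[x] || is_max[x] || deg[x] > 1) continue;
    removed[x] = 1;
    for (int y : adj[x]) {
      if (removed[y]) continue;
      if (--deg[y] <= 1 && !is_max[y]) q.push(y);
    }
  }
  LogicalVector keep(n);
  for (int i = 0; i < n; ++i) keep[i] = !removed[i];
  return keep;
}

// Enumerate critical paths on a tree/network: walks from each maximum along
// edges, stopping at the first maximum reached; interior nodes must not be
// maxima. Returns one record per unordered maxima pair with the connecting
// node sequence. Branching at non-maximum junctions explores all branches.
// [[Rcpp::export]]
List cpp_critical_paths(int n, const IntegerMatrix& edges,
                        const IntegerVector& maxima) {
  std::vector<std::vector<int>> adj(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    adj[edges(e, 0)].push_back(edges(e, 1));
    adj[edges(e, 1)].push_back(edges(e, 0));
  }
  std::vector<char> is_max(n, 0);
  for (int i = 0; i < maxima.size(); ++i) is_max[maxima[i]] = 1;
  List out;
  // DFS from each maximum; record path when another maximum is first hit.
  for (int s0 = 0; s0 < maxima.size(); ++s0) {
    const int s = maxima[s0];
    // stack of (node, parent); reconstruct paths via parent pointers local
    // to this source
    std::vector<int> par(n, -2);
    std::stack<int> st;
    st.push(s); par[s] = -1;
    while (!st.empty()) {
      const int x = st.top(); st.pop();
      for (int y : adj[x]) {
        if (par[y] != -2) continue;
        par[y] = x;
        if (is_max[y]) {
          if (y > s) {  // report each unordered pair once
            std::vector<int> path;
            for (int z = y; z != -1; z = par[z]) path.push_back(z);
            std::reverse(path.begin(), path.end());
            out.push_back(List::create(_["from"] = s, _["to"] = y,
                                       _["path"] = wrap(path)));
          }
        } else {
          st.push(y);
        }
      }
    }
  }
  return out;
}
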