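#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Trees are encoded as a parent vector over node ids 1..n_nodes:
// tips are 1..ntip, internal nodes ntip+1..n_nodes, and the tree is rooted at
// tip 1 (parent[0] == 0).  Rooting an unrooted binary tree at a leaf adds no
// node, so the encoding has exactly 2*ntip - 3 edges and every internal node
// has two children.  Leaf character data arrive as bitmasks over states 0..9;
// a missing cell carries the union mask of the states observed in its column.

struct FlatTree {
  int n_nodes, ntip;
  std::vector<int> child1, child2;   // 0 = absent, per node (1-based ids)
  std::vector<int> post;             // internal nodes in postorder
  int root_child;                    // the single child of tip 1

  FlatTree(const int* parent, int n_nodes_, int ntip_)
      : n_nodes(n_nodes_), ntip(ntip_),
        child1(n_nodes_ + 1, 0), child2(n_nodes_ + 1, 0), root_child(0) {
    for (int v = 2; v <= n_nodes; ++v) {
      int p = parent[v - 1];
      if (p == 0) continue;           // inactive slot (partial tree in b&b)
      if (p == 1) { root_child = v; continue; }
      if (child1[p] == 0) child1[p] = v; else child2[p] = v;
    }
    // postorder over internal nodes reachable from the root
    post.reserve(n_nodes - ntip);
    std::vector<int> stack;
    if (root_child > ntip) stack.push_back(root_child);
    std::vector<int> order;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      order.push_back(v);
      if (child1[v] > ntip) stack.push_back(child1[v]);
      if (child2[v] > ntip) stack.push_back(child2[v]);
    }
    for (int i = (int)order.size() - 1; i >= 0; --i) post.push_back(order[i]);
  }
};

// Fitch bottom-up pass for one encoded tree; returns per-character step counts.
static void fitch_pass(const FlatTree& tr, const IntegerMatrix& tipmask,
                       int* steps, int nchar) {
  std::vector<int> state((tr.n_nodes + 1) * 1);
  std::vector<int> st(tr.n_nodes + 1);
  for (int c = 0; c < nchar; ++c) {
    int s = 0;
    for (int t = 1; t <= tr.ntip; ++t) st[t] = tipmask(t - 1, c);
    for (size_t i = 0; i < tr.post.size(); ++i) {
      int v = tr.post[i];
      int a = st[tr.child1[v]], b = st[tr.child2[v]];
      int inter = a & b;
      if (inter) st[v] = inter; else { st[v] = a | b; ++s; }
    }
    if (tr.root_child) {
      int inter = st[1] & st[tr.root_child];
      if (!inter) ++s;
    }
    steps[c] = s;
  }
}

// [[Rcpp::export]]
IntegerVector fitch_steps_cpp(IntegerVector parent, int ntip,
                              IntegerMatrix tipmask) {
  int n_nodes = parent.size();
  int nchar = tipmask.ncol();
  FlatTree tr(parent.begin(), n_nodes, ntip);
  IntegerVector steps(nchar);
  fitch_pass(tr, tipmask, INTEGER(steps), nchar);
  return steps;
}

static int fitch_total_partial(const int* parent, int n_nodes, int ntip,
                               const IntegerMatrix& tipmask,
                               std::vector<int>& st) {
  // like fitch_pass but summed over characters; tolerates inactive slots
  FlatTree tr(parent, n_nodes, ntip);
  int nchar = tipmask.ncol();
  int total = 0;
  for (int c = 0; c < nchar; ++c) {
    for (int t = 1; t <= ntip; ++t) st[t] = tipmask(t - 1, c);
    for (size_t i = 0; i < tr.post.size(); ++i) {
      int v = tr.post[i];
      int a = st[tr.child1[v]], b = st[tr.child2[v]];
      int inter = a & b;
      if (inter) st[v] = inter; else { st[v] = a | b; ++total; }
    }
    if (tr.root_child) {
      if (!(st[1] & st[tr.root_child])) ++total;
    }
  }
  return total;
}

struct BabState {
  int n;                       // total tips
  int nchar;
  const IntegerMatrix* tipmask;
  std::vector<int> parent;     // 1-based slots, 0 = inactive/root
  int best;
  bool hit_cap;
  int max_trees;
  const int* lb_extra;         // indexed by number of placed tips (0..n)
  std::vector<std::vector<int>> optima;
  std::vector<int> scratch;
  long long nodes_visited;
};

static void bab_recurse(BabState& S, int k) {
  int n = S.n;
  if (k == n) {
    int len = fitch_total_partial(S.parent.data(), 2 * n - 2, n, *S.tipmask,
                                  S.scratch);
    if (len < S.best) { S.best = len; S.optima.clear(); S.hit_cap = false; }
    if (len == S.best) {
      if ((int)S.optima.size() < S.max_trees) S.optima.push_back(S.parent);
      else S.hit_cap = true;
    }
    return;
  }
  int t = k + 1;                // tip to insert
  int m = n + t - 2;            // its new internal node
  // edges of the current partial tree: (x, parent[x]) for active non-root x
  std::vector<int> edge_children;
  for (int x = 2; x <= k; ++x) edge_children.push_back(x);
  for (int x = n + 1; x <= n + k - 2; ++x) edge_children.push_back(x);
  for (size_t i = 0; i < edge_children.size(); ++i) {
    int c = edge_children[i];
    int p = S.parent[c - 1];
    S.parent[m - 1] = p;
    S.parent[c - 1] = m;
    S.parent[t - 1] = m;
    ++S.nodes_visited;
    int len = fitch_total_partial(S.parent.data(), 2 * n - 2, n, *S.tipmask,
                                  S.scratch);
    if (len + S.lb_extra[k + 1] <= S.best) bab_recurse(S, k + 1);
    S.parent[c - 1] = p;
    S.parent[m - 1] = 0;
    S.parent[t - 1] = 0;
  }
}

// Exact branch-and-bound over all unrooted binary topologies.  Tips must be
// supplied in the addition order; lb_extra[k] is a lower bound on the extra
// steps that tips k+1..n must add (0 is always valid).  Returns every
// topology attaining the optimum, as parent vectors, up to max_trees.
// [[Rcpp::export]]
List bab_cpp(IntegerMatrix tipmask, IntegerVector lb_extra, int upper_bound,
             int max_trees) {
  int n = tipmask.nrow();
  if (n < 4) stop("branch-and-bound needs at least 4 tips");
  BabState S;
  S.n = n; S.nchar = tipmask.ncol(); S.tipmask = &tipmask;
  S.parent.assign(2 * n - 2, 0);
  S.best = upper_bound;
  S.hit_cap = false;
  S.max_trees = max_trees;
  S.lb_extra = INTEGER(lb_extra);
  S.scratch.assign(2 * n - 1, 0);
  S.nodes_visited = 0;
  // 3-tip start: root tip 1, internal n+1 holds tips 2 and 3
  S.parent[0] = 0;
  S.parent[n] = 1;       // node n+1 -> tip 1
  S.parent[1] = n + 1;
  S.parent[2] = n + 1;
  bab_recurse(S, 3);
  List trees(S.optima.size());
  for (size_t i = 0; i < S.optima.size(); ++i)
    trees[i] = IntegerVector(S.optima[i].begin(), S.optima[i].end());
  return List::create(_["score"] = S.best, _["trees"] = trees,
                      _["hit_cap"] = S.hit_cap,
                      _["nodes_visited"] = (double)S.nodes_visited);
}
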