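#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Shared adjacency structure: bitset rows for O(1) membership tests plus
// plain neighbour lists for iteration.  Vertices are 0-based here; the R
// layer owns the label <-> index mapping.
struct BitGraph {
  int n, words;
  std::vector<uint64_t> bits;
  std::vector<std::vector<int> > adj;

  BitGraph(int n_, const IntegerMatrix& edges) :
    n(n_), words((n_ + 63) / 64),
    bits(static_cast<size_t>(n_) * words, 0ULL), adj(n_) {
    for (int e = 0; e < edges.nrow(); ++e) {
      int u = edges(e, 0), v = edges(e, 1);
      set(u, v); set(v, u);
      adj[u].push_back(v); adj[v].push_back(u);
    }
  }
  inline void set(int u, int v) {
    bits[static_cast<size_t>(u) * words + v / 64] |= (1ULL << (v % 64));
  }
  inline bool has(int u, int v) const {
    return (bits[static_cast<size_t>(u) * words + v / 64] >> (v % 64)) & 1ULL;
  }
};

// [[Rcpp::export]]
IntegerMatrix sample_gnp_cpp(int n, double p) {
  std::vector<int> us, vs;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (unif_rand() < p) { us.push_back(i); vs.push_back(j); }
  IntegerMatrix out(us.size(), 2);
  for (size_t k = 0; k < us.size(); ++k) { out(k, 0) = us[k]; out(k, 1) = vs[k]; }
  return out;
}

// ------------------------------------------------------------------
// Brute force: lexicographic enumeration of k-subsets, k descending.
// The first feasible subset at the largest feasible k is returned, so
// with vertices pre-sorted by label the reported optimum is the
// lexicographically smallest one.  No pruning: this is the oracle.
// ------------------------------------------------------------------
static bool brute_dfs(const BitGraph& g, int k, double req,
                      std::vector<int>& cur, int start, long e,
                      std::vector<int>& degS, std::vector<int>& out) {
  int s = static_cast<int>(cur.size());
  if (s == k) {
    if (static_cast<double>(e) >= req) { out = cur; return true; }
    return false;
  }
  int r = k - s;
  for (int v = start; v <= g.n - r; ++v) {
    int dv = degS[v];
    cur.push_back(v);
    for (int u : g.adj[v]) degS[u]++;
    if (brute_dfs(g, k, req, cur, v + 1, e + dv, degS, out)) return true;
    for (int u : g.adj[v]) degS[u]--;
    cur.pop_back();
  }
  return false;
}

// [[Rcpp::export]]
IntegerVector brute_force_cpp(int n, IntegerMatrix edges, NumericVector req,
                              int k_cap) {
  BitGraph g(n, edges);
  int kmax = std::min(n, k_cap);
  std::vector<int> degS(n, 0), cur, out;
  for (int k = kmax; k >= 2; --k) {
    cur.clear(); out.clear();
    std::fill(degS.begin(), degS.end(), 0);
    if (brute_dfs(g, k, req[k], cur, 0, 0, degS, out))
      return IntegerVector(out.begin(), out.end());
  }
  return IntegerVector::create(0);  // single vertex, always feasible
}

// ------------------------------------------------------------------
// Branch and bound.  For each target size k (ascending; by
// quasi-heredity the feasible sizes form a prefix 1..k_max) run a DFS
// over vertex subsets in descending-degree order.  A partial set S
// (s vertices, e internal edges) with r = k - s vertices still to pick
// from the remaining candidate list is pruned when
//   e + C(r,2) + (sum of the r largest deg-into-S among candidates)
// cannot reach the required edge count.
// ------------------------------------------------------------------
struct BnB {
  const BitGraph& g;
  std::vector<int> order;
  std::vector<int> degS, cur, out;
  double req;
  int k;
  long nodes, max_nodes;
  bool aborted;

  explicit BnB(const BitGraph& g_) : g(g_), degS(g_.n, 0),
    nodes(0), max_nodes(0), aborted(false) {
    order.resize(g.n);
    for (int i = 0; i < g.n; ++i) order[i] = i;
    std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
      return g.adj[a].size() > g.adj[b].size();
    });
  }

  bool dfs(int pos, long e) {
    int s = static_cast<int>(cur.size());
    if (s == k) {
      if (static_cast<double>(e) >= req) { out = cur; return true; }
      return false;
    }
    if (++nodes > max_nodes) { aborted = true; return false; }
    int m = static_cast<int>(order.size());
    int r = k - s;
    if (m - pos < r) return false;
    std::vector<int> ds;
    ds.reserve(m - pos);
    for (int i = pos; i < m; ++i) ds.push_back(degS[order[i]]);
    std::nth_element(ds.begin(), ds.begin() + (r - 1), ds.end(),
                     std::greater<int>());
    long cross = 0;
    for (int i = 0; i < r; ++i) cross += ds[i];
    double ub = static_cast<double>(e) +
      static_cast<double>(r) * (r - 1) / 2.0 + static_cast<double>(cross);
    if (ub < req) return false;
    for (int i = pos; i <= m - r; ++i) {
      int v = order[i];
      int dv = degS[v];
      cur.push_back(v);
      for (int u : g.adj[v]) degS[u]++;
      bool found = dfs(i + 1, e + dv);
      for (int u : g.adj[v]) degS[u]--;
      cur.pop_back();
      if (found) return true;
      if (aborted) return false;
    }
    return false;
  }

  bool feasible(int k_, double req_) {
    k = k_; req = req_;
    cur.clear(); out.clear();
    std::fill(degS.begin(), degS.end(), 0);
    return dfs(0, 0);
  }
};

// [[Rcpp::export]]
List bnb_cpp(int n, IntegerMatrix edges, NumericVector req, double max_nodes) {
  BitGraph g(n, edges);
  BnB bb(g);
  bb.max_nodes = static_cast<long>(max_nodes);
  std::vector<int> best(1, 0);
  long m = edges.nrow();
  bool optimal = true;
  for (int k = 2; k <= n; ++k) {
    if (k == n && static_cast<double>(m) >= req[n]) {
      best.resize(n);
      for (int i = 0; i < n; ++i) best[i] = i;
      break;
    }
    if (bb.feasible(k, req[k])) {
      best = bb.out;
    } else {
      if (bb.aborted) optimal = false;  // search truncated, not proven
      break;
    }
  }
  return List::create(_["subset"] = IntegerVector(best.begin(), best.end()),
                      _["optimal"] = optimal,
                      _["nodes"] = static_cast<double>(bb.nodes));
}

// ------------------------------------------------------------------
// GRASP: multi-start randomized greedy construction + local search.
// Construction builds a full greedy permutation (candidates ranked by
// edges into the current set; the next vertex drawn uniformly from the
// top alpha-fraction) and keeps the largest gamma-feasible prefix.
// Local search: single-vertex adds, and edge-increasing swaps that
// preserve feasibility, until no move applies.
// ------------------------------------------------------------------
static void ls_add_remove(const BitGraph& g, std::vector<char>& in,
                          std::vector<int>& degS, long& e, int v, bool add) {
  if (add) {
    e += degS[v]; in[v] = 1;
    for (int u : g.adj[v]) degS[u]++;
  } else {
    e -= degS[v]; in[v] = 0;
    for (int u : g.adj[v]) degS[u]--;
  }
}

// [[Rcpp::export]]
List grasp_cpp(int n, IntegerMatrix edges, NumericVector req,
               int iterations, double alpha) {
  BitGraph g(n, edges);
  std::vector<int> best;
  long best_e = 0;
  NumericVector trace(iterations);

  std::vector<int> deg(n);          // static degrees: greedy tiebreak
  for (int v = 0; v < n; ++v) deg[v] = static_cast<int>(g.adj[v].size());

  std::vector<int> degS(n), cand(n);
  std::vector<char> in(n);
  std::vector<long> ecum(n);

  for (int it = 0; it < iterations; ++it) {
    // ---- construction ----
    std::fill(degS.begin(), degS.end(), 0);
    int nc = n;
    for (int i = 0; i < n; ++i) cand[i] = i;
    std::vector<int> perm; perm.reserve(n);
    long e = 0;
    while (nc > 0) {
      int top = std::max(1, static_cast<int>(std::ceil(alpha * nc)));
      // partial selection of the `top` candidates with largest degS
      std::nth_element(cand.begin(), cand.begin() + (top - 1),
                       cand.begin() + nc, [&](int a, int b) {
                         if (degS[a] != degS[b]) return degS[a] > degS[b];
                         return deg[a] > deg[b];  // tiebreak: hub first
                       });
      int pick_at = static_cast<int>(unif_rand() * top);
      if (pick_at >= top) pick_at = top - 1;
      int v = cand[pick_at];
      e += degS[v];
      perm.push_back(v);
      ecum[perm.size() - 1] = e;
      for (int u : g.adj[v]) degS[u]++;
      cand[pick_at] = cand[nc - 1];
      --nc;
    }
    int s = 1;  // a single vertex is always feasible (req[1] == 0)
    for (int t = 2; t <= n; ++t)
      if (static_cast<double>(ecum[t - 1]) >= req[t]) s = t;

    // ---- local search on the best feasible prefix ----
    std::fill(in.begin(), in.end(), 0);
    std::fill(degS.begin(), degS.end(), 0);
    e = 0;
    for (int t = 0; t < s; ++t) ls_add_remove(g, in, degS, e, perm[t], true);
    bool moved = true;
    while (moved) {
      moved = false;
      // add move: best outside vertex keeping feasibility at size s+1
      int bv = -1, bd = -1;
      for (int v = 0; v < n; ++v)
        if (!in[v] && degS[v] > bd) { bd = degS[v]; bv = v; }
      if (bv >= 0 && static_cast<double>(e + bd) >= req[s + 1]) {
        ls_add_remove(g, in, degS, e, bv, true);
        ++s; moved = true; continue;
      }
      // swap move: drop the weakest member for the best outsider if the
      // edge count strictly increases and stays feasible
      if (s >= 2) {
        int wu = -1, wd = n + 1;
        for (int v = 0; v < n; ++v)
          if (in[v] && degS[v] < wd) { wd = degS[v]; wu = v; }
        int sv = -1; long se = -1;
        for (int v = 0; v < n; ++v) {
          if (in[v] || v == wu) continue;
          long e2 = e - wd + degS[v] - (g.has(wu, v) ? 1 : 0);
          if (e2 > se) { se = e2; sv = v; }
        }
        if (sv >= 0 && se > e && static_cast<double>(se) >= req[s]) {
          ls_add_remove(g, in, degS, e, wu, false);
          ls_add_remove(g, in, degS, e, sv, true);
          moved = true;
        }
      }
    }
    if (s > static_cast<int>(best.size()) ||
        (s == static_cast<int>(best.size()) && e > best_e)) {
      best.clear();
      for (int v = 0; v < n; ++v) if (in[v]) best.push_back(v);
      best_e = e;
    }
    trace[it] = static_cast<double>(best.size());
  }
  return List::create(_["subset"] = IntegerVector(best.begin(), best.end()),
                      _["trace"] = trace);
}
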