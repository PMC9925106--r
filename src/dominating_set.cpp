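// Exact solvers for (weighted) minimum dominating sets.
//
// Domination is a set-cover problem: node u covers its closed neighborhood
// N[u]. Two routes are provided: exhaustive enumeration over all 2^n subsets
// (n <= 20, used as an oracle) and a branch-and-bound that branches on the
// coverers of an undominated vertex, with a disjoint-neighborhood packing
// lower bound. Variable orderings are fixed so results are deterministic.

#include <Rcpp.h>
#include <chrono>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

typedef std::vector<uint64_t> BS;

static inline void bs_set(BS &b, int i) { b[i >> 6] |= (uint64_t)1 << (i & 63); }
static inline bool bs_get(const BS &b, int i) { return (b[i >> 6] >> (i & 63)) & 1; }
static inline bool bs_empty(const BS &b) {
  for (uint64_t w : b) if (w) return false;
  return true;
}
static inline void bs_or(BS &a, const BS &b) {
  for (size_t k = 0; k < a.size(); ++k) a[k] |= b[k];
}
static inline void bs_andnot(BS &a, const BS &b) {
  for (size_t k = 0; k < a.size(); ++k) a[k] &= ~b[k];
}

// Closed neighborhoods from a 1-based adjacency list.
static std::vector<BS> closed_neighborhoods(const List &adj, int n, int words) {
  std::vector<BS> closed(n, BS(words, 0));
  for (int i = 0; i < n; ++i) {
    bs_set(closed[i], i);
    IntegerVector nb = adj[i];
    for (int j = 0; j < nb.size(); ++j) bs_set(closed[i], nb[j] - 1);
  }
  return closed;
}

// ---------------------------------------------------------------------------
// Exhaustive enumeration, n <= 20.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_brute_force_dominating(List adj, NumericVector weights) {
  const int n = adj.size();
  if (n > 20) stop("brute-force enumeration is limited to 20 nodes");
  if (n == 0) stop("empty graph");

  std::vector<uint32_t> closed(n, 0);
  for (int i = 0; i < n; ++i) {
    closed[i] = (uint32_t)1 << i;
    IntegerVector nb = adj[i];
    for (int j = 0; j < nb.size(); ++j) closed[i] |= (uint32_t)1 << (nb[j] - 1);
  }
  const uint32_t full = (n == 32) ? ~0u : (((uint32_t)1 << n) - 1);
  const uint32_t nsub = (uint32_t)1 << n;

  // cover[s] built incrementally from s without its lowest set bit
  std::vector<uint32_t> cover(nsub, 0);
  int best_card = n + 1;
  double best_w = R_PosInf;
  uint32_t best_w_set = 0;
  std::vector<uint32_t> best_sets;

  for (uint32_t s = 1; s < nsub; ++s) {
    const int low = __builtin_ctz(s);
    cover[s] = cover[s & (s - 1)] | closed[low];
    if (cover[s] != full) continue;
    const int card = __builtin_popcount(s);
    if (card < best_card) {
      best_card = card;
      best_sets.clear();
    }
    if (card == best_card) best_sets.push_back(s);
    double ws = 0.0;
    for (uint32_t t = s; t; t &= t - 1) ws += weights[__builtin_ctz(t)];
    if (ws < best_w - 1e-12) { best_w = ws; best_w_set = s; }
  }

  List opt(best_sets.size());
  for (size_t k = 0; k < best_sets.size(); ++k) {
    IntegerVector v;
    for (uint32_t t = best_sets[k]; t; t &= t - 1) v.push_back(__builtin_ctz(t) + 1);
    opt[k] = v;
  }
  IntegerVector wopt;
  for (uint32_t t = best_w_set; t; t &= t - 1) wopt.push_back(__builtin_ctz(t) + 1);

  return List::create(_["min_cardinality"] = best_card,
                      _["optimal_sets"] = opt,
                      _["min_weight"] = best_w,
                      _["min_weight_set"] = wopt);
}

// ---------------------------------------------------------------------------
// Branch and bound.
// ---------------------------------------------------------------------------

struct BBSolver {
  int n, words;
  std::vector<BS> closed;   // N[i]
  std::vector<BS> twoball;  // nodes whose coverer set can intersect i's
  std::vector<double> w;
  std::vector<int> order;   // node indices sorted by (weight, index)

  double bestW;
  std::vector<int> bestSet, cur;
  long long nodes_explored, node_cap;
  bool timed_out;
  std::chrono::steady_clock::time_point deadline;

  bool time_up() {
    if ((nodes_explored & 1023) == 0 &&
        std::chrono::steady_clock::now() > deadline) timed_out = true;
    if (nodes_explored > node_cap) timed_out = true;
    return timed_out;
  }

  // packing lower bound over undominated set U with banned nodes X
  double lower_bound(const BS &U, const BS &X) {
    double lb = 0.0;
    BS marked(words, 0);
    for (int v = 0; v < n; ++v) {
      if (!bs_get(U, v) || bs_get(marked, v)) continue;
      double mn = R_PosInf;
      const BS &cv = closed[v];
      for (int u = 0; u < n; ++u)
        if (bs_get(cv, u) && !bs_get(X, u) && w[u] < mn) mn = w[u];
      if (!R_finite(mn)) return R_PosInf;  // v cannot be dominated
      lb += mn;
      bs_or(marked, twoball[v]);
    }
    return lb;
  }

  void recurse(const BS &U, BS X, double curW) {
    ++nodes_explored;
    if (timed_out || time_up()) return;
    if (bs_empty(U)) {
      if (curW < bestW - 1e-12) { bestW = curW; bestSet = cur; }
      return;
    }
    if (curW + lower_bound(U, X) >= bestW - 1e-12) return;

    // branch vertex: undominated v with fewest available coverers
    int bv = -1, bcnt = n + 1;
    for (int v = 0; v < n; ++v) {
      if (!bs_get(U, v)) continue;
      int c = 0;
      for (int u = 0; u < n && c < bcnt; ++u)
        if (bs_get(closed[v], u) && !bs_get(X, u)) ++c;
      if (c < bcnt) { bcnt = c; bv = v; }
    }
    if (bv < 0 || bcnt == 0) return;  // infeasible branch

    // coverers in fixed (weight, index) order; each branch bans the earlier ones
    for (int oi = 0; oi < n; ++oi) {
      int u = order[oi];
      if (!bs_get(closed[bv], u) || bs_get(X, u)) continue;
      BS U2 = U;
      bs_andnot(U2, closed[u]);
      cur.push_back(u);
      recurse(U2, X, curW + w[u]);
      cur.pop_back();
      if (timed_out) return;
      bs_set(X, u);  // subsequent branches exclude u
    }
  }
};

// [[Rcpp::export]]
List cpp_bb_wmds(List adj, NumericVector weights, IntegerVector init_set,
                 double init_obj, double time_limit, double node_cap) {
  const int n = adj.size();
  if (n == 0) stop("empty graph");
  BBSolver S;
  S.n = n;
  S.words = (n + 63) / 64;
  S.closed = closed_neighborhoods(adj, n, S.words);
  S.twoball.assign(n, BS(S.words, 0));
  for (int v = 0; v < n; ++v)
    for (int u = 0; u < n; ++u)
      if (bs_get(S.closed[v], u)) bs_or(S.twoball[v], S.closed[u]);
  S.w.assign(weights.begin(), weights.end());
  S.order.resize(n);
  for (int i = 0; i < n; ++i) S.order[i] = i;
  std::sort(S.order.begin(), S.order.end(), [&](int a, int b) {
    if (S.w[a] != S.w[b]) return S.w[a] < S.w[b];
    return a < b;
  });

  S.bestW = init_obj;
  S.bestSet.assign(init_set.begin(), init_set.end());
  for (int &i : S.bestSet) --i;
  S.nodes_explored = 0;
  S.node_cap = (long long)node_cap;
  S.timed_out = false;
  S.deadline = std::chrono::steady_clock::now() +
    std::chrono::milliseconds((long long)(time_limit * 1000.0));

  BS U(S.words, 0), X(S.words, 0);
  for (int i = 0; i < n; ++i) bs_set(U, i);
  S.recurse(U, X, 0.0);

  IntegerVector sel(S.bestSet.size());
  for (size_t k = 0; k < S.bestSet.size(); ++k) sel[k] = S.bestSet[k] + 1;
  double obj = 0.0;
  for (int i : S.bestSet) obj += S.w[i];
  return List::create(_["set"] = sel,
                      _["objective"] = obj,
                      _["optimal"] = !S.timed_out,
                      _["nodes_explored"] = (double)S.nodes_explored);
}
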