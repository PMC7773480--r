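// Network simplex solver for the minimum-cost maximum-flow matching step.
//
// Solves a min-cost b-flow on a directed graph with integer capacities and
// costs.  The implementation follows the classical primal network simplex
// with a spanning-tree basis, block pivot search, and the leaving-arc
// tie-break that keeps the basis strongly feasible.  Tree updates use
// child/sibling linked lists with an evert of the reattached subtree.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

typedef long long ll;
const ll LL_INF = (ll)4e18;

struct NetSimplex {
  int V;              // user nodes
  int N;              // V + 1 (artificial root)
  int root;
  int M;              // user arcs
  int A;              // M + V (artificial arcs)

  std::vector<int> tail, head;
  std::vector<ll> cap, flow, cost;
  std::vector<int> state;        // 1 lower, 0 tree, -1 upper

  std::vector<int> parent, parc, depth;
  std::vector<ll> pi;
  std::vector<int> firstChild, nextSib, prevSib;
  std::vector<ll> subSize;

  int in_arc, join, u_out, side_out; // side_out: 0 in-arc leaves, 1 side a, 2 side b
  ll delta;

  NetSimplex(int nV, const IntegerVector& t, const IntegerVector& h,
             const NumericVector& cp, const NumericVector& cs,
             const NumericVector& supply) {
    V = nV; N = V + 1; root = V;
    M = t.size(); A = M + V;
    tail.resize(A); head.resize(A); cap.resize(A); flow.assign(A, 0);
    cost.resize(A); state.assign(A, 1);

    ll maxc = 1;
    for (int a = 0; a < M; ++a) {
      tail[a] = t[a]; head[a] = h[a];
      cap[a] = (ll)cp[a]; cost[a] = (ll)cs[a];
      ll c = cost[a] < 0 ? -cost[a] : cost[a];
      if (c > maxc) maxc = c;
    }
    ll BIG = maxc * (ll)(N + 1) + 1;

    parent.assign(N, -1); parc.assign(N, -1); depth.assign(N, 0);
    pi.assign(N, 0);
    firstChild.assign(N, -1); nextSib.assign(N, -1); prevSib.assign(N, -1);
    subSize.assign(N, 1);

    // artificial star tree
    for (int v = 0; v < V; ++v) {
      int a = M + v;
      ll b = (ll)supply[v];
      if (b >= 0) { tail[a] = v; head[a] = root; flow[a] = b; pi[v] = -BIG; }
      else        { tail[a] = root; head[a] = v; flow[a] = -b; pi[v] = BIG; }
      cap[a] = LL_INF; cost[a] = BIG; state[a] = 0;
      parent[v] = root; parc[v] = a; depth[v] = 1;
      attachChild(root, v);
    }
    subSize[root] = N;
  }

  void attachChild(int p, int c) {
    prevSib[c] = -1; nextSib[c] = firstChild[p];
    if (firstChild[p] >= 0) prevSib[firstChild[p]] = c;
    firstChild[p] = c;
  }
  void detachChild(int p, int c) {
    if (prevSib[c] >= 0) nextSib[prevSib[c]] = nextSib[c];
    else firstChild[p] = nextSib[c];
    if (nextSib[c] >= 0) prevSib[nextSib[c]] = prevSib[c];
    prevSib[c] = nextSib[c] = -1;
  }

  inline ll redCost(int a) const { return cost[a] + pi[tail[a]] - pi[head[a]]; }
  inline bool arcUp(int u) const { return tail[parc[u]] == u; } // pred arc oriented u -> parent

  // block pivot search
  int next_arc = 0, block_size;
  bool findEnteringArc() {
    ll best = 0; int best_arc = -1;
    int cnt = block_size;
    for (int a = next_arc; a < A; ++a) {
      ll c = (ll)state[a] * redCost(a);
      if (c < best) { best = c; best_arc = a; }
      if (--cnt == 0) {
        if (best < 0) { in_arc = best_arc; next_arc = a + 1; return true; }
        cnt = block_size;
      }
    }
    for (int a = 0; a < next_arc; ++a) {
      ll c = (ll)state[a] * redCost(a);
      if (c < best) { best = c; best_arc = a; }
      if (--cnt == 0) {
        if (best < 0) { in_arc = best_arc; next_arc = a + 1; return true; }
        cnt = block_size;
      }
    }
    if (best < 0) { in_arc = best_arc; next_arc = 0; return true; }
    return false;
  }

  void findJoin(int a_end, int b_end) {
    int u = a_end, v = b_end;
    while (u != v) {
      if (depth[u] > depth[v]) u = parent[u];
      else if (depth[v] > depth[u]) v = parent[v];
      else { u = parent[u]; v = parent[v]; }
    }
    join = u;
  }

  // returns false if unbounded (cannot happen with finite user caps)
  void findLeavingArc(int a_end, int b_end) {
    delta = (state[in_arc] == 1) ? cap[in_arc] - flow[in_arc] : flow[in_arc];
    side_out = 0; u_out = -1;
    for (int u = a_end; u != join; u = parent[u]) {
      int e = parc[u];
      ll d = arcUp(u) ? flow[e] : (cap[e] >= LL_INF ? LL_INF : cap[e] - flow[e]);
      if (d < delta) { delta = d; u_out = u; side_out = 1; }
    }
    for (int u = b_end; u != join; u = parent[u]) {
      int e = parc[u];
      ll d = arcUp(u) ? (cap[e] >= LL_INF ? LL_INF : cap[e] - flow[e]) : flow[e];
      if (d <= delta) { delta = d; u_out = u; side_out = 2; }
    }
  }

  void augment(int a_end, int b_end) {
    if (delta <= 0) return;
    ll val = (ll)state[in_arc] * delta;
    flow[in_arc] += val;
    for (int u = a_end; u != join; u = parent[u])
      flow[parc[u]] += arcUp(u) ? -delta : delta;
    for (int u = b_end; u != join; u = parent[u])
      flow[parc[u]] += arcUp(u) ? delta : -delta;
  }

  // re-root subtree of w at node r_new (on path from r_new up to w), then
  // hang r_new under its new parent via in_arc
  void reattach(int w, int r_new, int outside) {
    int old_par = parent[w];
    ll sz = subSize[w];
    detachChild(old_par, w);
    // shrink old ancestors
    for (int u = old_par; u != -1; u = parent[u]) subSize[u] -= sz;
    // evert the path r_new .. w so the subtree is rooted at r_new
    std::vector<int> chain;
    for (int u = r_new; ; u = parent[u]) { chain.push_back(u); if (u == w) break; }
    int k = (int)chain.size() - 1;
    std::vector<int> ca(k);
    for (int i = 0; i < k; ++i) ca[i] = parc[chain[i]];
    for (int i = 0; i < k; ++i) detachChild(chain[i + 1], chain[i]);
    for (int i = 0; i < k; ++i) {
      parent[chain[i + 1]] = chain[i];
      parc[chain[i + 1]] = ca[i];
      attachChild(chain[i], chain[i + 1]);
    }
    parent[r_new] = outside; parc[r_new] = in_arc;
    attachChild(outside, r_new);
    for (int x = outside; x != -1; x = parent[x]) subSize[x] += sz;
    // recompute pi, depth, subSize inside the moved subtree
    refresh(r_new);
  }

  void refresh(int r_new) {
    // iterative DFS: set pi/depth pre-order, subSize post-order
    int par = parent[r_new];
    int e = parc[r_new];
    pi[r_new] = (tail[e] == r_new) ? pi[par] - cost[e] : pi[par] + cost[e];
    depth[r_new] = depth[par] + 1;
    std::vector<int> stack; stack.push_back(r_new);
    std::vector<int> order; order.reserve(64);
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      order.push_back(u);
      for (int c = firstChild[u]; c >= 0; c = nextSib[c]) {
        int g = parc[c];
        pi[c] = (tail[g] == c) ? pi[u] - cost[g] : pi[u] + cost[g];
        depth[c] = depth[u] + 1;
        stack.push_back(c);
      }
    }
    for (int i = (int)order.size() - 1; i >= 0; --i) {
      int u = order[i];
      ll s = 1;
      for (int c = firstChild[u]; c >= 0; c = nextSib[c]) s += subSize[c];
      subSize[u] = s;
    }
  }

  bool pivot() {
    if (!findEnteringArc()) return false;
    int a_end, b_end;
    if (state[in_arc] == 1) { a_end = tail[in_arc]; b_end = head[in_arc]; }
    else                    { a_end = head[in_arc]; b_end = tail[in_arc]; }
    findJoin(tail[in_arc], head[in_arc]);
    findLeavingArc(a_end, b_end);
    if (delta >= LL_INF) stop("unbounded flow problem");
    augment(a_end, b_end);
    if (side_out == 0) {
      state[in_arc] = -state[in_arc];
    } else {
      int w = u_out;
      int out_arc = parc[w];
      int r_new = (side_out == 1) ? a_end : b_end;
      int outside = (side_out == 1) ? b_end : a_end;
      state[out_arc] = (flow[out_arc] == 0) ? 1 : -1;
      state[in_arc] = 0;
      reattach(w, r_new, outside);
    }
    return true;
  }

  bool run() {
    block_size = (int)std::ceil(std::sqrt((double)A));
    if (block_size < 10) block_size = 10;
    long long guard = 0, guard_max = 2000LL * A + 10000000LL;
    while (pivot()) {
      if (++guard > guard_max)
        stop("network simplex exceeded pivot limit (degenerate cycling?)");
    }
    // feasible iff artificial arcs carry no flow
    for (int v = 0; v < V; ++v) if (flow[M + v] != 0) return false;
    return true;
  }
};

} // namespace

// [[Rcpp::export(name = ".Call_network_simplex")]]
List network_simplex_cpp(int n_nodes, IntegerVector tail, IntegerVector head,
                         NumericVector cap, NumericVector cost,
                         NumericVector supply) {
  if (tail.size() != head.size() || tail.size() != cap.size() ||
      tail.size() != cost.size())
    stop("arc vectors must have equal length");
  if (supply.size() != n_nodes) stop("supply must have one entry per node");
  for (int i = 0; i < tail.size(); ++i) {
    if (tail[i] < 0 || tail[i] >= n_nodes || head[i] < 0 || head[i] >= n_nodes)
      stop("arc endpoint out of range");
    if (cap[i] < 0) stop("negative capacity");
  }
  double bsum = 0;
  for (int i = 0; i < n_nodes; ++i) bsum += supply[i];
  if (std::fabs(bsum) > 1e-9) stop("supplies must sum to zero");

  NetSimplex ns(n_nodes, tail, head, cap, cost, supply);
  bool feasible = ns.run();

  NumericVector fl(tail.size());
  double total = 0;
  for (int a = 0; a < tail.size(); ++a) {
    fl[a] = (double)ns.flow[a];
    total += (double)ns.flow[a] * (double)ns.cost[a];
  }
  return List::create(_["flow"] = fl, _["cost"] = total,
                      _["feasible"] = feasible);
}
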