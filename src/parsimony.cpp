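// Compact maximum-parsimony engine.
//
// Trees are unrooted binary topologies over taxa 0..n-1 (matrix row order),
// internal nodes n..2n-3, passed around as 0-based edge lists. Character
// states are bitmasks (missing = full alphabet mask), so Fitch optimisation
// is a pair of AND/OR sweeps per node, vectorised across characters.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <string>
#include <random>
#include <functional>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

typedef std::pair<int, int> Edge;
typedef std::vector<Edge> EdgeList;

static const double EPS = 1e-9;

struct FitchEngine {
  int n, nchar;
  std::vector<int> states;  // row-major n x nchar bitmasks
  std::vector<double> w;
  // workspace
  std::vector<std::array<int, 3>> adj;
  std::vector<int> deg, post, parent, buf, stk;

  FitchEngine(const IntegerMatrix& S, const NumericVector& W) {
    n = S.nrow();
    nchar = S.ncol();
    states.resize((size_t)n * nchar);
    for (int t = 0; t < n; ++t)
      for (int c = 0; c < nchar; ++c) states[(size_t)t * nchar + c] = S(t, c);
    w.assign(W.begin(), W.end());
    int m = 2 * n - 2;
    adj.resize(m);
    deg.assign(m, 0);
    parent.assign(m, -1);
    post.reserve(m);
    buf.resize((size_t)m * nchar);
  }

  void set_weights(const NumericVector& W) { w.assign(W.begin(), W.end()); }

  void build_adj(const EdgeList& edges) {
    std::fill(deg.begin(), deg.end(), 0);
    for (const Edge& e : edges) {
      adj[e.first][deg[e.first]++] = e.second;
      adj[e.second][deg[e.second]++] = e.first;
    }
  }

  // Postorder from an internal root; fills `post` (preorder) and `parent`.
  void traverse() {
    int m = 2 * n - 2, root = -1;
    for (int v = 0; v < m; ++v)
      if (deg[v] > 1) { root = v; break; }
    post.clear();
    if (root < 0) return;
    stk.clear();
    stk.push_back(root);
    parent[root] = -1;
    while (!stk.empty()) {
      int v = stk.back();
      stk.pop_back();
      post.push_back(v);
      for (int i = 0; i < deg[v]; ++i) {
        int u = adj[v][i];
        if (u != parent[v]) {
          parent[u] = v;
          stk.push_back(u);
        }
      }
    }
  }

  double length(const EdgeList& edges) {
    build_adj(edges);
    traverse();
    double total = 0.0;
    for (int i = (int)post.size() - 1; i >= 0; --i) {
      int v = post[i];
      int* out = &buf[(size_t)v * nchar];
      if (v < n) {
        std::copy(states.begin() + (size_t)v * nchar,
                  states.begin() + (size_t)(v + 1) * nchar, out);
        continue;
      }
      bool first = true;
      for (int k = 0; k < deg[v]; ++k) {
        int u = adj[v][k];
        if (u == parent[v]) continue;
        const int* cu = &buf[(size_t)u * nchar];
        if (first) {
          std::copy(cu, cu + nchar, out);
          first = false;
        } else {
          for (int c = 0; c < nchar; ++c) {
            int inter = out[c] & cu[c];
            if (inter) {
              out[c] = inter;
            } else {
              out[c] |= cu[c];
              total += w[c];
            }
          }
        }
      }
    }
    return total;
  }
};

// Canonical topology key: sorted list of per-edge leaf bipartition masks,
// each complemented so taxon 0 lies outside the mask. Independent of node
// numbering and edge order.
static std::string tree_key(const EdgeList& edges, int n) {
  int m = 2 * n - 2;
  std::vector<std::vector<int>> adj(m);
  for (const Edge& e : edges) {
    adj[e.first].push_back(e.second);
    adj[e.second].push_back(e.first);
  }
  uint64_t full = (n == 64) ? ~0ULL : ((1ULL << n) - 1);
  std::vector<uint64_t> masks;
  // subtree mask below each directed edge via DFS per edge (n is small)
  for (const Edge& e : edges) {
    // mask of leaves on e.second side
    uint64_t mk = 0;
    std::vector<int> stk{e.second};
    std::vector<int> par(m, -2);
    par[e.second] = e.first;
    while (!stk.empty()) {
      int v = stk.back();
      stk.pop_back();
      if (v < n) mk |= (1ULL << v);
      for (int u : adj[v])
        if (u != par[v]) {
          par[u] = v;
          stk.push_back(u);
        }
    }
    if (mk & 1ULL) mk = full & ~mk;
    masks.push_back(mk);
  }
  std::sort(masks.begin(), masks.end());
  std::string key;
  key.reserve(masks.size() * 8);
  for (uint64_t mk : masks)
    for (int b = 0; b < 8; ++b) key.push_back((char)((mk >> (8 * b)) & 0xFF));
  return key;
}

static EdgeList mat_to_edges(const IntegerMatrix& E) {
  EdgeList edges;
  for (int i = 0; i < E.nrow(); ++i) edges.push_back({E(i, 0), E(i, 1)});
  return edges;
}

static IntegerMatrix edges_to_mat(const EdgeList& edges) {
  IntegerMatrix E(edges.size(), 2);
  for (size_t i = 0; i < edges.size(); ++i) {
    E(i, 0) = edges[i].first;
    E(i, 1) = edges[i].second;
  }
  return E;
}

// [[Rcpp::export]]
double cpp_tree_length(IntegerMatrix S, NumericVector W, IntegerMatrix E) {
  FitchEngine eng(S, W);
  return eng.length(mat_to_edges(E));
}

// [[Rcpp::export]]
List cpp_exhaustive_mp(IntegerMatrix S, NumericVector W, int maxtrees = 10000) {
  int n = S.nrow();
  if (n < 4 || n > 9) stop("exhaustive search supports 4 to 9 taxa");
  FitchEngine eng(S, W);
  EdgeList edges = {{0, n}, {1, n}, {2, n}};
  double best = R_PosInf;
  long count = 0;
  std::vector<EdgeList> besttrees;
  std::function<void(int)> rec = [&](int k) {
    if (k == n) {
      ++count;
      double L = eng.length(edges);
      if (L < best - EPS) {
        best = L;
        besttrees.clear();
      }
      if (L < best + EPS && (int)besttrees.size() < maxtrees)
        besttrees.push_back(edges);
      return;
    }
    int wnode = n + (k - 2);
    size_t ne = edges.size();
    for (size_t e = 0; e < ne; ++e) {
      Edge old = edges[e];
      edges[e] = {old.first, wnode};
      edges.push_back({wnode, old.second});
      edges.push_back({wnode, k});
      rec(k + 1);
      edges.pop_back();
      edges.pop_back();
      edges[e] = old;
    }
  };
  rec(3);
  List trees(besttrees.size());
  for (size_t i = 0; i < besttrees.size(); ++i) trees[i] = edges_to_mat(besttrees[i]);
  return List::create(_["length"] = best, _["trees"] = trees,
                      _["n_topologies"] = (double)count);
}

// Enumerate SPR (or NNI) neighbours of `edges`, invoking cb on each.
static void for_neighbors(const EdgeList& edges, int n, bool spr,
                          const std::function<void(const EdgeList&)>& cb) {
  int m = 2 * n - 2;
  std::vector<std::vector<int>> adj(m);
  for (const Edge& e : edges) {
    adj[e.first].push_back(e.second);
    adj[e.second].push_back(e.first);
  }
  if (!spr) {
    // NNI on internal edges
    for (const Edge& e : edges) {
      int u = e.first, v = e.second;
      if (adj[u].size() != 3 || adj[v].size() != 3) continue;
      int A = -1, B = -1, C = -1, D = -1;
      for (int x : adj[u])
        if (x != v) (A < 0 ? A : B) = x;
      for (int x : adj[v])
        if (x != u) (C < 0 ? C : D) = x;
      for (int pass = 0; pass < 2; ++pass) {
        int swapv = (pass == 0) ? C : D;
        EdgeList ne;
        for (const Edge& f : edges) {
          Edge g = f;
          if ((g.first == u && g.second == B) || (g.first == B && g.second == u))
            g = {u, swapv};
          else if ((g.first == v && g.second == swapv) ||
                   (g.first == swapv && g.second == v))
            g = {v, B};
          ne.push_back(g);
        }
        cb(ne);
      }
    }
    return;
  }
  // SPR: for each directed edge (a, b) with a internal, prune the b-side
  // subtree, suppress a, regraft on every remaining edge.
  for (const Edge& e0 : edges) {
    for (int dir = 0; dir < 2; ++dir) {
      int a = dir ? e0.second : e0.first;
      int b = dir ? e0.first : e0.second;
      if (adj[a].size() != 3) continue;
      // subtree on b's side
      std::vector<char> inS(m, 0);
      std::vector<int> stk{b};
      inS[b] = 1;
      std::vector<int> par(m, -2);
      par[b] = a;
      while (!stk.empty()) {
        int v = stk.back();
        stk.pop_back();
        for (int u : adj[v])
          if (u != par[v]) {
            par[u] = v;
            inS[u] = 1;
            stk.push_back(u);
          }
      }
      int x = -1, y = -1;
      for (int z : adj[a])
        if (z != b) (x < 0 ? x : y) = z;
      for (const Edge& t : edges) {
        int p = t.first, q = t.second;
        if (inS[p] || inS[q] || p == a || q == a) continue;
        // (p,q) lives in the remaining tree; regrafting onto it
        EdgeList ne;
        for (const Edge& f : edges) {
          bool drop = (f.first == a || f.second == a) ||
                      ((f.first == p && f.second == q) ||
                       (f.first == q && f.second == p));
          if (!drop) ne.push_back(f);
        }
        ne.push_back({x, y});
        ne.push_back({p, a});
        ne.push_back({a, q});
        ne.push_back({a, b});
        cb(ne);
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_heuristic_mp(IntegerMatrix S, NumericVector W, int n_add, bool spr,
                      int seed, bool collect_trees, int maxtrees = 1000) {
  int n = S.nrow();
  if (n < 4) stop("need at least 4 taxa");
  if (n > 64) stop("at most 64 taxa supported");
  FitchEngine eng(S, W);
  std::mt19937 rng((uint32_t)seed);
  double best = R_PosInf;
  std::map<std::string, EdgeList> bestset;

  auto consider = [&](const EdgeList& tr, double L) {
    if (L < best - EPS) {
      best = L;
      bestset.clear();
    }
    if (collect_trees && L < best + EPS && (int)bestset.size() < maxtrees)
      bestset.emplace(tree_key(tr, n), tr);
  };

  for (int rep = 0; rep < n_add; ++rep) {
    // random addition order
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    for (int i = n - 1; i > 0; --i) std::swap(ord[i], ord[rng() % (i + 1)]);
    EdgeList cur = {{ord[0], n}, {ord[1], n}, {ord[2], n}};
    for (int k = 3; k < n; ++k) {
      int leaf = ord[k], wnode = n + (k - 2);
      double bl = R_PosInf;
      std::vector<size_t> ties;
      size_t ne = cur.size();
      for (size_t e = 0; e < ne; ++e) {
        Edge old = cur[e];
        cur[e] = {old.first, wnode};
        cur.push_back({wnode, old.second});
        cur.push_back({wnode, leaf});
        double L = eng.length(cur);
        cur.pop_back();
        cur.pop_back();
        cur[e] = old;
        if (L < bl - EPS) {
          bl = L;
          ties.clear();
        }
        if (L < bl + EPS) ties.push_back(e);
      }
      size_t pick = ties[rng() % ties.size()];
      Edge old = cur[pick];
      cur[pick] = {old.first, wnode};
      cur.push_back({wnode, old.second});
      cur.push_back({wnode, leaf});
    }
    double curL = eng.length(cur);
    // branch swapping to convergence
    bool improved = true;
    while (improved) {
      improved = false;
      double bestNL = curL;
      std::vector<EdgeList> argmin;
      for_neighbors(cur, n, spr, [&](const EdgeList& ne) {
        double L = eng.length(ne);
        if (L < bestNL - EPS) {
          bestNL = L;
          argmin.clear();
        }
        if (L < bestNL + EPS && bestNL < curL - EPS && argmin.size() < 64)
          argmin.push_back(ne);
      });
      if (bestNL < curL - EPS) {
        cur = argmin[rng() % argmin.size()];
        curL = bestNL;
        improved = true;
      }
    }
    consider(cur, curL);
    if (collect_trees && curL < best + EPS) {
      // equal-length neighbours of the local optimum (MULTREES-style ties)
      for_neighbors(cur, n, spr, [&](const EdgeList& ne) {
        if ((int)bestset.size() >= maxtrees) return;
        double L = eng.length(ne);
        if (L < best + EPS) bestset.emplace(tree_key(ne, n), ne);
      });
    }
  }
  List trees(bestset.size());
  int i = 0;
  for (auto& kv : bestset) trees[i++] = edges_to_mat(kv.second);
  return List::create(_["length"] = best, _["trees"] = trees);
}

// Leaf bipartition masks (canonicalised, internal edges only), for split
// support tabulation in R. Requires n <= 53 so masks are exact doubles.
// [[Rcpp::export]]
NumericVector cpp_tree_splits(IntegerMatrix E, int n) {
  EdgeList edges = mat_to_edges(E);
  int m = 2 * n - 2;
  std::vector<std::vector<int>> adj(m);
  for (const Edge& e : edges) {
    adj[e.first].push_back(e.second);
    adj[e.second].push_back(e.first);
  }
  uint64_t full = (1ULL << n) - 1;
  std::vector<double> out;
  for (const Edge& e : edges) {
    if (e.first < n || e.second < n) continue;  // trivial split
    uint64_t mk = 0;
    std::vector<int> stk{e.second};
    std::vector<int> par(m, -2);
    par[e.second] = e.first;
    while (!stk.empty()) {
      int v = stk.back();
      stk.pop_back();
      if (v < n) mk |= (1ULL << v);
      for (int u : adj[v])
        if (u != par[v]) {
          par[u] = v;
          stk.push_back(u);
        }
    }
    if (mk & 1ULL) mk = full & ~mk;
    out.push_back((double)mk);
  }
  return wrap(out);
}
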