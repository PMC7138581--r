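#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<std::vector<int> > AdjList;

static AdjList to_adjlist(const IntegerMatrix &A) {
  int n = A.nrow();
  AdjList al(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && A(i, j) != 0) al[i].push_back(j);
  return al;
}

// single-source BFS hop distances; dist = -1 marks unreachable
static void bfs_row(const AdjList &al, int src, std::vector<int> &dist,
                    std::vector<int> &queue) {
  std::fill(dist.begin(), dist.end(), -1);
  dist[src] = 0;
  queue.clear();
  queue.push_back(src);
  for (size_t qi = 0; qi < queue.size(); ++qi) {
    int u = queue[qi];
    for (size_t vi = 0; vi < al[u].size(); ++vi) {
      int v = al[u][vi];
      if (dist[v] < 0) {
        dist[v] = dist[u] + 1;
        queue.push_back(v);
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_bfs_distances(IntegerMatrix adj) {
  int n = adj.nrow();
  AdjList al = to_adjlist(adj);
  NumericMatrix D(n, n);
  std::vector<int> dist(n);
  std::vector<int> queue;
  queue.reserve(n);
  for (int i = 0; i < n; ++i) {
    bfs_row(al, i, dist, queue);
    for (int j = 0; j < n; ++j)
      D(i, j) = dist[j] < 0 ? R_PosInf : (double)dist[j];
  }
  return D;
}

static double clustering_node(const IntegerMatrix &adj,
                              const std::vector<int> &nbrs) {
  int k = (int)nbrs.size();
  if (k < 2) return 0.0;
  int e = 0;
  for (int a = 0; a < k; ++a)
    for (int b = a + 1; b < k; ++b)
      if (adj(nbrs[a], nbrs[b]) != 0) ++e;
  return 2.0 * e / ((double)k * (k - 1));
}

// [[Rcpp::export]]
NumericVector cpp_clustering(IntegerMatrix adj) {
  int n = adj.nrow();
  AdjList al = to_adjlist(adj);
  NumericVector C(n);
  for (int i = 0; i < n; ++i) C[i] = clustering_node(adj, al[i]);
  return C;
}

// global efficiency of the subgraph induced by `nodes` (indices into adj)
static double sub_efficiency(const IntegerMatrix &adj,
                             const std::vector<int> &nodes) {
  int m = (int)nodes.size();
  if (m < 2) return 0.0;
  AdjList sal(m);
  for (int a = 0; a < m; ++a)
    for (int b = 0; b < m; ++b)
      if (a != b && adj(nodes[a], nodes[b]) != 0) sal[a].push_back(b);
  std::vector<int> dist(m);
  std::vector<int> queue;
  queue.reserve(m);
  double s = 0.0;
  for (int a = 0; a < m; ++a) {
    bfs_row(sal, a, dist, queue);
    for (int b = 0; b < m; ++b)
      if (b != a && dist[b] > 0) s += 1.0 / dist[b];
  }
  return s / ((double)m * (m - 1));
}

// [[Rcpp::export]]
NumericVector cpp_local_efficiency(IntegerMatrix adj) {
  int n = adj.nrow();
  AdjList al = to_adjlist(adj);
  NumericVector E(n);
  for (int i = 0; i < n; ++i) E[i] = sub_efficiency(adj, al[i]);
  return E;
}

// deterministic unbiased-enough index draw (Lemire reduction)
static inline int rand_index(std::mt19937 &rng, int n) {
  return (int)(((uint64_t)rng() * (uint64_t)n) >> 32);
}

struct EdgeGraph {
  int n;
  std::vector<std::pair<int, int> > edges; // i < j
  std::vector<char> has;                   // n*n adjacency flags

  void init(const IntegerMatrix &adj) {
    n = adj.nrow();
    edges.clear();
    has.assign((size_t)n * n, 0);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (adj(i, j) != 0) {
          edges.push_back(std::make_pair(i, j));
          has[(size_t)i * n + j] = has[(size_t)j * n + i] = 1;
        }
  }

  // Maslov-Sneppen double-edge swaps: pick (a,b),(c,d) with all four nodes
  // distinct, propose (a,d),(c,b), accept iff neither proposed edge exists.
  // Each picked edge gets a random orientation; without it the chain is not
  // reversible and the null ensemble's clustering is visibly biased.
  void rewire(std::mt19937 &rng, long attempts) {
    int E = (int)edges.size();
    if (E < 2) return;
    for (long t = 0; t < attempts; ++t) {
      int e1 = rand_index(rng, E), e2 = rand_index(rng, E);
      if (e1 == e2) continue;
      int a = edges[e1].first, b = edges[e1].second;
      if (rng() & 1u) std::swap(a, b);
      int c = edges[e2].first, d = edges[e2].second;
      if (rng() & 1u) std::swap(c, d);
      if (a == c || a == d || b == c || b == d) continue;
      if (has[(size_t)a * n + d] || has[(size_t)c * n + b]) continue;
      has[(size_t)a * n + b] = has[(size_t)b * n + a] = 0;
      has[(size_t)c * n + d] = has[(size_t)d * n + c] = 0;
      has[(size_t)a * n + d] = has[(size_t)d * n + a] = 1;
      has[(size_t)c * n + b] = has[(size_t)b * n + c] = 1;
      edges[e1] = std::make_pair(std::min(a, d), std::max(a, d));
      edges[e2] = std::make_pair(std::min(c, b), std::max(c, b));
    }
  }

  AdjList adjlist() const {
    AdjList al(n);
    for (size_t e = 0; e < edges.size(); ++e) {
      al[edges[e].first].push_back(edges[e].second);
      al[edges[e].second].push_back(edges[e].first);
    }
    return al;
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_rewire(IntegerMatrix adj, double swaps_per_edge, int seed) {
  EdgeGraph g;
  g.init(adj);
  std::mt19937 rng((uint32_t)seed);
  long attempts = (long)std::floor(swaps_per_edge * (double)g.edges.size() + 0.5);
  g.rewire(rng, attempts);
  int n = g.n;
  IntegerMatrix out(n, n);
  for (size_t e = 0; e < g.edges.size(); ++e) {
    out(g.edges[e].first, g.edges[e].second) = 1;
    out(g.edges[e].second, g.edges[e].first) = 1;
  }
  return out;
}

// Cp (mean clustering, zero for degree<2) and Lp (mean over finite pairs)
static void graph_cp_lp(const EdgeGraph &g, double &cp, double &lp) {
  int n = g.n;
  AdjList al = g.adjlist();
  double csum = 0.0;
  for (int i = 0; i < n; ++i) {
    int k = (int)al[i].size();
    if (k < 2) continue;
    int e = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (g.has[(size_t)al[i][a] * n + al[i][b]]) ++e;
    csum += 2.0 * e / ((double)k * (k - 1));
  }
  cp = csum / n;
  std::vector<int> dist(n);
  std::vector<int> queue;
  queue.reserve(n);
  double dsum = 0.0;
  long npairs = 0;
  for (int i = 0; i < n; ++i) {
    bfs_row(al, i, dist, queue);
    for (int j = i + 1; j < n; ++j)
      if (dist[j] > 0) {
        dsum += dist[j];
        ++npairs;
      }
  }
  lp = npairs > 0 ? dsum / npairs : R_NaReal;
}

// M degree-preserving nulls, one RNG substream per null (seeds[m]);
// returns M x 2 matrix of (Cp, Lp)
// [[Rcpp::export]]
NumericMatrix cpp_null_ensemble(IntegerMatrix adj, double swaps_per_edge,
                                IntegerVector seeds) {
  int M = seeds.size();
  NumericMatrix out(M, 2);
  EdgeGraph base;
  base.init(adj);
  long attempts = (long)std::floor(swaps_per_edge * (double)base.edges.size() + 0.5);
  for (int m = 0; m < M; ++m) {
    EdgeGraph g = base;
    std::mt19937 rng((uint32_t)seeds[m]);
    g.rewire(rng, attempts);
    double cp, lp;
    graph_cp_lp(g, cp, lp);
    out(m, 0) = cp;
    out(m, 1) = lp;
  }
  return out;
}
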