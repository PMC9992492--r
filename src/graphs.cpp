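#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Edges of the l-step accessibility graph: (v -> w) iff 1 <= d(v, w) <= ell
// and v != w, by truncated BFS from every node. Node ids are 1-based.
// [[Rcpp::export]]
List cpp_access_edges(int n, IntegerVector from, IntegerVector to, int ell) {
  int m = from.size();
  std::vector<std::vector<int> > adj(n);
  for (int e = 0; e < m; ++e) adj[from[e] - 1].push_back(to[e] - 1);
  std::vector<int> dist(n, -1);
  std::vector<int> bfs;
  bfs.reserve(n);
  std::vector<int> rf, rt;
  for (int s = 0; s < n; ++s) {
    bfs.clear();
    dist[s] = 0;
    bfs.push_back(s);
    for (size_t head = 0; head < bfs.size(); ++head) {
      int v = bfs[head];
      if (dist[v] == ell) break;  // BFS queue is ordered by distance
      for (size_t k = 0; k < adj[v].size(); ++k) {
        int w = adj[v][k];
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          bfs.push_back(w);
          rf.push_back(s + 1);
          rt.push_back(w + 1);
        }
      }
    }
    for (size_t k = 0; k < bfs.size(); ++k) dist[bfs[k]] = -1;
  }
  return List::create(_["from"] = wrap(rf), _["to"] = wrap(rt));
}

// Full-reachability edges (s -> w, w reachable from s) emitted only for the
// listed source nodes: the domination-equivalent reduction of the transitive
// closure (an input set dominates the closure iff it hits every source
// strongly connected component).
// [[Rcpp::export]]
List cpp_reach_edges(int n, IntegerVector from, IntegerVector to,
                     IntegerVector sources) {
  int m = from.size();
  std::vector<std::vector<int> > adj(n);
  for (int e = 0; e < m; ++e) adj[from[e] - 1].push_back(to[e] - 1);
  std::vector<char> seen(n, 0);
  std::vector<int> bfs;
  bfs.reserve(n);
  std::vector<int> rf, rt;
  for (int k = 0; k < sources.size(); ++k) {
    int s = sources[k] - 1;
    bfs.clear();
    seen[s] = 1;
    bfs.push_back(s);
    for (size_t head = 0; head < bfs.size(); ++head) {
      int v = bfs[head];
      for (size_t j = 0; j < adj[v].size(); ++j) {
        int w = adj[v][j];
        if (!seen[w]) {
          seen[w] = 1;
          bfs.push_back(w);
          rf.push_back(s + 1);
          rt.push_back(w + 1);
        }
      }
    }
    for (size_t j = 0; j < bfs.size(); ++j) seen[bfs[j]] = 0;
  }
  return List::create(_["from"] = wrap(rf), _["to"] = wrap(rt));
}

// Multi-source BFS distances from a node set; -1 marks unreachable nodes.
// [[Rcpp::export]]
IntegerVector cpp_multisource_dist(int n, IntegerVector from, IntegerVector to,
                                   IntegerVector sources) {
  int m = from.size();
  std::vector<std::vector<int> > adj(n);
  for (int e = 0; e < m; ++e) adj[from[e] - 1].push_back(to[e] - 1);
  IntegerVector dist(n, -1);
  std::vector<int> bfs;
  bfs.reserve(n);
  for (int k = 0; k < sources.size(); ++k) {
    int s = sources[k] - 1;
    if (dist[s] < 0) {
      dist[s] = 0;
      bfs.push_back(s);
    }
  }
  for (size_t head = 0; head < bfs.size(); ++head) {
    int v = bfs[head];
    for (size_t k = 0; k < adj[v].size(); ++k) {
      int w = adj[v][k];
      if (dist[w] < 0) {
        dist[w] = dist[v] + 1;
        bfs.push_back(w);
      }
    }
  }
  return dist;
}

// Degree-preserving double-edge swaps: `trials` attempts, each picking two
// links (a->b), (c->d) and replacing them by (a->d), (c->b) unless that
// would create a self-loop or a duplicate link. Uses R's RNG.
// [[Rcpp::export]]
List cpp_rewire(int n, IntegerVector from, IntegerVector to, double trials) {
  int m = from.size();
  std::vector<int> f(from.begin(), from.end()), t(to.begin(), to.end());
  std::unordered_set<long long> present;
  present.reserve(m * 2);
  const long long N = n;
  for (int e = 0; e < m; ++e)
    present.insert((long long)(f[e] - 1) * N + (t[e] - 1));
  double accepted = 0;
  for (double it = 0; it < trials; ++it) {
    int i = (int)(unif_rand() * m);
    int j = (int)(unif_rand() * m);
    if (i >= m) i = m - 1;
    if (j >= m) j = m - 1;
    if (i == j) continue;
    int a = f[i], b = t[i], c = f[j], d = t[j];
    if (a == d || c == b) continue;
    long long k1 = (long long)(a - 1) * N + (d - 1);
    long long k2 = (long long)(c - 1) * N + (b - 1);
    if (present.count(k1) || present.count(k2)) continue;
    present.erase((long long)(a - 1) * N + (b - 1));
    present.erase((long long)(c - 1) * N + (d - 1));
    present.insert(k1);
    present.insert(k2);
    t[i] = d;
    t[j] = b;
    accepted += 1;
  }
  return List::create(_["from"] = wrap(f), _["to"] = wrap(t),
                      _["accepted"] = accepted);
}
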