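#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// hot loops (all-pairs shortest paths over ~100 null networks per scan);
// request aggressive optimization independent of the build's default flags
#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3")
#endif

// Onnela-style weighted clustering coefficient, averaged over all nodes.
// `w` must already be scaled to (0, 1] (max-normalized by the R wrapper).
// Nodes with binary degree < 2 contribute 0.
// [[Rcpp::export]]
double cpp_clustering_onnela(const NumericMatrix& w) {
  const int n = w.nrow();
  std::vector<double> w3(static_cast<size_t>(n) * n, 0.0);
  std::vector<std::vector<int> > nbr(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      const double v = w(i, j);
      if (v > 0 && i != j) {
        w3[static_cast<size_t>(i) * n + j] = std::cbrt(v);
        nbr[i].push_back(j);
      }
    }
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    const int deg = static_cast<int>(nbr[i].size());
    if (deg < 2) continue;
    double cyc = 0.0;
    for (int a = 0; a < deg; ++a) {
      const int j = nbr[i][a];
      const double wij = w3[static_cast<size_t>(i) * n + j];
      const double* w3j = &w3[static_cast<size_t>(j) * n];
      for (int b = 0; b < deg; ++b) {
        const int k = nbr[i][b];
        if (k == j) continue;
        const double wjk = w3j[k];
        if (wjk > 0)
          cyc += wij * wjk * w3[static_cast<size_t>(k) * n + i];
      }
    }
    total += cyc / (static_cast<double>(deg) * (deg - 1));
  }
  return total / n;
}

// Weighted global efficiency: mean over ordered node pairs of 1/d(i,j),
// with edge length 1/weight and shortest paths by Floyd-Warshall.
// Disconnected pairs contribute 0.
// [[Rcpp::export]]
double cpp_global_efficiency(const NumericMatrix& w) {
  const int n = w.nrow();
  if (n < 2) return 0.0;
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> d(n * n, inf);
  for (int i = 0; i < n; ++i) {
    d[i * n + i] = 0.0;
    for (int j = 0; j < n; ++j)
      if (i != j && w(i, j) > 0) d[i * n + j] = 1.0 / w(i, j);
  }
  for (int k = 0; k < n; ++k) {
    const double* dk = &d[static_cast<size_t>(k) * n];
    for (int i = 0; i < n; ++i) {
      const double dik = d[static_cast<size_t>(i) * n + k];
      if (dik == inf) continue;
      double* di = &d[static_cast<size_t>(i) * n];
      for (int j = 0; j < n; ++j) {           // branch-free: vectorizes
        const double via = dik + dk[j];
        di[j] = via < di[j] ? via : di[j];
      }
    }
  }
  double acc = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && d[i * n + j] < inf) acc += 1.0 / d[i * n + j];
  return acc / (static_cast<double>(n) * (n - 1));
}

// Degree-preserving double-edge-swap rewiring of an undirected simple
// graph. `edges` is an m x 2 matrix of 1-based endpoints; the edge *slots*
// keep their identity (and hence their weights, managed by the caller) while
// their endpoints are rewired. Each attempt consumes exactly three draws
// from R's RNG: two edge indices and an orientation coin; attempts that
// would create a self-loop or a duplicate edge are rejected. Returns the
// rewired edge matrix with attribute `n_swapped`.
// [[Rcpp::export]]
IntegerMatrix cpp_rewire(const IntegerMatrix& edges, int n_nodes,
                         int n_attempts) {
  const int m = edges.nrow();
  IntegerMatrix out(clone(edges));
  std::vector<char> adj(static_cast<size_t>(n_nodes) * n_nodes, 0);
  for (int e = 0; e < m; ++e) {
    const int a = out(e, 0) - 1, b = out(e, 1) - 1;
    if (a < 0 || b < 0 || a >= n_nodes || b >= n_nodes || a == b)
      stop("invalid edge list");
    adj[a * n_nodes + b] = adj[b * n_nodes + a] = 1;
  }
  int swapped = 0;
  if (m >= 2) {
    for (int it = 0; it < n_attempts; ++it) {
      const double u1 = unif_rand();
      const double u2 = unif_rand();
      const double u3 = unif_rand();
      int e1 = static_cast<int>(u1 * m); if (e1 >= m) e1 = m - 1;
      int e2 = static_cast<int>(u2 * m); if (e2 >= m) e2 = m - 1;
      if (e1 == e2) continue;
      const int a = out(e1, 0) - 1, b = out(e1, 1) - 1;
      const int c = out(e2, 0) - 1, d = out(e2, 1) - 1;
      // proposal: (a,b),(c,d) -> (a,d),(c,b)   [u3 <  0.5]
      //                       -> (a,c),(b,d)   [u3 >= 0.5]
      int x1, y1, x2, y2;
      if (u3 < 0.5) { x1 = a; y1 = d; x2 = c; y2 = b; }
      else          { x1 = a; y1 = c; x2 = b; y2 = d; }
      if (x1 == y1 || x2 == y2) continue;
      if (adj[x1 * n_nodes + y1] || adj[x2 * n_nodes + y2]) continue;
      const int lo1 = std::min(x1, y1), hi1 = std::max(x1, y1);
      const int lo2 = std::min(x2, y2), hi2 = std::max(x2, y2);
      if (lo1 == lo2 && hi1 == hi2) continue;  // identical proposed edges
      adj[a * n_nodes + b] = adj[b * n_nodes + a] = 0;
      adj[c * n_nodes + d] = adj[d * n_nodes + c] = 0;
      adj[x1 * n_nodes + y1] = adj[y1 * n_nodes + x1] = 1;
      adj[x2 * n_nodes + y2] = adj[y2 * n_nodes + x2] = 1;
      out(e1, 0) = x1 + 1; out(e1, 1) = y1 + 1;
      out(e2, 0) = x2 + 1; out(e2, 1) = y2 + 1;
      ++swapped;
    }
  }
  out.attr("n_swapped") = swapped;
  return out;
}
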