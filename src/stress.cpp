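#include <Rcpp.h>
#include <deque>
#include <vector>
using namespace Rcpp;

// Stress centrality of every node in an unweighted undirected graph:
// the number of shortest paths between distinct node pairs that pass
// through the node (endpoints excluded), each unordered pair counted once.
//
// Brandes-style accumulation: for a BFS from source s, sigma[v] is the
// number of shortest s-v paths and phi[v] the number of shortest-path-DAG
// paths from v to any strict descendant, so sigma[v] * phi[v] is the number
// of shortest paths from s through v. Summing over all sources counts each
// unordered pair twice.
//
// adj: 0-based adjacency list, one integer vector per node.
// [[Rcpp::export]]
NumericVector stress_centrality_cpp(List adj) {
  const int n = adj.size();
  std::vector<std::vector<int>> A(n);
  for (int i = 0; i < n; ++i) A[i] = as<std::vector<int>>(adj[i]);

  NumericVector stress(n);
  std::vector<double> sigma(n), phi(n);
  std::vector<int> dist(n);
  std::vector<int> order;
  order.reserve(n);
  std::deque<int> q;

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(phi.begin(), phi.end(), 0.0);
    order.clear();
    q.clear();
    dist[s] = 0;
    sigma[s] = 1.0;
    q.push_back(s);
    while (!q.empty()) {
      int v = q.front();
      q.pop_front();
      order.push_back(v);
      for (int w : A[v]) {
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          q.push_back(w);
        }
        if (dist[w] == dist[v] + 1) sigma[w] += sigma[v];
      }
    }
    for (int i = (int)order.size() - 1; i >= 0; --i) {
      int v = order[i];
      double p = 0.0;
      for (int w : A[v])
        if (dist[w] == dist[v] + 1) p += 1.0 + phi[w];
      phi[v] = p;
      if (v != s) stress[v] += sigma[v] * phi[v];
    }
  }
  for (int i = 0; i < n; ++i) stress[i] /= 2.0;
  return stress;
}
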