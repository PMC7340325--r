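#ifndef CYTOPATTERN_SIM_COMMON_H
#define CYTOPATTERN_SIM_COMMON_H

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>

// Shared geometry / lattice utilities used both by the exported per-operation
// wrappers and by the full simulation kernel, so the two code paths cannot
// drift apart.

inline double sqdist(double x1, double y1, double x2, double y2) {
  double dx = x1 - x2, dy = y1 - y2;
  return dx * dx + dy * dy;
}

// k nearest sites to `site` (0-based) among sites with mask[i] != 0,
// excluding the query site itself. Ties broken by ascending site index.
// Scans the precomputed sorted neighbour list first and falls back to a
// full scan when the list does not contain k masked sites.
inline std::vector<int> knn_masked(const Rcpp::NumericMatrix& xy,
                                   const Rcpp::IntegerMatrix& nbor,
                                   const std::vector<char>& mask,
                                   int site, int k) {
  int n = xy.nrow();
  std::vector<int> out;
  out.reserve(k);
  int m = nbor.ncol();
  for (int j = 0; j < m && (int)out.size() < k; ++j) {
    int s = nbor(site, j);
    if (s < 0) break;
    if (mask[s]) out.push_back(s);
  }
  if ((int)out.size() >= k) return out;
  // fall back: full scan, sort by (distance, index)
  std::vector<std::pair<double, int> > cand;
  cand.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (i == site || !mask[i]) continue;
    cand.push_back(std::make_pair(
        sqdist(xy(site, 0), xy(site, 1), xy(i, 0), xy(i, 1)), i));
  }
  std::sort(cand.begin(), cand.end());
  out.clear();
  for (size_t i = 0; i < cand.size() && (int)out.size() < k; ++i)
    out.push_back(cand[i].second);
  return out;
}

// Globally nearest site to `site` with mask true (e.g. empty sites);
// -1 if none. Ties broken by ascending index.
inline int nearest_masked(const Rcpp::NumericMatrix& xy,
                          const std::vector<char>& mask, int site) {
  int n = xy.nrow(), best = -1;
  double bd = R_PosInf;
  for (int i = 0; i < n; ++i) {
    if (i == site || !mask[i]) continue;
    double d = sqdist(xy(site, 0), xy(site, 1), xy(i, 0), xy(i, 1));
    if (d < bd) { bd = d; best = i; }
  }
  return best;
}

// Path from `start` to `target` stepping through occupied sites on the
// k=8 nearest-site graph: greedy descent on distance-to-target, with a
// breadth-first-search fallback when the greedy walk stalls, and a direct
// two-site hop as last resort. Interior sites are occupied; the terminal
// site is `target` (assumed empty by the caller).
inline std::vector<int> path_via_occupied(const Rcpp::NumericMatrix& xy,
                                          const Rcpp::IntegerMatrix& nbor,
                                          const std::vector<char>& occ,
                                          int start, int target,
                                          int graph_k = 8) {
  std::vector<int> path;
  path.push_back(start);
  int cur = start;
  int m = std::min(graph_k, (int)nbor.ncol());
  double curd = sqdist(xy(cur, 0), xy(cur, 1), xy(target, 0), xy(target, 1));
  int guard = xy.nrow() + 2;
  bool stalled = false;
  while (cur != target && guard-- > 0) {
    int best = -1;
    double bd = curd;
    for (int j = 0; j < m; ++j) {
      int s = nbor(cur, j);
      if (s < 0) break;
      if (s == target) { best = target; bd = -1.0; break; }
      if (!occ[s]) continue;
      double d = sqdist(xy(s, 0), xy(s, 1), xy(target, 0), xy(target, 1));
      if (d < bd) { bd = d; best = s; }
    }
    if (best < 0) { stalled = true; break; }
    cur = best;
    curd = (best == target) ? 0.0
         : sqdist(xy(cur, 0), xy(cur, 1), xy(target, 0), xy(target, 1));
    path.push_back(cur);
  }
  if (cur == target && !stalled) return path;

  // BFS over the symmetrised 8-NN graph restricted to occupied sites
  // (target allowed as terminal).
  int n = xy.nrow();
  std::vector<std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      int s = nbor(i, j);
      if (s < 0) break;
      adj[i].push_back(s);
      adj[s].push_back(i);
    }
  std::vector<int> prev(n, -2);
  std::queue<int> q;
  q.push(start);
  prev[start] = -1;
  while (!q.empty()) {
    int u = q.front(); q.pop();
    if (u == target) break;
    for (size_t j = 0; j < adj[u].size(); ++j) {
      int v = adj[u][j];
      if (prev[v] != -2) continue;
      if (v != target && !occ[v]) continue;
      prev[v] = u;
      q.push(v);
    }
  }
  if (prev[target] != -2) {
    std::vector<int> rev;
    for (int v = target; v != -1; v = prev[v]) rev.push_back(v);
    std::reverse(rev.begin(), rev.end());
    return rev;
  }
  // disconnected (degenerate tiny lattices): direct hop
  std::vector<int> hop;
  hop.push_back(start);
  hop.push_back(target);
  return hop;
}

// Nearest occupied receiving (non-producer) cell whose surface is within
// `tol` of the point (tx, ty); -1 when no contact. A tip inside the cell
// also counts: contact iff centre distance <= radius + tol.
inline int deposit_target(const Rcpp::NumericMatrix& xy,
                          const std::vector<char>& occ,
                          const std::vector<char>& prod,
                          double tx, double ty, double radius, double tol) {
  int n = xy.nrow(), best = -1;
  double lim = (radius + tol) * (radius + tol), bd = R_PosInf;
  for (int i = 0; i < n; ++i) {
    if (!occ[i] || prod[i]) continue;
    double d = sqdist(tx, ty, xy(i, 0), xy(i, 1));
    if (d <= lim && d < bd) { bd = d; best = i; }
  }
  return best;
}

#endif
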