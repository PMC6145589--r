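#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <random>
#include <unordered_set>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact-ish planar segment geometry.
//
// Crossing convention: a proper interior intersection of the open segments is
// a crossing; a shared endpoint is not, unless the two segments are collinear
// and overlap beyond the shared point; an endpoint lying strictly inside the
// other segment (T-junction) is a crossing. Orientation tests use plain double
// arithmetic; fixtures live on integer lattices where this is exact.
// ---------------------------------------------------------------------------

static inline double cross3(double ax, double ay, double bx, double by,
                            double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// r is assumed collinear with segment (p, q); true if r lies strictly inside
static inline bool strictly_within(double px, double py, double qx, double qy,
                                   double rx, double ry) {
  if ((rx == px && ry == py) || (rx == qx && ry == qy)) return false;
  return std::min(px, qx) <= rx && rx <= std::max(px, qx) &&
         std::min(py, qy) <= ry && ry <= std::max(py, qy);
}

// Conflict between candidate segment (i, j) and existing segment (a, b),
// where arguments are 0-based node indices into coordinate vectors.
static bool seg_conflict(const std::vector<double>& x,
                         const std::vector<double>& y,
                         int i, int j, int a, int b) {
  if ((a == i && b == j) || (a == j && b == i)) return true;  // duplicate
  // shared endpoint: only collinear overlap conflicts
  int shared = -1, u = -1, v = -1;
  if (a == i || a == j) { shared = a; v = b; u = (a == i) ? j : i; }
  else if (b == i || b == j) { shared = b; v = a; u = (b == i) ? j : i; }
  if (shared >= 0) {
    if (cross3(x[shared], y[shared], x[v], y[v], x[u], y[u]) != 0.0) return false;
    return strictly_within(x[shared], y[shared], x[v], y[v], x[u], y[u]) ||
           strictly_within(x[shared], y[shared], x[u], y[u], x[v], y[v]);
  }
  double d1 = cross3(x[a], y[a], x[b], y[b], x[i], y[i]);
  double d2 = cross3(x[a], y[a], x[b], y[b], x[j], y[j]);
  double d3 = cross3(x[i], y[i], x[j], y[j], x[a], y[a]);
  double d4 = cross3(x[i], y[i], x[j], y[j], x[b], y[b]);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return true;
  if (d1 == 0.0 && strictly_within(x[a], y[a], x[b], y[b], x[i], y[i])) return true;
  if (d2 == 0.0 && strictly_within(x[a], y[a], x[b], y[b], x[j], y[j])) return true;
  if (d3 == 0.0 && strictly_within(x[i], y[i], x[j], y[j], x[a], y[a])) return true;
  if (d4 == 0.0 && strictly_within(x[i], y[i], x[j], y[j], x[b], y[b])) return true;
  return false;
}

// Uniform grid over the bounding box used to restrict crossing checks to
// nearby edges. Edges are bucketed by their bounding boxes.
struct EdgeGrid {
  int nc;
  double x0, y0, cw, ch;
  std::vector<std::vector<int> > cells;
  std::vector<int> seen;  // stamp per edge id
  int stamp;

  EdgeGrid(double xmin, double xmax, double ymin, double ymax, int n) {
    nc = std::max(1, (int)std::floor(std::sqrt((double)std::max(n, 1))));
    x0 = xmin; y0 = ymin;
    cw = (xmax - xmin) / nc; if (cw <= 0) cw = 1.0;
    ch = (ymax - ymin) / nc; if (ch <= 0) ch = 1.0;
    cells.resize((size_t)nc * nc);
    stamp = 0;
  }
  inline int cx(double x) const {
    int c = (int)((x - x0) / cw);
    return std::min(std::max(c, 0), nc - 1);
  }
  inline int cy(double y) const {
    int c = (int)((y - y0) / ch);
    return std::min(std::max(c, 0), nc - 1);
  }
  void insert(int id, double xa, double ya, double xb, double yb) {
    int cx0 = cx(std::min(xa, xb)), cx1 = cx(std::max(xa, xb));
    int cy0 = cy(std::min(ya, yb)), cy1 = cy(std::max(ya, yb));
    for (int ix = cx0; ix <= cx1; ++ix)
      for (int iy = cy0; iy <= cy1; ++iy)
        cells[(size_t)ix * nc + iy].push_back(id);
    seen.push_back(0);
  }
  template <typename F>
  bool any_nearby(double xa, double ya, double xb, double yb, F pred) {
    ++stamp;
    int cx0 = cx(std::min(xa, xb)), cx1 = cx(std::max(xa, xb));
    int cy0 = cy(std::min(ya, yb)), cy1 = cy(std::max(ya, yb));
    for (int ix = cx0; ix <= cx1; ++ix)
      for (int iy = cy0; iy <= cy1; ++iy) {
        const std::vector<int>& cell = cells[(size_t)ix * nc + iy];
        for (size_t k = 0; k < cell.size(); ++k) {
          int id = cell[k];
          if (seen[id] == stamp) continue;
          seen[id] = stamp;
          if (pred(id)) return true;
        }
      }
    return false;
  }
};

struct Cand {
  double d2;
  int i, j;
};
static bool cand_less(const Cand& a, const Cand& b) {
  if (a.d2 != b.d2) return a.d2 < b.d2;
  if (a.i != b.i) return a.i < b.i;
  return a.j < b.j;
}

// Greedy triangulation: connect node pairs in ascending order of Euclidean
// distance, skipping any pair whose straight segment would cross an accepted
// edge. Ties broken by (distance, smaller index, larger index). Stops after
// max_edges accepted edges (pass the 3N - 3 - h triangulation count, or -1
// to exhaust all pairs). Returns a 1-based M x 2 integer matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_gt_edges(NumericVector xr, NumericVector yr, int max_edges) {
  int n = xr.size();
  std::vector<double> x(xr.begin(), xr.end()), y(yr.begin(), yr.end());
  std::vector<Cand> cands;
  cands.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      Cand c; c.d2 = dx * dx + dy * dy; c.i = i; c.j = j;
      cands.push_back(c);
    }
  std::sort(cands.begin(), cands.end(), cand_less);

  double xmin = *std::min_element(x.begin(), x.end());
  double xmax = *std::max_element(x.begin(), x.end());
  double ymin = *std::min_element(y.begin(), y.end());
  double ymax = *std::max_element(y.begin(), y.end());
  EdgeGrid grid(xmin, xmax, ymin, ymax, n);

  std::vector<int> ea, eb;
  for (size_t c = 0; c < cands.size(); ++c) {
    if (max_edges >= 0 && (int)ea.size() >= max_edges) break;
    int i = cands[c].i, j = cands[c].j;
    bool bad = grid.any_nearby(x[i], y[i], x[j], y[j], [&](int id) {
      return seg_conflict(x, y, i, j, ea[id], eb[id]);
    });
    if (!bad) {
      int id = (int)ea.size();
      ea.push_back(i); eb.push_back(j);
      grid.insert(id, x[i], y[i], x[j], y[j]);
    }
  }
  IntegerMatrix out((int)ea.size(), 2);
  for (size_t k = 0; k < ea.size(); ++k) {
    out(k, 0) = ea[k] + 1;
    out(k, 1) = eb[k] + 1;
  }
  return out;
}

// Brute-force count of conflicting (crossing) edge pairs; used by the
// planarity checks in the test-suite and by the generators on small inputs.
// [[Rcpp::export]]
int cpp_count_crossings(NumericVector xr, NumericVector yr, IntegerMatrix edges) {
  int m = edges.nrow();
  std::vector<double> x(xr.begin(), xr.end()), y(yr.begin(), yr.end());
  int cnt = 0;
  for (int e = 0; e < m; ++e)
    for (int f = e + 1; f < m; ++f)
      if (seg_conflict(x, y, edges(e, 0) - 1, edges(e, 1) - 1,
                       edges(f, 0) - 1, edges(f, 1) - 1)) ++cnt;
  return cnt;
}

// Does the segment (a, b) (1-based node indices) conflict with any edge?
// [[Rcpp::export]]
bool cpp_segment_conflicts(NumericVector xr, NumericVector yr,
                           IntegerMatrix edges, int a, int b) {
  int m = edges.nrow();
  std::vector<double> x(xr.begin(), xr.end()), y(yr.begin(), yr.end());
  for (int e = 0; e < m; ++e)
    if (seg_conflict(x, y, a - 1, b - 1, edges(e, 0) - 1, edges(e, 1) - 1))
      return true;
  return false;
}

// deterministic uniform in [0, 1) from a 64-bit generator
static inline double runif01(std::mt19937_64& rng) {
  return (double)(rng() >> 11) * (1.0 / 9007199254740992.0);
}

static bool connected_bfs(int n, const std::vector<int>& ea,
                          const std::vector<int>& eb) {
  if (n <= 1) return true;
  std::vector<std::vector<int> > adj(n);
  for (size_t k = 0; k < ea.size(); ++k) {
    adj[ea[k]].push_back(eb[k]);
    adj[eb[k]].push_back(ea[k]);
  }
  std::vector<char> vis(n, 0);
  std::vector<int> stack;
  stack.push_back(0); vis[0] = 1;
  int cnt = 1;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    for (size_t k = 0; k < adj[v].size(); ++k) {
      int w = adj[v][k];
      if (!vis[w]) { vis[w] = 1; ++cnt; stack.push_back(w); }
    }
  }
  return cnt == n;
}

// Connected degree-preserving rewiring by double-edge swaps. A swap replacing
// (a,b),(c,d) with (a,d),(c,b) is accepted only if it creates no self-loop or
// duplicate edge and leaves the graph connected. Returns the rewired edge
// list plus the accepted / attempted counts.
// [[Rcpp::export]]
List cpp_rewire_connected(int n, IntegerMatrix edges, int target_swaps,
                          int max_tries, double seed) {
  int m = edges.nrow();
  std::vector<int> ea(m), eb(m);
  std::unordered_set<int64_t> have;
  have.reserve((size_t)m * 2);
  for (int k = 0; k < m; ++k) {
    int a = edges(k, 0) - 1, b = edges(k, 1) - 1;
    if (a > b) std::swap(a, b);
    ea[k] = a; eb[k] = b;
    have.insert((int64_t)a * n + b);
  }
  std::mt19937_64 rng((uint64_t)seed);
  int accepted = 0, attempts = 0;
  if (m >= 2) {
    while (accepted < target_swaps && attempts < max_tries) {
      ++attempts;
      int e1 = (int)(runif01(rng) * m);
      int e2 = (int)(runif01(rng) * m);
      if (e1 == e2) continue;
      int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
      if (runif01(rng) < 0.5) std::swap(c, d);
      // proposed: (a, d) and (c, b)
      if (a == d || c == b) continue;
      int p1 = std::min(a, d), q1 = std::max(a, d);
      int p2 = std::min(c, b), q2 = std::max(c, b);
      int64_t k1 = (int64_t)p1 * n + q1, k2 = (int64_t)p2 * n + q2;
      if (k1 == k2 || have.count(k1) || have.count(k2)) continue;
      // tentative apply
      int64_t old1 = (int64_t)ea[e1] * n + eb[e1];
      int64_t old2 = (int64_t)ea[e2] * n + eb[e2];
      have.erase(old1); have.erase(old2);
      have.insert(k1); have.insert(k2);
      int oa1 = ea[e1], ob1 = eb[e1], oa2 = ea[e2], ob2 = eb[e2];
      ea[e1] = p1; eb[e1] = q1; ea[e2] = p2; eb[e2] = q2;
      if (connected_bfs(n, ea, eb)) {
        ++accepted;
      } else {
        ea[e1] = oa1; eb[e1] = ob1; ea[e2] = oa2; eb[e2] = ob2;
        have.erase(k1); have.erase(k2);
        have.insert(old1); have.insert(old2);
      }
    }
  }
  IntegerMatrix out(m, 2);
  for (int k = 0; k < m; ++k) { out(k, 0) = ea[k] + 1; out(k, 1) = eb[k] + 1; }
  return List::create(_["edges"] = out, _["accepted"] = accepted,
                      _["attempts"] = attempts);
}

// bridge detection (iterative Tarjan) over the alive subset of edges
static void find_bridges(int n, const std::vector<int>& ea,
                         const std::vector<int>& eb,
                         const std::vector<char>& alive,
                         std::vector<char>& is_bridge) {
  int m = (int)ea.size();
  std::vector<std::vector<std::pair<int, int> > > adj(n);
  for (int k = 0; k < m; ++k) {
    if (!alive[k]) continue;
    adj[ea[k]].push_back(std::make_pair(eb[k], k));
    adj[eb[k]].push_back(std::make_pair(ea[k], k));
  }
  std::fill(is_bridge.begin(), is_bridge.end(), 0);
  std::vector<int> disc(n, -1), low(n, 0), par_edge(n, -1), it(n, 0), stack;
  int timer = 0;
  for (int s = 0; s < n; ++s) {
    if (disc[s] != -1) continue;
    stack.push_back(s);
    disc[s] = low[s] = timer++;
    while (!stack.empty()) {
      int v = stack.back();
      if (it[v] < (int)adj[v].size()) {
        int w = adj[v][it[v]].first, id = adj[v][it[v]].second;
        ++it[v];
        if (id == par_edge[v]) continue;
        if (disc[w] == -1) {
          disc[w] = low[w] = timer++;
          par_edge[w] = id;
          stack.push_back(w);
        } else {
          low[v] = std::min(low[v], disc[w]);
        }
      } else {
        stack.pop_back();
        if (!stack.empty()) {
          int u = stack.back();
          low[u] = std::min(low[u], low[v]);
          if (low[v] > disc[u] && par_edge[v] >= 0) is_bridge[par_edge[v]] = 1;
        }
      }
    }
  }
}

// Remove n_remove edges, sampled among current non-bridges with probability
// proportional to length^bias, so the graph stays connected throughout.
// Returns the surviving edges (1-based).
// [[Rcpp::export]]
IntegerMatrix cpp_prune_keep_connected(int n, IntegerMatrix edges,
                                       NumericVector len, int n_remove,
                                       double bias, double seed) {
  int m = edges.nrow();
  std::vector<int> ea(m), eb(m);
  for (int k = 0; k < m; ++k) { ea[k] = edges(k, 0) - 1; eb[k] = edges(k, 1) - 1; }
  std::vector<char> alive(m, 1), is_bridge(m, 0);
  std::vector<double> w(len.begin(), len.end());
  std::mt19937_64 rng((uint64_t)seed);
  int removed = 0;
  while (removed < n_remove) {
    find_bridges(n, ea, eb, alive, is_bridge);
    double total = 0.0;
    for (int k = 0; k < m; ++k)
      if (alive[k] && !is_bridge[k]) total += std::pow(w[k], bias);
    if (total <= 0.0) break;  // tree reached: nothing removable
    double u = runif01(rng) * total, acc = 0.0;
    int pick = -1;
    for (int k = 0; k < m; ++k) {
      if (!alive[k] || is_bridge[k]) continue;
      acc += std::pow(w[k], bias);
      if (u <= acc) { pick = k; break; }
    }
    if (pick < 0) {  // numeric edge case: take the last removable edge
      for (int k = m - 1; k >= 0; --k)
        if (alive[k] && !is_bridge[k]) { pick = k; break; }
      if (pick < 0) break;
    }
    alive[pick] = 0;
    ++removed;
  }
  int keep = 0;
  for (int k = 0; k < m; ++k) keep += alive[k];
  IntegerMatrix out(keep, 2);
  int r = 0;
  for (int k = 0; k < m; ++k)
    if (alive[k]) { out(r, 0) = ea[k] + 1; out(r, 1) = eb[k] + 1; ++r; }
  return out;
}

// union-find with path halving
static int uf_find(std::vector<int>& p, int v) {
  while (p[v] != v) { p[v] = p[p[v]]; v = p[v]; }
  return v;
}

// Size of the largest connected component after removing the first k edges of
// a removal order, for k = 0..M (computed by reverse union-find addition).
// order is a 1-based permutation of edge row indices.
// [[Rcpp::export]]
IntegerVector cpp_lcc_profile(int n, IntegerMatrix edges, IntegerVector order) {
  int m = edges.nrow();
  std::vector<int> parent(n), size(n, 1);
  for (int v = 0; v < n; ++v) parent[v] = v;
  IntegerVector out(m + 1);
  int maxc = (n >= 1) ? 1 : 0;
  out[m] = maxc;
  for (int k = m - 1; k >= 0; --k) {
    int id = order[k] - 1;
    int a = uf_find(parent, edges(id, 0) - 1);
    int b = uf_find(parent, edges(id, 1) - 1);
    if (a != b) {
      if (size[a] < size[b]) std::swap(a, b);
      parent[b] = a;
      size[a] += size[b];
      if (size[a] > maxc) maxc = size[a];
    }
    out[k] = maxc;
  }
  return out;
}
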