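#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cstdint>
using namespace Rcpp;

// Boykov-Kolmogorov max-flow / min-cut specialized to a 6-connected 3D grid
// with a constant pairwise capacity beta and merged terminal capacities
// tcap (positive: residual from source; negative: residual to sink).
// Returns 1 for voxels on the source side of the minimum cut, 0 otherwise
// (unreachable/free voxels go to the sink side).
//
// Directions: 0:z-1 1:z+1 2:y-1 3:y+1 4:x-1 5:x+1; opposite is d^1.

namespace {

const int8_t PARENT_TERMINAL = -1;
const int8_t PARENT_NONE = -2;

struct BK {
  int nz, ny, nx;
  R_xlen_t n;
  std::vector<double> ncap;   // n*6 residual caps to neighbors
  std::vector<double> tcap;   // merged terminal residuals
  std::vector<int8_t> tree;   // 0 free, 1 S, 2 T
  std::vector<int8_t> parent; // direction to parent, or PARENT_*
  std::vector<int32_t> dist;
  std::vector<int32_t> ts;
  std::vector<uint8_t> in_active;
  std::deque<R_xlen_t> active;
  std::deque<R_xlen_t> orphans;
  int32_t TIME;

  inline R_xlen_t neighbor(R_xlen_t v, int d) const {
    // caller guarantees in-bounds (ncap 0 otherwise, but parent walks rely
    // on stored directions which always point to valid nodes)
    switch (d) {
      case 0: return v - 1;
      case 1: return v + 1;
      case 2: return v - nz;
      case 3: return v + nz;
      case 4: return v - (R_xlen_t)nz * ny;
      default: return v + (R_xlen_t)nz * ny;
    }
  }

  inline bool has_neighbor(R_xlen_t v, int d) const {
    const int z = (int)(v % nz);
    const int y = (int)((v / nz) % ny);
    const int x = (int)(v / ((R_xlen_t)nz * ny));
    switch (d) {
      case 0: return z > 0;
      case 1: return z < nz - 1;
      case 2: return y > 0;
      case 3: return y < ny - 1;
      case 4: return x > 0;
      default: return x < nx - 1;
    }
  }

  void activate(R_xlen_t v) {
    if (!in_active[v]) { in_active[v] = 1; active.push_back(v); }
  }

  // distance from v to its tree root, or -1 if v's origin is invalid
  // (path hits a node without a parent). Caches ts/dist on success.
  int32_t origin_dist(R_xlen_t v) {
    std::vector<R_xlen_t> path;
    R_xlen_t w = v;
    int32_t d = -1;
    while (true) {
      if (ts[w] == TIME) { d = dist[w]; break; }
      const int8_t p = parent[w];
      if (p == PARENT_TERMINAL) { d = 0; ts[w] = TIME; dist[w] = 0; break; }
      if (p == PARENT_NONE) return -1;
      path.push_back(w);
      w = neighbor(w, p);
    }
    // walk back, caching
    for (R_xlen_t i = (R_xlen_t)path.size(); i-- > 0; ) {
      ++d;
      ts[path[i]] = TIME;
      dist[path[i]] = d;
    }
    return dist[v] = d, ts[v] = TIME, d;
  }

  // grow trees; on success sets (pS, pT, dir) with arc pS->pT and returns true
  bool grow(R_xlen_t& pS, R_xlen_t& pT, int& dir) {
    while (!active.empty()) {
      const R_xlen_t v = active.front();
      if (tree[v] == 0) { active.pop_front(); in_active[v] = 0; continue; }
      const bool vS = (tree[v] == 1);
      for (int d = 0; d < 6; ++d) {
        if (!has_neighbor(v, d)) continue;
        const R_xlen_t u = neighbor(v, d);
        const double r = vS ? ncap[(size_t)v * 6 + d]
                            : ncap[(size_t)u * 6 + (d ^ 1)];
        if (r <= 0.0) continue;
        if (tree[u] == 0) {
          tree[u] = tree[v];
          parent[u] = (int8_t)(d ^ 1);
          dist[u] = dist[v] + 1;
          ts[u] = ts[v];
          activate(u);
        } else if (tree[u] != tree[v]) {
          if (vS) { pS = v; pT = u; dir = d; }
          else    { pS = u; pT = v; dir = d ^ 1; }
          return true;
        }
      }
      active.pop_front();
      in_active[v] = 0;
    }
    return false;
  }

  void augment(R_xlen_t pS, R_xlen_t pT, int dir) {
    // bottleneck
    double bn = ncap[(size_t)pS * 6 + dir];
    R_xlen_t v = pS;
    while (parent[v] >= 0) {
      const int8_t p = parent[v];
      const R_xlen_t u = neighbor(v, p);
      const double r = ncap[(size_t)u * 6 + (p ^ 1)]; // arc parent->child
      if (r < bn) bn = r;
      v = u;
    }
    if (tcap[v] < bn) bn = tcap[v];
    v = pT;
    while (parent[v] >= 0) {
      const int8_t p = parent[v];
      const double r = ncap[(size_t)v * 6 + p]; // arc child->parent
      if (r < bn) bn = r;
      v = neighbor(v, p);
    }
    if (-tcap[v] < bn) bn = -tcap[v];

    // apply
    ncap[(size_t)pS * 6 + dir] -= bn;
    ncap[(size_t)pT * 6 + (dir ^ 1)] += bn;
    v = pS;
    while (parent[v] >= 0) {
      const int8_t p = parent[v];
      const R_xlen_t u = neighbor(v, p);
      ncap[(size_t)u * 6 + (p ^ 1)] -= bn;
      ncap[(size_t)v * 6 + p] += bn;
      if (ncap[(size_t)u * 6 + (p ^ 1)] <= 0.0) {
        parent[v] = PARENT_NONE;
        orphans.push_back(v);
      }
      v = u;
    }
    tcap[v] -= bn;
    if (tcap[v] <= 0.0) { parent[v] = PARENT_NONE; orphans.push_back(v); }
    v = pT;
    while (parent[v] >= 0) {
      const int8_t p = parent[v];
      const R_xlen_t u = neighbor(v, p);
      ncap[(size_t)v * 6 + p] -= bn;
      ncap[(size_t)u * 6 + (p ^ 1)] += bn;
      if (ncap[(size_t)v * 6 + p] <= 0.0) {
        parent[v] = PARENT_NONE;
        orphans.push_back(v);
      }
      v = u;
    }
    tcap[v] += bn;
    if (tcap[v] >= 0.0) { parent[v] = PARENT_NONE; orphans.push_back(v); }
  }

  void adopt() {
    while (!orphans.empty()) {
      const R_xlen_t v = orphans.front();
      orphans.pop_front();
      if (tree[v] == 0) continue;
      const bool vS = (tree[v] == 1);
      int best_d = -1;
      int32_t best_dist = INT32_MAX;
      for (int d = 0; d < 6; ++d) {
        if (!has_neighbor(v, d)) continue;
        const R_xlen_t u = neighbor(v, d);
        if (tree[u] != tree[v]) continue;
        const double r = vS ? ncap[(size_t)u * 6 + (d ^ 1)]
                            : ncap[(size_t)v * 6 + d];
        if (r <= 0.0) continue;
        const int32_t od = origin_dist(u);
        if (od >= 0 && od < best_dist) { best_dist = od; best_d = d; }
      }
      if (best_d >= 0) {
        parent[v] = (int8_t)best_d;
        dist[v] = best_dist + 1;
        ts[v] = TIME;
      } else {
        // v leaves the tree
        for (int d = 0; d < 6; ++d) {
          if (!has_neighbor(v, d)) continue;
          const R_xlen_t u = neighbor(v, d);
          if (tree[u] != tree[v]) continue;
          const double r = vS ? ncap[(size_t)u * 6 + (d ^ 1)]
                              : ncap[(size_t)v * 6 + d];
          if (r > 0.0) activate(u);
          if (parent[u] == (int8_t)(d ^ 1)) {
            parent[u] = PARENT_NONE;
            orphans.push_back(u);
          }
        }
        tree[v] = 0;
      }
    }
  }
};

} // namespace

// [[Rcpp::export]]
IntegerVector grid_maxflow_cpp(const NumericVector& tcap,
                               const IntegerVector& dims, double beta) {
  BK bk;
  bk.nz = dims[0]; bk.ny = dims[1]; bk.nx = dims[2];
  bk.n = (R_xlen_t)bk.nz * bk.ny * bk.nx;
  if (beta < 0) stop("beta must be nonnegative");
  bk.tcap.assign(REAL(tcap), REAL(tcap) + bk.n);
  bk.ncap.assign((size_t)bk.n * 6, 0.0);
  if (beta > 0) {
    for (R_xlen_t v = 0; v < bk.n; ++v)
      for (int d = 0; d < 6; ++d)
        if (bk.has_neighbor(v, d)) bk.ncap[(size_t)v * 6 + d] = beta;
  }
  bk.tree.assign(bk.n, 0);
  bk.parent.assign(bk.n, PARENT_NONE);
  bk.dist.assign(bk.n, 0);
  bk.ts.assign(bk.n, 0);
  bk.in_active.assign(bk.n, 0);
  bk.TIME = 0;

  for (R_xlen_t v = 0; v < bk.n; ++v) {
    if (bk.tcap[v] > 0) {
      bk.tree[v] = 1; bk.parent[v] = PARENT_TERMINAL; bk.activate(v);
    } else if (bk.tcap[v] < 0) {
      bk.tree[v] = 2; bk.parent[v] = PARENT_TERMINAL; bk.activate(v);
    }
  }

  R_xlen_t pS, pT;
  int dir;
  while (bk.grow(pS, pT, dir)) {
    ++bk.TIME;
    bk.augment(pS, pT, dir);
    bk.adopt();
  }

  IntegerVector out(bk.n);
  for (R_xlen_t v = 0; v < bk.n; ++v) out[v] = (bk.tree[v] == 1) ? 1 : 0;
  out.attr("dim") = dims;
  return out;
}
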