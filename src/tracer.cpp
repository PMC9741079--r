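#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <climits>
#include <algorithm>
using namespace Rcpp;

// Linear voxel index convention matches R column-major arrays:
// idx = ix + nx * (iy + ny * iz), 0-based.

// [[Rcpp::export]]
NumericVector cpp_clearance_grid(NumericMatrix atoms, NumericVector vdw,
                                 NumericVector origin, double spacing,
                                 IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = atoms.nrow();
  NumericVector out((R_xlen_t)nx * ny * nz);
  R_xlen_t idx = 0;
  for (int iz = 0; iz < nz; ++iz) {
    const double pz = origin[2] + iz * spacing;
    for (int iy = 0; iy < ny; ++iy) {
      const double py = origin[1] + iy * spacing;
      for (int ix = 0; ix < nx; ++ix, ++idx) {
        const double px = origin[0] + ix * spacing;
        double best = R_PosInf;
        for (int a = 0; a < na; ++a) {
          const double dx = px - atoms(a, 0);
          const double dy = py - atoms(a, 1);
          const double dz = pz - atoms(a, 2);
          const double c = std::sqrt(dx * dx + dy * dy + dz * dz) - vdw[a];
          if (c < best) best = c;
        }
        out[idx] = best;
      }
    }
  }
  return out;
}

struct QEntry {
  double bottleneck;
  int steps;
  int idx;
};

// widest path first; ties: fewer steps, then smaller voxel index
struct QCompare {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.bottleneck != b.bottleneck) return a.bottleneck < b.bottleneck;
    if (a.steps != b.steps) return a.steps > b.steps;
    return a.idx > b.idx;
  }
};

// Widest-bottleneck (maximin clearance) path from the start voxel to any
// voxel on the grid boundary, over 26-connected voxels with clearance >=
// min_radius. Deterministic: the priority queue breaks ties by step count
// then voxel index.
// [[Rcpp::export]]
List cpp_widest_path(NumericVector clearance, IntegerVector dims,
                     int start, double min_radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> best(n, R_NegInf);
  std::vector<int> steps(n, INT_MAX);
  std::vector<int> parent(n, -1);

  if (clearance[start] < min_radius)
    return List::create(_["found"] = false, _["reason"] = "start occluded");

  std::priority_queue<QEntry, std::vector<QEntry>, QCompare> pq;
  best[start] = clearance[start];
  steps[start] = 0;
  pq.push({best[start], 0, start});

  auto on_boundary = [&](int ix, int iy, int iz) {
    return ix == 0 || ix == nx - 1 || iy == 0 || iy == ny - 1 ||
           iz == 0 || iz == nz - 1;
  };

  int best_target = -1;
  while (!pq.empty()) {
    QEntry e = pq.top();
    pq.pop();
    if (e.bottleneck < best[e.idx] ||
        (e.bottleneck == best[e.idx] && e.steps > steps[e.idx]))
      continue;  // stale entry
    const int ix = e.idx % nx;
    const int iy = (e.idx / nx) % ny;
    const int iz = e.idx / (nx * ny);
    if (on_boundary(ix, iy, iz)) {
      // first boundary voxel popped has the best (bottleneck, steps, idx)
      best_target = e.idx;
      break;
    }
    for (int dz = -1; dz <= 1; ++dz) {
      const int jz = iz + dz;
      if (jz < 0 || jz >= nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        const int jy = iy + dy;
        if (jy < 0 || jy >= ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          const int jx = ix + dx;
          if (jx < 0 || jx >= nx) continue;
          const int j = jx + nx * (jy + ny * jz);
          if (clearance[j] < min_radius) continue;
          const double nb = std::min(e.bottleneck, clearance[j]);
          const int ns = e.steps + 1;
          if (nb > best[j] || (nb == best[j] && ns < steps[j])) {
            best[j] = nb;
            steps[j] = ns;
            parent[j] = e.idx;
            pq.push({nb, ns, j});
          }
        }
      }
    }
  }

  if (best_target < 0)
    return List::create(_["found"] = false, _["reason"] = "no channel found");

  std::vector<int> path;
  for (int v = best_target; v >= 0; v = parent[v]) path.push_back(v);
  std::reverse(path.begin(), path.end());
  IntegerVector path_out(path.size());
  for (size_t i = 0; i < path.size(); ++i) path_out[i] = path[i] + 1;  // 1-based
  return List::create(_["found"] = true, _["path"] = path_out,
                      _["bottleneck"] = best[best_target],
                      _["steps"] = steps[best_target]);
}
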