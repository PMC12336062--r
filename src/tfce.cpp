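#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Union-find with path halving and union by size.
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Threshold-free cluster enhancement of a non-negative 3D statistic map.
//
// TFCE(v) = sum_h e(h, v)^E * h^H * dh over thresholds h (midpoint rule),
// where e(h, v) is the size of the supra-threshold connected component
// containing v. Implemented by activating voxels in descending order of
// height and merging components with union-find, so each threshold costs
// O(active voxels).
//
// values: non-negative map, NA treated as 0; dims: 3 ints; conn: 6, 18 or 26.
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector values, IntegerVector dims,
                       double E, double H, double dh, int conn) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<double> v(n);
  double vmax = 0.0;
  for (int i = 0; i < n; ++i) {
    double x = values[i];
    v[i] = (NumericVector::is_na(x) || x < 0) ? 0.0 : x;
    if (v[i] > vmax) vmax = v[i];
  }
  NumericVector out(n, 0.0);
  if (vmax <= 0.0 || dh <= 0.0) return out;

  // neighbour offsets
  std::vector<std::array<int,3>> offs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if ((conn == 6 && m > 1) || (conn == 18 && m > 2)) continue;
        offs.push_back({dx, dy, dz});
      }

  // voxels sorted by descending height
  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; ++i) if (v[i] > 0) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return v[a] > v[b]; });

  std::vector<int> parent(n), csize(n, 0);
  std::vector<char> active(n, 0);
  for (int i = 0; i < n; ++i) parent[i] = i;

  const int nsteps = (int)std::ceil(vmax / dh);
  size_t ptr = 0;
  std::vector<int> activated;
  activated.reserve(order.size());

  for (int s = nsteps; s >= 1; --s) {
    const double h = (s - 0.5) * dh;   // midpoint threshold
    // activate voxels with height >= h
    while (ptr < order.size() && v[order[ptr]] >= h) {
      int i = order[ptr++];
      active[i] = 1;
      csize[i] = 1;
      activated.push_back(i);
      int z = i / (nx * ny), rem = i % (nx * ny);
      int y = rem / nx, x = rem % nx;
      for (const auto &o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int j = xx + nx * (yy + ny * zz);
        if (!active[j]) continue;
        int ri = uf_find(parent, i), rj = uf_find(parent, j);
        if (ri == rj) continue;
        if (csize[ri] < csize[rj]) std::swap(ri, rj);
        parent[rj] = ri;
        csize[ri] += csize[rj];
      }
    }
    // accumulate contribution at this threshold
    const double hp = std::pow(h, H) * dh;
    for (int i : activated) {
      int r = uf_find(parent, i);
      out[i] += std::pow((double)csize[r], E) * hp;
    }
  }
  return out;
}
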