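#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <queue>
using namespace Rcpp;

// Solid voxelization of a triangulated surface by vertical ray parity.
// A voxel is solid when its centre lies inside the mesh: for each (x, y)
// voxel column we collect the z-crossings of the ray through the column
// centre with every triangle, sort them, and mark voxels whose centre falls
// between an odd/even crossing pair. Column sample points are nudged by a
// tiny irrational offset so rays do not pass exactly through mesh edges.
// [[Rcpp::export(name = ".voxelize_tris")]]
IntegerVector voxelize_tris(NumericMatrix tris, double pitch,
                            NumericVector origin, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double jit = pitch * 1.1920928955078125e-06;  // sub-voxel nudge
  IntegerVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  std::vector<std::vector<double>> cross(static_cast<size_t>(nx) * ny);

  const int ntri = tris.nrow();
  for (int t = 0; t < ntri; ++t) {
    double x1 = tris(t, 0), y1 = tris(t, 1), z1 = tris(t, 2);
    double x2 = tris(t, 3), y2 = tris(t, 4), z2 = tris(t, 5);
    double x3 = tris(t, 6), y3 = tris(t, 7), z3 = tris(t, 8);
    double xmin = std::min({x1, x2, x3}), xmax = std::max({x1, x2, x3});
    double ymin = std::min({y1, y2, y3}), ymax = std::max({y1, y2, y3});
    int i0 = std::max(0, (int)std::floor((xmin - ox) / pitch - 0.5));
    int i1 = std::min(nx - 1, (int)std::ceil((xmax - ox) / pitch));
    int j0 = std::max(0, (int)std::floor((ymin - oy) / pitch - 0.5));
    int j1 = std::min(ny - 1, (int)std::ceil((ymax - oy) / pitch));
    for (int i = i0; i <= i1; ++i) {
      double px = ox + (i + 0.5) * pitch + jit;
      for (int j = j0; j <= j1; ++j) {
        double py = oy + (j + 0.5) * pitch + jit * 0.618033988749895;
        // 2-D point-in-triangle via signed areas
        double d1 = (px - x2) * (y1 - y2) - (x1 - x2) * (py - y2);
        double d2 = (px - x3) * (y2 - y3) - (x2 - x3) * (py - y3);
        double d3 = (px - x1) * (y3 - y1) - (x3 - x1) * (py - y1);
        bool has_neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
        bool has_pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
        if (has_neg && has_pos) continue;
        double denom = d1 + d2 + d3;
        if (denom == 0.0) continue;  // degenerate projection
        double w1 = d2 / denom, w2 = d3 / denom, w3 = d1 / denom;
        double zc = w1 * z1 + w2 * z2 + w3 * z3;
        cross[(size_t)i * ny + j].push_back(zc);
      }
    }
  }

  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      std::vector<double>& zs = cross[(size_t)i * ny + j];
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      for (size_t p = 0; p + 1 < zs.size(); p += 2) {
        int k0 = (int)std::ceil((zs[p] - oz) / pitch - 0.5);
        int k1 = (int)std::floor((zs[p + 1] - oz) / pitch - 0.5);
        k0 = std::max(k0, 0);
        k1 = std::min(k1, nz - 1);
        for (int k = k0; k <= k1; ++k)
          out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = 1;
      }
    }
  }
  return out;
}

// Felzenszwalb & Huttenlocher exact 1-D squared distance transform.
static void dt1d(const double* f, double* d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (in voxel units) from every voxel to the
// nearest "site" voxel (mask != 0), separably along the three axes.
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector dist(n);
  const double BIG = 1e18;
  for (R_xlen_t i = 0; i < n; ++i) dist[i] = mask[i] ? 0.0 : BIG;
  int nmax = std::max({nx, ny, nz});
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);

  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = dist[base + i];
      dt1d(f.data(), d.data(), nx, v, z);
      for (int i = 0; i < nx; ++i) dist[base + i] = d[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = dist[base + (R_xlen_t)nx * j];
      dt1d(f.data(), d.data(), ny, v, z);
      for (int j = 0; j < ny; ++j) dist[base + (R_xlen_t)nx * j] = d[j];
    }
  // along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)nx * j;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int k = 0; k < nz; ++k) f[k] = dist[base + stride * k];
      dt1d(f.data(), d.data(), nz, v, z);
      for (int k = 0; k < nz; ++k) dist[base + stride * k] = d[k];
    }
  return dist;
}

// 6-connected flood fill over zero-labelled voxels, seeded from the whole
// top face (k = 0). Returns a logical mask of reached voxels.
// [[Rcpp::export(name = ".flood_from_top")]]
LogicalVector flood_from_top(IntegerVector labels, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector reached(n, false);
  std::queue<R_xlen_t> q;
  auto idx = [&](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
  };
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t id = idx(i, j, 0);
      if (labels[id] == 0) { reached[id] = true; q.push(id); }
    }
  while (!q.empty()) {
    R_xlen_t id = q.front(); q.pop();
    int k = (int)(id / ((R_xlen_t)nx * ny));
    int rem = (int)(id % ((R_xlen_t)nx * ny));
    int j = rem / nx, i = rem % nx;
    const int di[6] = {1, -1, 0, 0, 0, 0};
    const int dj[6] = {0, 0, 1, -1, 0, 0};
    const int dk[6] = {0, 0, 0, 0, 1, -1};
    for (int m = 0; m < 6; ++m) {
      int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      R_xlen_t id2 = idx(ii, jj, kk);
      if (!reached[id2] && labels[id2] == 0) {
        reached[id2] = true;
        q.push(id2);
      }
    }
  }
  return reached;
}
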