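#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation of a 3D volume at continuous 0-based voxel
// coordinates (voxel-center convention). Samples outside the volume, and
// corner contributions from outside the index range, count as 0.
static inline double trilin(const double* vol, int nx, int ny, int nz,
                            double x, double y, double z) {
  if (x <= -1.0 || y <= -1.0 || z <= -1.0 ||
      x >= (double)nx || y >= (double)ny || z >= (double)nz)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int zz = z0 + dz;
    if (zz < 0 || zz >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    for (int dy = 0; dy <= 1; ++dy) {
      int yy = y0 + dy;
      if (yy < 0 || yy >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      for (int dx = 0; dx <= 1; ++dx) {
        int xx = x0 + dx;
        if (xx < 0 || xx >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        acc += wx * wy * wz * vol[xx + (size_t)nx * (yy + (size_t)ny * zz)];
      }
    }
  }
  return acc;
}

static inline void world_to_voxel(const double* ia, double wx, double wy,
                                  double wz, double& vx, double& vy, double& vz) {
  // ia is a 4x4 inverse affine, column-major
  vx = ia[0] * wx + ia[4] * wy + ia[8]  * wz + ia[12];
  vy = ia[1] * wx + ia[5] * wy + ia[9]  * wz + ia[13];
  vz = ia[2] * wx + ia[6] * wy + ia[10] * wz + ia[14];
}

// [[Rcpp::export]]
double cpp_sample_point(NumericVector vol, IntegerVector dim,
                        NumericMatrix invaff, NumericVector world) {
  double vx, vy, vz;
  world_to_voxel(REAL(invaff), world[0], world[1], world[2], vx, vy, vz);
  return trilin(REAL(vol), dim[0], dim[1], dim[2], vx, vy, vz);
}

// Resample the volume on an oblique plane. Grid is (2n+1) x (2n+1); row i,
// col j correspond to in-plane offsets ((i-1)-n)*pitch along u and
// ((j-1)-n)*pitch along v from the origin (1-based R indices).
// [[Rcpp::export]]
NumericMatrix cpp_sample_plane(NumericVector vol, IntegerVector dim,
                               NumericMatrix invaff, NumericVector origin,
                               NumericVector u, NumericVector v,
                               double pitch, int n) {
  int m = 2 * n + 1;
  NumericMatrix out(m, m);
  const double* pv = REAL(vol);
  const double* ia = REAL(invaff);
  int nx = dim[0], ny = dim[1], nz = dim[2];
  for (int j = 0; j < m; ++j) {
    double ov = (j - n) * pitch;
    for (int i = 0; i < m; ++i) {
      double ou = (i - n) * pitch;
      double wx = origin[0] + ou * u[0] + ov * v[0];
      double wy = origin[1] + ou * u[1] + ov * v[1];
      double wz = origin[2] + ou * u[2] + ov * v[2];
      double vx, vy, vz;
      world_to_voxel(ia, wx, wy, wz, vx, vy, vz);
      out(i, j) = trilin(pv, nx, ny, nz, vx, vy, vz);
    }
  }
  return out;
}

// 4-connected flood fill on a binary matrix from a seed (0-based), with the
// seed snapped to the nearest foreground pixel within `snap` pixels
// (Euclidean). Returns the component mask, or an empty matrix when no
// foreground is found near the seed.
// [[Rcpp::export]]
List cpp_flood_fill(IntegerMatrix grid, int seed_r, int seed_c, int snap) {
  int nr = grid.nrow(), nc = grid.ncol();
  int sr = seed_r, sc = seed_c;
  bool found = false;
  if (sr >= 0 && sr < nr && sc >= 0 && sc < nc && grid(sr, sc) != 0) {
    found = true;
  } else {
    double best = 1e30;
    int lo_r = std::max(0, seed_r - snap), hi_r = std::min(nr - 1, seed_r + snap);
    int lo_c = std::max(0, seed_c - snap), hi_c = std::min(nc - 1, seed_c + snap);
    for (int r = lo_r; r <= hi_r; ++r)
      for (int c = lo_c; c <= hi_c; ++c)
        if (grid(r, c) != 0) {
          double d2 = (double)(r - seed_r) * (r - seed_r) +
                      (double)(c - seed_c) * (c - seed_c);
          if (d2 <= (double)snap * snap && d2 < best) {
            best = d2; sr = r; sc = c; found = true;
          }
        }
  }
  if (!found)
    return List::create(_["found"] = false);
  IntegerMatrix comp(nr, nc);
  std::queue<std::pair<int, int> > q;
  comp(sr, sc) = 1;
  q.push(std::make_pair(sr, sc));
  int count = 0;
  const int dr[4] = {1, -1, 0, 0}, dc[4] = {0, 0, 1, -1};
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    ++count;
    for (int k = 0; k < 4; ++k) {
      int r = p.first + dr[k], c = p.second + dc[k];
      if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
      if (grid(r, c) != 0 && comp(r, c) == 0) {
        comp(r, c) = 1;
        q.push(std::make_pair(r, c));
      }
    }
  }
  return List::create(_["found"] = true, _["region"] = comp,
                      _["count"] = count,
                      _["seed"] = IntegerVector::create(sr, sc));
}

// Connected cross-sectional area for one candidate plane: resample,
// threshold at 0.5, flood fill from the grid center. Returns the foreground
// pixel count of the component and a sub-pixel area estimate (sum of the
// interpolated values over the component dilated by `dilate` pixels, which
// captures the soft interpolation skirt around the thresholded region and
// varies smoothly with plane orientation). count = -1 when no lumen is
// found near the seed. This is the wobble hot path.
// [[Rcpp::export]]
NumericVector cpp_plane_component_count(NumericVector vol, IntegerVector dim,
                                        NumericMatrix invaff,
                                        NumericVector origin,
                                        NumericVector u, NumericVector v,
                                        double pitch, int n, int snap,
                                        int dilate) {
  int m = 2 * n + 1;
  // lazy sampling: pixels are interpolated only when the region growth
  // touches them, which keeps the per-candidate cost proportional to the
  // cross-section size rather than the full field of view. Buffers are
  // reused across calls (single-threaded R) and only touched entries are
  // reset, avoiding a full-grid clear per wobble candidate.
  static std::vector<signed char> state;   // -1 unknown, 0 bg, 1 fg
  static std::vector<float> vals;
  static std::vector<unsigned char> seen, mark;
  static std::vector<size_t> touched;
  size_t need = (size_t)m * m;
  if (state.size() < need) {
    state.assign(need, -1);
    vals.assign(need, 0.0f);
    seen.assign(need, 0);
    mark.assign(need, 0);
  }
  touched.clear();
  const double* pv = REAL(vol);
  const double* ia = REAL(invaff);
  const double* po = REAL(origin);
  const double* pu = REAL(u);
  const double* pw = REAL(v);
  int nx = dim[0], ny = dim[1], nz = dim[2];
  auto sample_px = [&](int i, int j) -> int {
    size_t idx = (size_t)i + (size_t)m * j;
    if (state[idx] < 0) {
      double ou = (i - n) * pitch, ov = (j - n) * pitch;
      double wx = po[0] + ou * pu[0] + ov * pw[0];
      double wy = po[1] + ou * pu[1] + ov * pw[1];
      double wz = po[2] + ou * pu[2] + ov * pw[2];
      double vx, vy, vz;
      world_to_voxel(ia, wx, wy, wz, vx, vy, vz);
      double val = trilin(pv, nx, ny, nz, vx, vy, vz);
      vals[idx] = (float)val;
      state[idx] = val >= 0.5 ? 1 : 0;
      touched.push_back(idx);
    }
    return state[idx];
  };
  // every pixel that was sampled, grown into or marked is in `touched`
  // (seen/mark are only ever set on sampled pixels), so resetting those
  // entries restores the buffers for the next call
  auto reset_buffers = [&]() {
    for (size_t t = 0; t < touched.size(); ++t) {
      state[touched[t]] = -1;
      seen[touched[t]] = 0;
      mark[touched[t]] = 0;
    }
  };
  int sr = n, sc = n;
  if (sample_px(sr, sc) != 1) {
    double best = 1e30;
    bool found = false;
    for (int r = std::max(0, n - snap); r <= std::min(m - 1, n + snap); ++r)
      for (int c = std::max(0, n - snap); c <= std::min(m - 1, n + snap); ++c)
        if (sample_px(r, c) == 1) {
          double d2 = (double)(r - n) * (r - n) + (double)(c - n) * (c - n);
          if (d2 <= (double)snap * snap && d2 < best) {
            best = d2; sr = r; sc = c; found = true;
          }
        }
    if (!found) {
      reset_buffers();
      return NumericVector::create(-1.0, 0.0);
    }
  }
  std::vector<std::pair<int, int> > comp;
  std::queue<std::pair<int, int> > q;
  seen[(size_t)sr + (size_t)m * sc] = 1;
  q.push(std::make_pair(sr, sc));
  const int dr[4] = {1, -1, 0, 0}, dc[4] = {0, 0, 1, -1};
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    comp.push_back(p);
    for (int k = 0; k < 4; ++k) {
      int r = p.first + dr[k], c = p.second + dc[k];
      if (r < 0 || r >= m || c < 0 || c >= m) continue;
      size_t idx = (size_t)r + (size_t)m * c;
      if (!seen[idx] && sample_px(r, c) == 1) {
        seen[idx] = 1;
        q.push(std::make_pair(r, c));
      }
    }
  }
  // soft area: interpolated values over the component dilated by `dilate`
  double soft = 0.0;
  for (size_t ci = 0; ci < comp.size(); ++ci)
    for (int dj = -dilate; dj <= dilate; ++dj)
      for (int di = -dilate; di <= dilate; ++di) {
        int r = comp[ci].first + di, c = comp[ci].second + dj;
        if (r < 0 || r >= m || c < 0 || c >= m) continue;
        size_t idx = (size_t)r + (size_t)m * c;
        if (!mark[idx]) {
          mark[idx] = 1;
          sample_px(r, c);
          soft += vals[idx];
        }
      }
  reset_buffers();
  return NumericVector::create((double)comp.size(), soft);
}

// Voxelize a closed triangulated surface by parity ray casting along the
// third (z) axis through every voxel-center column. Vertices in world mm;
// faces are 0-based vertex indices. Voxel center (i,j,k) (0-based) sits at
// origin + (i,j,k)*spacing.
// [[Rcpp::export]]
LogicalVector cpp_voxelize(NumericMatrix verts, IntegerMatrix faces,
                           NumericVector origin, NumericVector spacing,
                           IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((size_t)nx * ny * nz);
  int nf = faces.nrow();
  // tiny deterministic offset so rays avoid triangle edges/vertices
  double eps_x = 1e-6 * spacing[0], eps_y = 1e-6 * spacing[1];
  std::vector<double> zs;
  for (int j = 0; j < ny; ++j) {
    double ry = origin[1] + j * spacing[1] + eps_y;
    for (int i = 0; i < nx; ++i) {
      double rx = origin[0] + i * spacing[0] + eps_x;
      zs.clear();
      for (int f = 0; f < nf; ++f) {
        int a = faces(f, 0), b = faces(f, 1), c = faces(f, 2);
        double ax = verts(a, 0) - rx, ay = verts(a, 1) - ry;
        double bx = verts(b, 0) - rx, by = verts(b, 1) - ry;
        double cx = verts(c, 0) - rx, cy = verts(c, 1) - ry;
        // 2D signed areas of sub-triangles with the ray point
        double d1 = ax * by - ay * bx;
        double d2 = bx * cy - by * cx;
        double d3 = cx * ay - cy * ax;
        bool has_neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
        bool has_pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
        if (has_neg && has_pos) continue;  // outside projected triangle
        double denom = d1 + d2 + d3;
        if (denom == 0.0) continue;        // degenerate / edge-on
        double w1 = d2 / denom, w2 = d3 / denom, w3 = d1 / denom;
        double z = w1 * verts(a, 2) + w2 * verts(b, 2) + w3 * verts(c, 2);
        zs.push_back(z);
      }
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      // walk crossing pairs; an unpaired trailing crossing is dropped
      size_t np = zs.size() / 2;
      for (size_t p = 0; p < np; ++p) {
        double z0 = zs[2 * p], z1 = zs[2 * p + 1];
        int k0 = (int)std::ceil((z0 - origin[2]) / spacing[2]);
        int k1 = (int)std::floor((z1 - origin[2]) / spacing[2]);
        if (k0 < 0) k0 = 0;
        if (k1 > nz - 1) k1 = nz - 1;
        for (int k = k0; k <= k1; ++k)
          out[(size_t)i + (size_t)nx * (j + (size_t)ny * k)] = true;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
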