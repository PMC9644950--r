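// Voxel-level primitives for 3D cortical bone image analysis:
// exact Euclidean distance transforms, connected-component labelling,
// topology-preserving curve thinning, model-independent (sphere-fitting)
// local thickness, and solid rasterisers for the synthetic phantom.
//
// All arrays are R logical/numeric 3D arrays in column-major order
// (x fastest). Voxel (i,j,k), 0-based, has its centre at
// (i + 0.5, j + 0.5, k + 0.5) in voxel units.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>

using namespace Rcpp;

static const double DT_INF = 1e20;

// ---------------------------------------------------------------------------
// 1D squared-distance transform (Felzenszwalb & Huttenlocher lower envelope)
// ---------------------------------------------------------------------------
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (voxel units) from every voxel to the nearest
// TRUE voxel of `sites`. Voxels with no site anywhere get a huge value.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector sites, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector d(n);
  for (R_xlen_t i = 0; i < n; i++) d[i] = sites[i] ? 0.0 : DT_INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int zz = 0; zz < nz; zz++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; x++) f[x] = d[base + x];
      dt1d(f, out, v, z, nx);
      for (int x = 0; x < nx; x++) d[base + x] = out[x];
    }
  // y pass
  for (int zz = 0; zz < nz; zz++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)zz * nx * ny + x;
      for (int y = 0; y < ny; y++) f[y] = d[base + (R_xlen_t)y * nx];
      dt1d(f, out, v, z, ny);
      for (int y = 0; y < ny; y++) d[base + (R_xlen_t)y * nx] = out[y];
    }
  // z pass
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int zz = 0; zz < nz; zz++) f[zz] = d[base + (R_xlen_t)zz * nxy];
      dt1d(f, out, v, z, nz);
      for (int zz = 0; zz < nz; zz++) d[base + (R_xlen_t)zz * nxy] = out[zz];
    }
  return d;
}

// ---------------------------------------------------------------------------
// Connected-component labelling (6 or 26 connectivity), BFS.
// Returns integer labels, 0 for background.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        dxs.push_back(dx);
        dys.push_back(dy);
        dzs.push_back(dz);
      }
  int nnb = (int)dxs.size();

  std::vector<R_xlen_t> queue;
  int next = 0;
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    queue.clear();
    queue.push_back(s);
    size_t head = 0;
    while (head < queue.size()) {
      R_xlen_t cur = queue[head++];
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int zz = (int)(cur / nxy);
      for (int t = 0; t < nnb; t++) {
        int xx = x + dxs[t], yy = y + dys[t], zc = zz + dzs[t];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zc < 0 || zc >= nz)
          continue;
        R_xlen_t nb = (R_xlen_t)zc * nxy + (R_xlen_t)yy * nx + xx;
        if (mask[nb] && lab[nb] == 0) {
          lab[nb] = next;
          queue.push_back(nb);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Simple-point test (Malandain & Bertrand characterisation):
// a foreground voxel is simple iff
//  (a) its foreground 26-neighbours form exactly one 26-connected component,
//  (b) the background voxels in its 18-neighbourhood that are 6-connected to
//      it form exactly one 6-connected component within that neighbourhood.
// nb: 27 occupancy values for the 3x3x3 cube, index i -> offsets
// (i%3-1, (i/3)%3-1, i/9-1); centre at 13.
// ---------------------------------------------------------------------------
static inline void cube_coord(int i, int& dx, int& dy, int& dz) {
  dx = i % 3 - 1;
  dy = (i / 3) % 3 - 1;
  dz = i / 9 - 1;
}

static bool is_simple_point(const int* nb) {
  // (a) one 26-component of foreground among the 26 neighbours
  int seen[27] = {0};
  int ncomp_fg = 0;
  for (int i = 0; i < 27; i++) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ncomp_fg++;
    if (ncomp_fg > 1) return false;
    // BFS
    int stack[27], top = 0;
    stack[top++] = i;
    seen[i] = 1;
    while (top > 0) {
      int c = stack[--top];
      int cx, cy, cz;
      cube_coord(c, cx, cy, cz);
      for (int j = 0; j < 27; j++) {
        if (j == 13 || !nb[j] || seen[j]) continue;
        int jx, jy, jz;
        cube_coord(j, jx, jy, jz);
        if (std::abs(jx - cx) <= 1 && std::abs(jy - cy) <= 1 &&
            std::abs(jz - cz) <= 1) {
          seen[j] = 1;
          stack[top++] = j;
        }
      }
    }
  }
  if (ncomp_fg != 1) return false;

  // (b) one 6-component of background in the 18-neighbourhood touching a
  // face neighbour of the centre
  int seenb[27] = {0};
  int ncomp_bg = 0;
  for (int i = 0; i < 27; i++) {
    int ix, iy, iz;
    cube_coord(i, ix, iy, iz);
    int manh = std::abs(ix) + std::abs(iy) + std::abs(iz);
    if (manh != 1) continue;  // start BFS only from face neighbours
    if (nb[i] || seenb[i]) continue;
    ncomp_bg++;
    if (ncomp_bg > 1) return false;
    int stack[27], top = 0;
    stack[top++] = i;
    seenb[i] = 1;
    while (top > 0) {
      int c = stack[--top];
      int cx, cy, cz;
      cube_coord(c, cx, cy, cz);
      for (int j = 0; j < 27; j++) {
        int jx, jy, jz;
        cube_coord(j, jx, jy, jz);
        int mj = std::abs(jx) + std::abs(jy) + std::abs(jz);
        if (mj < 1 || mj > 2) continue;  // restrict to 18-neighbourhood
        if (nb[j] || seenb[j]) continue;
        if (std::abs(jx - cx) + std::abs(jy - cy) + std::abs(jz - cz) == 1) {
          seenb[j] = 1;
          stack[top++] = j;
        }
      }
    }
  }
  return ncomp_bg == 1;
}

static inline void gather_cube(const std::vector<char>& m, int x, int y, int z,
                               int nx, int ny, int nz, int* nb) {
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  int q = 0;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++, q++) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          nb[q] = 0;
        else
          nb[q] = m[(R_xlen_t)zz * nxy + (R_xlen_t)yy * nx + xx] ? 1 : 0;
      }
}

// Topology-preserving thinning to a curve skeleton with directional
// subiterations: each outer iteration peels the six face directions in
// turn, sequentially removing voxels whose face-neighbour in the current
// direction is background, provided they are simple points and not curve
// endpoints (<= 1 foreground 26-neighbour). Candidates within a pass are
// processed in increasing `priority` order (ties by index); priority is
// typically the squared distance to background, which keeps the skeleton
// medial. Directional peeling removes one border layer per direction per
// iteration, so tube cores are reduced to single-voxel lines instead of
// being contracted away.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dim,
                         NumericVector priority, IntegerVector anchors,
                         int max_iter = -1) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  std::vector<char> m(n), prot(n, 0);
  for (R_xlen_t i = 0; i < n; i++) m[i] = mask[i] ? 1 : 0;
  // anchors (0-based linear indices) are never removed: one per connected
  // component (its distance-map maximum), so no component can vanish
  for (int a = 0; a < anchors.size(); a++) prot[anchors[a]] = 1;

  const int dirx[6] = {-1, 1, 0, 0, 0, 0};
  const int diry[6] = {0, 0, -1, 1, 0, 0};
  const int dirz[6] = {0, 0, 0, 0, -1, 1};

  // active list of foreground voxels (compacted as thinning progresses)
  std::vector<R_xlen_t> active;
  for (R_xlen_t i = 0; i < n; i++)
    if (m[i]) active.push_back(i);

  int nb[27];
  std::vector<R_xlen_t> cand;
  bool changed = true;
  int iter = 0;
  while (changed && (max_iter < 0 || iter++ < max_iter)) {
    changed = false;
    for (int dir = 0; dir < 6; dir++) {
      cand.clear();
      for (R_xlen_t i : active) {
        if (!m[i] || prot[i]) continue;
        int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / nxy);
        int xx = x + dirx[dir], yy = y + diry[dir], zz = z + dirz[dir];
        bool open;  // face neighbour in this direction is background
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          open = true;
        else
          open = !m[(R_xlen_t)zz * nxy + (R_xlen_t)yy * nx + xx];
        if (open) cand.push_back(i);
      }
      std::stable_sort(cand.begin(), cand.end(),
                       [&](R_xlen_t a, R_xlen_t b) {
                         if (priority[a] != priority[b])
                           return priority[a] < priority[b];
                         return a < b;
                       });
      for (R_xlen_t idx : cand) {
        if (!m[idx]) continue;
        int x = (int)(idx % nx), y = (int)((idx / nx) % ny),
            z = (int)(idx / nxy);
        gather_cube(m, x, y, z, nx, ny, nz, nb);
        int cnt = 0;
        for (int q = 0; q < 27; q++)
          if (q != 13 && nb[q]) cnt++;
        if (cnt <= 1) continue;  // endpoint / isolated voxel: preserve
        if (is_simple_point(nb)) {
          m[idx] = 0;
          changed = true;
        }
      }
    }
    // compact the active list
    size_t keep = 0;
    for (R_xlen_t i : active)
      if (m[i]) active[keep++] = i;
    active.resize(keep);
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = m[i] != 0;
  return out;
}

// Re-extend skeleton endpoints along their local tangent direction while
// still inside `mask`. Thinning retreats tube ends by roughly the tube
// radius; this restores the full centreline length deterministically.
// [[Rcpp::export]]
LogicalVector cpp_extend_endpoints(LogicalVector skel, LogicalVector mask,
                                   IntegerVector dim, int back_steps,
                                   int max_steps) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  std::vector<char> s(n), mk(n);
  for (R_xlen_t i = 0; i < n; i++) {
    s[i] = skel[i] ? 1 : 0;
    mk[i] = mask[i] ? 1 : 0;
  }

  auto fg_neighbors = [&](R_xlen_t idx, std::vector<R_xlen_t>& out) {
    out.clear();
    int x = (int)(idx % nx), y = (int)((idx / nx) % ny), z = (int)(idx / nxy);
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          R_xlen_t nb = (R_xlen_t)zz * nxy + (R_xlen_t)yy * nx + xx;
          if (s[nb]) out.push_back(nb);
        }
  };

  // endpoints of the original skeleton
  std::vector<R_xlen_t> endpoints;
  std::vector<R_xlen_t> nbs, nbs2;
  for (R_xlen_t i = 0; i < n; i++) {
    if (!s[i]) continue;
    fg_neighbors(i, nbs);
    if (nbs.size() == 1) endpoints.push_back(i);
  }

  for (R_xlen_t e : endpoints) {
    // walk back along the (unique) path to estimate the tangent
    R_xlen_t prev = e, cur = e;
    fg_neighbors(cur, nbs);
    if (nbs.size() != 1) continue;
    R_xlen_t nxt = nbs[0];
    int steps = 0;
    while (steps < back_steps) {
      fg_neighbors(nxt, nbs2);
      R_xlen_t cont = (R_xlen_t)-1;
      int cnt = 0;
      for (R_xlen_t q : nbs2)
        if (q != cur && q != prev) {
          cont = q;
          cnt++;
        }
      prev = cur;
      cur = nxt;
      steps++;
      if (cnt != 1) break;  // junction or far endpoint
      nxt = cont;
    }
    R_xlen_t tail = cur;
    if (tail == e) continue;
    double ex = e % nx + 0.5, ey = (e / nx) % ny + 0.5, ez = e / nxy + 0.5;
    double tx = tail % nx + 0.5, ty = (tail / nx) % ny + 0.5,
           tz = tail / nxy + 0.5;
    double dx = ex - tx, dy = ey - ty, dz = ez - tz;
    double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (nrm < 1e-9) continue;
    dx /= nrm;
    dy /= nrm;
    dz /= nrm;

    R_xlen_t tip = e;
    double px = ex, py = ey, pz = ez;
    int added = 0;
    double t = 0.0;
    while (added < max_steps) {
      t += 0.5;
      double cxp = px + dx * t, cyp = py + dy * t, czp = pz + dz * t;
      int vx = (int)std::floor(cxp), vy = (int)std::floor(cyp),
          vz = (int)std::floor(czp);
      if (vx < 0 || vx >= nx || vy < 0 || vy >= ny || vz < 0 || vz >= nz)
        break;
      R_xlen_t vi = (R_xlen_t)vz * nxy + (R_xlen_t)vy * nx + vx;
      if (vi == tip) continue;
      if (!mk[vi]) break;
      if (s[vi]) break;  // reached another part of the skeleton
      // avoid creating contacts with skeleton voxels other than the tip
      bool clash = false;
      int txi = (int)(tip % nx), tyi = (int)((tip / nx) % ny),
          tzi = (int)(tip / nxy);
      for (int ddz = -1; ddz <= 1 && !clash; ddz++)
        for (int ddy = -1; ddy <= 1 && !clash; ddy++)
          for (int ddx = -1; ddx <= 1 && !clash; ddx++) {
            int xx = vx + ddx, yy = vy + ddy, zz = vz + ddz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 ||
                zz >= nz)
              continue;
            if (xx == txi && yy == tyi && zz == tzi) continue;
            R_xlen_t qq = (R_xlen_t)zz * nxy + (R_xlen_t)yy * nx + xx;
            if (qq == vi) continue;
            if (s[qq]) clash = true;
          }
      if (clash) break;
      s[vi] = 1;
      tip = vi;
      added++;
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = s[i] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Model-independent local thickness (Hildebrand & Ruegsegger):
// local thickness at a voxel = diameter of the largest sphere that contains
// the voxel and fits inside the structure. Computed as a distance-ridge
// sphere painting over the Euclidean distance map (edt_sq = squared distance
// of each voxel to the nearest background voxel). Radii are corrected by
// half a voxel so the structure surface sits between voxel centres.
// Returns thickness in voxel units (0 outside the mask).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector mask, IntegerVector dim,
                                  NumericVector edt_sq) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  R_xlen_t nxy = (R_xlen_t)nx * ny;

  // distance ridge: drop voxels whose sphere is contained in a neighbour's
  std::vector<R_xlen_t> ridge;
  const double step[3] = {1.0, std::sqrt(2.0), std::sqrt(3.0)};
  for (R_xlen_t i = 0; i < n; i++) {
    if (!mask[i]) continue;
    double r = std::sqrt(edt_sq[i]);
    int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / nxy);
    bool dominated = false;
    for (int dz = -1; dz <= 1 && !dominated; dz++)
      for (int dy = -1; dy <= 1 && !dominated; dy++)
        for (int dx = -1; dx <= 1 && !dominated; dx++) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          R_xlen_t nb = (R_xlen_t)zz * nxy + (R_xlen_t)yy * nx + xx;
          if (!mask[nb]) continue;
          double d = step[std::abs(dx) + std::abs(dy) + std::abs(dz) - 1];
          if (std::sqrt(edt_sq[nb]) >= r + d - 1e-9) dominated = true;
        }
    if (!dominated) ridge.push_back(i);
  }

  std::stable_sort(ridge.begin(), ridge.end(), [&](R_xlen_t a, R_xlen_t b) {
    return edt_sq[a] > edt_sq[b];
  });

  // Spheres are painted over voxel centres within the full EDT radius (the
  // extent of the maximal inscribed ball), while the reported diameter
  // carries the half-voxel surface correction.
  NumericVector th(n, 0.0);
  for (R_xlen_t rp : ridge) {
    double rincl = std::sqrt(edt_sq[rp]);
    double val = 2.0 * std::max(0.0, rincl - 0.5);
    int x = (int)(rp % nx), y = (int)((rp / nx) % ny), z = (int)(rp / nxy);
    int ir = (int)std::ceil(rincl);
    double r2 = rincl * rincl + 1e-9;
    for (int dz = -ir; dz <= ir; dz++) {
      int zz = z + dz;
      if (zz < 0 || zz >= nz) continue;
      for (int dy = -ir; dy <= ir; dy++) {
        int yy = y + dy;
        if (yy < 0 || yy >= ny) continue;
        double dzy = (double)dz * dz + (double)dy * dy;
        if (dzy > r2) continue;
        R_xlen_t base = (R_xlen_t)zz * nxy + (R_xlen_t)yy * nx;
        for (int dx = -ir; dx <= ir; dx++) {
          int xx = x + dx;
          if (xx < 0 || xx >= nx) continue;
          if (dzy + (double)dx * dx > r2) continue;
          R_xlen_t vi = base + xx;
          if (!mask[vi]) continue;
          if (th[vi] >= val) continue;  // painted by a larger sphere already
          th[vi] = val;
        }
      }
    }
  }
  return th;
}

// ---------------------------------------------------------------------------
// Rasterisers for the synthetic phantom (all coordinates in voxel units).
// Canals are flat-ended cylinders along each polyline sub-segment with
// spherical joints at interior vertices; lacunae are axis-aligned ellipsoids.
// Both modify `mask` in place (the R wrappers own a fresh array).
// ---------------------------------------------------------------------------
static void paint_segment(std::vector<char>& m, int nx, int ny, int nz,
                          const double* p0, const double* p1, double r) {
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  double ux = p1[0] - p0[0], uy = p1[1] - p0[1], uz = p1[2] - p0[2];
  double L = std::sqrt(ux * ux + uy * uy + uz * uz);
  if (L < 1e-12) return;
  ux /= L;
  uy /= L;
  uz /= L;
  double lo[3], hi[3];
  for (int a = 0; a < 3; a++) {
    lo[a] = std::min(p0[a], p1[a]) - r - 1;
    hi[a] = std::max(p0[a], p1[a]) + r + 1;
  }
  int x0 = std::max(0, (int)std::floor(lo[0])),
      x1 = std::min(nx - 1, (int)std::ceil(hi[0]));
  int y0 = std::max(0, (int)std::floor(lo[1])),
      y1 = std::min(ny - 1, (int)std::ceil(hi[1]));
  int z0 = std::max(0, (int)std::floor(lo[2])),
      z1 = std::min(nz - 1, (int)std::ceil(hi[2]));
  double r2 = r * r;
  for (int z = z0; z <= z1; z++)
    for (int y = y0; y <= y1; y++)
      for (int x = x0; x <= x1; x++) {
        double cx = x + 0.5 - p0[0], cy = y + 0.5 - p0[1],
               cz = z + 0.5 - p0[2];
        double t = cx * ux + cy * uy + cz * uz;
        if (t < 0 || t > L) continue;
        double wx = cx - t * ux, wy = cy - t * uy, wz = cz - t * uz;
        if (wx * wx + wy * wy + wz * wz <= r2)
          m[(R_xlen_t)z * nxy + (R_xlen_t)y * nx + x] = 1;
      }
}

static void paint_sphere(std::vector<char>& m, int nx, int ny, int nz,
                         const double* c, double r) {
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  int x0 = std::max(0, (int)std::floor(c[0] - r - 1)),
      x1 = std::min(nx - 1, (int)std::ceil(c[0] + r + 1));
  int y0 = std::max(0, (int)std::floor(c[1] - r - 1)),
      y1 = std::min(ny - 1, (int)std::ceil(c[1] + r + 1));
  int z0 = std::max(0, (int)std::floor(c[2] - r - 1)),
      z1 = std::min(nz - 1, (int)std::ceil(c[2] + r + 1));
  double r2 = r * r;
  for (int z = z0; z <= z1; z++)
    for (int y = y0; y <= y1; y++)
      for (int x = x0; x <= x1; x++) {
        double dx = x + 0.5 - c[0], dy = y + 0.5 - c[1], dz = z + 0.5 - c[2];
        if (dx * dx + dy * dy + dz * dz <= r2)
          m[(R_xlen_t)z * nxy + (R_xlen_t)y * nx + x] = 1;
      }
}

// [[Rcpp::export]]
LogicalVector cpp_paint_canals(LogicalVector mask, IntegerVector dim,
                               List polylines, NumericVector radii) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> m(n);
  for (R_xlen_t i = 0; i < n; i++) m[i] = mask[i] ? 1 : 0;

  for (int c = 0; c < polylines.size(); c++) {
    NumericMatrix P = polylines[c];
    double r = radii[c];
    int np = P.nrow();
    for (int s = 0; s + 1 < np; s++) {
      double p0[3] = {P(s, 0), P(s, 1), P(s, 2)};
      double p1[3] = {P(s + 1, 0), P(s + 1, 1), P(s + 1, 2)};
      paint_segment(m, nx, ny, nz, p0, p1, r);
    }
    for (int s = 1; s + 1 < np; s++) {  // spherical joints
      double pc[3] = {P(s, 0), P(s, 1), P(s, 2)};
      paint_sphere(m, nx, ny, nz, pc, r);
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = m[i] != 0;
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_paint_ellipsoids(LogicalVector mask, IntegerVector dim,
                                   NumericMatrix centers,
                                   NumericMatrix semiaxes) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  std::vector<char> m(n);
  for (R_xlen_t i = 0; i < n; i++) m[i] = mask[i] ? 1 : 0;

  for (int e = 0; e < centers.nrow(); e++) {
    double cx = centers(e, 0), cy = centers(e, 1), cz = centers(e, 2);
    double a = semiaxes(e, 0), b = semiaxes(e, 1), c = semiaxes(e, 2);
    int x0 = std::max(0, (int)std::floor(cx - a - 1)),
        x1 = std::min(nx - 1, (int)std::ceil(cx + a + 1));
    int y0 = std::max(0, (int)std::floor(cy - b - 1)),
        y1 = std::min(ny - 1, (int)std::ceil(cy + b + 1));
    int z0 = std::max(0, (int)std::floor(cz - c - 1)),
        z1 = std::min(nz - 1, (int)std::ceil(cz + c + 1));
    for (int z = z0; z <= z1; z++)
      for (int y = y0; y <= y1; y++)
        for (int x = x0; x <= x1; x++) {
          double qx = (x + 0.5 - cx) / a, qy = (y + 0.5 - cy) / b,
                 qz = (z + 0.5 - cz) / c;
          if (qx * qx + qy * qy + qz * qz <= 1.0)
            m[(R_xlen_t)z * nxy + (R_xlen_t)y * nx + x] = 1;
        }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = m[i] != 0;
  return out;
}

// Tabulate voxel counts per label (labels 1..nlab).
// [[Rcpp::export]]
NumericVector cpp_label_counts(IntegerVector lab, int nlab) {
  NumericVector cnt(nlab, 0.0);
  R_xlen_t n = lab.size();
  for (R_xlen_t i = 0; i < n; i++) {
    int l = lab[i];
    if (l > 0) cnt[l - 1] += 1.0;
  }
  return cnt;
}
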