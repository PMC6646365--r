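// Voxel-level primitives for 3D binary morphometry: Euclidean distance
// transform, Hildebrand-Rüegsegger local thickness, cubical-complex Euler
// characteristic, connected-component labelling and cavity filling, and
// marching-tetrahedra isosurface area.
//
// All arrays are R arrays with dim = c(nx, ny, nz), x fastest (column-major).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t vidx(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

// ---------------------------------------------------------------------------
// 1D squared distance transform (Felzenszwalb & Huttenlocher), lower envelope
// of parabolas. f: input costs, d: output, n: length. v/z are scratch.
static void dt1d(const double* f, double* d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = 1e20;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (voxel units) from each voxel to the nearest
// background voxel centre. Background voxels get 0. If the mask has no
// background, all distances are huge (caller must handle).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = 1e18;
  NumericVector D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int zc = 0; zc < nz; ++zc)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = vidx(0, y, zc, nx, ny);
      for (int x = 0; x < nx; ++x) f[x] = D[base + x];
      dt1d(f.data(), d.data(), nx, v, z);
      for (int x = 0; x < nx; ++x) D[base + x] = d[x];
    }
  // pass along y
  for (int zc = 0; zc < nz; ++zc)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = D[vidx(x, y, zc, nx, ny)];
      dt1d(f.data(), d.data(), ny, v, z);
      for (int y = 0; y < ny; ++y) D[vidx(x, y, zc, nx, ny)] = d[y];
    }
  // pass along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int zc = 0; zc < nz; ++zc) f[zc] = D[vidx(x, y, zc, nx, ny)];
      dt1d(f.data(), d.data(), nz, v, z);
      for (int zc = 0; zc < nz; ++zc) D[vidx(x, y, zc, nx, ny)] = d[zc];
    }
  return D;
}

// ---------------------------------------------------------------------------
// Local thickness (model-free, Hildebrand-Rüegsegger): the value at a
// foreground voxel is the diameter of the largest inscribed sphere that
// contains it. Distance transform -> distance ridge (centres of maximal
// spheres) -> sphere painting in decreasing radius order.
//
// Radii are measured to the structure surface, taken to lie half a voxel
// beyond the last foreground centre: r_surf = sqrt(edt) - 0.5.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector mask, IntegerVector dim,
                                  double margin) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector D = cpp_edt_sq(mask, dim);

  std::vector<double> R(n);
  for (R_xlen_t i = 0; i < n; ++i) R[i] = mask[i] ? std::sqrt(D[i]) : 0.0;

  // distance ridge: keep p unless a 26-neighbour q has a sphere that
  // strictly contains p's sphere (R_q >= |p-q| + R_p).
  std::vector<R_xlen_t> ridge;
  std::vector<double> rrad;
  const double eps = 1e-9;
  for (int zc = 0; zc < nz; ++zc)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = vidx(x, y, zc, nx, ny);
        if (!mask[i]) continue;
        double Rp = R[i];
        bool keep = true;
        for (int dz = -1; dz <= 1 && keep; ++dz)
          for (int dy = -1; dy <= 1 && keep; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xq = x + dx, yq = y + dy, zq = zc + dz;
              if (xq < 0 || xq >= nx || yq < 0 || yq >= ny || zq < 0 || zq >= nz)
                continue;
              R_xlen_t q = vidx(xq, yq, zq, nx, ny);
              if (!mask[q]) continue;
              double dpq = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
              if (R[q] >= dpq + Rp - eps) { keep = false; break; }
            }
        if (keep) { ridge.push_back(i); rrad.push_back(Rp); }
      }

  // paint in decreasing radius order
  std::vector<size_t> ord(ridge.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t b) { return rrad[a] > rrad[b]; });

  // Paint each maximal sphere. The sphere of centre-to-background distance
  // R extends to the structure surface, half a voxel beyond the outermost
  // foreground centre, so foreground centres up to R + 1/2 away lie inside
  // it; the reported diameter likewise measures to the surface:
  // t = 2 (R - 1/2). Painting is restricted to foreground voxels, so the
  // half-voxel reach cannot leak across the background.
  NumericVector TH(n);
  for (size_t oi = 0; oi < ord.size(); ++oi) {
    size_t ii = ord[oi];
    R_xlen_t c = ridge[ii];
    double Rc = rrad[ii];
    double t = 2.0 * std::max(0.5, Rc - 0.5);
    // prune spheres nested deep inside much larger painted spheres: a
    // centre already painted with a diameter at least `margin` voxels
    // larger sits well inside that sphere and its own sphere would mostly
    // repaint the same voxels with a smaller value; margin = Inf disables
    // pruning (exact painting of every maximal sphere)
    if (TH[c] >= t + margin) continue;
    double Rcov = Rc + 0.5;
    int cz = (int)(c / ((R_xlen_t)nx * ny));
    int rem = (int)(c % ((R_xlen_t)nx * ny));
    int cy = rem / nx, cx = rem % nx;
    int rr = (int)std::floor(Rcov);
    double Rs2 = Rcov * Rcov + 1e-9;
    for (int dz = -rr; dz <= rr; ++dz) {
      int zq = cz + dz;
      if (zq < 0 || zq >= nz) continue;
      for (int dy = -rr; dy <= rr; ++dy) {
        int yq = cy + dy;
        if (yq < 0 || yq >= ny) continue;
        double d2 = (double)dz * dz + (double)dy * dy;
        if (d2 > Rs2) continue;
        int xr = (int)std::floor(std::sqrt(Rs2 - d2));
        int x0 = std::max(0, cx - xr), x1 = std::min(nx - 1, cx + xr);
        R_xlen_t base = vidx(0, yq, zq, nx, ny);
        for (int xq = x0; xq <= x1; ++xq)
          if (mask[base + xq] && TH[base + xq] < t) TH[base + xq] = t;
      }
    }
  }
  // any foreground voxel not reached by a painted sphere keeps its own
  // inscribed-sphere diameter
  for (R_xlen_t i = 0; i < n; ++i)
    if (mask[i] && TH[i] == 0.0) {
      double Rs = R[i] - 0.5;
      TH[i] = 2.0 * (Rs < 0.5 ? 0.5 : Rs);
    }
  return TH;
}

// ---------------------------------------------------------------------------
// Euler characteristic of the cubical complex spanned by foreground voxels
// (each voxel a closed unit cube): chi = V - E + F - C, where a cell is
// present iff at least one incident voxel is foreground.
// [[Rcpp::export]]
double cpp_euler_characteristic(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  auto fg = [&](int x, int y, int zc) -> bool {
    if (x < 0 || x >= nx || y < 0 || y >= ny || zc < 0 || zc >= nz) return false;
    return mask[vidx(x, y, zc, nx, ny)];
  };
  double V = 0, E = 0, F = 0, C = 0;
  // vertices at (x,y,z) in [0..nx] x [0..ny] x [0..nz]; incident voxels
  // (x-1..x, y-1..y, z-1..z)
  for (int zc = 0; zc <= nz; ++zc)
    for (int y = 0; y <= ny; ++y)
      for (int x = 0; x <= nx; ++x) {
        bool p = fg(x - 1, y - 1, zc - 1) || fg(x, y - 1, zc - 1) ||
                 fg(x - 1, y, zc - 1)     || fg(x, y, zc - 1) ||
                 fg(x - 1, y - 1, zc)     || fg(x, y - 1, zc) ||
                 fg(x - 1, y, zc)         || fg(x, y, zc);
        if (p) V += 1;
      }
  // x-edges: from vertex (x,y,z) to (x+1,y,z); incident voxels (x, y-1..y, z-1..z)
  for (int zc = 0; zc <= nz; ++zc)
    for (int y = 0; y <= ny; ++y)
      for (int x = 0; x < nx; ++x)
        if (fg(x, y - 1, zc - 1) || fg(x, y, zc - 1) ||
            fg(x, y - 1, zc) || fg(x, y, zc)) E += 1;
  // y-edges
  for (int zc = 0; zc <= nz; ++zc)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x <= nx; ++x)
        if (fg(x - 1, y, zc - 1) || fg(x, y, zc - 1) ||
            fg(x - 1, y, zc) || fg(x, y, zc)) E += 1;
  // z-edges
  for (int zc = 0; zc < nz; ++zc)
    for (int y = 0; y <= ny; ++y)
      for (int x = 0; x <= nx; ++x)
        if (fg(x - 1, y - 1, zc) || fg(x, y - 1, zc) ||
            fg(x - 1, y, zc) || fg(x, y, zc)) E += 1;
  // faces normal to z: span x,y; incident voxels (x, y, z-1..z)
  for (int zc = 0; zc <= nz; ++zc)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        if (fg(x, y, zc - 1) || fg(x, y, zc)) F += 1;
  // faces normal to y
  for (int zc = 0; zc < nz; ++zc)
    for (int y = 0; y <= ny; ++y)
      for (int x = 0; x < nx; ++x)
        if (fg(x, y - 1, zc) || fg(x, y, zc)) F += 1;
  // faces normal to x
  for (int zc = 0; zc < nz; ++zc)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x <= nx; ++x)
        if (fg(x - 1, y, zc) || fg(x, y, zc)) F += 1;
  // cells
  for (R_xlen_t i = 0; i < (R_xlen_t)nx * ny * nz; ++i)
    if (mask[i]) C += 1;
  return V - E + F - C;
}

// ---------------------------------------------------------------------------
// Connected-component labelling, BFS. connectivity = 6 or 26.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m > 1) continue;
        nb.push_back({dx, dy, dz});
      }
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t i = stack.back();
      stack.pop_back();
      int zc = (int)(i / ((R_xlen_t)nx * ny));
      int rem = (int)(i % ((R_xlen_t)nx * ny));
      int y = rem / nx, x = rem % nx;
      for (auto& d : nb) {
        int xq = x + d[0], yq = y + d[1], zq = zc + d[2];
        if (xq < 0 || xq >= nx || yq < 0 || yq >= ny || zq < 0 || zq >= nz)
          continue;
        R_xlen_t q = vidx(xq, yq, zq, nx, ny);
        if (mask[q] && !lab[q]) { lab[q] = cur; stack.push_back(q); }
      }
    }
  }
  return lab;
}

// Fill enclosed cavities: background 6-connected to the volume border stays
// background, all other background becomes foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_cavities(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::vector<R_xlen_t> stack;
  auto push = [&](int x, int y, int zc) {
    if (x < 0 || x >= nx || y < 0 || y >= ny || zc < 0 || zc >= nz) return;
    R_xlen_t i = vidx(x, y, zc, nx, ny);
    if (!mask[i] && !outside[i]) { outside[i] = 1; stack.push_back(i); }
  };
  for (int zc = 0; zc < nz; ++zc)
    for (int y = 0; y < ny; ++y) { push(0, y, zc); push(nx - 1, y, zc); }
  for (int zc = 0; zc < nz; ++zc)
    for (int x = 0; x < nx; ++x) { push(x, 0, zc); push(x, ny - 1, zc); }
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) { push(x, y, 0); push(x, y, nz - 1); }
  while (!stack.empty()) {
    R_xlen_t i = stack.back();
    stack.pop_back();
    int zc = (int)(i / ((R_xlen_t)nx * ny));
    int rem = (int)(i % ((R_xlen_t)nx * ny));
    int y = rem / nx, x = rem % nx;
    push(x - 1, y, zc); push(x + 1, y, zc);
    push(x, y - 1, zc); push(x, y + 1, zc);
    push(x, y, zc - 1); push(x, y, zc + 1);
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra: area (voxel^2) of the iso-level surface of a scalar
// field sampled at voxel centres. Cells between centres only (open
// boundaries: no surface is closed at the volume edge).
static const int TETS[6][4] = {
  {0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
  {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}
};
static const int CUBE_OFF[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};

static inline double tri_area(const double* a, const double* b, const double* c) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double w[3] = {u[1] * v[2] - u[2] * v[1],
                 u[2] * v[0] - u[0] * v[2],
                 u[0] * v[1] - u[1] * v[0]};
  return 0.5 * std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
}

// [[Rcpp::export]]
double cpp_surface_area_mt(NumericVector field, IntegerVector dim, double iso) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double area = 0.0;
  double fv[8];
  double pv[8][3];
  for (int zc = 0; zc < nz - 1; ++zc)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        bool anyAbove = false, anyBelow = false;
        for (int v = 0; v < 8; ++v) {
          int xx = x + CUBE_OFF[v][0], yy = y + CUBE_OFF[v][1],
              zz = zc + CUBE_OFF[v][2];
          fv[v] = field[vidx(xx, yy, zz, nx, ny)];
          pv[v][0] = xx; pv[v][1] = yy; pv[v][2] = zz;
          if (fv[v] > iso) anyAbove = true; else anyBelow = true;
        }
        if (!anyAbove || !anyBelow) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int code = 0;
          for (int v = 0; v < 4; ++v)
            if (fv[T[v]] > iso) code |= (1 << v);
          if (code == 0 || code == 15) continue;
          // edge interpolation helper
          auto interp = [&](int a, int b, double* out) {
            double fa = fv[T[a]], fb = fv[T[b]];
            double s = (iso - fa) / (fb - fa);
            for (int k = 0; k < 3; ++k)
              out[k] = pv[T[a]][k] + s * (pv[T[b]][k] - pv[T[a]][k]);
          };
          int above[4], below[4], na = 0, nbw = 0;
          for (int v = 0; v < 4; ++v)
            if (code & (1 << v)) above[na++] = v; else below[nbw++] = v;
          if (na == 1 || na == 3) {
            int apex = (na == 1) ? above[0] : below[0];
            int others[3], no = 0;
            for (int v = 0; v < 4; ++v) if (v != apex) others[no++] = v;
            double p0[3], p1[3], p2[3];
            interp(apex, others[0], p0);
            interp(apex, others[1], p1);
            interp(apex, others[2], p2);
            area += tri_area(p0, p1, p2);
          } else { // na == 2: quad
            double q0[3], q1[3], q2[3], q3[3];
            interp(above[0], below[0], q0);
            interp(above[0], below[1], q1);
            interp(above[1], below[1], q2);
            interp(above[1], below[0], q3);
            area += tri_area(q0, q1, q2);
            area += tri_area(q0, q2, q3);
          }
        }
      }
  return area;
}

// Separable [1,2,1]/4 smoothing with edge clamping, applied along each axis.
// [[Rcpp::export]]
NumericVector cpp_smooth121(NumericVector field, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector a(clone(field)), b(n);
  auto pass = [&](NumericVector& src, NumericVector& dst, int axis) {
    for (int zc = 0; zc < nz; ++zc)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int xm = x, xp = x, ym = y, yp = y, zm = zc, zp = zc;
          if (axis == 0) { xm = std::max(0, x - 1); xp = std::min(nx - 1, x + 1); }
          if (axis == 1) { ym = std::max(0, y - 1); yp = std::min(ny - 1, y + 1); }
          if (axis == 2) { zm = std::max(0, zc - 1); zp = std::min(nz - 1, zc + 1); }
          dst[vidx(x, y, zc, nx, ny)] =
            0.25 * src[vidx(xm, ym, zm, nx, ny)] +
            0.5  * src[vidx(x, y, zc, nx, ny)] +
            0.25 * src[vidx(xp, yp, zp, nx, ny)];
        }
  };
  pass(a, b, 0);
  pass(b, a, 1);
  pass(a, b, 2);
  return b;
}
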