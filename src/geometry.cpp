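// Mean-intercept-length sampling, capsule voxelization and parallel-beam
// forward projection (discrete radon transform).

#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline R_xlen_t vidx(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

// ---------------------------------------------------------------------------
// Mean intercept length along a set of directions. For each direction,
// n_lines parallel test lines are cast through the volume with random
// lateral offsets (R's RNG); samples are taken every `step` voxels by
// nearest-neighbour lookup. Returns a matrix (n_directions x 2) with the
// total foreground intercept length and the number of phase crossings.
// [[Rcpp::export]]
NumericMatrix cpp_mil(LogicalVector mask, IntegerVector dim,
                      NumericMatrix directions, int n_lines, double step) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nd = directions.nrow();
  NumericMatrix out(nd, 2);
  double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1), cz = 0.5 * (nz - 1);
  double Rhalf = 0.5 * std::sqrt((double)nx * nx + (double)ny * ny + (double)nz * nz);

  for (int d = 0; d < nd; ++d) {
    double wx = directions(d, 0), wy = directions(d, 1), wz = directions(d, 2);
    // orthonormal basis perpendicular to the direction
    double ax = 1, ay = 0, az = 0;
    if (std::fabs(wx) > 0.9) { ax = 0; ay = 1; }
    double e1x = wy * az - wz * ay, e1y = wz * ax - wx * az, e1z = wx * ay - wy * ax;
    double n1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
    e1x /= n1; e1y /= n1; e1z /= n1;
    double e2x = wy * e1z - wz * e1y, e2y = wz * e1x - wx * e1z,
           e2z = wx * e1y - wy * e1x;

    double len = 0.0, crossings = 0.0;
    int nsteps = (int)std::ceil(2.0 * Rhalf / step);
    for (int l = 0; l < n_lines; ++l) {
      double a1 = (2.0 * R::unif_rand() - 1.0) * Rhalf;
      double a2 = (2.0 * R::unif_rand() - 1.0) * Rhalf;
      double ox = cx + a1 * e1x + a2 * e2x - Rhalf * wx;
      double oy = cy + a1 * e1y + a2 * e2y - Rhalf * wy;
      double oz = cz + a1 * e1z + a2 * e2z - Rhalf * wz;
      int prev = -1; // -1 outside volume, else 0/1 phase
      for (int s = 0; s <= nsteps; ++s) {
        double px = ox + s * step * wx;
        double py = oy + s * step * wy;
        double pz = oz + s * step * wz;
        int xi = (int)std::lround(px), yi = (int)std::lround(py),
            zi = (int)std::lround(pz);
        if (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz) {
          prev = -1;
          continue;
        }
        int cur = mask[vidx(xi, yi, zi, nx, ny)] ? 1 : 0;
        if (cur == 1) len += step;
        if (prev >= 0 && cur != prev) crossings += 1.0;
        prev = cur;
      }
    }
    out(d, 0) = len;
    out(d, 1) = crossings;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Union of capsules (cylinders with hemispherical caps). Coordinates are in
// voxel units with voxel centres at integer positions 0..n-1. Modifies the
// logical mask in place semantics by returning the updated copy; the count of
// newly set voxels is attached as attribute "added".
// [[Rcpp::export]]
LogicalVector cpp_add_capsule(LogicalVector mask, IntegerVector dim,
                              NumericVector p0, NumericVector p1, double r) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out = clone(mask);
  double vx = p1[0] - p0[0], vy = p1[1] - p0[1], vz = p1[2] - p0[2];
  double L2 = vx * vx + vy * vy + vz * vz;
  int x0 = std::max(0, (int)std::floor(std::min(p0[0], p1[0]) - r - 1));
  int x1 = std::min(nx - 1, (int)std::ceil(std::max(p0[0], p1[0]) + r + 1));
  int y0 = std::max(0, (int)std::floor(std::min(p0[1], p1[1]) - r - 1));
  int y1 = std::min(ny - 1, (int)std::ceil(std::max(p0[1], p1[1]) + r + 1));
  int z0 = std::max(0, (int)std::floor(std::min(p0[2], p1[2]) - r - 1));
  int z1 = std::min(nz - 1, (int)std::ceil(std::max(p0[2], p1[2]) + r + 1));
  double r2 = r * r;
  double added = 0.0;
  for (int zc = z0; zc <= z1; ++zc)
    for (int y = y0; y <= y1; ++y)
      for (int x = x0; x <= x1; ++x) {
        double dx = x - p0[0], dy = y - p0[1], dz = zc - p0[2];
        double t = L2 > 0 ? (dx * vx + dy * vy + dz * vz) / L2 : 0.0;
        if (t < 0) t = 0; else if (t > 1) t = 1;
        double ex = dx - t * vx, ey = dy - t * vy, ez = dz - t * vz;
        if (ex * ex + ey * ey + ez * ez <= r2) {
          R_xlen_t i = vidx(x, y, zc, nx, ny);
          if (!out[i]) { out[i] = true; added += 1.0; }
        }
      }
  out.attr("added") = added;
  return out;
}

// ---------------------------------------------------------------------------
// Parallel-beam projection of a volume about the z axis. For each angle the
// line integral along direction (cos a, sin a, 0) is accumulated on a 1D
// detector (u axis, nu bins) per z slice with linear weight splitting.
// Output array: (nu, nz, n_angles). Length unit = one voxel.
// [[Rcpp::export]]
NumericVector cpp_radon(NumericVector vol, IntegerVector dim,
                        NumericVector angles, int nu) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int na = angles.size();
  NumericVector out((R_xlen_t)nu * nz * na);
  double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1), cu = 0.5 * (nu - 1);
  for (int a = 0; a < na; ++a) {
    double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    R_xlen_t abase = (R_xlen_t)a * nu * nz;
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        // detector coordinate of the ray through this (x, y) column:
        // u = perpendicular distance from the rotation centre
        double u = -(x - cx) * sa + (y - cy) * ca + cu;
        int i0 = (int)std::floor(u);
        double w = u - i0;
        bool ok0 = i0 >= 0 && i0 < nu, ok1 = i0 + 1 >= 0 && i0 + 1 < nu;
        if (!ok0 && !ok1) continue;
        R_xlen_t v = vidx(x, y, 0, nx, ny);
        R_xlen_t stride = (R_xlen_t)nx * ny;
        for (int zc = 0; zc < nz; ++zc, v += stride) {
          double val = vol[v];
          if (val == 0.0) continue;
          R_xlen_t o = abase + (R_xlen_t)zc * nu;
          if (ok0) out[o + i0] += val * (1.0 - w);
          if (ok1) out[o + i0 + 1] += val * w;
        }
      }
    }
  }
  return out;
}
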