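#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Grid convention shared with the R side: the physical position of voxel
// (ix,iy,iz), 0-based, is origin + voxel_size * (ix,iy,iz); x is the fastest
// index in memory (R column-major with dim = c(nx,ny,nz)).

namespace {

struct Window {
  int x0, x1, y0, y1, z0, z1;
  bool empty;
};

// Voxel index window covered by a truncated Gaussian centred at (px,py,pz).
Window atom_window(double px, double py, double pz, double radius,
                   double voxel, const NumericVector &origin,
                   int nx, int ny, int nz) {
  Window w;
  double gx = (px - origin[0]) / voxel;
  double gy = (py - origin[1]) / voxel;
  double gz = (pz - origin[2]) / voxel;
  double r = radius / voxel;
  w.x0 = std::max(0, (int)std::ceil(gx - r));
  w.x1 = std::min(nx - 1, (int)std::floor(gx + r));
  w.y0 = std::max(0, (int)std::ceil(gy - r));
  w.y1 = std::min(ny - 1, (int)std::floor(gy + r));
  w.z0 = std::max(0, (int)std::ceil(gz - r));
  w.z1 = std::min(nz - 1, (int)std::floor(gz + r));
  w.empty = (w.x0 > w.x1) || (w.y0 > w.y1) || (w.z0 > w.z1);
  return w;
}

} // namespace

// Sum of weighted amplitude-1 Gaussians rendered onto the grid, truncated at
// trunc_sigmas standard deviations.
// [[Rcpp::export]]
NumericVector cpp_render(const NumericMatrix &pos, const NumericVector &w,
                         double sigma, const IntegerVector &dims,
                         double voxel, const NumericVector &origin,
                         double trunc_sigmas) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = pos.nrow();
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double radius = trunc_sigmas * sigma;
  const double r2max = radius * radius;
  for (int a = 0; a < n; ++a) {
    const double px = pos(a, 0), py = pos(a, 1), pz = pos(a, 2);
    const double wa = w[a];
    Window win = atom_window(px, py, pz, radius, voxel, origin, nx, ny, nz);
    if (win.empty) continue;
    for (int iz = win.z0; iz <= win.z1; ++iz) {
      const double dz = origin[2] + voxel * iz - pz;
      const double dz2 = dz * dz;
      for (int iy = win.y0; iy <= win.y1; ++iy) {
        const double dy = origin[1] + voxel * iy - py;
        const double dyz2 = dz2 + dy * dy;
        if (dyz2 > r2max) continue;
        R_xlen_t base = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        for (int ix = win.x0; ix <= win.x1; ++ix) {
          const double dx = origin[0] + voxel * ix - px;
          const double r2 = dyz2 + dx * dx;
          if (r2 <= r2max) out[base + ix] += wa * std::exp(-r2 * inv2s2);
        }
      }
    }
  }
  return out;
}

// Per-atom inner products sum_vox g_i(vox) * field(vox) with the truncated
// unit-amplitude Gaussian of each atom.
// [[Rcpp::export]]
NumericVector cpp_backproject(const NumericMatrix &pos, double sigma,
                              const IntegerVector &dims, double voxel,
                              const NumericVector &origin,
                              const NumericVector &field,
                              double trunc_sigmas) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = pos.nrow();
  NumericVector out(n);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double radius = trunc_sigmas * sigma;
  const double r2max = radius * radius;
  for (int a = 0; a < n; ++a) {
    const double px = pos(a, 0), py = pos(a, 1), pz = pos(a, 2);
    Window win = atom_window(px, py, pz, radius, voxel, origin, nx, ny, nz);
    if (win.empty) continue;
    double acc = 0.0;
    for (int iz = win.z0; iz <= win.z1; ++iz) {
      const double dz = origin[2] + voxel * iz - pz;
      const double dz2 = dz * dz;
      for (int iy = win.y0; iy <= win.y1; ++iy) {
        const double dy = origin[1] + voxel * iy - py;
        const double dyz2 = dz2 + dy * dy;
        if (dyz2 > r2max) continue;
        R_xlen_t base = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        for (int ix = win.x0; ix <= win.x1; ++ix) {
          const double dx = origin[0] + voxel * ix - px;
          const double r2 = dyz2 + dx * dx;
          if (r2 <= r2max) acc += std::exp(-r2 * inv2s2) * field[base + ix];
        }
      }
    }
    out[a] = acc;
  }
  return out;
}

// Damped Gauss-Newton displacement for each atom position against the
// residual field (render - target). Step for atom i is
//   dr_i = -sum_vox res * g_i * (x_vox - r_i) / (w_i * sum_vox g_i^2),
// clamped to at most max_step in norm.
// [[Rcpp::export]]
NumericMatrix cpp_position_step(const NumericMatrix &pos,
                                const NumericVector &w, double sigma,
                                const IntegerVector &dims, double voxel,
                                const NumericVector &origin,
                                const NumericVector &residual,
                                double trunc_sigmas, double max_step) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = pos.nrow();
  NumericMatrix step(n, 3);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double radius = trunc_sigmas * sigma;
  const double r2max = radius * radius;
  for (int a = 0; a < n; ++a) {
    const double px = pos(a, 0), py = pos(a, 1), pz = pos(a, 2);
    Window win = atom_window(px, py, pz, radius, voxel, origin, nx, ny, nz);
    if (win.empty) continue;
    double gx = 0.0, gy = 0.0, gz = 0.0, g2 = 0.0;
    for (int iz = win.z0; iz <= win.z1; ++iz) {
      const double dz = origin[2] + voxel * iz - pz;
      const double dz2 = dz * dz;
      for (int iy = win.y0; iy <= win.y1; ++iy) {
        const double dy = origin[1] + voxel * iy - py;
        const double dyz2 = dz2 + dy * dy;
        if (dyz2 > r2max) continue;
        R_xlen_t base = (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        for (int ix = win.x0; ix <= win.x1; ++ix) {
          const double dx = origin[0] + voxel * ix - px;
          const double r2 = dyz2 + dx * dx;
          if (r2 > r2max) continue;
          const double g = std::exp(-r2 * inv2s2);
          const double rg = residual[base + ix] * g;
          gx += rg * dx;
          gy += rg * dy;
          gz += rg * dz;
          g2 += g * g;
        }
      }
    }
    const double denom = w[a] * g2;
    if (denom <= 1e-300) continue;
    double sx = -gx / denom, sy = -gy / denom, sz = -gz / denom;
    const double norm = std::sqrt(sx * sx + sy * sy + sz * sz);
    if (norm > max_step) {
      const double f = max_step / norm;
      sx *= f; sy *= f; sz *= f;
    }
    step(a, 0) = sx; step(a, 1) = sy; step(a, 2) = sz;
  }
  return step;
}

// All unordered pairs with distance strictly below cutoff.
// [[Rcpp::export]]
List cpp_pairs_within(const NumericMatrix &pos, double cutoff) {
  const int n = pos.nrow();
  const double c2 = cutoff * cutoff;
  std::vector<int> vi, vj;
  std::vector<double> vd;
  for (int i = 0; i < n - 1; ++i) {
    const double xi = pos(i, 0), yi = pos(i, 1), zi = pos(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = pos(j, 0) - xi, dy = pos(j, 1) - yi,
                   dz = pos(j, 2) - zi;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < c2) {
        vi.push_back(i + 1);
        vj.push_back(j + 1);
        vd.push_back(std::sqrt(d2));
      }
    }
  }
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj),
                      _["d"] = wrap(vd));
}

// Per-atom nearest-neighbour distance.
// [[Rcpp::export]]
NumericVector cpp_nn_distances(const NumericMatrix &pos) {
  const int n = pos.nrow();
  NumericVector out(n, R_PosInf);
  for (int i = 0; i < n - 1; ++i) {
    const double xi = pos(i, 0), yi = pos(i, 1), zi = pos(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = pos(j, 0) - xi, dy = pos(j, 1) - yi,
                   dz = pos(j, 2) - zi;
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < out[i]) out[i] = d;
      if (d < out[j]) out[j] = d;
    }
  }
  return out;
}

// Minimum-spanning-tree bottleneck edge length of the complete Euclidean
// graph (Prim's algorithm, O(n^2) time, O(n) memory).
// [[Rcpp::export]]
double cpp_mst_bottleneck(const NumericMatrix &pos) {
  const int n = pos.nrow();
  if (n < 2) return 0.0;
  std::vector<double> best(n, R_PosInf);
  std::vector<bool> used(n, false);
  used[0] = true;
  for (int j = 1; j < n; ++j) {
    const double dx = pos(j, 0) - pos(0, 0), dy = pos(j, 1) - pos(0, 1),
                 dz = pos(j, 2) - pos(0, 2);
    best[j] = std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  double bottleneck = 0.0;
  for (int it = 1; it < n; ++it) {
    int k = -1;
    double bmin = R_PosInf;
    for (int j = 0; j < n; ++j)
      if (!used[j] && best[j] < bmin) { bmin = best[j]; k = j; }
    used[k] = true;
    if (bmin > bottleneck) bottleneck = bmin;
    const double xk = pos(k, 0), yk = pos(k, 1), zk = pos(k, 2);
    for (int j = 0; j < n; ++j) {
      if (used[j]) continue;
      const double dx = pos(j, 0) - xk, dy = pos(j, 1) - yk,
                   dz = pos(j, 2) - zk;
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < best[j]) best[j] = d;
    }
  }
  return bottleneck;
}
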