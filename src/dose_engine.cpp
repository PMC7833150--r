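// Core lattice convolution and voxel ray traversal.
//
// Dose at a target cell is the triple sum over response-function offsets
// (l, m) and source layers n of R * A, where A is the per-cell activity in
// kBq and R the (resized, vertically aligned) response in dose rate per
// kBq.  Obstacle attenuation multiplies each term by exp(-mu * L_st) with
// L_st the chord length of the source->target segment inside occupied
// voxels.  Elevated targets shift the response-layer index by the terrain
// offset h (cloud shine only).  Summation order is fixed (layer, then m,
// then l, ascending) so serial and parallel runs are bit-identical.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Grid {
  double x_min, y_min, dx;
  int nx, ny, nz;
  const double *zed;  // nz + 1 edges
  const int *occ;     // nx * ny * nz, 0/1; may be null
  bool has_occ() const { return occ != nullptr; }
  bool occupied(int i, int j, int k) const {
    return occ[(size_t)k * nx * ny + (size_t)j * nx + i] != 0;
  }
  int zlayer(double z) const {
    // layer containing z, or -1 outside [zed[0], zed[nz]]
    if (z < zed[0] || z >= zed[nz]) return -1;
    int lo = 0, hi = nz;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (z >= zed[mid]) lo = mid; else hi = mid;
    }
    return lo;
  }
};

// Chord length of segment S->T inside occupied voxels (m).  Uniform cells
// in x/y, arbitrary strictly increasing layer edges in z.  Parametric
// traversal: clip the segment to the grid box, then walk voxel boundaries.
double chord_length(const Grid &g, double sx, double sy, double sz,
                    double tx, double ty, double tz) {
  if (!g.has_occ()) return 0.0;
  const double dx = tx - sx, dy = ty - sy, dz = tz - sz;
  const double len = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (len <= 0) return 0.0;
  const double x_max = g.x_min + g.nx * g.dx;
  const double y_max = g.y_min + g.ny * g.dx;
  double t0 = 0.0, t1 = 1.0;
  // clip to box [x_min,x_max] x [y_min,y_max] x [zed0, zedN]
  const double lo[3] = {g.x_min, g.y_min, g.zed[0]};
  const double hi[3] = {x_max, y_max, g.zed[g.nz]};
  const double p0[3] = {sx, sy, sz};
  const double d[3] = {dx, dy, dz};
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-300) {
      if (p0[a] < lo[a] || p0[a] > hi[a]) return 0.0;
    } else {
      double ta = (lo[a] - p0[a]) / d[a];
      double tb = (hi[a] - p0[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
    }
  }
  if (t1 <= t0) return 0.0;

  // incremental voxel traversal (Amanatides-Woo, non-uniform z layers)
  const double eps = 1e-12;
  const double x0 = sx + (t0 + eps) * dx;
  const double y0 = sy + (t0 + eps) * dy;
  const double z0 = sz + (t0 + eps) * dz;
  int i = (int)std::floor((x0 - g.x_min) / g.dx);
  int j = (int)std::floor((y0 - g.y_min) / g.dx);
  int k = g.zlayer(z0);
  if (i < 0) i = 0; if (i >= g.nx) i = g.nx - 1;
  if (j < 0) j = 0; if (j >= g.ny) j = g.ny - 1;
  if (k < 0) k = (z0 <= g.zed[0]) ? 0 : g.nz - 1;
  const int step_i = (dx > 0) - (dx < 0);
  const int step_j = (dy > 0) - (dy < 0);
  const int step_k = (dz > 0) - (dz < 0);
  const double inf = std::numeric_limits<double>::infinity();
  const double tdx = (step_i != 0) ? g.dx / std::fabs(dx) : inf;
  const double tdy = (step_j != 0) ? g.dx / std::fabs(dy) : inf;
  double tmx = inf, tmy = inf, tmz = inf;
  if (step_i > 0) tmx = (g.x_min + (i + 1) * g.dx - sx) / dx;
  else if (step_i < 0) tmx = (g.x_min + i * g.dx - sx) / dx;
  if (step_j > 0) tmy = (g.y_min + (j + 1) * g.dx - sy) / dy;
  else if (step_j < 0) tmy = (g.y_min + j * g.dx - sy) / dy;
  if (step_k > 0) tmz = (g.zed[k + 1] - sz) / dz;
  else if (step_k < 0) tmz = (g.zed[k] - sz) / dz;

  double total = 0.0;
  double t_cur = t0;
  while (t_cur < t1) {
    double t_next = std::min(std::min(tmx, tmy), std::min(tmz, t1));
    if (t_next > t_cur && g.occupied(i, j, k))
      total += (t_next - t_cur) * len;
    if (t_next >= t1) break;
    if (tmx <= tmy && tmx <= tmz) {
      i += step_i;
      if (i < 0 || i >= g.nx) break;
      tmx += tdx;
    } else if (tmy <= tmz) {
      j += step_j;
      if (j < 0 || j >= g.ny) break;
      tmy += tdy;
    } else {
      k += step_k;
      if (k < 0 || k >= g.nz) break;
      tmz = (step_k > 0) ? (g.zed[k + 1] - sz) / dz : (g.zed[k] - sz) / dz;
    }
    t_cur = t_next;
  }
  return total;
}

}  // namespace

// [[Rcpp::export(name = ".obstacle_chord_cpp")]]
double obstacle_chord_cpp(NumericVector src, NumericVector tgt,
                          IntegerVector occ, IntegerVector occ_dim,
                          double x_min, double y_min, double dx,
                          NumericVector z_edges) {
  Grid g;
  g.x_min = x_min; g.y_min = y_min; g.dx = dx;
  g.nx = occ_dim[0]; g.ny = occ_dim[1]; g.nz = occ_dim[2];
  g.zed = z_edges.begin();
  g.occ = occ.begin();
  return chord_length(g, src[0], src[1], src[2], tgt[0], tgt[1], tgt[2]);
}

// Compute doses for a set of target cells (0-based linear indices into the
// target window, i fastest).  Returns NA for skipped (obstacle-occupied)
// targets.
// [[Rcpp::export(name = ".dose_cells_cpp")]]
NumericVector dose_cells_cpp(IntegerVector cells,
                             int ti0, int tj0, int tw,   // window origin (0-based), width
                             int nx, int ny,
                             double x_min, double y_min, double dx,
                             NumericVector groundA,      // nx*ny or empty
                             NumericVector cloudA,       // nx*ny*N or empty
                             int n_layers,
                             NumericVector rfg,          // (2L+1)*(2M+1) or empty
                             NumericVector rfc,          // (2L+1)*(2M+1)*N or empty
                             int L, int M,
                             IntegerVector occ,          // nx*ny*K or empty
                             NumericVector z_edges,      // K+1 (mask layers)
                             double mu,
                             IntegerVector hoff,         // nx*ny or empty
                             double vsize,               // elevation cell size
                             NumericVector z_centers) {  // N source altitudes
  const bool has_ground = groundA.size() > 0 && rfg.size() > 0;
  const bool has_cloud = cloudA.size() > 0 && rfc.size() > 0;
  const bool has_mask = occ.size() > 0;
  const bool has_elev = hoff.size() > 0;
  const int nl = 2 * L + 1;
  const int nm = 2 * M + 1;
  Grid g;
  g.x_min = x_min; g.y_min = y_min; g.dx = dx;
  g.nx = nx; g.ny = ny;
  g.nz = z_edges.size() - 1;
  g.zed = z_edges.begin();
  g.occ = has_mask ? occ.begin() : nullptr;

  NumericVector out(cells.size());
  const double *gA = groundA.begin();
  const double *cA = cloudA.begin();
  const double *Rg = rfg.begin();
  const double *Rc = rfc.begin();

  for (int c = 0; c < cells.size(); ++c) {
    const int q = cells[c];
    const int i = ti0 + (q % tw);
    const int j = tj0 + (q / tw);
    const int h = has_elev ? hoff[(size_t)j * nx + i] : 0;
    const double xt = x_min + (i + 0.5) * dx;
    const double yt = y_min + (j + 0.5) * dx;
    const double zt = 1.0 + h * vsize;
    if (has_mask) {
      int kt = g.zlayer(zt);
      if (kt >= 0 && g.occupied(i, j, kt)) {
        out[c] = NA_REAL;
        continue;
      }
    }
    double dose = 0.0;
    const int llo = std::max(-L, -i), lhi = std::min(L, nx - 1 - i);
    const int mlo = std::max(-M, -j), mhi = std::min(M, ny - 1 - j);
    // ground shine (layer 0): flat targets only
    if (has_ground && h == 0) {
      for (int m = mlo; m <= mhi; ++m) {
        const int js = j + m;
        for (int l = llo; l <= lhi; ++l) {
          const int is = i + l;
          const double A = gA[(size_t)js * nx + is];
          if (A <= 0) continue;
          double term = Rg[(size_t)(m + M) * nl + (l + L)] * A;
          if (term == 0) continue;
          if (has_mask && mu > 0) {
            const double xs = x_min + (is + 0.5) * dx;
            const double ys = y_min + (js + 0.5) * dx;
            const double Lst = chord_length(g, xs, ys, 1e-6, xt, yt, zt);
            if (Lst > 0) term *= std::exp(-mu * Lst);
          }
          dose += term;
        }
      }
    }
    // cloud shine with elevation index shift: source layer n (0-based)
    // uses response layer n - h
    if (has_cloud) {
      for (int n = h; n < n_layers; ++n) {
        const int rl = n - h;
        const double zs = z_centers[n];
        const double *An = cA + (size_t)n * nx * ny;
        const double *Rn = Rc + (size_t)rl * nl * nm;
        for (int m = mlo; m <= mhi; ++m) {
          const int js = j + m;
          for (int l = llo; l <= lhi; ++l) {
            const int is = i + l;
            const double A = An[(size_t)js * nx + is];
            if (A <= 0) continue;
            double term = Rn[(size_t)(m + M) * nl + (l + L)] * A;
            if (term == 0) continue;
            if (has_mask && mu > 0) {
              const double xs = x_min + (is + 0.5) * dx;
              const double ys = y_min + (js + 0.5) * dx;
              const double Lst = chord_length(g, xs, ys, zs, xt, yt, zt);
              if (Lst > 0) term *= std::exp(-mu * Lst);
            }
            dose += term;
          }
        }
      }
    }
    out[c] = dose;
  }
  return out;
}
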