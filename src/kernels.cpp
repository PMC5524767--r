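// Low-level 3D kernels for the soma census pipeline.
//
// Volumes are passed as numeric/integer vectors in R array layout with
// dim = (z, y, x), i.e. z is the fastest-varying index. All distances that
// mix axes are computed in physical micrometres via per-axis voxel edge
// lengths (sz, sy, sx): voxels are anisotropic and never treated as cubes.

#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <vector>
#include <limits>
#include <algorithm>

using namespace Rcpp;

static inline R_xlen_t idx3(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// read-only view over an INTSXP or REALSXP volume, avoiding an R-side
// coercion copy (fresh large allocations are the dominant cost here)
struct VolView {
  const int *ip = nullptr;
  const double *dp = nullptr;
  explicit VolView(SEXP x) {
    if (TYPEOF(x) == INTSXP) ip = INTEGER(x);
    else if (TYPEOF(x) == REALSXP) dp = REAL(x);
    else stop("volume must be integer or double");
  }
  inline double at(R_xlen_t i) const { return ip ? (double)ip[i] : dp[i]; }
};

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing with per-axis sigma in voxel units.
// Kernel truncated at 3 sigma and renormalized; sigma <= 0 skips the axis.
// ---------------------------------------------------------------------------

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s2 = 2.0 * sigma * sigma, sum = 0.0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-(double)i * i / s2); sum += k[i + r]; }
  for (double &v : k) v /= sum;
  return k;
}

static void smooth_axis(std::vector<double> &vol, int nz, int ny, int nx,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  std::vector<double> k = gauss_kernel(sigma);
  int r = ((int)k.size() - 1) / 2;
  int n_axis = axis == 0 ? nz : (axis == 1 ? ny : nx);
  std::vector<double> line(n_axis), out(n_axis);
  for (int a = 0; a < (axis == 0 ? ny : nz); ++a) {
    for (int b = 0; b < (axis == 2 ? ny : nx); ++b) {
      // gather the line
      for (int t = 0; t < n_axis; ++t) {
        R_xlen_t id;
        if (axis == 0)      id = idx3(t, a, b, nz, ny);
        else if (axis == 1) id = idx3(a, t, b, nz, ny);
        else                id = idx3(a, b, t, nz, ny);
        line[t] = vol[id];
      }
      // convolve with edge clamping (replicate border)
      for (int t = 0; t < n_axis; ++t) {
        double acc = 0.0;
        for (int j = -r; j <= r; ++j) {
          int tt = t + j;
          if (tt < 0) tt = 0;
          if (tt >= n_axis) tt = n_axis - 1;
          acc += line[tt] * k[j + r];
        }
        out[t] = acc;
      }
      for (int t = 0; t < n_axis; ++t) {
        R_xlen_t id;
        if (axis == 0)      id = idx3(t, a, b, nz, ny);
        else if (axis == 1) id = idx3(a, t, b, nz, ny);
        else                id = idx3(a, b, t, nz, ny);
        vol[id] = out[t];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(SEXP vol, IntegerVector dim,
                               NumericVector sigma_vox) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  VolView vv(vol);
  R_xlen_t nvox = (R_xlen_t)nz * ny * nx;
  std::vector<double> v(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) v[i] = vv.at(i);
  smooth_axis(v, nz, ny, nx, 0, sigma_vox[0]);
  smooth_axis(v, nz, ny, nx, 1, sigma_vox[1]);
  smooth_axis(v, nz, ny, nx, 2, sigma_vox[2]);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// 26-neighborhood local maxima above a threshold (>= all neighbors, > thr).
// Returns 0-based (z, y, x) coordinates and values.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_local_maxima(NumericVector vol, IntegerVector dim, double thr) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> zz, yy, xx;
  std::vector<double> vv;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double v = vol[idx3(z, y, x, nz, ny)];
        if (v <= thr) continue;
        bool ismax = true;
        for (int dx = -1; dx <= 1 && ismax; ++dx)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dz = -1; dz <= 1 && ismax; ++dz) {
              if (!dx && !dy && !dz) continue;
              int z2 = z + dz, y2 = y + dy, x2 = x + dx;
              if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
                continue;
              if (vol[idx3(z2, y2, x2, nz, ny)] > v) ismax = false;
            }
        if (ismax) { zz.push_back(z); yy.push_back(y); xx.push_back(x); vv.push_back(v); }
      }
  return DataFrame::create(_["z"] = zz, _["y"] = yy, _["x"] = xx, _["value"] = vv);
}

// ---------------------------------------------------------------------------
// Seeded region growing with nearest-seed partition of contested voxels.
//
// Each seed grows over 26-connected voxels whose smoothed intensity is
// >= bg + frac * (seed_value - bg), within max_reach_um (physical) of the
// seed. A voxel claimed by several seeds goes to the physically nearest one.
// Returns an integer claim volume (0 = unclaimed, k = seed k, 1-based).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_region_grow(SEXP vol_, IntegerVector dim,
                              IntegerVector seed_z, IntegerVector seed_y,
                              IntegerVector seed_x, NumericVector seed_val,
                              double bg, double frac, double max_reach_um,
                              NumericVector voxel_um) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  VolView vol(vol_);
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  double sz = voxel_um[0], sy = voxel_um[1], sx = voxel_um[2];
  IntegerVector claim(n, 0);
  std::vector<double> claim_d2(n, std::numeric_limits<double>::infinity());
  std::vector<int> stamp(n, -1);
  double reach2 = max_reach_um * max_reach_um;
  int ns = seed_z.size();

  std::vector<int> qz, qy, qx;
  for (int s = 0; s < ns; ++s) {
    double thr = bg + frac * (seed_val[s] - bg);
    qz.clear(); qy.clear(); qx.clear();
    qz.push_back(seed_z[s]); qy.push_back(seed_y[s]); qx.push_back(seed_x[s]);
    stamp[idx3(seed_z[s], seed_y[s], seed_x[s], nz, ny)] = s;
    size_t head = 0;
    while (head < qz.size()) {
      int z = qz[head], y = qy[head], x = qx[head]; ++head;
      R_xlen_t id = idx3(z, y, x, nz, ny);
      double dz = (z - seed_z[s]) * sz, dy = (y - seed_y[s]) * sy,
             dx = (x - seed_x[s]) * sx;
      double d2 = dz * dz + dy * dy + dx * dx;
      if (d2 < claim_d2[id]) { claim_d2[id] = d2; claim[id] = s + 1; }
      for (int ox = -1; ox <= 1; ++ox)
        for (int oy = -1; oy <= 1; ++oy)
          for (int oz = -1; oz <= 1; ++oz) {
            if (!ox && !oy && !oz) continue;
            int z2 = z + oz, y2 = y + oy, x2 = x + ox;
            if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
              continue;
            R_xlen_t id2 = idx3(z2, y2, x2, nz, ny);
            if (stamp[id2] == s) continue;
            double ddz = (z2 - seed_z[s]) * sz, ddy = (y2 - seed_y[s]) * sy,
                   ddx = (x2 - seed_x[s]) * sx;
            if (ddz * ddz + ddy * ddy + ddx * ddx > reach2) continue;
            if (vol.at(id2) < thr) continue;
            stamp[id2] = s;
            qz.push_back(z2); qy.push_back(y2); qx.push_back(x2);
          }
    }
  }
  claim.attr("dim") = dim;
  return claim;
}

// ---------------------------------------------------------------------------
// Binary erosion / dilation with an ellipsoidal structuring element whose
// physical radius is radius_um along every axis (anisotropic voxel counts).
// mode: 0 = erode, 1 = dilate. Outside the volume counts as background.
// ---------------------------------------------------------------------------

static void ball_offsets(double radius_um, NumericVector voxel_um,
                         std::vector<int> &oz, std::vector<int> &oy,
                         std::vector<int> &ox) {
  double sz = voxel_um[0], sy = voxel_um[1], sx = voxel_um[2];
  int rz = (int)std::floor(radius_um / sz), ry = (int)std::floor(radius_um / sy),
      rx = (int)std::floor(radius_um / sx);
  for (int x = -rx; x <= rx; ++x)
    for (int y = -ry; y <= ry; ++y)
      for (int z = -rz; z <= rz; ++z) {
        double d2 = z * sz * z * sz + y * sy * y * sy + x * sx * x * sx;
        if (d2 <= radius_um * radius_um) {
          oz.push_back(z); oy.push_back(y); ox.push_back(x);
        }
      }
}

// [[Rcpp::export]]
LogicalVector cpp_binary_morph(LogicalVector mask, IntegerVector dim,
                               double radius_um, NumericVector voxel_um,
                               int mode) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> oz, oy, ox;
  ball_offsets(radius_um, voxel_um, oz, oy, ox);
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector out(n);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        bool erode_ok = true, dilate_hit = false;
        for (size_t k = 0; k < oz.size(); ++k) {
          int z2 = z + oz[k], y2 = y + oy[k], x2 = x + ox[k];
          bool inside = (z2 >= 0 && z2 < nz && y2 >= 0 && y2 < ny &&
                         x2 >= 0 && x2 < nx);
          bool v = inside ? (bool)mask[idx3(z2, y2, x2, nz, ny)] : false;
          if (mode == 0 && !v) { erode_ok = false; break; }
          if (mode == 1 && v) { dilate_hit = true; break; }
        }
        out[idx3(z, y, x, nz, ny)] = (mode == 0) ? erode_ok : dilate_hit;
      }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// 26-connected component labeling of a logical volume.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> q;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t id0 = idx3(z, y, x, nz, ny);
        if (!mask[id0] || lab[id0]) continue;
        ++next;
        q.clear(); q.push_back(id0); lab[id0] = next;
        size_t head = 0;
        while (head < q.size()) {
          R_xlen_t id = q[head++];
          int xz = (int)(id % nz);
          int xy = (int)((id / nz) % ny);
          int xx = (int)(id / ((R_xlen_t)nz * ny));
          for (int ox = -1; ox <= 1; ++ox)
            for (int oy = -1; oy <= 1; ++oy)
              for (int oz = -1; oz <= 1; ++oz) {
                if (!ox && !oy && !oz) continue;
                int z2 = xz + oz, y2 = xy + oy, x2 = xx + ox;
                if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 ||
                    x2 >= nx)
                  continue;
                R_xlen_t id2 = idx3(z2, y2, x2, nz, ny);
                if (mask[id2] && !lab[id2]) { lab[id2] = next; q.push_back(id2); }
              }
        }
      }
  lab.attr("dim") = dim;
  return lab;
}

// ---------------------------------------------------------------------------
// Ellipsoid / cylinder rendering into an existing volume (max compositing).
//
// Somas: oriented ellipsoids with quadratic intensity falloff
//   I(u) = peak * (1 - |u|^2), |u| <= 1 in the ellipsoid frame.
// Trunks: cylinders of given radius from a start point along a direction,
// same quadratic falloff in the radial coordinate.
// Rotation passed as a row-major 3x3 matrix per object mapping world (x,y,z)
// offsets into the ellipsoid frame.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
void cpp_render_ellipsoids(NumericVector vol, IntegerVector dim,
                           NumericMatrix center_um,
                           NumericMatrix semi_um,
                           NumericMatrix rot,
                           NumericVector peak, NumericVector voxel_um) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double sz = voxel_um[0], sy = voxel_um[1], sx = voxel_um[2];
  int n = center_um.nrow();
  for (int i = 0; i < n; ++i) {
    double cx = center_um(i, 0), cy = center_um(i, 1), cz = center_um(i, 2);
    double rmax = std::max(semi_um(i, 0), std::max(semi_um(i, 1), semi_um(i, 2)));
    int x0 = std::max(0, (int)std::floor((cx - rmax) / sx));
    int x1 = std::min(nx - 1, (int)std::ceil((cx + rmax) / sx));
    int y0 = std::max(0, (int)std::floor((cy - rmax) / sy));
    int y1 = std::min(ny - 1, (int)std::ceil((cy + rmax) / sy));
    int z0 = std::max(0, (int)std::floor((cz - rmax) / sz));
    int z1 = std::min(nz - 1, (int)std::ceil((cz + rmax) / sz));
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y)
        for (int z = z0; z <= z1; ++z) {
          double wx = (x + 0.5) * sx - cx, wy = (y + 0.5) * sy - cy,
                 wz = (z + 0.5) * sz - cz;
          double ux = rot(i, 0) * wx + rot(i, 1) * wy + rot(i, 2) * wz;
          double uy = rot(i, 3) * wx + rot(i, 4) * wy + rot(i, 5) * wz;
          double uz = rot(i, 6) * wx + rot(i, 7) * wy + rot(i, 8) * wz;
          double q = ux * ux / (semi_um(i, 0) * semi_um(i, 0)) +
                     uy * uy / (semi_um(i, 1) * semi_um(i, 1)) +
                     uz * uz / (semi_um(i, 2) * semi_um(i, 2));
          if (q > 1.0) continue;
          double v = peak[i] * (1.0 - q);
          R_xlen_t id = idx3(z, y, x, nz, ny);
          if (v > vol[id]) vol[id] = v;
        }
  }
}

// [[Rcpp::export]]
void cpp_render_cylinders(NumericVector vol, IntegerVector dim,
                          IntegerVector owner_out,
                          NumericMatrix start_um,
                          NumericMatrix dir_unit,
                          NumericVector length_um, NumericVector radius_um,
                          NumericVector peak, IntegerVector owner_id,
                          NumericVector voxel_um) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double sz = voxel_um[0], sy = voxel_um[1], sx = voxel_um[2];
  bool track = owner_out.size() > 0;
  int n = start_um.nrow();
  for (int i = 0; i < n; ++i) {
    double ox = start_um(i, 0), oy = start_um(i, 1), oz = start_um(i, 2);
    double dx = dir_unit(i, 0), dy = dir_unit(i, 1), dz = dir_unit(i, 2);
    double L = length_um[i], R = radius_um[i];
    double exl = std::max(std::fabs(dx) * L, 0.0) + R;
    double eyl = std::max(std::fabs(dy) * L, 0.0) + R;
    double ezl = std::max(std::fabs(dz) * L, 0.0) + R;
    double mx0 = std::min(ox, ox + dx * L) - R, mx1 = std::max(ox, ox + dx * L) + R;
    double my0 = std::min(oy, oy + dy * L) - R, my1 = std::max(oy, oy + dy * L) + R;
    double mz0 = std::min(oz, oz + dz * L) - R, mz1 = std::max(oz, oz + dz * L) + R;
    (void)exl; (void)eyl; (void)ezl;
    int x0 = std::max(0, (int)std::floor(mx0 / sx));
    int x1 = std::min(nx - 1, (int)std::ceil(mx1 / sx));
    int y0 = std::max(0, (int)std::floor(my0 / sy));
    int y1 = std::min(ny - 1, (int)std::ceil(my1 / sy));
    int z0 = std::max(0, (int)std::floor(mz0 / sz));
    int z1 = std::min(nz - 1, (int)std::ceil(mz1 / sz));
    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y)
        for (int z = z0; z <= z1; ++z) {
          double wx = (x + 0.5) * sx - ox, wy = (y + 0.5) * sy - oy,
                 wz = (z + 0.5) * sz - oz;
          double t = wx * dx + wy * dy + wz * dz;
          if (t < 0 || t > L) continue;
          double px = wx - t * dx, py = wy - t * dy, pz = wz - t * dz;
          double r2 = px * px + py * py + pz * pz;
          if (r2 > R * R) continue;
          double v = peak[i] * (1.0 - r2 / (R * R));
          R_xlen_t id = idx3(z, y, x, nz, ny);
          if (v > vol[id]) vol[id] = v;
          if (track) owner_out[id] = owner_id[i];
        }
  }
}

// ---------------------------------------------------------------------------
// Surface area of a binary mask by marching tetrahedra on a smoothed
// indicator field at iso-level 0.5; vertices interpolated along cell edges,
// coordinates in physical micrometres. `field` must already be padded so
// the 0.5 level set closes inside the volume.
// ---------------------------------------------------------------------------

static inline void lerp_vert(const double *p1, const double *p2, double v1,
                             double v2, double iso, double *out) {
  double t = (iso - v1) / (v2 - v1);
  out[0] = p1[0] + t * (p2[0] - p1[0]);
  out[1] = p1[1] + t * (p2[1] - p1[1]);
  out[2] = p1[2] + t * (p2[2] - p1[2]);
}

static inline double tri_area(const double *a, const double *b, const double *c) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// tetrahedron decomposition of the unit cube (6 tets sharing diagonal 0-6)
static const int TETS[6][4] = {{0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
                               {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};
// cube corner offsets (x, y, z)
static const int CORN[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                               {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};

// [[Rcpp::export]]
double cpp_mt_surface_area(NumericVector field, IntegerVector dim,
                           NumericVector voxel_um, double iso) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double sz = voxel_um[0], sy = voxel_um[1], sx = voxel_um[2];
  double area = 0.0;
  double P[8][3], V[8];
  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int cx = x + CORN[c][0], cy = y + CORN[c][1], cz = z + CORN[c][2];
          V[c] = field[idx3(cz, cy, cx, nz, ny)];
          P[c][0] = cx * sx; P[c][1] = cy * sy; P[c][2] = cz * sz;
          if (V[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int above[4], nab = 0;
          for (int k = 0; k < 4; ++k) above[k] = V[T[k]] > iso ? (++nab, 1) : 0;
          if (nab == 0 || nab == 4) continue;
          // collect crossing-edge vertices
          double verts[4][3];
          int nv = 0;
          static const int EDGES[6][2] = {{0, 1}, {0, 2}, {0, 3},
                                          {1, 2}, {1, 3}, {2, 3}};
          for (int e = 0; e < 6; ++e) {
            int a = T[EDGES[e][0]], b = T[EDGES[e][1]];
            if ((V[a] > iso) != (V[b] > iso)) {
              lerp_vert(P[a], P[b], V[a], V[b], iso, verts[nv]);
              ++nv;
            }
          }
          if (nv == 3) {
            area += tri_area(verts[0], verts[1], verts[2]);
          } else if (nv == 4) {
            // quad: order vertices around the cut; split along shorter diag.
            // With 2-above/2-below tet cuts, the four crossing edges form a
            // quad whose opposite corners are (0,3) and (1,2) in edge order;
            // triangulate as (0,1,2) + (1,3,2) after pairing by shared tet
            // vertices. Edge order from EDGES gives a "Z" pattern: reorder.
            double q[4][3];
            // edges crossing: pattern is always edges {a-c, a-d, b-c, b-d}
            // in EDGES order for above-set {a,b}; swap last two for a loop.
            for (int k = 0; k < 3; ++k) {
              q[0][k] = verts[0][k]; q[1][k] = verts[1][k];
              q[2][k] = verts[3][k]; q[3][k] = verts[2][k];
            }
            area += tri_area(q[0], q[1], q[2]) + tri_area(q[0], q[2], q[3]);
          }
        }
      }
  return area;
}

// ---------------------------------------------------------------------------
// Nearest-neighbor distance per point via uniform grid binning.
// Exactly reproduces brute force: squared distances in double, sqrt at end.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_nn_distance(NumericMatrix pts) {
  int n = pts.nrow();
  NumericVector out(n, NA_REAL);
  if (n < 2) return out;
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = hi[d] = pts(0, d);
    for (int i = 1; i < n; ++i) {
      lo[d] = std::min(lo[d], pts(i, d));
      hi[d] = std::max(hi[d], pts(i, d));
    }
  }
  // per-dimension grid, ~n^(1/3) cells per axis; degenerate (zero-extent)
  // axes collapse to a single cell
  int m = std::max(1, (int)std::floor(std::cbrt((double)n)));
  int nc[3];
  double cell[3];
  for (int d = 0; d < 3; ++d) {
    double ext = hi[d] - lo[d];
    if (ext <= 0) { nc[d] = 1; cell[d] = 1.0; }
    else { nc[d] = m; cell[d] = ext / m * (1 + 1e-12); }
  }
  auto cell_of = [&](int i, int d) {
    int c = (int)std::floor((pts(i, d) - lo[d]) / cell[d]);
    if (c < 0) c = 0;
    if (c >= nc[d]) c = nc[d] - 1;
    return c;
  };
  std::vector<std::vector<int>> bins((size_t)nc[0] * nc[1] * nc[2]);
  auto bin_id = [&](int cx, int cy, int cz) {
    return (size_t)cx + (size_t)nc[0] * ((size_t)cy + (size_t)nc[1] * cz);
  };
  for (int i = 0; i < n; ++i)
    bins[bin_id(cell_of(i, 0), cell_of(i, 1), cell_of(i, 2))].push_back(i);

  // ring r covers all points within r * cover of the query cell, where
  // cover is the smallest cell edge among non-degenerate axes
  double cover = std::numeric_limits<double>::infinity();
  for (int d = 0; d < 3; ++d)
    if (nc[d] > 1) cover = std::min(cover, cell[d]);
  int max_ring = std::max(nc[0], std::max(nc[1], nc[2]));

  for (int i = 0; i < n; ++i) {
    int cx = cell_of(i, 0), cy = cell_of(i, 1), cz = cell_of(i, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int ring = 0; ring <= max_ring; ++ring) {
      for (int dx = -ring; dx <= ring; ++dx)
        for (int dy = -ring; dy <= ring; ++dy)
          for (int dz = -ring; dz <= ring; ++dz) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != ring)
              continue;
            int bx = cx + dx, by = cy + dy, bz = cz + dz;
            if (bx < 0 || bx >= nc[0] || by < 0 || by >= nc[1] || bz < 0 ||
                bz >= nc[2])
              continue;
            for (int j : bins[bin_id(bx, by, bz)]) {
              if (j == i) continue;
              double a = pts(i, 0) - pts(j, 0), b = pts(i, 1) - pts(j, 1),
                     c = pts(i, 2) - pts(j, 2);
              double d2 = a * a + b * b + c * c;
              if (d2 < best) best = d2;
            }
          }
      if (best < std::numeric_limits<double>::infinity() &&
          std::sqrt(best) <= ring * cover)
        break;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Hungarian algorithm (potentials / shortest augmenting path, O(n^3)) for a
// square cost matrix. Returns, for each row, the assigned column (1-based).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_hungarian(NumericMatrix cost) {
  int n = cost.nrow();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector assign(n);
  for (int j = 1; j <= n; ++j)
    if (p[j] > 0) assign[p[j] - 1] = j;
  return assign;
}
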