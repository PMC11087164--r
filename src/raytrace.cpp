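// Deterministic ray-trace dose engine core: water-equivalent (radiological)
// depth by fixed-step midpoint marching through a voxelized relative
// electron density volume, and point doses for a divergent beam with
// inverse-square falloff and a buildup-then-exponential depth factor.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  const double *v;
  int nx, ny, nz;
  double x0, y0, z0, dx, dy, dz;
  double background;

  double lookup(double x, double y, double z) const {
    int i = (int)std::floor((x - x0) / dx + 0.5);
    int j = (int)std::floor((y - y0) / dy + 0.5);
    int k = (int)std::floor((z - z0) / dz + 0.5);
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz)
      return background;
    return v[i + (size_t)nx * (j + (size_t)ny * k)];
  }
};

// Clip parameter interval [0, L] of the segment s + t*u to the grid's
// voxel-edge bounding box.  Returns false when the segment misses it.
bool clip_to_box(const Grid &g, const double s[3], const double u[3],
                 double L, double &t0, double &t1) {
  double lo[3] = {g.x0 - 0.5 * g.dx, g.y0 - 0.5 * g.dy, g.z0 - 0.5 * g.dz};
  double hi[3] = {g.x0 + (g.nx - 0.5) * g.dx, g.y0 + (g.ny - 0.5) * g.dy,
                  g.z0 + (g.nz - 0.5) * g.dz};
  t0 = 0.0; t1 = L;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(u[a]) < 1e-14) {
      if (s[a] < lo[a] || s[a] > hi[a]) return false;
    } else {
      double ta = (lo[a] - s[a]) / u[a], tb = (hi[a] - s[a]) / u[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
      if (t0 > t1) return false;
    }
  }
  return true;
}

// Water-equivalent path length from source to target.
double weq_depth(const Grid &g, const double src[3], const double tgt[3],
                 double step) {
  double u[3] = {tgt[0] - src[0], tgt[1] - src[1], tgt[2] - src[2]};
  double L = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  if (L < 1e-12) return 0.0;
  for (int a = 0; a < 3; ++a) u[a] /= L;
  double t0, t1;
  double depth = 0.0;
  if (clip_to_box(g, src, u, L, t0, t1) && t1 > t0) {
    int m = (int)std::ceil((t1 - t0) / step);
    double h = (t1 - t0) / m;
    for (int k = 0; k < m; ++k) {
      double t = t0 + (k + 0.5) * h;
      depth += h * g.lookup(src[0] + t * u[0], src[1] + t * u[1],
                            src[2] + t * u[2]);
    }
    depth += g.background * (t0 + (L - t1));
  } else {
    depth = g.background * L;
  }
  return depth;
}

Grid make_grid(const NumericVector &red, const IntegerVector &dims,
               const NumericVector &origin, const NumericVector &spacing,
               double background) {
  Grid g;
  g.v = REAL(red);
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.x0 = origin[0]; g.y0 = origin[1]; g.z0 = origin[2];
  g.dx = spacing[0]; g.dy = spacing[1]; g.dz = spacing[2];
  g.background = background;
  return g;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_radiological_depth(NumericVector red, IntegerVector dims,
                                     NumericVector origin, NumericVector spacing,
                                     NumericVector source, NumericMatrix targets,
                                     double step, double background) {
  if (step <= 0) stop("step must be positive");
  Grid g = make_grid(red, dims, origin, spacing, background);
  double src[3] = {source[0], source[1], source[2]};
  int n = targets.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double tgt[3] = {targets(i, 0), targets(i, 1), targets(i, 2)};
    out[i] = weq_depth(g, src, tgt, step);
  }
  return out;
}

// Dose at arbitrary points for one beam.
//   source      beam focal spot (mm, phantom frame)
//   e_cross     unit vector, crossline field direction at the isocenter
//   e_axial     unit vector, axial field direction (cylinder axis)
//   half_fx/fy  field half-widths at the isocenter plane (mm)
//   lateral_shift  shift (mm) of the field-membership test along e_cross
// [[Rcpp::export]]
NumericVector cpp_dose_points(NumericVector red, IntegerVector dims,
                              NumericVector origin, NumericVector spacing,
                              NumericVector source, NumericMatrix pts,
                              double step, double background,
                              double sad, double mu_water,
                              double buildup_depth, double entrance_factor,
                              double dose_per_mu, double mu,
                              NumericVector e_cross, NumericVector e_axial,
                              double half_fx, double half_fy,
                              double lateral_shift) {
  if (step <= 0) stop("step must be positive");
  Grid g = make_grid(red, dims, origin, spacing, background);
  double src[3] = {source[0], source[1], source[2]};
  // beam axis: source -> isocenter (origin of the phantom frame)
  double b[3] = {-src[0], -src[1], -src[2]};
  double bn = std::sqrt(b[0] * b[0] + b[1] * b[1] + b[2] * b[2]);
  for (int a = 0; a < 3; ++a) b[a] /= bn;
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double v[3] = {p[0] - src[0], p[1] - src[1], p[2] - src[2]};
    double r2 = v[0] * v[0] + v[1] * v[1] + v[2] * v[2];
    double u = v[0] * b[0] + v[1] * b[1] + v[2] * b[2];  // depth along axis
    if (u <= 1e-9) { out[i] = 0.0; continue; }
    // field membership, tested at the laterally shifted point
    double ps[3] = {p[0] + lateral_shift * e_cross[0],
                    p[1] + lateral_shift * e_cross[1],
                    p[2] + lateral_shift * e_cross[2]};
    double vs[3] = {ps[0] - src[0], ps[1] - src[1], ps[2] - src[2]};
    double us = vs[0] * b[0] + vs[1] * b[1] + vs[2] * b[2];
    double cx = (vs[0] * e_cross[0] + vs[1] * e_cross[1] + vs[2] * e_cross[2]) *
                sad / us;
    double cz = (vs[0] * e_axial[0] + vs[1] * e_axial[1] + vs[2] * e_axial[2]) *
                sad / us;
    if (std::fabs(cx) > half_fx || std::fabs(cz) > half_fy) {
      out[i] = 0.0; continue;
    }
    double d = weq_depth(g, src, p, step);
    double ramp = (buildup_depth > 0 && d < buildup_depth)
      ? entrance_factor + (1.0 - entrance_factor) * d / buildup_depth
      : 1.0;
    out[i] = mu * dose_per_mu * (sad * sad / r2) * ramp * std::exp(-mu_water * d);
  }
  return out;
}
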