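#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

// Array layout convention (fixed repo-wide): R arrays dim = (nx, ny, nz),
// column-major, voxel (i,j,k) 0-based at linear index i + nx*(j + ny*k).
// Physical position of voxel (i,j,k) = origin + (i,j,k) * spacing (micron).

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---------------------------------------------------------------------------
// Interpolation
// ---------------------------------------------------------------------------

// mode: 0 = nearest, 1 = trilinear, 2 = tricubic (Keys / Catmull-Rom)
// pts are continuous 0-based voxel coordinates; outside the domain -> background
// [[Rcpp::export]]
NumericVector cpp_interp(NumericVector img, NumericMatrix pts, int mode,
                         double background) {
  IntegerVector dim = img.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double *d = img.begin();

  for (int s = 0; s < n; ++s) {
    double x = pts(s, 0), y = pts(s, 1), z = pts(s, 2);
    if (x < -0.5 || y < -0.5 || z < -0.5 ||
        x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5) {
      out[s] = background;
      continue;
    }
    if (mode == 0) {
      int i = (int)clampd(std::floor(x + 0.5), 0, nx - 1);
      int j = (int)clampd(std::floor(y + 0.5), 0, ny - 1);
      int k = (int)clampd(std::floor(z + 0.5), 0, nz - 1);
      out[s] = d[i + (size_t)nx * (j + (size_t)ny * k)];
    } else if (mode == 1) {
      double xc = clampd(x, 0, nx - 1), yc = clampd(y, 0, ny - 1),
             zc = clampd(z, 0, nz - 1);
      int i0 = (int)std::floor(xc); if (i0 > nx - 2) i0 = nx - 2; if (nx == 1) i0 = 0;
      int j0 = (int)std::floor(yc); if (j0 > ny - 2) j0 = ny - 2; if (ny == 1) j0 = 0;
      int k0 = (int)std::floor(zc); if (k0 > nz - 2) k0 = nz - 2; if (nz == 1) k0 = 0;
      double tx = xc - i0, ty = yc - j0, tz = zc - k0;
      int i1 = nx == 1 ? i0 : i0 + 1, j1 = ny == 1 ? j0 : j0 + 1,
          k1 = nz == 1 ? k0 : k0 + 1;
      double v = 0.0;
      for (int dk = 0; dk < 2; ++dk)
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            double w = (di ? tx : 1 - tx) * (dj ? ty : 1 - ty) * (dk ? tz : 1 - tz);
            int ii = di ? i1 : i0, jj = dj ? j1 : j0, kk = dk ? k1 : k0;
            v += w * d[ii + (size_t)nx * (jj + (size_t)ny * kk)];
          }
      out[s] = v;
    } else {
      // tricubic Keys kernel, clamp-to-edge
      double xc = clampd(x, 0, nx - 1), yc = clampd(y, 0, ny - 1),
             zc = clampd(z, 0, nz - 1);
      int i0 = (int)std::floor(xc), j0 = (int)std::floor(yc),
          k0 = (int)std::floor(zc);
      double tx = xc - i0, ty = yc - j0, tz = zc - k0;
      double wx[4], wy[4], wz[4];
      auto keys = [](double t, double w[4]) {
        w[0] = ((-t + 2) * t - 1) * t / 2;
        w[1] = ((3 * t - 5) * t * t + 2) / 2;
        w[2] = ((-3 * t + 4) * t + 1) * t / 2;
        w[3] = (t - 1) * t * t / 2;
      };
      keys(tx, wx); keys(ty, wy); keys(tz, wz);
      double v = 0.0;
      for (int dk = 0; dk < 4; ++dk) {
        int kk = (int)clampd(k0 - 1 + dk, 0, nz - 1);
        for (int dj = 0; dj < 4; ++dj) {
          int jj = (int)clampd(j0 - 1 + dj, 0, ny - 1);
          double wyz = wy[dj] * wz[dk];
          for (int di = 0; di < 4; ++di) {
            int ii = (int)clampd(i0 - 1 + di, 0, nx - 1);
            v += wx[di] * wyz * d[ii + (size_t)nx * (jj + (size_t)ny * kk)];
          }
        }
      }
      out[s] = v;
    }
  }
  return out;
}

// Trilinear value + gradient (d value / d voxel-coordinate).
// [[Rcpp::export]]
List cpp_interp_grad(NumericVector img, NumericMatrix pts, double background) {
  IntegerVector dim = img.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector val(n);
  NumericMatrix grad(n, 3);
  LogicalVector inside(n);
  const double *d = img.begin();

  for (int s = 0; s < n; ++s) {
    double x = pts(s, 0), y = pts(s, 1), z = pts(s, 2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      val[s] = background;
      inside[s] = false;
      continue;
    }
    inside[s] = true;
    int i0 = (int)std::floor(x); if (i0 > nx - 2) i0 = nx - 2; if (nx == 1) i0 = 0;
    int j0 = (int)std::floor(y); if (j0 > ny - 2) j0 = ny - 2; if (ny == 1) j0 = 0;
    int k0 = (int)std::floor(z); if (k0 > nz - 2) k0 = nz - 2; if (nz == 1) k0 = 0;
    double tx = x - i0, ty = y - j0, tz = z - k0;
    double c[2][2][2];
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          int ii = std::min(i0 + di, nx - 1), jj = std::min(j0 + dj, ny - 1),
              kk = std::min(k0 + dk, nz - 1);
          c[di][dj][dk] = d[ii + (size_t)nx * (jj + (size_t)ny * kk)];
        }
    double v = 0, gx = 0, gy = 0, gz = 0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          double wx = di ? tx : 1 - tx, wy = dj ? ty : 1 - ty,
                 wz = dk ? tz : 1 - tz;
          double sx = di ? 1.0 : -1.0, sy = dj ? 1.0 : -1.0,
                 sz = dk ? 1.0 : -1.0;
          double cc = c[di][dj][dk];
          v += wx * wy * wz * cc;
          gx += sx * wy * wz * cc;
          gy += wx * sy * wz * cc;
          gz += wx * wy * sz * cc;
        }
    val[s] = v;
    grad(s, 0) = gx; grad(s, 1) = gy; grad(s, 2) = gz;
  }
  return List::create(_["value"] = val, _["grad"] = grad,
                      _["inside"] = inside);
}

// ---------------------------------------------------------------------------
// Cubic B-spline free-form deformation
// ---------------------------------------------------------------------------

static inline void bspline_w(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  w[1] = (4 - 6 * t2 + 3 * t3) / 6.0;
  w[2] = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// coef: array (ncx, ncy, ncz, 3) of control-point displacements (micron),
// control node g has physical position grid_origin + g * grid_spacing.
// pts: N x 3 physical points. Nodes outside the grid contribute zero
// displacement (identity extrapolation).
// [[Rcpp::export]]
NumericMatrix cpp_bspline_disp(NumericVector coef, NumericVector grid_origin,
                               NumericVector grid_spacing, NumericMatrix pts) {
  IntegerVector dim = coef.attr("dim");
  const int ncx = dim[0], ncy = dim[1], ncz = dim[2];
  const size_t plane = (size_t)ncx * ncy * ncz;
  const int n = pts.nrow();
  NumericMatrix out(n, 3);
  const double *cf = coef.begin();

  for (int s = 0; s < n; ++s) {
    double u[3], w[3][4];
    int base[3];
    for (int d = 0; d < 3; ++d) {
      u[d] = (pts(s, d) - grid_origin[d]) / grid_spacing[d];
      double fl = std::floor(u[d]);
      base[d] = (int)fl - 1;
      bspline_w(u[d] - fl, w[d]);
    }
    double acc[3] = {0, 0, 0};
    for (int dk = 0; dk < 4; ++dk) {
      int kk = base[2] + dk;
      if (kk < 0 || kk >= ncz) continue;
      for (int dj = 0; dj < 4; ++dj) {
        int jj = base[1] + dj;
        if (jj < 0 || jj >= ncy) continue;
        double wjk = w[1][dj] * w[2][dk];
        for (int di = 0; di < 4; ++di) {
          int ii = base[0] + di;
          if (ii < 0 || ii >= ncx) continue;
          double ww = w[0][di] * wjk;
          size_t idx = ii + (size_t)ncx * (jj + (size_t)ncy * kk);
          acc[0] += ww * cf[idx];
          acc[1] += ww * cf[idx + plane];
          acc[2] += ww * cf[idx + 2 * plane];
        }
      }
    }
    out(s, 0) = acc[0]; out(s, 1) = acc[1]; out(s, 2) = acc[2];
  }
  return out;
}

// NCC between fixed samples and the moving image evaluated at the B-spline
// deformed sample positions, plus the gradient of NCC with respect to the
// control-point displacements.  pts are fixed-space physical points; the
// transform is x -> x + base(x) + B(x) where base_disp carries the
// displacement accumulated by coarser levels (pass a 0 x 3 matrix for
// none).  Samples falling outside the moving domain contribute no
// gradient.
// [[Rcpp::export]]
List cpp_bspline_ncc_grad(NumericVector fixed_vals, NumericVector mov,
                          NumericVector mov_spacing, NumericVector mov_origin,
                          NumericMatrix pts, NumericMatrix base_disp,
                          NumericVector coef, NumericVector grid_origin,
                          NumericVector grid_spacing) {
  IntegerVector mdim = mov.attr("dim");
  const int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  IntegerVector cdim = coef.attr("dim");
  const int ncx = cdim[0], ncy = cdim[1], ncz = cdim[2];
  const size_t plane = (size_t)ncx * ncy * ncz;
  const int n = pts.nrow();
  const double *d = mov.begin();
  const double *cf = coef.begin();

  std::vector<double> mval(n), gphys(3 * (size_t)n);
  std::vector<char> ok(n);

  // pass 1: moving values + physical-space intensity gradients
  for (int s = 0; s < n; ++s) {
    double u[3], w[3][4];
    int base[3];
    double disp[3] = {0, 0, 0};
    for (int dd = 0; dd < 3; ++dd) {
      u[dd] = (pts(s, dd) - grid_origin[dd]) / grid_spacing[dd];
      double fl = std::floor(u[dd]);
      base[dd] = (int)fl - 1;
      bspline_w(u[dd] - fl, w[dd]);
    }
    for (int dk = 0; dk < 4; ++dk) {
      int kk = base[2] + dk;
      if (kk < 0 || kk >= ncz) continue;
      for (int dj = 0; dj < 4; ++dj) {
        int jj = base[1] + dj;
        if (jj < 0 || jj >= ncy) continue;
        double wjk = w[1][dj] * w[2][dk];
        for (int di = 0; di < 4; ++di) {
          int ii = base[0] + di;
          if (ii < 0 || ii >= ncx) continue;
          double ww = w[0][di] * wjk;
          size_t idx = ii + (size_t)ncx * (jj + (size_t)ncy * kk);
          disp[0] += ww * cf[idx];
          disp[1] += ww * cf[idx + plane];
          disp[2] += ww * cf[idx + 2 * plane];
        }
      }
    }
    const bool has_base = base_disp.nrow() == n;
    double bx = has_base ? base_disp(s, 0) : 0.0;
    double by = has_base ? base_disp(s, 1) : 0.0;
    double bz = has_base ? base_disp(s, 2) : 0.0;
    double vx = (pts(s, 0) + bx + disp[0] - mov_origin[0]) / mov_spacing[0];
    double vy = (pts(s, 1) + by + disp[1] - mov_origin[1]) / mov_spacing[1];
    double vz = (pts(s, 2) + bz + disp[2] - mov_origin[2]) / mov_spacing[2];
    if (vx < 0 || vy < 0 || vz < 0 || vx > nx - 1 || vy > ny - 1 ||
        vz > nz - 1) {
      ok[s] = 0; mval[s] = 0;
      gphys[3 * (size_t)s] = gphys[3 * (size_t)s + 1] = gphys[3 * (size_t)s + 2] = 0;
      continue;
    }
    ok[s] = 1;
    int i0 = (int)std::floor(vx); if (i0 > nx - 2) i0 = nx - 2;
    int j0 = (int)std::floor(vy); if (j0 > ny - 2) j0 = ny - 2;
    int k0 = (int)std::floor(vz); if (k0 > nz - 2) k0 = nz - 2;
    double tx = vx - i0, ty = vy - j0, tz = vz - k0;
    double v = 0, gx = 0, gy = 0, gz = 0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          double wx = di ? tx : 1 - tx, wy = dj ? ty : 1 - ty,
                 wz = dk ? tz : 1 - tz;
          double cc = d[(i0 + di) +
                        (size_t)nx * ((j0 + dj) + (size_t)ny * (k0 + dk))];
          v += wx * wy * wz * cc;
          gx += (di ? 1.0 : -1.0) * wy * wz * cc;
          gy += wx * (dj ? 1.0 : -1.0) * wz * cc;
          gz += wx * wy * (dk ? 1.0 : -1.0) * cc;
        }
    mval[s] = v;
    gphys[3 * (size_t)s]     = gx / mov_spacing[0];
    gphys[3 * (size_t)s + 1] = gy / mov_spacing[1];
    gphys[3 * (size_t)s + 2] = gz / mov_spacing[2];
  }

  // NCC over valid samples
  double fsum = 0, msum = 0;
  int nv = 0;
  for (int s = 0; s < n; ++s)
    if (ok[s]) { fsum += fixed_vals[s]; msum += mval[s]; ++nv; }
  NumericVector gradR(coef.size());
  gradR.attr("dim") = cdim;
  if (nv < 8) {
    return List::create(_["ncc"] = 0.0, _["grad"] = gradR, _["n"] = nv);
  }
  double fbar = fsum / nv, mbar = msum / nv;
  double sff = 0, smm = 0, sfm = 0;
  for (int s = 0; s < n; ++s) {
    if (!ok[s]) continue;
    double fc = fixed_vals[s] - fbar, mc = mval[s] - mbar;
    sff += fc * fc; smm += mc * mc; sfm += fc * mc;
  }
  if (sff < 1e-12 || smm < 1e-12) {
    return List::create(_["ncc"] = 0.0, _["grad"] = gradR, _["n"] = nv);
  }
  double denom = std::sqrt(sff * smm);
  double ncc = sfm / denom;

  // pass 2: scatter dNCC/d coef
  double *gr = gradR.begin();
  for (int s = 0; s < n; ++s) {
    if (!ok[s]) continue;
    double fc = fixed_vals[s] - fbar, mc = mval[s] - mbar;
    double dm = (fc - (sfm / smm) * mc) / denom;  // dNCC / d mval[s]
    double u[3], w[3][4];
    int base[3];
    for (int dd = 0; dd < 3; ++dd) {
      u[dd] = (pts(s, dd) - grid_origin[dd]) / grid_spacing[dd];
      double fl = std::floor(u[dd]);
      base[dd] = (int)fl - 1;
      bspline_w(u[dd] - fl, w[dd]);
    }
    double gx = dm * gphys[3 * (size_t)s], gy = dm * gphys[3 * (size_t)s + 1],
           gz = dm * gphys[3 * (size_t)s + 2];
    for (int dk = 0; dk < 4; ++dk) {
      int kk = base[2] + dk;
      if (kk < 0 || kk >= ncz) continue;
      for (int dj = 0; dj < 4; ++dj) {
        int jj = base[1] + dj;
        if (jj < 0 || jj >= ncy) continue;
        double wjk = w[1][dj] * w[2][dk];
        for (int di = 0; di < 4; ++di) {
          int ii = base[0] + di;
          if (ii < 0 || ii >= ncx) continue;
          double ww = w[0][di] * wjk;
          size_t idx = ii + (size_t)ncx * (jj + (size_t)ncy * kk);
          gr[idx] += ww * gx;
          gr[idx + plane] += ww * gy;
          gr[idx + 2 * plane] += ww * gz;
        }
      }
    }
  }
  return List::create(_["ncc"] = ncc, _["grad"] = gradR, _["n"] = nv);
}

// Mean Euclidean distance between B-spline-transformed points and targets,
// plus its gradient with respect to the control-point displacements.
// [[Rcpp::export]]
List cpp_point_term_grad(NumericVector coef, NumericVector grid_origin,
                         NumericVector grid_spacing, NumericMatrix pts,
                         NumericMatrix targets) {
  IntegerVector cdim = coef.attr("dim");
  const int ncx = cdim[0], ncy = cdim[1], ncz = cdim[2];
  const size_t plane = (size_t)ncx * ncy * ncz;
  const int n = pts.nrow();
  const double *cf = coef.begin();
  NumericVector gradR(coef.size());
  gradR.attr("dim") = cdim;
  double *gr = gradR.begin();
  double total = 0;

  for (int s = 0; s < n; ++s) {
    double u[3], w[3][4];
    int base[3];
    double disp[3] = {0, 0, 0};
    for (int dd = 0; dd < 3; ++dd) {
      u[dd] = (pts(s, dd) - grid_origin[dd]) / grid_spacing[dd];
      double fl = std::floor(u[dd]);
      base[dd] = (int)fl - 1;
      bspline_w(u[dd] - fl, w[dd]);
    }
    for (int dk = 0; dk < 4; ++dk) {
      int kk = base[2] + dk;
      if (kk < 0 || kk >= ncz) continue;
      for (int dj = 0; dj < 4; ++dj) {
        int jj = base[1] + dj;
        if (jj < 0 || jj >= ncy) continue;
        double wjk = w[1][dj] * w[2][dk];
        for (int di = 0; di < 4; ++di) {
          int ii = base[0] + di;
          if (ii < 0 || ii >= ncx) continue;
          double ww = w[0][di] * wjk;
          size_t idx = ii + (size_t)ncx * (jj + (size_t)ncy * kk);
          disp[0] += ww * cf[idx];
          disp[1] += ww * cf[idx + plane];
          disp[2] += ww * cf[idx + 2 * plane];
        }
      }
    }
    double e[3] = {pts(s, 0) + disp[0] - targets(s, 0),
                   pts(s, 1) + disp[1] - targets(s, 1),
                   pts(s, 2) + disp[2] - targets(s, 2)};
    double dist = std::sqrt(e[0] * e[0] + e[1] * e[1] + e[2] * e[2]);
    total += dist;
    if (dist < 1e-12) continue;
    double gx = e[0] / dist / n, gy = e[1] / dist / n, gz = e[2] / dist / n;
    for (int dk = 0; dk < 4; ++dk) {
      int kk = base[2] + dk;
      if (kk < 0 || kk >= ncz) continue;
      for (int dj = 0; dj < 4; ++dj) {
        int jj = base[1] + dj;
        if (jj < 0 || jj >= ncy) continue;
        double wjk = w[1][dj] * w[2][dk];
        for (int di = 0; di < 4; ++di) {
          int ii = base[0] + di;
          if (ii < 0 || ii >= ncx) continue;
          double ww = w[0][di] * wjk;
          size_t idx = ii + (size_t)ncx * (jj + (size_t)ncy * kk);
          gr[idx] += ww * gx;
          gr[idx + plane] += ww * gy;
          gr[idx + 2 * plane] += ww * gz;
        }
      }
    }
  }
  return List::create(_["value"] = total / n, _["grad"] = gradR);
}

// ---------------------------------------------------------------------------
// Anisotropic Euclidean distance transform (Felzenszwalb & Huttenlocher)
// ---------------------------------------------------------------------------

// large finite sentinel standing in for "no source on this line";
// far above any realizable squared distance yet safe in arithmetic
static const double DT_BIG = 1e15;

static void dt1d(std::vector<double> &f, std::vector<double> &out, int n,
                 double s2) {
  // squared distance transform along one axis with squared spacing s2
  static thread_local std::vector<int> v;
  static thread_local std::vector<double> zb;
  v.assign(n, 0);
  zb.assign(n + 1, 0.0);
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double sval;
    while (true) {
      double sden = 2.0 * s2 * (q - v[k]);
      sval = ((f[q] + s2 * (double)q * q) -
              (f[v[k]] + s2 * (double)v[k] * v[k])) / sden;
      if (sval <= zb[k] && k > 0) { --k; } else break;
    }
    if (sval <= zb[k]) {  // k == 0: new parabola dominates everywhere
      v[0] = q;
      zb[1] = std::numeric_limits<double>::infinity();
      continue;
    }
    ++k;
    v[k] = q;
    zb[k] = sval;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    out[q] = s2 * dq * dq + f[v[k]];
  }
}

// Distance (micron) from every voxel center to the nearest foreground
// (mask != 0) voxel center, anisotropy-aware.
// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, NumericVector spacing) {
  IntegerVector dim = mask.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvox = (size_t)nx * ny * nz;
  std::vector<double> D(nvox);
  for (size_t i = 0; i < nvox; ++i) D[i] = mask[i] ? 0.0 : DT_BIG;

  std::vector<double> f, o;
  // x axis
  f.resize(nx); o.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t off = (size_t)nx * (j + (size_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = D[off + i];
      dt1d(f, o, nx, spacing[0] * spacing[0]);
      for (int i = 0; i < nx; ++i) D[off + i] = o[i];
    }
  // y axis
  f.resize(ny); o.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j)
        f[j] = D[i + (size_t)nx * (j + (size_t)ny * k)];
      dt1d(f, o, ny, spacing[1] * spacing[1]);
      for (int j = 0; j < ny; ++j)
        D[i + (size_t)nx * (j + (size_t)ny * k)] = o[j];
    }
  // z axis
  f.resize(nz); o.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k)
        f[k] = D[i + (size_t)nx * (j + (size_t)ny * k)];
      dt1d(f, o, nz, spacing[2] * spacing[2]);
      for (int k = 0; k < nz; ++k)
        D[i + (size_t)nx * (j + (size_t)ny * k)] = o[k];
    }

  NumericVector out(nvox);
  out.attr("dim") = dim;
  for (size_t i = 0; i < nvox; ++i)
    out[i] = D[i] >= DT_BIG ? R_PosInf : std::sqrt(D[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Connected components (6-connectivity), BFS
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_cc(IntegerVector mask) {
  IntegerVector dim = mask.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvox = (size_t)nx * ny * nz;
  IntegerVector lab(nvox);
  lab.attr("dim") = dim;
  int next = 0;
  std::queue<size_t> q;
  const int dxs[6] = {-1, 1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, -1, 1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, -1, 1};

  for (size_t s = 0; s < nvox; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      size_t cur = q.front(); q.pop();
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((size_t)nx * ny);
      for (int m = 0; m < 6; ++m) {
        int ii = i + dxs[m], jj = j + dys[m], kk = k + dzs[m];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        size_t nb = ii + (size_t)nx * (jj + (size_t)ny * kk);
        if (mask[nb] && !lab[nb]) { lab[nb] = next; q.push(nb); }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing (reflected boundary)
// ---------------------------------------------------------------------------

static void smooth_axis(std::vector<double> &data, int nx, int ny, int nz,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  int radius = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * radius + 1);
  double sum = 0;
  for (int t = -radius; t <= radius; ++t) {
    kern[t + radius] = std::exp(-0.5 * t * t / (sigma * sigma));
    sum += kern[t + radius];
  }
  for (auto &v : kern) v /= sum;
  int n = axis == 0 ? nx : (axis == 1 ? ny : nz);
  size_t stride = axis == 0 ? 1 : (axis == 1 ? (size_t)nx : (size_t)nx * ny);
  std::vector<double> line(n);
  int n1 = axis == 0 ? ny : nx;
  int n2 = axis == 2 ? ny : nz;
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      size_t off;
      if (axis == 0) off = (size_t)nx * (a + (size_t)ny * b);
      else if (axis == 1) off = a + (size_t)nx * ny * b;
      else off = a + (size_t)nx * b;
      for (int p = 0; p < n; ++p) line[p] = data[off + stride * p];
      for (int p = 0; p < n; ++p) {
        double acc = 0;
        for (int t = -radius; t <= radius; ++t) {
          int pp = p + t;
          if (pp < 0) pp = -pp - 1;
          if (pp >= n) pp = 2 * n - pp - 1;
          if (pp < 0) pp = 0;
          if (pp >= n) pp = n - 1;
          acc += kern[t + radius] * line[pp];
        }
        data[off + stride * p] = acc;
      }
    }
}

// sigma per axis in voxel units
// [[Rcpp::export]]
NumericVector cpp_smooth_gauss(NumericVector img, NumericVector sigma) {
  IntegerVector dim = img.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> data(img.begin(), img.end());
  smooth_axis(data, nx, ny, nz, 0, sigma[0]);
  smooth_axis(data, nx, ny, nz, 1, sigma[1]);
  smooth_axis(data, nx, ny, nz, 2, sigma[2]);
  NumericVector out(data.begin(), data.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Voxelwise fusion across a stack of images (columns of a matrix)
// ---------------------------------------------------------------------------

// method 0 = mean, 1 = median with even count -> lower of the two middle
// values (preserves original 8-bit gray levels).
// [[Rcpp::export]]
NumericVector cpp_fuse(NumericMatrix stack, int method) {
  const int n = stack.nrow(), k = stack.ncol();
  NumericVector out(n);
  std::vector<double> buf(k);
  for (int i = 0; i < n; ++i) {
    if (method == 0) {
      double s = 0;
      for (int j = 0; j < k; ++j) s += stack(i, j);
      out[i] = s / k;
    } else {
      for (int j = 0; j < k; ++j) buf[j] = stack(i, j);
      int mid = (k - 1) / 2;  // lower middle for even k
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      out[i] = buf[mid];
    }
  }
  return out;
}
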