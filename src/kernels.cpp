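// Cone-beam projection / backprojection kernels.
//
// Conventions (shared with the R layer):
//  * 0-based index k on an axis with n elements and spacing d maps to the
//    centered physical coordinate (k - (n-1)/2) * d.
//  * Volume array dims (nu, nv, nz), column-major; the rotated frame at view
//    angle theta has the lateral detector axis u' and the depth axis v', with
//    U = u'*cos(theta) + v'*sin(theta), V = -u'*sin(theta) + v'*cos(theta).
//    The source sits at v' = -DSO (u' = sourceX for displaced-source views),
//    the detector plane at v' = +DDO.
//  * Projection stack dims (rows = detector y, cols = detector x, views).
//  * Misalignment chain, projector direction (real pixel -> ideal coord):
//    Eq-1 shift-then-skew rotation, then inverse inclination per axis
//    (roll acts on x, tilt on y). The backprojector applies the exact
//    inverse chain. All branches are skipped when the corresponding
//    parameter is exactly zero so that the all-zero path is arithmetically
//    identical to the ideal kernels.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// View parameter matrix columns (one row per view)
enum VP { VP_THETA = 0, VP_XS, VP_YS, VP_SKEW, VP_ROLL, VP_TILT,
          VP_ZSHIFT, VP_DSO, VP_DDO, VP_SRCX, VP_NCOL };

// inclined-detector map: ideal in-plane coordinate -> position on detector
// inclined by eps about the piercing point; L = source-detector distance.
static inline double incl_fwd(double pa, double eps, double L) {
  double den = L * std::cos(eps) + pa * std::sin(eps);
  return L * pa / den;
}
// exact inverse of incl_fwd
static inline double incl_inv(double pa2, double eps, double L) {
  double den = L - pa2 * std::sin(eps);
  return L * pa2 * std::cos(eps) / den;
}

static inline double tri_sample(const double* f, int nu, int nv, int nz,
                                double fu, double fv, double fz) {
  int u0 = (int)std::floor(fu), v0 = (int)std::floor(fv),
      z0 = (int)std::floor(fz);
  double du = fu - u0, dv = fv - v0, dz = fz - z0;
  double acc = 0.0;
  for (int a = 0; a < 2; ++a) {
    int uu = u0 + a;
    if (uu < 0 || uu >= nu) continue;
    double wa = a ? du : 1.0 - du;
    if (wa == 0.0) continue;
    for (int b = 0; b < 2; ++b) {
      int vv = v0 + b;
      if (vv < 0 || vv >= nv) continue;
      double wb = b ? dv : 1.0 - dv;
      if (wb == 0.0) continue;
      for (int c = 0; c < 2; ++c) {
        int zz = z0 + c;
        if (zz < 0 || zz >= nz) continue;
        double wc = c ? dz : 1.0 - dz;
        if (wc == 0.0) continue;
        acc += wa * wb * wc * f[uu + (size_t)nu * (vv + (size_t)nv * zz)];
      }
    }
  }
  return acc;
}

static inline double bi_sample(const double* p, int nr, int nc,
                               double fy, double fx) {
  int y0 = (int)std::floor(fy), x0 = (int)std::floor(fx);
  double dy = fy - y0, dx = fx - x0;
  double acc = 0.0;
  for (int a = 0; a < 2; ++a) {
    int yy = y0 + a;
    if (yy < 0 || yy >= nr) continue;
    double wa = a ? dy : 1.0 - dy;
    if (wa == 0.0) continue;
    for (int b = 0; b < 2; ++b) {
      int xx = x0 + b;
      if (xx < 0 || xx >= nc) continue;
      double wb = b ? dx : 1.0 - dx;
      if (wb == 0.0) continue;
      acc += wa * wb * p[yy + (size_t)nr * xx];
    }
  }
  return acc;
}

// overlap of interval [a,b] with the cell [k-1/2, k+1/2]
static inline double cell_overlap(double a, double b, int k) {
  double lo = std::max(a, k - 0.5), hi = std::min(b, k + 0.5);
  return hi > lo ? hi - lo : 0.0;
}

// real-pixel -> ideal-coordinate misalignment chain (projector direction)
static inline void mis_to_ideal(double& x, double& y, const double* vp,
                                double L) {
  double xs = vp[VP_XS], ys = vp[VP_YS], skew = vp[VP_SKEW];
  if (xs != 0.0 || ys != 0.0 || skew != 0.0) {
    double xp = x + xs, yp = y + ys;
    if (skew != 0.0) {
      double cs = std::cos(skew), sn = std::sin(skew);
      x = cs * xp - sn * yp;
      y = sn * xp + cs * yp;
    } else {
      x = xp; y = yp;
    }
  }
  if (vp[VP_ROLL] != 0.0) x = incl_inv(x, vp[VP_ROLL], L);
  if (vp[VP_TILT] != 0.0) y = incl_inv(y, vp[VP_TILT], L);
}

// ideal-coordinate -> real-pixel chain (backprojector direction, exact
// inverse of mis_to_ideal)
static inline void mis_to_real(double& x, double& y, const double* vp,
                               double L) {
  if (vp[VP_ROLL] != 0.0) x = incl_fwd(x, vp[VP_ROLL], L);
  if (vp[VP_TILT] != 0.0) y = incl_fwd(y, vp[VP_TILT], L);
  double xs = vp[VP_XS], ys = vp[VP_YS], skew = vp[VP_SKEW];
  if (xs != 0.0 || ys != 0.0 || skew != 0.0) {
    if (skew != 0.0) {
      double cs = std::cos(skew), sn = std::sin(skew);
      double xr = cs * x + sn * y;
      double yr = -sn * x + cs * y;
      x = xr; y = yr;
    }
    x -= xs; y -= ys;
  }
}

static void get_view(const NumericMatrix& vpars, int w, double* vp) {
  for (int c = 0; c < VP_NCOL; ++c) vp[c] = vpars(w, c);
}

// distance-driven averaged sample in the volume at depth v' = v.
// latAxis: 0 -> overlap along volume u (fixed continuous V), 1 -> overlap
// along volume v (fixed continuous U). z interval always overlapped.
static double dd_volume_sample(const double* f, int nu, int nv, int nz,
                               int latAxis, double lat1, double lat2,
                               double fixedIdx, double z1, double z2) {
  int nLat = latAxis == 0 ? nu : nv;
  if (lat2 < lat1) std::swap(lat1, lat2);
  if (z2 < z1) std::swap(z1, z2);
  const double eps = 1e-9;
  double wLat = lat2 - lat1, wZ = z2 - z1;
  int lLo, lHi, zLo, zHi;
  if (wLat <= eps) { lLo = (int)std::floor(lat1); lHi = lLo + 1; }
  else { lLo = (int)std::floor(lat1 + 0.5); lHi = (int)std::floor(lat2 + 0.5); }
  if (wZ <= eps) { zLo = (int)std::floor(z1); zHi = zLo + 1; }
  else { zLo = (int)std::floor(z1 + 0.5); zHi = (int)std::floor(z2 + 0.5); }

  int j0 = (int)std::floor(fixedIdx);
  double tj = fixedIdx - j0;

  double acc = 0.0;
  for (int l = lLo; l <= lHi; ++l) {
    double wl;
    if (wLat <= eps) {
      // degenerate interval: linear interpolation
      if (l == lLo) wl = 1.0 - (lat1 - lLo);
      else wl = lat1 - lLo;
      if (wl <= 0.0) continue;
    } else {
      wl = cell_overlap(lat1, lat2, l) / wLat;
      if (wl <= 0.0) continue;
    }
    for (int z = zLo; z <= zHi; ++z) {
      double wz;
      if (wZ <= eps) {
        if (z == zLo) wz = 1.0 - (z1 - zLo);
        else wz = z1 - zLo;
        if (wz <= 0.0) continue;
      } else {
        wz = cell_overlap(z1, z2, z) / wZ;
        if (wz <= 0.0) continue;
      }
      if (z < 0 || z >= nz) continue;
      // interpolate along the fixed axis
      for (int c = 0; c < 2; ++c) {
        int j = j0 + c;
        double wj = c ? tj : 1.0 - tj;
        if (wj == 0.0) continue;
        int iu, iv;
        if (latAxis == 0) { iu = l; iv = j; } else { iu = j; iv = l; }
        if (iu < 0 || iu >= nu || iv < 0 || iv >= nv) continue;
        (void)nLat;
        acc += wl * wz * wj * f[iu + (size_t)nu * (iv + (size_t)nv * z)];
      }
    }
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector cpp_project(NumericVector vol, IntegerVector volDim,
                          NumericVector voxel, int fullNz, int z0,
                          int detRows, int detCols, NumericVector pixel,
                          NumericMatrix vpars, double step, double rad,
                          bool distanceDriven) {
  const int nu = volDim[0], nv = volDim[1], nz = volDim[2];
  const int nViews = vpars.nrow();
  const double du = voxel[0], dv = voxel[1], dz = voxel[2];
  const double px = pixel[0], py = pixel[1];
  const double cx = (detCols - 1) / 2.0, cy = (detRows - 1) / 2.0;
  const double cu = (nu - 1) / 2.0, cvv = (nv - 1) / 2.0;
  const double cz = (fullNz - 1) / 2.0 - z0;  // slab-local z center index
  const int nStep = (int)std::floor(2.0 * rad / step) + 1;
  const double* f = vol.begin();

  NumericVector out((size_t)detRows * detCols * nViews);
  double* o = out.begin();

  for (int w = 0; w < nViews; ++w) {
    double vp[VP_NCOL];
    get_view(vpars, w, vp);
    const double theta = vp[VP_THETA];
    const double dso = vp[VP_DSO], ddo = vp[VP_DDO], srcx = vp[VP_SRCX];
    const double L = dso + ddo;
    const double ct = std::cos(theta), st = std::sin(theta);
    const double zshift = vp[VP_ZSHIFT] * dz;

    for (int i = 0; i < detCols; ++i) {
      const double xp = (i - cx) * px;
      for (int j = 0; j < detRows; ++j) {
        const double yp = (j - cy) * py;
        double x = xp, y = yp;
        mis_to_ideal(x, y, vp, L);
        const double cosA = L / std::sqrt(L * L + x * x + y * y);
        double acc = 0.0;

        if (!distanceDriven) {
          for (int k = 0; k < nStep; ++k) {
            const double v = -rad + k * step;
            const double im = (dso + v) / L;
            const double u = srcx + (x - srcx) * im;
            const double zc = y * im - zshift;
            const double U = u * ct + v * st;
            const double V = -u * st + v * ct;
            acc += tri_sample(f, nu, nv, nz, U / du + cu, V / dv + cvv,
                              zc / dz + cz);
          }
        } else {
          // boundary corners of the pixel, through the same chain
          double xb1 = xp - px / 2.0, yb1 = yp - py / 2.0;
          double xb2 = xp + px / 2.0, yb2 = yp + py / 2.0;
          mis_to_ideal(xb1, yb1, vp, L);
          mis_to_ideal(xb2, yb2, vp, L);
          const int latAxis = (std::fabs(ct) >= std::fabs(st)) ? 0 : 1;
          for (int k = 0; k < nStep; ++k) {
            const double v = -rad + k * step;
            const double im = (dso + v) / L;
            const double u1 = srcx + (xb1 - srcx) * im;
            const double u2 = srcx + (xb2 - srcx) * im;
            const double uc = srcx + (x - srcx) * im;
            const double z1 = (yb1 * im - zshift) / dz + cz;
            const double z2 = (yb2 * im - zshift) / dz + cz;
            double lat1, lat2, fixedIdx;
            if (latAxis == 0) {
              lat1 = (u1 * ct + v * st) / du + cu;
              lat2 = (u2 * ct + v * st) / du + cu;
              fixedIdx = (-uc * st + v * ct) / dv + cvv;
            } else {
              lat1 = (-u1 * st + v * ct) / dv + cvv;
              lat2 = (-u2 * st + v * ct) / dv + cvv;
              fixedIdx = (uc * ct + v * st) / du + cu;
            }
            acc += dd_volume_sample(f, nu, nv, nz, latAxis, lat1, lat2,
                                    fixedIdx, z1, z2);
          }
        }
        o[j + (size_t)detRows * (i + (size_t)detCols * w)] =
            step * acc / cosA;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(detRows, detCols, nViews);
  return out;
}

// Ideal-geometry ray-driven projector: separately coded reference without
// misalignment handling (used to validate the zero-misalignment path).
// [[Rcpp::export]]
NumericVector cpp_project_ideal(NumericVector vol, IntegerVector volDim,
                                NumericVector voxel, int detRows, int detCols,
                                NumericVector pixel, NumericVector thetas,
                                double dso, double ddo, double step,
                                double rad) {
  const int nu = volDim[0], nv = volDim[1], nz = volDim[2];
  const int nViews = thetas.size();
  const double du = voxel[0], dvx = voxel[1], dz = voxel[2];
  const double px = pixel[0], py = pixel[1];
  const double cx = (detCols - 1) / 2.0, cy = (detRows - 1) / 2.0;
  const double cu = (nu - 1) / 2.0, cvv = (nv - 1) / 2.0, cz = (nz - 1) / 2.0;
  const double L = dso + ddo;
  const int nStep = (int)std::floor(2.0 * rad / step) + 1;
  const double* f = vol.begin();

  NumericVector out((size_t)detRows * detCols * nViews);
  double* o = out.begin();
  for (int w = 0; w < nViews; ++w) {
    const double ct = std::cos(thetas[w]), st = std::sin(thetas[w]);
    for (int i = 0; i < detCols; ++i) {
      const double x = (i - cx) * px;
      for (int j = 0; j < detRows; ++j) {
        const double y = (j - cy) * py;
        const double cosA = L / std::sqrt(L * L + x * x + y * y);
        double acc = 0.0;
        for (int k = 0; k < nStep; ++k) {
          const double v = -rad + k * step;
          const double im = (dso + v) / L;
          const double u = x * im;
          const double zc = y * im;
          const double U = u * ct + v * st;
          const double V = -u * st + v * ct;
          acc += tri_sample(f, nu, nv, nz, U / du + cu, V / dvx + cvv,
                            zc / dz + cz);
        }
        o[j + (size_t)detRows * (i + (size_t)detCols * w)] =
            step * acc / cosA;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(detRows, detCols, nViews);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector stack, IntegerVector stkDim,
                              NumericVector pixel, IntegerVector volDim,
                              NumericVector voxel, int fullNz, int z0,
                              NumericMatrix vpars, NumericVector dtheta,
                              bool applyW2, bool distanceDriven) {
  const int nr = stkDim[0], nc = stkDim[1], nViews = stkDim[2];
  const int nu = volDim[0], nv = volDim[1], nz = volDim[2];
  const double du = voxel[0], dvx = voxel[1], dz = voxel[2];
  const double px = pixel[0], py = pixel[1];
  const double cx = (nc - 1) / 2.0, cy = (nr - 1) / 2.0;
  const double cu = (nu - 1) / 2.0, cvv = (nv - 1) / 2.0;
  const double czc = (fullNz - 1) / 2.0 - z0;
  const double* s = stack.begin();

  NumericVector out((size_t)nu * nv * nz);
  double* o = out.begin();

  for (int w = 0; w < nViews; ++w) {
    double vp[VP_NCOL];
    get_view(vpars, w, vp);
    const double theta = vp[VP_THETA];
    const double dso = vp[VP_DSO], ddo = vp[VP_DDO], srcx = vp[VP_SRCX];
    const double L = dso + ddo;
    const double ct = std::cos(theta), st = std::sin(theta);
    const double zshift = vp[VP_ZSHIFT] * dz;
    const double dth = dtheta[w];
    const double* pw = s + (size_t)nr * nc * w;
    const int latAxis = (std::fabs(ct) >= std::fabs(st)) ? 0 : 1;

    for (int iz = 0; iz < nz; ++iz) {
      const double z = (iz - czc) * dz + zshift;
      for (int iv = 0; iv < nv; ++iv) {
        const double vphys = (iv - cvv) * dvx;
        for (int iu = 0; iu < nu; ++iu) {
          const double uphys = (iu - cu) * du;
          const double vr = uphys * st + vphys * ct;
          const double den = dso + vr;
          if (den <= 1e-9) continue;
          const double mag = L / den;
          double val;
          double w2 = 1.0;
          if (applyW2) w2 = (dso / den) * (dso / den);

          if (!distanceDriven) {
            const double ur = uphys * ct - vphys * st;
            double x = srcx + (ur - srcx) * mag;
            double y = z * mag;
            mis_to_real(x, y, vp, L);
            val = bi_sample(pw, nr, nc, y / py + cy, x / px + cx);
          } else {
            // lateral boundaries from the in-plane axis most orthogonal to
            // the ray direction; z boundaries with the central magnification
            double ua, ub, va, vb;
            if (latAxis == 0) {
              ua = uphys - du / 2.0; ub = uphys + du / 2.0; va = vb = vphys;
            } else {
              ua = ub = uphys; va = vphys - dvx / 2.0; vb = vphys + dvx / 2.0;
            }
            const double ur1 = ua * ct - va * st, vr1 = ua * st + va * ct;
            const double ur2 = ub * ct - vb * st, vr2 = ub * st + vb * ct;
            const double den1 = dso + vr1, den2 = dso + vr2;
            if (den1 <= 1e-9 || den2 <= 1e-9) continue;
            double x1 = srcx + (ur1 - srcx) * (L / den1);
            double x2 = srcx + (ur2 - srcx) * (L / den2);
            double y1 = (z - dz / 2.0) * mag;
            double y2 = (z + dz / 2.0) * mag;
            mis_to_real(x1, y1, vp, L);
            mis_to_real(x2, y2, vp, L);
            double fx1 = x1 / px + cx, fx2 = x2 / px + cx;
            double fy1 = y1 / py + cy, fy2 = y2 / py + cy;
            if (fx2 < fx1) std::swap(fx1, fx2);
            if (fy2 < fy1) std::swap(fy1, fy2);
            const double eps = 1e-9;
            const double wx = fx2 - fx1, wy = fy2 - fy1;
            double acc = 0.0;
            if (wx <= eps && wy <= eps) {
              acc = bi_sample(pw, nr, nc, (fy1 + fy2) / 2.0,
                              (fx1 + fx2) / 2.0);
            } else {
              int xLo = (int)std::floor(fx1 + 0.5),
                  xHi = (int)std::floor(fx2 + 0.5);
              int yLo = (int)std::floor(fy1 + 0.5),
                  yHi = (int)std::floor(fy2 + 0.5);
              if (wx <= eps) { xLo = (int)std::floor(fx1); xHi = xLo + 1; }
              if (wy <= eps) { yLo = (int)std::floor(fy1); yHi = yLo + 1; }
              for (int xi = xLo; xi <= xHi; ++xi) {
                double wxc;
                if (wx <= eps)
                  wxc = (xi == xLo) ? 1.0 - (fx1 - xLo) : fx1 - xLo;
                else
                  wxc = cell_overlap(fx1, fx2, xi) / wx;
                if (wxc <= 0.0 || xi < 0 || xi >= nc) continue;
                for (int yi = yLo; yi <= yHi; ++yi) {
                  double wyc;
                  if (wy <= eps)
                    wyc = (yi == yLo) ? 1.0 - (fy1 - yLo) : fy1 - yLo;
                  else
                    wyc = cell_overlap(fy1, fy2, yi) / wy;
                  if (wyc <= 0.0 || yi < 0 || yi >= nr) continue;
                  acc += wxc * wyc * pw[yi + (size_t)nr * xi];
                }
              }
            }
            val = acc;
          }
          o[iu + (size_t)nu * (iv + (size_t)nv * iz)] += dth * w2 * val;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nu, nv, nz);
  return out;
}

// Ideal-geometry voxel-driven backprojector (reference, no misalignment).
// [[Rcpp::export]]
NumericVector cpp_backproject_ideal(NumericVector stack, IntegerVector stkDim,
                                    NumericVector pixel, IntegerVector volDim,
                                    NumericVector voxel, NumericVector thetas,
                                    double dso, double ddo,
                                    NumericVector dtheta, bool applyW2) {
  const int nr = stkDim[0], nc = stkDim[1], nViews = stkDim[2];
  const int nu = volDim[0], nv = volDim[1], nz = volDim[2];
  const double du = voxel[0], dvx = voxel[1], dz = voxel[2];
  const double px = pixel[0], py = pixel[1];
  const double cx = (nc - 1) / 2.0, cy = (nr - 1) / 2.0;
  const double cu = (nu - 1) / 2.0, cvv = (nv - 1) / 2.0, cz = (nz - 1) / 2.0;
  const double L = dso + ddo;
  const double* s = stack.begin();
  NumericVector out((size_t)nu * nv * nz);
  double* o = out.begin();
  for (int w = 0; w < nViews; ++w) {
    const double ct = std::cos(thetas[w]), st = std::sin(thetas[w]);
    const double dth = dtheta[w];
    const double* pw = s + (size_t)nr * nc * w;
    for (int iz = 0; iz < nz; ++iz) {
      const double z = (iz - cz) * dz;
      for (int iv = 0; iv < nv; ++iv) {
        const double vphys = (iv - cvv) * dvx;
        for (int iu = 0; iu < nu; ++iu) {
          const double uphys = (iu - cu) * du;
          const double vr = uphys * st + vphys * ct;
          const double den = dso + vr;
          if (den <= 1e-9) continue;
          const double mag = L / den;
          const double ur = uphys * ct - vphys * st;
          double w2 = 1.0;
          if (applyW2) w2 = (dso / den) * (dso / den);
          const double val = bi_sample(pw, nr, nc, z * mag / py + cy,
                                       ur * mag / px + cx);
          o[iu + (size_t)nu * (iv + (size_t)nv * iz)] += dth * w2 * val;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nu, nv, nz);
  return out;
}

// circular convolution of each padded row with a kernel of the same length
// (spatial-domain backend of the ramp filter)
// [[Rcpp::export]]
NumericVector cpp_circular_convolve_rows(NumericMatrix rows,
                                         NumericVector kernel) {
  const int n = rows.nrow(), m = rows.ncol();
  if (kernel.size() != m) stop("kernel length must match padded row length");
  NumericMatrix out(n, m);
  for (int r = 0; r < n; ++r) {
    for (int j = 0; j < m; ++j) {
      double acc = 0.0;
      for (int k = 0; k < m; ++k) {
        int idx = j - k;
        if (idx < 0) idx += m;
        acc += rows(r, k) * kernel[idx];
      }
      out(r, j) = acc;
    }
  }
  return out;
}
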