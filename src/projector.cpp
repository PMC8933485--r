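#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cone-beam projector pair (Joseph's method) plus a voxel-driven
// FDK backprojector.
//
// Conventions (fixed across the package):
//  - volume: column-major NumericVector, dims (nx, ny, nz);
//    voxel centre world position = origin + (index + 0.5) * spacing,
//    indices 0-based.
//  - sinogram: column-major, dims (rows, cols, n_views).
//  - geometry: per-view 3-vectors as rows of (n_views x 3) matrices:
//    source position, detector centre, u (column step, scaled by pixel
//    pitch), v (row step, scaled by pixel pitch).
//  - detector pixel (r, c) centre = det + u*(c - (cols-1)/2) + v*(r - (rows-1)/2),
//    r, c 0-based.
//
// cpp_backward_project is the exact matrix transpose of
// cpp_forward_project: both walk the same slices with the same bilinear
// weights, one gathering, the other scattering.

static inline int imax3(double x, double y, double z) {
  if (std::fabs(x) >= std::fabs(y) && std::fabs(x) >= std::fabs(z)) return 0;
  if (std::fabs(y) >= std::fabs(z)) return 1;
  return 2;
}

// Traverse one ray; if forward, accumulate into *out; if not, scatter val.
// vol used read-only in forward mode, written in adjoint mode.
static void joseph_ray(double* vol, const int* dims,
                       const double* spacing, const double* origin,
                       const double sx, const double sy, const double sz,
                       const double px, const double py, const double pz,
                       const bool forward, double* out, const double val) {
  const double s[3] = {sx, sy, sz};
  const double d[3] = {px - sx, py - sy, pz - sz};
  const int a = imax3(d[0], d[1], d[2]);
  if (d[a] == 0.0) return;
  const int b = (a + 1) % 3, c = (a + 2) % 3;
  const double dlen = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  const double step = spacing[a] * dlen / std::fabs(d[a]);
  const int na = dims[a], nb = dims[b], nc = dims[c];
  // strides of axis in column-major (nx, ny, nz)
  int stride[3];
  stride[0] = 1; stride[1] = dims[0]; stride[2] = dims[0] * dims[1];
  const int sa = stride[a], sb = stride[b], sc = stride[c];
  // t and the interpolation coordinates are linear in the slice index:
  // t(ia) = t0 + ia*dt; restrict ia to t in (0, 1].
  const double dt = spacing[a] / d[a];
  const double t0 = (origin[a] + 0.5 * spacing[a] - s[a]) / d[a];
  int lo = 0, hi = na - 1;
  if (dt > 0) {
    if (t0 <= 0) lo = (int)std::ceil(-t0 / dt + 1e-12);
    if (t0 + hi * dt > 1.0) hi = (int)std::floor((1.0 - t0) / dt);
  } else {
    if (t0 > 1.0) lo = (int)std::ceil((1.0 - t0) / dt);
    if (t0 + hi * dt <= 0) hi = (int)std::floor(-t0 / dt - 1e-12);
  }
  if (lo < 0) lo = 0;
  if (hi > na - 1) hi = na - 1;
  const double dfb = dt * d[b] / spacing[b];
  const double dfc = dt * d[c] / spacing[c];
  double fb = (s[b] + (t0 + lo * dt) * d[b] - origin[b]) / spacing[b] - 0.5;
  double fc = (s[c] + (t0 + lo * dt) * d[c] - origin[c]) / spacing[c] - 0.5;
  double acc = 0.0;
  for (int ia = lo; ia <= hi; ++ia, fb += dfb, fc += dfc) {
    const int ib = (int)std::floor(fb);
    const int ic = (int)std::floor(fc);
    if (ib < -1 || ib > nb - 1 || ic < -1 || ic > nc - 1) continue;
    const double wb = fb - ib, wc = fc - ic;
    const int base = ia * sa;
    const bool b0 = ib >= 0, b1 = ib + 1 < nb;
    const bool c0 = ic >= 0, c1 = ic + 1 < nc;
    if (forward) {
      double v00 = 0, v10 = 0, v01 = 0, v11 = 0;
      if (b0 && c0) v00 = vol[base + ib * sb + ic * sc];
      if (b1 && c0) v10 = vol[base + (ib + 1) * sb + ic * sc];
      if (b0 && c1) v01 = vol[base + ib * sb + (ic + 1) * sc];
      if (b1 && c1) v11 = vol[base + (ib + 1) * sb + (ic + 1) * sc];
      acc += (1 - wc) * ((1 - wb) * v00 + wb * v10) +
             wc * ((1 - wb) * v01 + wb * v11);
    } else {
      const double w = val * step;
      if (b0 && c0) vol[base + ib * sb + ic * sc] += w * (1 - wb) * (1 - wc);
      if (b1 && c0) vol[base + (ib + 1) * sb + ic * sc] += w * wb * (1 - wc);
      if (b0 && c1) vol[base + ib * sb + (ic + 1) * sc] += w * (1 - wb) * wc;
      if (b1 && c1) vol[base + (ib + 1) * sb + (ic + 1) * sc] += w * wb * wc;
    }
  }
  if (forward) *out = acc * step;
}

struct Geom {
  const double *src, *det, *u, *v;   // column-major (nv x 3) matrices
  int nv, rows, cols;
};

// forward: gather line integrals of vol into sino (overwrites sino);
// adjoint: scatter sino into vol (caller zeroes vol first).
static void project_all(double* vol, const int* dm, const double* sp,
                        const double* og, const Geom& g, double* sino,
                        const bool forward) {
  const double cc = (g.cols - 1) / 2.0, rc = (g.rows - 1) / 2.0;
  for (int k = 0; k < g.nv; ++k) {
    const double sx = g.src[k], sy = g.src[k + g.nv], sz = g.src[k + 2*g.nv];
    const double dx = g.det[k], dy = g.det[k + g.nv], dz = g.det[k + 2*g.nv];
    const double ux = g.u[k], uy = g.u[k + g.nv], uz = g.u[k + 2*g.nv];
    const double vx = g.v[k], vy = g.v[k + g.nv], vz = g.v[k + 2*g.nv];
    for (int c = 0; c < g.cols; ++c) {
      const double uo = c - cc;
      for (int r = 0; r < g.rows; ++r) {
        const double vo = r - rc;
        const double px = dx + ux*uo + vx*vo;
        const double py = dy + uy*uo + vy*vo;
        const double pz = dz + uz*uo + vz*vo;
        const R_xlen_t si = r + (R_xlen_t)g.rows * (c + (R_xlen_t)g.cols * k);
        if (forward) {
          double out = 0.0;
          joseph_ray(vol, dm, sp, og, sx, sy, sz, px, py, pz, true, &out, 0.0);
          sino[si] = out;
        } else {
          const double val = sino[si];
          if (val != 0.0)
            joseph_ray(vol, dm, sp, og, sx, sy, sz, px, py, pz, false,
                       (double*)0, val);
        }
      }
    }
  }
}

static Geom make_geom(const NumericMatrix& src, const NumericMatrix& det,
                      const NumericMatrix& uvec, const NumericMatrix& vvec,
                      int rows, int cols) {
  Geom g;
  g.src = src.begin(); g.det = det.begin();
  g.u = uvec.begin(); g.v = vvec.begin();
  g.nv = src.nrow(); g.rows = rows; g.cols = cols;
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector vol, IntegerVector dims,
                                  NumericVector spacing, NumericVector origin,
                                  NumericMatrix src, NumericMatrix det,
                                  NumericMatrix uvec, NumericMatrix vvec,
                                  int rows, int cols) {
  Geom g = make_geom(src, det, uvec, vvec, rows, cols);
  NumericVector sino(rows * cols * (R_xlen_t)g.nv);
  int dm[3] = {dims[0], dims[1], dims[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double og[3] = {origin[0], origin[1], origin[2]};
  project_all(REAL(vol), dm, sp, og, g, REAL(sino), true);
  sino.attr("dim") = IntegerVector::create(rows, cols, g.nv);
  return sino;
}

// [[Rcpp::export]]
NumericVector cpp_backward_project(NumericVector sino, IntegerVector dims,
                                   NumericVector spacing, NumericVector origin,
                                   NumericMatrix src, NumericMatrix det,
                                   NumericMatrix uvec, NumericMatrix vvec,
                                   int rows, int cols) {
  Geom g = make_geom(src, det, uvec, vvec, rows, cols);
  NumericVector vol((R_xlen_t)dims[0] * dims[1] * dims[2]);
  int dm[3] = {dims[0], dims[1], dims[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double og[3] = {origin[0], origin[1], origin[2]};
  project_all(REAL(vol), dm, sp, og, g, REAL(sino), false);
  vol.attr("dim") = IntegerVector::create(dims[0], dims[1], dims[2]);
  return vol;
}

// Full SIRT iteration in compiled code:
//   x <- x + C * P^T(R * (b - P x)),  R/C inverse row/column sums of P.
// Returns the solution and the residual norm per iteration.
// [[Rcpp::export]]
List cpp_sirt(NumericVector b, IntegerVector dims,
              NumericVector spacing, NumericVector origin,
              NumericMatrix src, NumericMatrix det,
              NumericMatrix uvec, NumericMatrix vvec,
              int rows, int cols, int n_iter, bool nonneg) {
  Geom g = make_geom(src, det, uvec, vvec, rows, cols);
  const R_xlen_t nvox = (R_xlen_t)dims[0] * dims[1] * dims[2];
  const R_xlen_t nray = (R_xlen_t)rows * cols * g.nv;
  int dm[3] = {dims[0], dims[1], dims[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double og[3] = {origin[0], origin[1], origin[2]};
  std::vector<double> ones_vol(nvox, 1.0), Rw(nray), Cw(nvox, 0.0),
    r(nray), upd(nvox);
  NumericVector x(nvox), resid(n_iter);
  project_all(ones_vol.data(), dm, sp, og, g, Rw.data(), true);
  for (R_xlen_t i = 0; i < nray; ++i)
    Rw[i] = Rw[i] > 1e-12 ? 1.0 / Rw[i] : 0.0;
  std::fill(r.begin(), r.end(), 1.0);
  project_all(Cw.data(), dm, sp, og, g, r.data(), false);
  for (R_xlen_t i = 0; i < nvox; ++i)
    Cw[i] = Cw[i] > 1e-12 ? 1.0 / Cw[i] : 0.0;
  double res0 = 0.0;
  for (int it = 0; it < n_iter; ++it) {
    project_all(REAL(x), dm, sp, og, g, r.data(), true);
    double rn = 0.0;
    for (R_xlen_t i = 0; i < nray; ++i) {
      r[i] = b[i] - r[i];
      rn += r[i] * r[i];
      r[i] *= Rw[i];
    }
    resid[it] = std::sqrt(rn);
    if (it == 0) res0 = resid[it];
    if (res0 > 0 && resid[it] > 10.0 * res0)
      stop("SIRT diverged at iteration %d (residual %g > 10 x %g)",
           it + 1, resid[it], res0);
    std::fill(upd.begin(), upd.end(), 0.0);
    project_all(upd.data(), dm, sp, og, g, r.data(), false);
    for (R_xlen_t i = 0; i < nvox; ++i) {
      x[i] += Cw[i] * upd[i];
      if (nonneg && x[i] < 0) x[i] = 0;
    }
    Rcpp::checkUserInterrupt();
  }
  x.attr("dim") = IntegerVector::create(dims[0], dims[1], dims[2]);
  return List::create(_["x"] = x, _["residuals"] = resid);
}

// Voxel-driven FDK backprojection of an already cosine-weighted,
// ramp-filtered sinogram. Detector coordinates are rescaled to the
// isocenter plane (pitch * sod/sdd); caller multiplies the result by
// delta_beta / 2 for full-scan normalization.
// [[Rcpp::export]]
NumericVector cpp_fdk_backproject(NumericVector sino, IntegerVector dims,
                                  NumericVector spacing, NumericVector origin,
                                  NumericMatrix src, NumericMatrix det,
                                  NumericMatrix uvec, NumericMatrix vvec,
                                  int rows, int cols,
                                  double sod, double sdd) {
  const int nv = src.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector vol((R_xlen_t)nx * ny * nz);
  const double cc = (cols - 1) / 2.0, rc = (rows - 1) / 2.0;
  for (int k = 0; k < nv; ++k) {
    const double sx = src(k,0), sy = src(k,1), sz = src(k,2);
    // beam axis (unit): source -> detector centre
    double nxv = det(k,0)-sx, nyv = det(k,1)-sy, nzv = det(k,2)-sz;
    const double nn = std::sqrt(nxv*nxv + nyv*nyv + nzv*nzv);
    nxv /= nn; nyv /= nn; nzv /= nn;
    const double du = std::sqrt(uvec(k,0)*uvec(k,0)+uvec(k,1)*uvec(k,1)+uvec(k,2)*uvec(k,2));
    const double dv = std::sqrt(vvec(k,0)*vvec(k,0)+vvec(k,1)*vvec(k,1)+vvec(k,2)*vvec(k,2));
    const double ux = uvec(k,0)/du, uy = uvec(k,1)/du, uz = uvec(k,2)/du;
    const double vx = vvec(k,0)/dv, vy = vvec(k,1)/dv, vz = vvec(k,2)/dv;
    const double du_iso = du * sod / sdd, dv_iso = dv * sod / sdd;
    const double* sk = REAL(sino) + (R_xlen_t)rows * cols * k;
    double* pv = REAL(vol);
    for (int iz = 0; iz < nz; ++iz) {
      const double wz = origin[2] + (iz + 0.5) * spacing[2] - sz;
      for (int iy = 0; iy < ny; ++iy) {
        const double wy = origin[1] + (iy + 0.5) * spacing[1] - sy;
        for (int ix = 0; ix < nx; ++ix) {
          const double wx = origin[0] + (ix + 0.5) * spacing[0] - sx;
          const double U = wx*nxv + wy*nyv + wz*nzv;
          if (U <= 1e-9) continue;
          const double up = sod * (wx*ux + wy*uy + wz*uz) / U;
          const double vp = sod * (wx*vx + wy*vy + wz*vz) / U;
          const double fc = up / du_iso + cc;
          const double fr = vp / dv_iso + rc;
          int ic = (int)std::floor(fc);
          int ir = (int)std::floor(fr);
          const double wc = fc - ic, wr = fr - ir;
          double q = 0.0;
          for (int jc = 0; jc <= 1; ++jc) {
            const int kc = ic + jc;
            if (kc < 0 || kc >= cols) continue;
            const double wgc = jc ? wc : (1.0 - wc);
            for (int jr = 0; jr <= 1; ++jr) {
              const int kr = ir + jr;
              if (kr < 0 || kr >= rows) continue;
              const double wgr = jr ? wr : (1.0 - wr);
              q += wgc * wgr * sk[kr + rows * kc];
            }
          }
          pv[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] +=
            q * sod * sod / (U * U);
        }
      }
    }
  }
  vol.attr("dim") = IntegerVector::create(nx, ny, nz);
  return vol;
}
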