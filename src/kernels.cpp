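#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation with clamp-to-edge, voxel coordinates (0-based).
static inline double trilinear(const double* v, int nx, int ny, int nz,
                               double x, double y, double z) {
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
  if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
  if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const long sx = 1, sy = nx, sz = (long)nx * ny;
  const double* p = v + x0 + (long)y0 * sy + (long)z0 * sz;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sy + sz] * (1 - fx) + p[sy + sz + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Ray-driven cone-beam forward projection for one gantry angle.
// Fixed-step midpoint sampling with trilinear interpolation; the ray is
// clipped to the volume bounding box so empty space costs nothing.
// Geometry: gantry rotates about z; at angle beta the source sits at
// sid*(cos b, sin b, 0), the flat detector (centered on the source-isocenter
// axis, full fan) at distance sdd from the source, axes
// u = (-sin b, cos b, 0), v = (0, 0, 1).
// [[Rcpp::export]]
NumericMatrix forward_project_cpp(NumericVector vol, IntegerVector dim,
                                  NumericVector spacing, NumericVector origin,
                                  double sid, double sdd,
                                  int nu, int nv, double pitch,
                                  double angle_deg, double step_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = vol.begin();
  const double b = angle_deg * M_PI / 180.0;
  const double cb = std::cos(b), sb = std::sin(b);
  const double sx = sid * cb, sy = sid * sb, sz = 0.0;           // source
  const double dcx = -(sdd - sid) * cb, dcy = -(sdd - sid) * sb; // detector centre
  const double ux = -sb, uy = cb;                                // detector u axis
  // volume bounding box (half-voxel beyond outer voxel centres)
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = origin[a] - 0.5 * spacing[a];
    hi[a] = origin[a] + (dim[a] - 0.5) * spacing[a];
  }
  const double cu = 0.5 * (nu - 1), cv = 0.5 * (nv - 1);
  NumericMatrix out(nu, nv);
  for (int iv = 0; iv < nv; ++iv) {
    const double pv = (iv - cv) * pitch;
    for (int iu = 0; iu < nu; ++iu) {
      const double pu = (iu - cu) * pitch;
      // pixel position in world coordinates
      const double px = dcx + pu * ux;
      const double py = dcy + pu * uy;
      const double pz = pv;
      double dx = px - sx, dy = py - sy, dz = pz - sz;
      const double len = std::sqrt(dx * dx + dy * dy + dz * dz);
      dx /= len; dy /= len; dz /= len;
      // slab clipping against the bounding box
      double tmin = 0.0, tmax = len;
      const double d[3] = {dx, dy, dz}, s0[3] = {sx, sy, sz};
      bool miss = false;
      for (int a = 0; a < 3; ++a) {
        if (std::fabs(d[a]) < 1e-12) {
          if (s0[a] < lo[a] || s0[a] > hi[a]) { miss = true; break; }
        } else {
          double t1 = (lo[a] - s0[a]) / d[a];
          double t2 = (hi[a] - s0[a]) / d[a];
          if (t1 > t2) std::swap(t1, t2);
          if (t1 > tmin) tmin = t1;
          if (t2 < tmax) tmax = t2;
          if (tmin >= tmax) { miss = true; break; }
        }
      }
      double acc = 0.0;
      if (!miss) {
        const double span = tmax - tmin;
        const int nstep = (int)std::ceil(span / step_mm);
        const double h = span / nstep;
        for (int k = 0; k < nstep; ++k) {
          const double t = tmin + (k + 0.5) * h;
          const double wx = (sx + t * dx - origin[0]) / spacing[0];
          const double wy = (sy + t * dy - origin[1]) / spacing[1];
          const double wz = (sz + t * dz - origin[2]) / spacing[2];
          acc += trilinear(v, nx, ny, nz, wx, wy, wz);
        }
        acc *= h;
      }
      out(iu, iv) = acc;
    }
  }
  return out;
}

// Voxel-driven FDK backprojection of filtered projections.
// proj: nu x nv x np array of filtered, weighted projections; per projection
// angle (deg) and angular weight dbeta (radians). Accumulates
// dbeta * (sid/U)^2 * bilinear(proj; u, v) per voxel, with (u, v) the cone-beam
// projection of the voxel expressed in pixel indices.
// [[Rcpp::export]]
NumericVector backproject_cpp(NumericVector proj, IntegerVector pdim,
                              NumericVector angles_deg, NumericVector dbeta,
                              double sid, double sdd, double pitch,
                              IntegerVector dim, NumericVector spacing,
                              NumericVector origin) {
  const int nu = pdim[0], nv = pdim[1], np = pdim[2];
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((long)nx * ny * nz);
  double* o = out.begin();
  const double* pr = proj.begin();
  const double cu = 0.5 * (nu - 1), cv = 0.5 * (nv - 1);
  for (int ip = 0; ip < np; ++ip) {
    const double b = angles_deg[ip] * M_PI / 180.0;
    const double cb = std::cos(b), sb = std::sin(b);
    const double w_ang = dbeta[ip];
    const double* im = pr + (long)ip * nu * nv;
    long idx = 0;
    for (int kz = 0; kz < nz; ++kz) {
      const double z = origin[2] + kz * spacing[2];
      for (int jy = 0; jy < ny; ++jy) {
        const double y = origin[1] + jy * spacing[1];
        for (int ix = 0; ix < nx; ++ix, ++idx) {
          const double x = origin[0] + ix * spacing[0];
          const double U = sid - (x * cb + y * sb);     // source-plane distance
          if (U < 1e-6) continue;
          const double up = (sdd * (-x * sb + y * cb) / U) / pitch + cu;
          const double vp = (sdd * z / U) / pitch + cv;
          if (up < 0 || up > nu - 1 || vp < 0 || vp > nv - 1) continue;
          int u0 = (int)up, v0 = (int)vp;
          if (u0 > nu - 2) u0 = nu - 2;
          if (v0 > nv - 2) v0 = nv - 2;
          const double fu = up - u0, fv = vp - v0;
          const double* q = im + u0 + (long)v0 * nu;
          const double val = (q[0] * (1 - fu) + q[1] * fu) * (1 - fv) +
                             (q[nu] * (1 - fu) + q[nu + 1] * fu) * fv;
          const double r = sid / U;
          o[idx] += w_ang * r * r * val;
        }
      }
    }
  }
  return out;
}

// Pull-style warp: out(x) = in(x + d(x)), displacements in mm, clamp-to-edge.
// dvf is a nx*ny*nz*3 array.
// [[Rcpp::export]]
NumericVector warp_cpp(NumericVector vol, NumericVector dvf, IntegerVector dim,
                       NumericVector spacing, NumericVector origin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  NumericVector out(n);
  const double* v = vol.begin();
  const double* d = dvf.begin();
  long idx = 0;
  for (int kz = 0; kz < nz; ++kz)
    for (int jy = 0; jy < ny; ++jy)
      for (int ix = 0; ix < nx; ++ix, ++idx) {
        const double wx = ix + d[idx] / spacing[0];
        const double wy = jy + d[idx + n] / spacing[1];
        const double wz = kz + d[idx + 2 * n] / spacing[2];
        out[idx] = trilinear(v, nx, ny, nz, wx, wy, wz);
      }
  return out;
}

// Resample a volume at x + shift_mm (trilinear, clamp-to-edge).
// [[Rcpp::export]]
NumericVector shift_sample_cpp(NumericVector vol, IntegerVector dim,
                               NumericVector spacing, NumericVector shift_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((long)nx * ny * nz);
  const double* v = vol.begin();
  const double ox = shift_mm[0] / spacing[0];
  const double oy = shift_mm[1] / spacing[1];
  const double oz = shift_mm[2] / spacing[2];
  long idx = 0;
  for (int kz = 0; kz < nz; ++kz)
    for (int jy = 0; jy < ny; ++jy)
      for (int ix = 0; ix < nx; ++ix, ++idx)
        out[idx] = trilinear(v, nx, ny, nz, ix + ox, jy + oy, kz + oz);
  return out;
}

// Fixed-point inversion of a displacement field:
//   dinv_{k+1}(x) = -d(x + dinv_k(x))
// Returns list(dvf = inverse field, residual = max |dinv(x) + d(x + dinv(x))| mm,
// iterations). Converges for displacement fields with Jacobian perturbation < 1.
// [[Rcpp::export]]
List invert_dvf_cpp(NumericVector dvf, IntegerVector dim, NumericVector spacing,
                    double tol_mm, int max_iter) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long n = (long)nx * ny * nz;
  const double* d = dvf.begin();
  NumericVector inv(3 * n);
  for (long i = 0; i < 3 * n; ++i) inv[i] = -d[i];
  double maxup = R_PosInf;
  int it = 0;
  for (it = 0; it < max_iter && maxup > tol_mm; ++it) {
    maxup = 0.0;
    long idx = 0;
    for (int kz = 0; kz < nz; ++kz)
      for (int jy = 0; jy < ny; ++jy)
        for (int ix = 0; ix < nx; ++ix, ++idx) {
          const double wx = ix + inv[idx] / spacing[0];
          const double wy = jy + inv[idx + n] / spacing[1];
          const double wz = kz + inv[idx + 2 * n] / spacing[2];
          const double nx0 = -trilinear(d, nx, ny, nz, wx, wy, wz);
          const double ny0 = -trilinear(d + n, nx, ny, nz, wx, wy, wz);
          const double nz0 = -trilinear(d + 2 * n, nx, ny, nz, wx, wy, wz);
          const double up = std::fabs(nx0 - inv[idx]) + std::fabs(ny0 - inv[idx + n]) +
                            std::fabs(nz0 - inv[idx + 2 * n]);
          if (up > maxup) maxup = up;
          inv[idx] = nx0; inv[idx + n] = ny0; inv[idx + 2 * n] = nz0;
        }
  }
  // composition residual |dinv(x) + d(x + dinv(x))|
  double res = 0.0;
  long idx = 0;
  for (int kz = 0; kz < nz; ++kz)
    for (int jy = 0; jy < ny; ++jy)
      for (int ix = 0; ix < nx; ++ix, ++idx) {
        const double wx = ix + inv[idx] / spacing[0];
        const double wy = jy + inv[idx + n] / spacing[1];
        const double wz = kz + inv[idx + 2 * n] / spacing[2];
        const double rx = inv[idx] + trilinear(d, nx, ny, nz, wx, wy, wz);
        const double ry = inv[idx + n] + trilinear(d + n, nx, ny, nz, wx, wy, wz);
        const double rz = inv[idx + 2 * n] + trilinear(d + 2 * n, nx, ny, nz, wx, wy, wz);
        const double r = std::sqrt(rx * rx + ry * ry + rz * rz);
        if (r > res) res = r;
      }
  return List::create(_["dvf"] = inv, _["residual_mm"] = res, _["iterations"] = it);
}

// Normalized cross-correlation between fixed and moving sampled at x + offset,
// over a voxel-index box [lo, hi] (0-based, inclusive) with stride, for a set
// of candidate offsets (mm). Returns one NCC value per offset.
// [[Rcpp::export]]
NumericVector ncc_offsets_cpp(NumericVector moving, NumericVector fixed,
                              IntegerVector dim, NumericVector spacing,
                              IntegerVector lo, IntegerVector hi, int stride,
                              NumericMatrix offsets_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* mv = moving.begin();
  const double* fx = fixed.begin();
  const int noff = offsets_mm.nrow();
  NumericVector out(noff);
  for (int io = 0; io < noff; ++io) {
    const double ox = offsets_mm(io, 0) / spacing[0];
    const double oy = offsets_mm(io, 1) / spacing[1];
    const double oz = offsets_mm(io, 2) / spacing[2];
    double sm = 0, sf = 0, smm = 0, sff = 0, smf = 0;
    long cnt = 0;
    for (int kz = lo[2]; kz <= hi[2]; kz += stride)
      for (int jy = lo[1]; jy <= hi[1]; jy += stride)
        for (int ix = lo[0]; ix <= hi[0]; ix += stride) {
          const double f = fx[ix + (long)nx * jy + (long)nx * ny * kz];
          const double m = trilinear(mv, nx, ny, nz, ix + ox, jy + oy, kz + oz);
          sm += m; sf += f; smm += m * m; sff += f * f; smf += m * f; ++cnt;
        }
    const double varm = smm - sm * sm / cnt;
    const double varf = sff - sf * sf / cnt;
    out[io] = (varm <= 0 || varf <= 0) ? NA_REAL
                                       : (smf - sm * sf / cnt) / std::sqrt(varm * varf);
  }
  return out;
}
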