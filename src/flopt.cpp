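#include <Rcpp.h>
using namespace Rcpp;

// Trilinear sample of a volume stored as an R array with dim (nx, ny, nz)
// (x fastest), in voxel coordinates g (valid range [0, n-1] per axis).
static inline double trilinear(const double* v, int nx, int ny, int nz,
                               double gx, double gy, double gz) {
  if (gx < 0.0 || gy < 0.0 || gz < 0.0 ||
      gx > nx - 1.0 || gy > ny - 1.0 || gz > nz - 1.0) return 0.0;
  int x0 = (int)gx, y0 = (int)gy, z0 = (int)gz;
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  double fx = gx - x0, fy = gy - y0, fz = gz - z0;
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  const double* p = v + x0 * sx + y0 * sy + z0 * sz;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Pinhole ray-cast line integrals of a posed volume. The volume lives in the
// sample frame; pose (R, T) maps sample to world; (Rg, tg) maps world to
// camera. Rays are cast per pixel through the pinhole and integrated with
// trilinear sampling at spacing `step` (world units).
// [[Rcpp::export(name = ".raycastRender")]]
NumericMatrix raycast_render(NumericVector vol, IntegerVector vdim,
                             double voxelSize, NumericVector origin,
                             NumericMatrix R, NumericVector T,
                             NumericMatrix Rg, NumericVector tg,
                             double f, double pitch, double u0, double v0,
                             int W, int H, double step) {
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  const double* v = vol.begin();
  NumericMatrix out(H, W);

  // camera centre in world coords: C = -Rg^T tg
  double C[3];
  for (int i = 0; i < 3; i++)
    C[i] = -(Rg(0, i) * tg[0] + Rg(1, i) * tg[1] + Rg(2, i) * tg[2]);
  // ray origin in sample frame: o = R^T (C - T)
  double o[3];
  for (int i = 0; i < 3; i++)
    o[i] = R(0, i) * (C[0] - T[0]) + R(1, i) * (C[1] - T[1]) +
           R(2, i) * (C[2] - T[2]);

  // volume bounding box in sample-frame world units
  double lo[3], hi[3];
  int nvx[3] = {nx, ny, nz};
  for (int i = 0; i < 3; i++) {
    lo[i] = origin[i] - 0.5 * voxelSize;
    hi[i] = origin[i] + (nvx[i] - 0.5) * voxelSize;
  }

  for (int uu = 0; uu < W; uu++) {
    double x = (uu - u0) * pitch;
    for (int vv = 0; vv < H; vv++) {
      double y = (vv - v0) * pitch;
      // ray direction in camera coords, then world, then sample frame
      double dc[3] = {x / f, y / f, 1.0};
      double dw[3], ds[3];
      for (int i = 0; i < 3; i++)
        dw[i] = Rg(0, i) * dc[0] + Rg(1, i) * dc[1] + Rg(2, i) * dc[2];
      for (int i = 0; i < 3; i++)
        ds[i] = R(0, i) * dw[0] + R(1, i) * dw[1] + R(2, i) * dw[2];
      double nrm = std::sqrt(ds[0] * ds[0] + ds[1] * ds[1] + ds[2] * ds[2]);
      for (int i = 0; i < 3; i++) ds[i] /= nrm;

      // slab intersection with the volume box
      double tmin = -1e300, tmax = 1e300;
      bool miss = false;
      for (int i = 0; i < 3 && !miss; i++) {
        if (std::fabs(ds[i]) < 1e-12) {
          if (o[i] < lo[i] || o[i] > hi[i]) miss = true;
        } else {
          double t1 = (lo[i] - o[i]) / ds[i];
          double t2 = (hi[i] - o[i]) / ds[i];
          if (t1 > t2) std::swap(t1, t2);
          if (t1 > tmin) tmin = t1;
          if (t2 < tmax) tmax = t2;
        }
      }
      if (miss || tmax <= tmin) { out(vv, uu) = 0.0; continue; }
      if (tmin < 0) tmin = 0;

      double acc = 0.0;
      for (double t = tmin + 0.5 * step; t < tmax; t += step) {
        double gx = (o[0] + t * ds[0] - origin[0]) / voxelSize;
        double gy = (o[1] + t * ds[1] - origin[1]) / voxelSize;
        double gz = (o[2] + t * ds[2] - origin[2]) / voxelSize;
        acc += trilinear(v, nx, ny, nz, gx, gy, gz);
      }
      out(vv, uu) = acc * step;
    }
  }
  return out;
}

// Voxel-driven back-projection gather: every grid voxel (sample frame) is
// mapped through the frame's pose and the camera to a pixel position, and
// gathers that position's bilinearly interpolated frame intensity.
// Accumulates into `grid` in place; returns the fraction of voxels that
// projected outside the frame.
// [[Rcpp::export(name = ".backprojectGather")]]
double backproject_gather(NumericMatrix frame, NumericVector grid,
                          IntegerVector gdim, double gvs,
                          NumericVector gorigin,
                          NumericMatrix R, NumericVector T,
                          NumericMatrix Rg, NumericVector tg,
                          double f, double pitch, double u0, double v0) {
  const int H = frame.nrow(), W = frame.ncol();
  const int nx = gdim[0], ny = gdim[1], nz = gdim[2];
  double* g = grid.begin();
  const double* fr = frame.begin();

  // combined transform: X_c = A s + b
  double A[3][3], b[3];
  for (int i = 0; i < 3; i++) {
    for (int j = 0; j < 3; j++) {
      A[i][j] = Rg(i, 0) * R(0, j) + Rg(i, 1) * R(1, j) + Rg(i, 2) * R(2, j);
    }
    b[i] = Rg(i, 0) * T[0] + Rg(i, 1) * T[1] + Rg(i, 2) * T[2] + tg[i];
  }

  R_xlen_t outside = 0, total = (R_xlen_t)nx * ny * nz;
  size_t idx = 0;
  for (int k = 0; k < nz; k++) {
    double sz = gorigin[2] + k * gvs;
    for (int j = 0; j < ny; j++) {
      double sy = gorigin[1] + j * gvs;
      for (int i = 0; i < nx; i++, idx++) {
        double sx = gorigin[0] + i * gvs;
        double Xc = A[0][0] * sx + A[0][1] * sy + A[0][2] * sz + b[0];
        double Yc = A[1][0] * sx + A[1][1] * sy + A[1][2] * sz + b[1];
        double Zc = A[2][0] * sx + A[2][1] * sy + A[2][2] * sz + b[2];
        if (Zc <= 0) { outside++; continue; }
        double u = (f * Xc / Zc) / pitch + u0;
        double v = (f * Yc / Zc) / pitch + v0;
        if (u < 0 || v < 0 || u > W - 1.0 || v > H - 1.0) { outside++; continue; }
        int iu = (int)u, iv = (int)v;
        if (iu == W - 1) iu--;
        if (iv == H - 1) iv--;
        double fu = u - iu, fv = v - iv;
        const double* p = fr + iv + (size_t)iu * H;  // column-major H x W
        double val = p[0] * (1 - fv) * (1 - fu) + p[1] * fv * (1 - fu) +
                     p[H] * (1 - fv) * fu + p[H + 1] * fv * fu;
        g[idx] += val;
      }
    }
  }
  return (double)outside / (double)total;
}
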