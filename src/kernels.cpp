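// Low-level array kernels: 3D convolution, trilinear warping and its exact
// transpose (splatting), pooling/upsampling and separable Gaussian blur.
// All arrays are column-major numeric vectors with explicit dims, laid out
// [x, y, z, channel]. Displacement fields are [x, y, z, 3] in voxel units.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t idx4(int i, int j, int k, int c,
                            int nx, int ny, int nz) {
  return (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * (k + (R_xlen_t)nz * c));
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---------------------------------------------------------------------------
// 3D convolution, zero padding, stride 1, odd kernel size.
// x: [nx,ny,nz,cin], w: [k,k,k,cin,cout], b: [cout] -> y: [nx,ny,nz,cout]
//
// Implemented tap-wise: for each (dx,dy,dz,ci,co) kernel tap the whole
// shifted volume contributes one scaled vector accumulation over the valid
// (contiguous along x) range, which vectorizes well.
static inline R_xlen_t widx(int dx, int dy, int dz, int ci, int co,
                            int ksz, int cin, int p) {
  return (R_xlen_t)(dx + p) + (R_xlen_t)ksz * ((dy + p) +
         (R_xlen_t)ksz * ((dz + p) + (R_xlen_t)ksz * (ci + (R_xlen_t)cin * co)));
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             IntegerVector xdim, int ksz, int cout) {
  int nx = xdim[0], ny = xdim[1], nz = xdim[2], cin = xdim[3];
  int p = ksz / 2;
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector y(nvox * cout);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *py = y.begin();
  for (int co = 0; co < cout; ++co) {
    double bc = pb[co];
    double *yc = py + nvox * co;
    for (R_xlen_t t = 0; t < nvox; ++t) yc[t] = bc;
  }
  for (int co = 0; co < cout; ++co) {
    double *yc = py + nvox * co;
    for (int ci = 0; ci < cin; ++ci) {
      const double *xc = px + nvox * ci;
      for (int dz = -p; dz <= p; ++dz) {
        int k0 = dz < 0 ? -dz : 0, k1 = dz > 0 ? nz - dz : nz;
        for (int dy = -p; dy <= p; ++dy) {
          int j0 = dy < 0 ? -dy : 0, j1 = dy > 0 ? ny - dy : ny;
          for (int dx = -p; dx <= p; ++dx) {
            int i0 = dx < 0 ? -dx : 0, i1 = dx > 0 ? nx - dx : nx;
            double wv = pw[widx(dx, dy, dz, ci, co, ksz, cin, p)];
            if (wv == 0.0) continue;
            R_xlen_t off = (R_xlen_t)dx + (R_xlen_t)nx * (dy + (R_xlen_t)ny * dz);
            for (int k = k0; k < k1; ++k)
              for (int j = j0; j < j1; ++j) {
                R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
                double *yrow = yc + base;
                const double *xrow = xc + base + off;
                for (int i = i0; i < i1; ++i) yrow[i] += wv * xrow[i];
              }
          }
        }
      }
    }
  }
  return y;
}

// Backward pass: returns grads w.r.t. x, w, b (same tap-wise structure).
// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                    IntegerVector xdim, int ksz, int cout) {
  int nx = xdim[0], ny = xdim[1], nz = xdim[2], cin = xdim[3];
  int p = ksz / 2;
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector gx(nvox * cin);
  NumericVector gw(w.size());
  NumericVector gb(cout);
  const double *px = x.begin(), *pw = w.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  for (int co = 0; co < cout; ++co) {
    const double *gc = pg + nvox * co;
    double s = 0.0;
    for (R_xlen_t t = 0; t < nvox; ++t) s += gc[t];
    pgb[co] = s;
  }
  for (int co = 0; co < cout; ++co) {
    const double *gc = pg + nvox * co;
    for (int ci = 0; ci < cin; ++ci) {
      const double *xc = px + nvox * ci;
      double *gxc = pgx + nvox * ci;
      for (int dz = -p; dz <= p; ++dz) {
        int k0 = dz < 0 ? -dz : 0, k1 = dz > 0 ? nz - dz : nz;
        for (int dy = -p; dy <= p; ++dy) {
          int j0 = dy < 0 ? -dy : 0, j1 = dy > 0 ? ny - dy : ny;
          for (int dx = -p; dx <= p; ++dx) {
            int i0 = dx < 0 ? -dx : 0, i1 = dx > 0 ? nx - dx : nx;
            R_xlen_t wi = widx(dx, dy, dz, ci, co, ksz, cin, p);
            double wv = pw[wi];
            R_xlen_t off = (R_xlen_t)dx + (R_xlen_t)nx * (dy + (R_xlen_t)ny * dz);
            double acc = 0.0;
            for (int k = k0; k < k1; ++k)
              for (int j = j0; j < j1; ++j) {
                R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
                const double *grow = gc + base;
                const double *xrow = xc + base + off;
                double *gxrow = gxc + base + off;
                for (int i = i0; i < i1; ++i) {
                  acc += xrow[i] * grow[i];
                  gxrow[i] += wv * grow[i];
                }
              }
            pgw[wi] += acc;
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// Trilinear warp: out(v) = vol(v + disp(v)), clamp-to-edge sampling.
// vol: [nx,ny,nz,C], disp: [nx,ny,nz,3].
// [[Rcpp::export]]
NumericVector warp_fwd_cpp(NumericVector vol, NumericVector disp,
                           IntegerVector vdim) {
  int nx = vdim[0], ny = vdim[1], nz = vdim[2], C = vdim[3];
  NumericVector out(vol.size());
  const double *pv = vol.begin(), *pd = disp.begin();
  double *po = out.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double sx = clampd(i + pd[idx4(i, j, k, 0, nx, ny, nz)], 0.0, nx - 1.0);
        double sy = clampd(j + pd[idx4(i, j, k, 1, nx, ny, nz)], 0.0, ny - 1.0);
        double sz = clampd(k + pd[idx4(i, j, k, 2, nx, ny, nz)], 0.0, nz - 1.0);
        int i0 = (int)std::floor(sx), j0 = (int)std::floor(sy), k0 = (int)std::floor(sz);
        i0 = clampi(i0, 0, nx - 1); j0 = clampi(j0, 0, ny - 1); k0 = clampi(k0, 0, nz - 1);
        int i1 = clampi(i0 + 1, 0, nx - 1), j1 = clampi(j0 + 1, 0, ny - 1), k1 = clampi(k0 + 1, 0, nz - 1);
        double fx = sx - i0, fy = sy - j0, fz = sz - k0;
        for (int c = 0; c < C; ++c) {
          double v000 = pv[idx4(i0, j0, k0, c, nx, ny, nz)];
          double v100 = pv[idx4(i1, j0, k0, c, nx, ny, nz)];
          double v010 = pv[idx4(i0, j1, k0, c, nx, ny, nz)];
          double v110 = pv[idx4(i1, j1, k0, c, nx, ny, nz)];
          double v001 = pv[idx4(i0, j0, k1, c, nx, ny, nz)];
          double v101 = pv[idx4(i1, j0, k1, c, nx, ny, nz)];
          double v011 = pv[idx4(i0, j1, k1, c, nx, ny, nz)];
          double v111 = pv[idx4(i1, j1, k1, c, nx, ny, nz)];
          double c00 = v000 * (1 - fx) + v100 * fx;
          double c10 = v010 * (1 - fx) + v110 * fx;
          double c01 = v001 * (1 - fx) + v101 * fx;
          double c11 = v011 * (1 - fx) + v111 * fx;
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          po[idx4(i, j, k, c, nx, ny, nz)] = c0 * (1 - fz) + c1 * fz;
        }
      }
  return out;
}

// Exact transpose of warp_fwd in the volume argument (splatting): for fixed
// disp, warp is a sparse linear map A; this computes A^T y.
// [[Rcpp::export]]
NumericVector warp_splat_cpp(NumericVector y, NumericVector disp,
                             IntegerVector vdim) {
  int nx = vdim[0], ny = vdim[1], nz = vdim[2], C = vdim[3];
  NumericVector out(y.size());
  const double *py = y.begin(), *pd = disp.begin();
  double *po = out.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double sx = clampd(i + pd[idx4(i, j, k, 0, nx, ny, nz)], 0.0, nx - 1.0);
        double sy = clampd(j + pd[idx4(i, j, k, 1, nx, ny, nz)], 0.0, ny - 1.0);
        double sz = clampd(k + pd[idx4(i, j, k, 2, nx, ny, nz)], 0.0, nz - 1.0);
        int i0 = clampi((int)std::floor(sx), 0, nx - 1);
        int j0 = clampi((int)std::floor(sy), 0, ny - 1);
        int k0 = clampi((int)std::floor(sz), 0, nz - 1);
        int i1 = clampi(i0 + 1, 0, nx - 1), j1 = clampi(j0 + 1, 0, ny - 1), k1 = clampi(k0 + 1, 0, nz - 1);
        double fx = sx - i0, fy = sy - j0, fz = sz - k0;
        double w000 = (1 - fx) * (1 - fy) * (1 - fz);
        double w100 = fx * (1 - fy) * (1 - fz);
        double w010 = (1 - fx) * fy * (1 - fz);
        double w110 = fx * fy * (1 - fz);
        double w001 = (1 - fx) * (1 - fy) * fz;
        double w101 = fx * (1 - fy) * fz;
        double w011 = (1 - fx) * fy * fz;
        double w111 = fx * fy * fz;
        for (int c = 0; c < C; ++c) {
          double g = py[idx4(i, j, k, c, nx, ny, nz)];
          if (g == 0.0) continue;
          po[idx4(i0, j0, k0, c, nx, ny, nz)] += w000 * g;
          po[idx4(i1, j0, k0, c, nx, ny, nz)] += w100 * g;
          po[idx4(i0, j1, k0, c, nx, ny, nz)] += w010 * g;
          po[idx4(i1, j1, k0, c, nx, ny, nz)] += w110 * g;
          po[idx4(i0, j0, k1, c, nx, ny, nz)] += w001 * g;
          po[idx4(i1, j0, k1, c, nx, ny, nz)] += w101 * g;
          po[idx4(i0, j1, k1, c, nx, ny, nz)] += w011 * g;
          po[idx4(i1, j1, k1, c, nx, ny, nz)] += w111 * g;
        }
      }
  return out;
}

// Gradient of warp w.r.t. the displacement field. The derivative of the
// trilinear sample w.r.t. the sample position is the analytic gradient of the
// interpolant inside the enclosing cell; zero where coordinates clamp.
// [[Rcpp::export]]
NumericVector warp_bwd_disp_cpp(NumericVector vol, NumericVector disp,
                                NumericVector gy, IntegerVector vdim) {
  int nx = vdim[0], ny = vdim[1], nz = vdim[2], C = vdim[3];
  NumericVector gd((R_xlen_t)nx * ny * nz * 3);
  const double *pv = vol.begin(), *pd = disp.begin(), *pg = gy.begin();
  double *pgd = gd.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double ux = i + pd[idx4(i, j, k, 0, nx, ny, nz)];
        double uy = j + pd[idx4(i, j, k, 1, nx, ny, nz)];
        double uz = k + pd[idx4(i, j, k, 2, nx, ny, nz)];
        bool inx = (ux > 0.0 && ux < nx - 1.0);
        bool iny = (uy > 0.0 && uy < ny - 1.0);
        bool inz = (uz > 0.0 && uz < nz - 1.0);
        double sx = clampd(ux, 0.0, nx - 1.0);
        double sy = clampd(uy, 0.0, ny - 1.0);
        double sz = clampd(uz, 0.0, nz - 1.0);
        int i0 = clampi((int)std::floor(sx), 0, nx - 1);
        int j0 = clampi((int)std::floor(sy), 0, ny - 1);
        int k0 = clampi((int)std::floor(sz), 0, nz - 1);
        int i1 = clampi(i0 + 1, 0, nx - 1), j1 = clampi(j0 + 1, 0, ny - 1), k1 = clampi(k0 + 1, 0, nz - 1);
        double fx = sx - i0, fy = sy - j0, fz = sz - k0;
        double ax = 0.0, ay = 0.0, az = 0.0;
        for (int c = 0; c < C; ++c) {
          double g = pg[idx4(i, j, k, c, nx, ny, nz)];
          if (g == 0.0) continue;
          double v000 = pv[idx4(i0, j0, k0, c, nx, ny, nz)];
          double v100 = pv[idx4(i1, j0, k0, c, nx, ny, nz)];
          double v010 = pv[idx4(i0, j1, k0, c, nx, ny, nz)];
          double v110 = pv[idx4(i1, j1, k0, c, nx, ny, nz)];
          double v001 = pv[idx4(i0, j0, k1, c, nx, ny, nz)];
          double v101 = pv[idx4(i1, j0, k1, c, nx, ny, nz)];
          double v011 = pv[idx4(i0, j1, k1, c, nx, ny, nz)];
          double v111 = pv[idx4(i1, j1, k1, c, nx, ny, nz)];
          double dvx = (1 - fy) * (1 - fz) * (v100 - v000) + fy * (1 - fz) * (v110 - v010) +
                       (1 - fy) * fz * (v101 - v001) + fy * fz * (v111 - v011);
          double dvy = (1 - fx) * (1 - fz) * (v010 - v000) + fx * (1 - fz) * (v110 - v100) +
                       (1 - fx) * fz * (v011 - v001) + fx * fz * (v111 - v101);
          double dvz = (1 - fx) * (1 - fy) * (v001 - v000) + fx * (1 - fy) * (v101 - v100) +
                       (1 - fx) * fy * (v011 - v010) + fx * fy * (v111 - v110);
          ax += g * dvx; ay += g * dvy; az += g * dvz;
        }
        if (inx) pgd[idx4(i, j, k, 0, nx, ny, nz)] = ax;
        if (iny) pgd[idx4(i, j, k, 1, nx, ny, nz)] = ay;
        if (inz) pgd[idx4(i, j, k, 2, nx, ny, nz)] = az;
      }
  return gd;
}

// ---------------------------------------------------------------------------
// 2x average pooling (each output voxel = mean of its 2x2x2 block).
// Input dims must be even in x,y,z.
// [[Rcpp::export]]
NumericVector avgpool2_fwd_cpp(NumericVector x, IntegerVector xdim) {
  int nx = xdim[0], ny = xdim[1], nz = xdim[2], C = xdim[3];
  int mx = nx / 2, my = ny / 2, mz = nz / 2;
  NumericVector y((R_xlen_t)mx * my * mz * C);
  const double *px = x.begin();
  double *py = y.begin();
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < mz; ++k)
      for (int j = 0; j < my; ++j)
        for (int i = 0; i < mx; ++i) {
          double acc = 0.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx)
                acc += px[idx4(2 * i + dx, 2 * j + dy, 2 * k + dz, c, nx, ny, nz)];
          py[idx4(i, j, k, c, mx, my, mz)] = acc / 8.0;
        }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool2_bwd_cpp(NumericVector gy, IntegerVector xdim) {
  int nx = xdim[0], ny = xdim[1], nz = xdim[2], C = xdim[3];
  int mx = nx / 2, my = ny / 2, mz = nz / 2;
  NumericVector gx((R_xlen_t)nx * ny * nz * C);
  const double *pg = gy.begin();
  double *px = gx.begin();
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < mz; ++k)
      for (int j = 0; j < my; ++j)
        for (int i = 0; i < mx; ++i) {
          double g = pg[idx4(i, j, k, c, mx, my, mz)] / 8.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx)
                px[idx4(2 * i + dx, 2 * j + dy, 2 * k + dz, c, nx, ny, nz)] = g;
        }
  return gx;
}

// Trilinear 2x upsampling: output voxel p samples input at (p + 0.5)/2 - 0.5,
// clamp-to-edge (adjoint of this map is used for the backward pass).
// [[Rcpp::export]]
NumericVector upsample2_fwd_cpp(NumericVector x, IntegerVector xdim) {
  int mx = xdim[0], my = xdim[1], mz = xdim[2], C = xdim[3];
  int nx = 2 * mx, ny = 2 * my, nz = 2 * mz;
  NumericVector y((R_xlen_t)nx * ny * nz * C);
  const double *px = x.begin();
  double *py = y.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double sx = clampd((i + 0.5) / 2.0 - 0.5, 0.0, mx - 1.0);
        double sy = clampd((j + 0.5) / 2.0 - 0.5, 0.0, my - 1.0);
        double sz = clampd((k + 0.5) / 2.0 - 0.5, 0.0, mz - 1.0);
        int i0 = clampi((int)std::floor(sx), 0, mx - 1);
        int j0 = clampi((int)std::floor(sy), 0, my - 1);
        int k0 = clampi((int)std::floor(sz), 0, mz - 1);
        int i1 = clampi(i0 + 1, 0, mx - 1), j1 = clampi(j0 + 1, 0, my - 1), k1 = clampi(k0 + 1, 0, mz - 1);
        double fx = sx - i0, fy = sy - j0, fz = sz - k0;
        for (int c = 0; c < C; ++c) {
          double c00 = px[idx4(i0, j0, k0, c, mx, my, mz)] * (1 - fx) + px[idx4(i1, j0, k0, c, mx, my, mz)] * fx;
          double c10 = px[idx4(i0, j1, k0, c, mx, my, mz)] * (1 - fx) + px[idx4(i1, j1, k0, c, mx, my, mz)] * fx;
          double c01 = px[idx4(i0, j0, k1, c, mx, my, mz)] * (1 - fx) + px[idx4(i1, j0, k1, c, mx, my, mz)] * fx;
          double c11 = px[idx4(i0, j1, k1, c, mx, my, mz)] * (1 - fx) + px[idx4(i1, j1, k1, c, mx, my, mz)] * fx;
          double c0 = c00 * (1 - fy) + c10 * fy;
          double c1 = c01 * (1 - fy) + c11 * fy;
          py[idx4(i, j, k, c, nx, ny, nz)] = c0 * (1 - fz) + c1 * fz;
        }
      }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd_cpp(NumericVector gy, IntegerVector xdim) {
  int mx = xdim[0], my = xdim[1], mz = xdim[2], C = xdim[3];
  int nx = 2 * mx, ny = 2 * my, nz = 2 * mz;
  NumericVector gx((R_xlen_t)mx * my * mz * C);
  const double *pg = gy.begin();
  double *px = gx.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double sx = clampd((i + 0.5) / 2.0 - 0.5, 0.0, mx - 1.0);
        double sy = clampd((j + 0.5) / 2.0 - 0.5, 0.0, my - 1.0);
        double sz = clampd((k + 0.5) / 2.0 - 0.5, 0.0, mz - 1.0);
        int i0 = clampi((int)std::floor(sx), 0, mx - 1);
        int j0 = clampi((int)std::floor(sy), 0, my - 1);
        int k0 = clampi((int)std::floor(sz), 0, mz - 1);
        int i1 = clampi(i0 + 1, 0, mx - 1), j1 = clampi(j0 + 1, 0, my - 1), k1 = clampi(k0 + 1, 0, mz - 1);
        double fx = sx - i0, fy = sy - j0, fz = sz - k0;
        double w000 = (1 - fx) * (1 - fy) * (1 - fz), w100 = fx * (1 - fy) * (1 - fz);
        double w010 = (1 - fx) * fy * (1 - fz), w110 = fx * fy * (1 - fz);
        double w001 = (1 - fx) * (1 - fy) * fz, w101 = fx * (1 - fy) * fz;
        double w011 = (1 - fx) * fy * fz, w111 = fx * fy * fz;
        for (int c = 0; c < C; ++c) {
          double g = pg[idx4(i, j, k, c, nx, ny, nz)];
          if (g == 0.0) continue;
          px[idx4(i0, j0, k0, c, mx, my, mz)] += w000 * g;
          px[idx4(i1, j0, k0, c, mx, my, mz)] += w100 * g;
          px[idx4(i0, j1, k0, c, mx, my, mz)] += w010 * g;
          px[idx4(i1, j1, k0, c, mx, my, mz)] += w110 * g;
          px[idx4(i0, j0, k1, c, mx, my, mz)] += w001 * g;
          px[idx4(i1, j0, k1, c, mx, my, mz)] += w101 * g;
          px[idx4(i0, j1, k1, c, mx, my, mz)] += w011 * g;
          px[idx4(i1, j1, k1, c, mx, my, mz)] += w111 * g;
        }
      }
  return gx;
}

// ---------------------------------------------------------------------------
// Separable 1D convolution along one axis (for Gaussian windows in SSIM),
// reflected (symmetric) boundary.
// [[Rcpp::export]]
NumericVector sepconv3_cpp(NumericVector x, NumericVector kern,
                           IntegerVector xdim, int axis) {
  int nx = xdim[0], ny = xdim[1], nz = xdim[2];
  int C = xdim.size() > 3 ? xdim[3] : 1;
  int kl = kern.size(), p = kl / 2;
  NumericVector y(x.size());
  const double *px = x.begin(), *pk = kern.begin();
  double *py = y.begin();
  int n[3] = {nx, ny, nz};
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double acc = 0.0;
          int pos[3] = {i, j, k};
          for (int t = -p; t <= p; ++t) {
            int q = pos[axis] + t;
            if (q < 0) q = -q - 1;
            if (q >= n[axis]) q = 2 * n[axis] - q - 1;
            int ii = i, jj = j, kk = k;
            if (axis == 0) ii = q; else if (axis == 1) jj = q; else kk = q;
            acc += px[idx4(ii, jj, kk, c, nx, ny, nz)] * pk[t + p];
          }
          py[idx4(i, j, k, c, nx, ny, nz)] = acc;
        }
  return y;
}
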