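#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cubic B-spline kernel beta^3(t), support (-2, 2).
static inline double bspl3(double t) {
  t = std::fabs(t);
  if (t < 1.0) return 2.0 / 3.0 - t * t + 0.5 * t * t * t;
  if (t < 2.0) { double u = 2.0 - t; return u * u * u / 6.0; }
  return 0.0;
}

// Trilinear / nearest / cubic-B-spline interpolation of a 3D volume at
// continuous 0-based index coordinates. For scheme = 3 the volume is expected
// to hold B-spline coefficients (see cpp_bspline_prefilter); points outside
// the node-centered domain [0, n-1] per axis return `fill`.
// [[Rcpp::export]]
NumericVector cpp_interp3(NumericVector vol, IntegerVector dim,
                          NumericMatrix idx, int scheme, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = idx.nrow();
  NumericVector out(n);
  const double *v = vol.begin();
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  for (R_xlen_t k = 0; k < n; ++k) {
    double x = idx(k, 0), y = idx(k, 1), z = idx(k, 2);
    if (!std::isfinite(x) || !std::isfinite(y) || !std::isfinite(z) ||
        x < 0.0 || y < 0.0 || z < 0.0 ||
        x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) {
      out[k] = fill;
      continue;
    }
    if (scheme == 0) { // nearest
      int ix = (int)std::floor(x + 0.5), iy = (int)std::floor(y + 0.5),
          iz = (int)std::floor(z + 0.5);
      if (ix > nx - 1) ix = nx - 1;
      if (iy > ny - 1) iy = ny - 1;
      if (iz > nz - 1) iz = nz - 1;
      out[k] = v[ix * sx + iy * sy + iz * sz];
    } else if (scheme == 1) { // trilinear
      int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
      if (ix > nx - 2) ix = nx - 2;
      if (iy > ny - 2) iy = ny - 2;
      if (iz > nz - 2) iz = nz - 2;
      if (ix < 0) ix = 0;
      if (iy < 0) iy = 0;
      if (iz < 0) iz = 0;
      double fx = x - ix, fy = y - iy, fz = z - iz;
      // degenerate (single-node) axes: zero stride so the (weight-zero)
      // upper neighbour is never read out of bounds
      const R_xlen_t ux = (nx > 1) ? sx : 0, uy = (ny > 1) ? sy : 0,
                     uz = (nz > 1) ? sz : 0;
      const double *p = v + ix * sx + iy * sy + iz * sz;
      double c00 = p[0] * (1 - fx) + p[ux] * fx;
      double c10 = p[uy] * (1 - fx) + p[uy + ux] * fx;
      double c01 = p[uz] * (1 - fx) + p[uz + ux] * fx;
      double c11 = p[uz + uy] * (1 - fx) + p[uz + uy + ux] * fx;
      double c0 = c00 * (1 - fy) + c10 * fy;
      double c1 = c01 * (1 - fy) + c11 * fy;
      out[k] = c0 * (1 - fz) + c1 * fz;
    } else { // cubic B-spline on coefficient volume, mirrored borders
      int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
      double wx[4], wy[4], wz[4];
      int jx[4], jy[4], jz[4];
      for (int j = 0; j < 4; ++j) {
        int gx = ix - 1 + j, gy = iy - 1 + j, gz = iz - 1 + j;
        wx[j] = bspl3(x - gx);
        wy[j] = bspl3(y - gy);
        wz[j] = bspl3(z - gz);
        // mirror boundary
        if (gx < 0) gx = -gx;
        if (gy < 0) gy = -gy;
        if (gz < 0) gz = -gz;
        if (gx > nx - 1) gx = 2 * (nx - 1) - gx;
        if (gy > ny - 1) gy = 2 * (ny - 1) - gy;
        if (gz > nz - 1) gz = 2 * (nz - 1) - gz;
        jx[j] = gx; jy[j] = gy; jz[j] = gz;
      }
      double acc = 0.0;
      for (int c = 0; c < 4; ++c) {
        if (wz[c] == 0.0) continue;
        double accy = 0.0;
        for (int b = 0; b < 4; ++b) {
          if (wy[b] == 0.0) continue;
          const double *p = v + jy[b] * sy + jz[c] * sz;
          double accx = p[jx[0]] * wx[0] + p[jx[1]] * wx[1] +
                        p[jx[2]] * wx[2] + p[jx[3]] * wx[3];
          accy += accx * wy[b];
        }
        acc += accy * wz[c];
      }
      out[k] = acc;
    }
  }
  return out;
}

// Trilinear interpolation together with the exact gradient of the
// interpolant (in index units) at continuous 0-based index coordinates.
// Returns an n x 4 matrix: value, d/dx, d/dy, d/dz. Outside the domain the
// value is `fill` and the gradient is zero.
// [[Rcpp::export]]
NumericMatrix cpp_interp3_grad(NumericVector vol, IntegerVector dim,
                               NumericMatrix idx, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = idx.nrow();
  NumericMatrix out(n, 4);
  const double *v = vol.begin();
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t k = 0; k < n; ++k) {
    double x = idx(k, 0), y = idx(k, 1), z = idx(k, 2);
    if (!std::isfinite(x) || !std::isfinite(y) || !std::isfinite(z) ||
        x < 0.0 || y < 0.0 || z < 0.0 ||
        x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) {
      out(k, 0) = fill;
      continue;
    }
    int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
    if (ix > nx - 2) ix = nx - 2;
    if (iy > ny - 2) iy = ny - 2;
    if (iz > nz - 2) iz = nz - 2;
    if (ix < 0) ix = 0;
    if (iy < 0) iy = 0;
    if (iz < 0) iz = 0;
    double fx = x - ix, fy = y - iy, fz = z - iz;
    const R_xlen_t ux = (nx > 1) ? sx : 0, uy = (ny > 1) ? sy : 0,
                   uz = (nz > 1) ? sz : 0;
    const double *p = v + ix * sx + iy * sy + iz * sz;
    double v000 = p[0], v100 = p[ux], v010 = p[uy], v110 = p[uy + ux];
    double v001 = p[uz], v101 = p[uz + ux], v011 = p[uz + uy],
           v111 = p[uz + uy + ux];
    double c00 = v000 * (1 - fx) + v100 * fx;
    double c10 = v010 * (1 - fx) + v110 * fx;
    double c01 = v001 * (1 - fx) + v101 * fx;
    double c11 = v011 * (1 - fx) + v111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out(k, 0) = c0 * (1 - fz) + c1 * fz;
    double gx00 = v100 - v000, gx10 = v110 - v010, gx01 = v101 - v001,
           gx11 = v111 - v011;
    out(k, 1) = ((gx00 * (1 - fy) + gx10 * fy) * (1 - fz) +
                 (gx01 * (1 - fy) + gx11 * fy) * fz);
    out(k, 2) = ((c10 - c00) * (1 - fz) + (c11 - c01) * fz);
    out(k, 3) = c1 - c0;
  }
  return out;
}

// Recursive prefilter along one line (Unser): converts samples to cubic
// B-spline interpolation coefficients. Pole z1 = sqrt(3) - 2.
static void prefilter_line(double *c, int n, R_xlen_t stride) {
  if (n < 2) return;
  const double z1 = std::sqrt(3.0) - 2.0;
  const double lambda = 6.0;
  // causal init under mirror boundary: exact formula for short signals,
  // truncated impulse response otherwise
  int maxh = (int)std::ceil(std::log(1e-14) / std::log(std::fabs(z1)));
  double sum;
  if (n < maxh) {
    double zn = z1;
    sum = c[0];
    for (int k = 1; k <= 2 * n - 3; ++k) {
      int idx = (k < n) ? k : (2 * n - 2 - k);
      sum += zn * c[(R_xlen_t)idx * stride];
      zn *= z1;
    }
    sum /= (1.0 - std::pow(z1, 2 * n - 2));
  } else {
    double zn = z1;
    sum = c[0];
    for (int i = 1; i < maxh; ++i) {
      sum += zn * c[(R_xlen_t)i * stride];
      zn *= z1;
    }
  }
  double prev = sum;
  c[0] = prev;
  for (int i = 1; i < n; ++i) {
    prev = c[(R_xlen_t)i * stride] + z1 * prev;
    c[(R_xlen_t)i * stride] = prev;
  }
  // anticausal init
  double last = c[(R_xlen_t)(n - 1) * stride];
  double before = c[(R_xlen_t)(n - 2) * stride];
  double next = (z1 / (z1 * z1 - 1.0)) * (last + z1 * before);
  c[(R_xlen_t)(n - 1) * stride] = next;
  for (int i = n - 2; i >= 0; --i) {
    next = z1 * (next - c[(R_xlen_t)i * stride]);
    c[(R_xlen_t)i * stride] = next;
  }
  for (int i = 0; i < n; ++i) c[(R_xlen_t)i * stride] *= lambda;
}

// [[Rcpp::export]]
NumericVector cpp_bspline_prefilter(NumericVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(vol);
  double *v = out.begin();
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      prefilter_line(v + y * sy + z * sz, nx, 1);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      prefilter_line(v + x + z * sz, ny, sy);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      prefilter_line(v + x + y * sy, nz, sz);
  return out;
}

// Bilinear / nearest interpolation of a 2D image at continuous 0-based
// index coordinates.
// [[Rcpp::export]]
NumericVector cpp_interp2(NumericVector img, IntegerVector dim,
                          NumericMatrix idx, int scheme, double fill) {
  const int nx = dim[0], ny = dim[1];
  const R_xlen_t n = idx.nrow();
  NumericVector out(n);
  const double *v = img.begin();
  for (R_xlen_t k = 0; k < n; ++k) {
    double x = idx(k, 0), y = idx(k, 1);
    if (!std::isfinite(x) || !std::isfinite(y) ||
        x < 0.0 || y < 0.0 || x > nx - 1.0 || y > ny - 1.0) {
      out[k] = fill;
      continue;
    }
    if (scheme == 0) {
      int ix = (int)std::floor(x + 0.5), iy = (int)std::floor(y + 0.5);
      if (ix > nx - 1) ix = nx - 1;
      if (iy > ny - 1) iy = ny - 1;
      out[k] = v[ix + (R_xlen_t)iy * nx];
    } else {
      int ix = (int)std::floor(x), iy = (int)std::floor(y);
      if (ix > nx - 2) ix = nx - 2;
      if (iy > ny - 2) iy = ny - 2;
      if (ix < 0) ix = 0;
      if (iy < 0) iy = 0;
      double fx = x - ix, fy = y - iy;
      const R_xlen_t ux = (nx > 1) ? 1 : 0, uy = (ny > 1) ? nx : 0;
      const double *p = v + ix + (R_xlen_t)iy * nx;
      out[k] = (p[0] * (1 - fx) + p[ux] * fx) * (1 - fy) +
               (p[uy] * (1 - fx) + p[uy + ux] * fx) * fy;
    }
  }
  return out;
}

// Displacement of a free-form cubic B-spline transform at world points.
// coef is [ncx, ncy, ncz, 3] (column-major); identity (zero) outside the
// control-grid support.
// [[Rcpp::export]]
NumericMatrix cpp_bspline_disp(NumericVector coef, IntegerVector cdim,
                               NumericVector origin, NumericVector spacing,
                               NumericMatrix pts) {
  const int nx = cdim[0], ny = cdim[1], nz = cdim[2];
  const R_xlen_t n = pts.nrow();
  NumericMatrix out(n, 3);
  const double *cf = coef.begin();
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny, sa = (R_xlen_t)nx * ny * nz;
  for (R_xlen_t k = 0; k < n; ++k) {
    double g[3];
    bool ok = true;
    for (int a = 0; a < 3; ++a) {
      g[a] = (pts(k, a) - origin[a]) / spacing[a];
      if (!std::isfinite(g[a])) ok = false;
    }
    if (!ok) { out(k, 0) = out(k, 1) = out(k, 2) = 0.0; continue; }
    int i0[3]; double w[3][4];
    for (int a = 0; a < 3; ++a) {
      i0[a] = (int)std::floor(g[a]) - 1;
      for (int j = 0; j < 4; ++j) w[a][j] = bspl3(g[a] - (i0[a] + j));
    }
    // outside support (needs full 4-point neighborhood) -> zero displacement
    if (i0[0] < 0 || i0[1] < 0 || i0[2] < 0 ||
        i0[0] + 3 > nx - 1 || i0[1] + 3 > ny - 1 || i0[2] + 3 > nz - 1) {
      out(k, 0) = out(k, 1) = out(k, 2) = 0.0;
      continue;
    }
    for (int axis = 0; axis < 3; ++axis) {
      double acc = 0.0;
      const double *base = cf + axis * sa;
      for (int c = 0; c < 4; ++c) {
        if (w[2][c] == 0.0) continue;
        double accy = 0.0;
        for (int b = 0; b < 4; ++b) {
          if (w[1][b] == 0.0) continue;
          const double *p = base + i0[0] + (i0[1] + b) * sy + (R_xlen_t)(i0[2] + c) * sz;
          accy += (p[0] * w[0][0] + p[1] * w[0][1] + p[2] * w[0][2] + p[3] * w[0][3]) * w[1][b];
        }
        acc += accy * w[2][c];
      }
      out(k, axis) = acc;
    }
  }
  return out;
}

// Scatter-accumulate the gradient of a point-wise cost onto B-spline
// coefficients: grad[cp, axis] = sum_k dvals[k, axis] * w_k(cp).
// [[Rcpp::export]]
NumericVector cpp_bspline_grad_accum(IntegerVector cdim, NumericVector origin,
                                     NumericVector spacing, NumericMatrix pts,
                                     NumericMatrix dvals) {
  const int nx = cdim[0], ny = cdim[1], nz = cdim[2];
  const R_xlen_t n = pts.nrow();
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny, sa = (R_xlen_t)nx * ny * nz;
  NumericVector grad(sa * 3);
  double *g3 = grad.begin();
  for (R_xlen_t k = 0; k < n; ++k) {
    double g[3];
    for (int a = 0; a < 3; ++a) g[a] = (pts(k, a) - origin[a]) / spacing[a];
    int i0[3]; double w[3][4];
    for (int a = 0; a < 3; ++a) {
      i0[a] = (int)std::floor(g[a]) - 1;
      for (int j = 0; j < 4; ++j) w[a][j] = bspl3(g[a] - (i0[a] + j));
    }
    if (i0[0] < 0 || i0[1] < 0 || i0[2] < 0 ||
        i0[0] + 3 > nx - 1 || i0[1] + 3 > ny - 1 || i0[2] + 3 > nz - 1)
      continue;
    for (int c = 0; c < 4; ++c)
      for (int b = 0; b < 4; ++b)
        for (int a = 0; a < 4; ++a) {
          double wt = w[0][a] * w[1][b] * w[2][c];
          if (wt == 0.0) continue;
          R_xlen_t off = (i0[0] + a) + (i0[1] + b) * sy + (R_xlen_t)(i0[2] + c) * sz;
          g3[off] += wt * dvals(k, 0);
          g3[off + sa] += wt * dvals(k, 1);
          g3[off + 2 * sa] += wt * dvals(k, 2);
        }
  }
  return grad;
}

// Separable 1D convolution along one axis of a 3D volume with a symmetric
// kernel, mirrored borders. axis: 0 = x, 1 = y, 2 = z.
// [[Rcpp::export]]
NumericVector cpp_smooth_axis(NumericVector vol, IntegerVector dim,
                              NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kn = kernel.size(), half = kn / 2;
  NumericVector out(vol.size());
  const double *v = vol.begin();
  double *o = out.begin();
  const R_xlen_t s[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int n[3] = {nx, ny, nz};
  const int na = n[axis];
  const R_xlen_t sa = s[axis];
  // iterate over all lines along `axis`
  int a1 = (axis == 0) ? 1 : 0;
  int a2 = (axis == 2) ? 1 : 2;
  for (int j2 = 0; j2 < n[a2]; ++j2)
    for (int j1 = 0; j1 < n[a1]; ++j1) {
      R_xlen_t base = (R_xlen_t)j1 * s[a1] + (R_xlen_t)j2 * s[a2];
      for (int i = 0; i < na; ++i) {
        double acc = 0.0;
        for (int kk = 0; kk < kn; ++kk) {
          int ii = i + kk - half;
          if (ii < 0) ii = -ii;
          if (ii > na - 1) ii = 2 * (na - 1) - ii;
          acc += kernel[kk] * v[base + (R_xlen_t)ii * sa];
        }
        o[base + (R_xlen_t)i * sa] = acc;
      }
    }
  return out;
}
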