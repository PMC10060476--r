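#include <Rcpp.h>
using namespace Rcpp;

// Trilinear sampling of a 3D array at arbitrary (0-based) voxel coordinates.
// Points outside the source field of view evaluate to 0 (no wrapping).
// pts is 3 x n. Intensities are interpolated as stored ("preserve
// concentrations": no Jacobian modulation).
// [[Rcpp::export]]
NumericVector cpp_trilinear(const NumericVector& arr, const IntegerVector& dim,
                            const NumericMatrix& pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.ncol();
  NumericVector out(n);
  const double* a = arr.begin();
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double x = pts(0, i), y = pts(1, i), z = pts(2, i);
    if (!(x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
          z >= 0.0 && z <= nz - 1.0)) {
      out[i] = 0.0;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1) --x0;
    if (y0 == ny - 1) --y0;
    if (z0 == nz - 1) --z0;
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    const double gx = 1.0 - fx, gy = 1.0 - fy, gz = 1.0 - fz;
    const R_xlen_t base = x0 * sx + y0 * sy + z0 * sz;
    const R_xlen_t dx = (nx > 1) ? sx : 0, dy = (ny > 1) ? sy : 0,
                   dz = (nz > 1) ? sz : 0;
    out[i] =
        gz * (gy * (gx * a[base] + fx * a[base + dx]) +
              fy * (gx * a[base + dy] + fx * a[base + dx + dy])) +
        fz * (gy * (gx * a[base + dz] + fx * a[base + dx + dz]) +
              fy * (gx * a[base + dy + dz] + fx * a[base + dx + dy + dz]));
  }
  return out;
}

// Separable 1D convolution along one axis (0=x,1=y,2=z) with reflective
// boundary handling; kernel must be normalized by the caller.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(const NumericVector& arr, const IntegerVector& dim,
                            const NumericVector& kernel, const int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kl = kernel.size(), r = (kl - 1) / 2;
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double* a = arr.begin();
  double* o = out.begin();
  const int n[3] = {nx, ny, nz};
  const R_xlen_t s[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int na = n[axis];
  const R_xlen_t sa = s[axis];
  // iterate over all lines along `axis`
  const int b1 = (axis == 0) ? 1 : 0;
  const int b2 = (axis == 2) ? 1 : 2;
  for (int j2 = 0; j2 < n[b2]; ++j2) {
    for (int j1 = 0; j1 < n[b1]; ++j1) {
      const R_xlen_t base = (R_xlen_t)j1 * s[b1] + (R_xlen_t)j2 * s[b2];
      for (int i = 0; i < na; ++i) {
        double acc = 0.0;
        for (int k = 0; k < kl; ++k) {
          int idx = i + k - r;
          // reflect (symmetric, edge repeated mirror: -1 -> 0? use mirror
          // about the boundary sample: -1 -> 1, na -> na-2)
          while (idx < 0 || idx >= na) {
            if (idx < 0) idx = -idx;
            if (idx >= na) idx = 2 * na - 2 - idx;
            if (na == 1) { idx = 0; break; }
          }
          acc += kernel[k] * a[base + (R_xlen_t)idx * sa];
        }
        o[base + (R_xlen_t)i * sa] = acc;
      }
    }
  }
  return out;
}
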