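#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// 1D lower envelope of parabolas (Felzenszwalb & Huttenlocher), grid step s.
// f: squared distances at n sites spaced s apart; result overwrites d.
static void dt1d(const double *f, double *d, int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double fq = f[q];
    double sint;
    while (true) {
      double xv = v[k] * s;
      sint = ((fq + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (sint <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sint;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest TRUE voxel.
// Voxels where mask is TRUE get 0. All-FALSE masks yield Inf everywhere.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // large finite sentinel: the envelope algebra stays well defined (infinities
  // would produce NaN breakpoints); restored to Inf on output
  const double INF = 1e30;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);

  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f.data(), d.data(), nx, sx);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f.data(), d.data(), ny, sy);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = out[base + z * nxy];
      dt1d(f.data(), d.data(), nz, sz);
      for (int z = 0; z < nz; ++z) out[base + z * nxy] = d[z];
    }
  const double REALINF = std::numeric_limits<double>::infinity();
  for (R_xlen_t i = 0; i < n; ++i) if (out[i] >= 1e29) out[i] = REALINF;
  return out;
}

// 6-connected component labelling; labels 1..k in first-encounter order, 0 outside mask.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++cur;
    stack.push_back(i);
    lab[i] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / nxy);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t w = (R_xlen_t)zz * nxy + (R_xlen_t)yy * nx + xx;
        if (mask[w] && lab[w] == 0) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  return lab;
}

// Trilinear interpolation at fractional 0-based voxel coordinates (rows of coords).
// Out-of-volume samples return `fill`.
// [[Rcpp::export]]
NumericVector trilinear_sample_cpp(NumericVector img, IntegerVector dim,
                                   NumericMatrix coords, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t m = coords.nrow();
  NumericVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    double x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[i] = fill;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1) --x0;
    if (y0 == ny - 1) --y0;
    if (z0 == nz - 1) --z0;
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1), z1 = std::min(z0 + 1, nz - 1);
    double c000 = img[(R_xlen_t)z0 * nxy + (R_xlen_t)y0 * nx + x0];
    double c100 = img[(R_xlen_t)z0 * nxy + (R_xlen_t)y0 * nx + x1];
    double c010 = img[(R_xlen_t)z0 * nxy + (R_xlen_t)y1 * nx + x0];
    double c110 = img[(R_xlen_t)z0 * nxy + (R_xlen_t)y1 * nx + x1];
    double c001 = img[(R_xlen_t)z1 * nxy + (R_xlen_t)y0 * nx + x0];
    double c101 = img[(R_xlen_t)z1 * nxy + (R_xlen_t)y0 * nx + x1];
    double c011 = img[(R_xlen_t)z1 * nxy + (R_xlen_t)y1 * nx + x0];
    double c111 = img[(R_xlen_t)z1 * nxy + (R_xlen_t)y1 * nx + x1];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[i] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}
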