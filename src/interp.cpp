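#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear / nearest sampling of a rank-3 volume at arbitrary world
// coordinates.  Voxel centres sit at (i + 0.5) * d, 0-based, world in um.
// border: 0 = fill with bg outside the field of view, 1 = clamp to edge.

static inline double sample3(const double *v, int nx, int ny, int nz,
                             double x, double y, double z,
                             int mode, int border, double bg) {
  // to continuous voxel coordinates
  if (border == 1) {
    x = std::min(std::max(x, 0.0), (double)(nx - 1));
    y = std::min(std::max(y, 0.0), (double)(ny - 1));
    z = std::min(std::max(z, 0.0), (double)(nz - 1));
  }
  if (mode == 1) { // nearest
    int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return bg;
    return v[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
  }
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  if (i0 < -1 || j0 < -1 || k0 < -1 || i0 > nx - 1 || j0 > ny - 1 || k0 > nz - 1)
    return bg;
  double acc = 0.0, wsum = 0.0;
  for (int dk = 0; dk <= 1; ++dk)
    for (int dj = 0; dj <= 1; ++dj)
      for (int di = 0; di <= 1; ++di) {
        int i = i0 + di, j = j0 + dj, k = k0 + dk;
        double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
        if (w <= 0) continue;
        if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) {
          acc += w * bg;
        } else {
          acc += w * v[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        }
        wsum += w;
      }
  (void)wsum;
  return acc;
}

// [[Rcpp::export(name = ".cpp_interp3")]]
NumericVector cpp_interp3(NumericVector vol, IntegerVector dims,
                          NumericMatrix coords, NumericVector vsize,
                          int mode, int border, double bg) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = coords.nrow();
  NumericVector out(n);
  const double *v = vol.begin();
  double dx = vsize[0], dy = vsize[1], dz = vsize[2];
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = coords(p, 0) / dx - 0.5;
    double y = coords(p, 1) / dy - 0.5;
    double z = coords(p, 2) / dz - 0.5;
    out[p] = sample3(v, nx, ny, nz, x, y, z, mode, border, bg);
  }
  return out;
}

static inline double sample2(const double *v, int nx, int ny,
                             double x, double y, int mode, int border, double bg) {
  if (border == 1) {
    x = std::min(std::max(x, 0.0), (double)(nx - 1));
    y = std::min(std::max(y, 0.0), (double)(ny - 1));
  }
  if (mode == 1) {
    int i = (int)std::lround(x), j = (int)std::lround(y);
    if (i < 0 || j < 0 || i >= nx || j >= ny) return bg;
    return v[i + (R_xlen_t)nx * j];
  }
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y);
  double fx = x - i0, fy = y - j0;
  if (i0 < -1 || j0 < -1 || i0 > nx - 1 || j0 > ny - 1) return bg;
  double acc = 0.0;
  for (int dj = 0; dj <= 1; ++dj)
    for (int di = 0; di <= 1; ++di) {
      int i = i0 + di, j = j0 + dj;
      double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy);
      if (w <= 0) continue;
      if (i < 0 || j < 0 || i >= nx || j >= ny) acc += w * bg;
      else acc += w * v[i + (R_xlen_t)nx * j];
    }
  return acc;
}

// [[Rcpp::export(name = ".cpp_interp2")]]
NumericVector cpp_interp2(NumericMatrix img, NumericMatrix coords,
                          NumericVector psize, int mode, int border, double bg) {
  int nx = img.nrow(), ny = img.ncol();
  R_xlen_t n = coords.nrow();
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = coords(p, 0) / psize[0] - 0.5;
    double y = coords(p, 1) / psize[1] - 0.5;
    out[p] = sample2(img.begin(), nx, ny, x, y, mode, border, bg);
  }
  return out;
}
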