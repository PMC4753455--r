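#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cubic B-spline free-form deformation on a regular control lattice spanning
// the reference volume: cells per axis = g - 3 for g control points, so the
// displacement at world x is sum_{l,m,n=0..3} B_l(u)B_m(v)B_n(w) phi[i0+l,...]
// with i0 = floor(x/h) - 1, h = extent/(g-3).  Indices clamped to the lattice.

static inline void bsp(double u, double *B) {
  double u2 = u * u, u3 = u2 * u;
  B[0] = (1 - 3 * u + 3 * u2 - u3) / 6.0;
  B[1] = (3 * u3 - 6 * u2 + 4) / 6.0;
  B[2] = (-3 * u3 + 3 * u2 + 3 * u + 1) / 6.0;
  B[3] = u3 / 6.0;
}

static inline int clampi(int i, int n) { return i < 0 ? 0 : (i >= n ? n - 1 : i); }

// [[Rcpp::export(name = ".cpp_bspline_disp")]]
NumericMatrix cpp_bspline_disp(NumericVector grid, IntegerVector gdim,
                               NumericMatrix coords, NumericVector extent) {
  int gx = gdim[0], gy = gdim[1], gz = gdim[2];
  double hx = extent[0] / (gx - 3), hy = extent[1] / (gy - 3), hz = extent[2] / (gz - 3);
  R_xlen_t n = coords.nrow();
  R_xlen_t gsz = (R_xlen_t)gx * gy * gz;
  const double *G = grid.begin();
  NumericMatrix out(n, 3);
  double Bx[4], By[4], Bz[4];
  for (R_xlen_t p = 0; p < n; ++p) {
    double sx = coords(p, 0) / hx, sy = coords(p, 1) / hy, sz = coords(p, 2) / hz;
    int i0 = (int)std::floor(sx) - 1, j0 = (int)std::floor(sy) - 1, k0 = (int)std::floor(sz) - 1;
    bsp(sx - std::floor(sx), Bx); bsp(sy - std::floor(sy), By); bsp(sz - std::floor(sz), Bz);
    double d0 = 0, d1 = 0, d2 = 0;
    for (int c = 0; c < 4; ++c) {
      int k = clampi(k0 + c, gz);
      for (int b = 0; b < 4; ++b) {
        int j = clampi(j0 + b, gy);
        double wbc = By[b] * Bz[c];
        for (int a = 0; a < 4; ++a) {
          int i = clampi(i0 + a, gx);
          double w = Bx[a] * wbc;
          R_xlen_t q = i + (R_xlen_t)gx * (j + (R_xlen_t)gy * k);
          d0 += w * G[q];
          d1 += w * G[q + gsz];
          d2 += w * G[q + 2 * gsz];
        }
      }
    }
    out(p, 0) = d0; out(p, 1) = d1; out(p, 2) = d2;
  }
  return out;
}

static inline double tri_clamped(const double *v, int nx, int ny, int nz,
                                 double x, double y, double z) {
  x = std::min(std::max(x, 0.0), (double)(nx - 1));
  y = std::min(std::max(y, 0.0), (double)(ny - 1));
  z = std::min(std::max(z, 0.0), (double)(nz - 1));
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 >= nx - 1) i0 = nx - 2; if (j0 >= ny - 1) j0 = ny - 2; if (k0 >= nz - 1) k0 = nz - 2;
  if (nx == 1) i0 = 0; if (ny == 1) j0 = 0; if (nz == 1) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double acc = 0;
  for (int dk = 0; dk <= (nz > 1); ++dk)
    for (int dj = 0; dj <= (ny > 1); ++dj)
      for (int di = 0; di <= (nx > 1); ++di) {
        double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
        acc += w * v[(i0 + di) + (R_xlen_t)nx * ((j0 + dj) + (R_xlen_t)ny * (k0 + dk))];
      }
  return acc;
}

static double mi_bits(const std::vector<double> &H, int nb, double n) {
  std::vector<double> px(nb, 0.0), py(nb, 0.0);
  for (int j = 0; j < nb; ++j)
    for (int i = 0; i < nb; ++i) {
      px[i] += H[i + (size_t)nb * j];
      py[j] += H[i + (size_t)nb * j];
    }
  double mi = 0, l2 = std::log(2.0);
  for (int j = 0; j < nb; ++j)
    for (int i = 0; i < nb; ++i) {
      double h = H[i + (size_t)nb * j];
      if (h <= 0) continue;
      double p = h / n;
      mi += p * std::log(p * n * n / (px[i] * py[j])) / l2;
    }
  return mi;
}

// Mutual information of (reference bins, deformed floating intensities) and
// its finite-difference gradient w.r.t. every control-point displacement.
// The perturbation of one control point only moves samples in its 4x4x4-cell
// support, so each gradient entry is a local histogram update, not a full
// re-evaluation.
// [[Rcpp::export(name = ".cpp_ffd_mi_grad")]]
List cpp_ffd_mi_grad(IntegerVector refbin, NumericMatrix X,
                     NumericMatrix bulkA, NumericVector bulkT,
                     NumericVector grid, IntegerVector gdim, NumericVector extent,
                     NumericVector flo, IntegerVector fdim, NumericVector fvs,
                     int nbins, double fmin, double fmax, double eps,
                     bool want_grad) {
  int gx = gdim[0], gy = gdim[1], gz = gdim[2];
  double hx = extent[0] / (gx - 3), hy = extent[1] / (gy - 3), hz = extent[2] / (gz - 3);
  int fnx = fdim[0], fny = fdim[1], fnz = fdim[2];
  const double *F = flo.begin();
  const double *G = grid.begin();
  R_xlen_t gsz = (R_xlen_t)gx * gy * gz;
  R_xlen_t n = X.nrow();
  double frange = fmax - fmin;
  if (frange <= 0) frange = 1;

  std::vector<double> cx(n), cy(n), cz(n);       // deformed world coords
  std::vector<float> Bxs(n * 4), Bys(n * 4), Bzs(n * 4);
  std::vector<int> i0s(n), j0s(n), k0s(n), fbin(n);
  std::vector<double> H((size_t)nbins * nbins, 0.0);

  double Bx[4], By[4], Bz[4];
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = X(p, 0), y = X(p, 1), z = X(p, 2);
    double sx = x / hx, sy = y / hy, sz = z / hz;
    int i0 = (int)std::floor(sx) - 1, j0 = (int)std::floor(sy) - 1, k0 = (int)std::floor(sz) - 1;
    bsp(sx - std::floor(sx), Bx); bsp(sy - std::floor(sy), By); bsp(sz - std::floor(sz), Bz);
    i0s[p] = i0; j0s[p] = j0; k0s[p] = k0;
    for (int a = 0; a < 4; ++a) {
      Bxs[p * 4 + a] = (float)Bx[a]; Bys[p * 4 + a] = (float)By[a]; Bzs[p * 4 + a] = (float)Bz[a];
    }
    double d0 = 0, d1 = 0, d2 = 0;
    for (int c = 0; c < 4; ++c) {
      int k = clampi(k0 + c, gz);
      for (int b = 0; b < 4; ++b) {
        int j = clampi(j0 + b, gy);
        double wbc = By[b] * Bz[c];
        for (int a = 0; a < 4; ++a) {
          int i = clampi(i0 + a, gx);
          double w = Bx[a] * wbc;
          R_xlen_t q = i + (R_xlen_t)gx * (j + (R_xlen_t)gy * k);
          d0 += w * G[q]; d1 += w * G[q + gsz]; d2 += w * G[q + 2 * gsz];
        }
      }
    }
    double wx = bulkA(0, 0) * x + bulkA(0, 1) * y + bulkA(0, 2) * z + bulkT[0] + d0;
    double wy = bulkA(1, 0) * x + bulkA(1, 1) * y + bulkA(1, 2) * z + bulkT[1] + d1;
    double wz = bulkA(2, 0) * x + bulkA(2, 1) * y + bulkA(2, 2) * z + bulkT[2] + d2;
    cx[p] = wx; cy[p] = wy; cz[p] = wz;
    double v = tri_clamped(F, fnx, fny, fnz, wx / fvs[0] - 0.5, wy / fvs[1] - 0.5, wz / fvs[2] - 0.5);
    int b = (int)((v - fmin) / frange * nbins);
    b = b < 0 ? 0 : (b >= nbins ? nbins - 1 : b);
    fbin[p] = b;
    H[(size_t)refbin[p] + (size_t)nbins * b] += 1.0;
  }
  double mi0 = mi_bits(H, nbins, (double)n);
  if (!want_grad)
    return List::create(_["mi"] = mi0, _["grad"] = R_NilValue);

  // bucket samples by lattice cell (i0+1, j0+1, k0+1)
  int ncx = gx - 2, ncy = gy - 2, ncz = gz - 2;
  size_t ncell = (size_t)ncx * ncy * ncz;
  std::vector<int> cnt(ncell + 1, 0);
  for (R_xlen_t p = 0; p < n; ++p) {
    int ci = clampi(i0s[p] + 1, ncx), cj = clampi(j0s[p] + 1, ncy), ck = clampi(k0s[p] + 1, ncz);
    cnt[(size_t)ci + (size_t)ncx * (cj + (size_t)ncy * ck) + 1]++;
  }
  for (size_t c = 1; c <= ncell; ++c) cnt[c] += cnt[c - 1];
  std::vector<int> order(n);
  { std::vector<int> pos(cnt.begin(), cnt.end() - 1);
    for (R_xlen_t p = 0; p < n; ++p) {
      int ci = clampi(i0s[p] + 1, ncx), cj = clampi(j0s[p] + 1, ncy), ck = clampi(k0s[p] + 1, ncz);
      order[pos[(size_t)ci + (size_t)ncx * (cj + (size_t)ncy * ck)]++] = p;
    } }

  NumericVector grad(gsz * 3);
  std::vector<double> Hp((size_t)nbins * nbins);
  std::vector<int> touched; touched.reserve(4096);

  for (int ck = 0; ck < gz; ++ck)
    for (int cj = 0; cj < gy; ++cj)
      for (int ci = 0; ci < gx; ++ci) {
        // support cells: i0 in [ci-3, ci] -> bucket index i0+1 in [ci-2, ci+1]
        for (int axis = 0; axis < 3; ++axis) {
          std::copy(H.begin(), H.end(), Hp.begin());
          bool any = false;
          for (int bk = ck - 2; bk <= ck + 1; ++bk) {
            if (bk < 0 || bk >= ncz) continue;
            for (int bj = cj - 2; bj <= cj + 1; ++bj) {
              if (bj < 0 || bj >= ncy) continue;
              for (int bi = ci - 2; bi <= ci + 1; ++bi) {
                if (bi < 0 || bi >= ncx) continue;
                size_t cell = (size_t)bi + (size_t)ncx * (bj + (size_t)ncy * bk);
                for (int s = cnt[cell]; s < cnt[cell + 1]; ++s) {
                  int p = order[s];
                  double wxs = 0, wys = 0, wzs = 0;
                  for (int a = 0; a < 4; ++a) {
                    if (clampi(i0s[p] + a, gx) == ci) wxs += Bxs[p * 4 + a];
                    if (clampi(j0s[p] + a, gy) == cj) wys += Bys[p * 4 + a];
                    if (clampi(k0s[p] + a, gz) == ck) wzs += Bzs[p * 4 + a];
                  }
                  double w = wxs * wys * wzs;
                  if (w < 1e-10) continue;
                  double nx_ = cx[p], ny_ = cy[p], nz_ = cz[p];
                  if (axis == 0) nx_ += eps * w;
                  else if (axis == 1) ny_ += eps * w;
                  else nz_ += eps * w;
                  double v = tri_clamped(F, fnx, fny, fnz,
                                         nx_ / fvs[0] - 0.5, ny_ / fvs[1] - 0.5, nz_ / fvs[2] - 0.5);
                  int b = (int)((v - fmin) / frange * nbins);
                  b = b < 0 ? 0 : (b >= nbins ? nbins - 1 : b);
                  if (b != fbin[p]) {
                    Hp[(size_t)refbin[p] + (size_t)nbins * fbin[p]] -= 1.0;
                    Hp[(size_t)refbin[p] + (size_t)nbins * b] += 1.0;
                    any = true;
                  }
                }
              }
            }
          }
          double g = 0.0;
          if (any) g = (mi_bits(Hp, nbins, (double)n) - mi0) / eps;
          grad[(R_xlen_t)ci + (R_xlen_t)gx * (cj + (R_xlen_t)gy * ck) + axis * gsz] = g;
        }
      }
  grad.attr("dim") = IntegerVector::create(gx, gy, gz, 3);
  return List::create(_["mi"] = mi0, _["grad"] = grad);
}
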