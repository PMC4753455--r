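#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exhaustive integer-displacement block search maximising the Pearson
// correlation coefficient, with parabolic sub-pixel refinement along each
// axis.  Returns one correspondence row per block with sufficient variance:
// (centre..., displacement..., cc).

static inline double block_cc(const double *a, const double *b, int n,
                              double amean, double avar) {
  double bsum = 0, bsq = 0, ab = 0;
  for (int i = 0; i < n; ++i) { bsum += b[i]; bsq += b[i] * b[i]; ab += a[i] * b[i]; }
  double bmean = bsum / n;
  double bvar = bsq / n - bmean * bmean;
  if (bvar <= 1e-12 || avar <= 1e-12) return -2.0;
  double cov = ab / n - amean * bmean;
  return cov / std::sqrt(avar * bvar);
}

static inline double subpix(double cm, double c0, double cp) {
  // vertex of the parabola through (-1,cm) (0,c0) (1,cp); clamped to [-1,1]
  double denom = cm - 2 * c0 + cp;
  if (std::fabs(denom) < 1e-12) return 0.0;
  double d = 0.5 * (cm - cp) / denom;
  if (d > 1) d = 1; if (d < -1) d = -1;
  return d;
}

// [[Rcpp::export(name = ".cpp_block_match_2d")]]
NumericMatrix cpp_block_match_2d(NumericMatrix ref, NumericMatrix flo,
                                 int half, int step, int search, double min_var) {
  int nx = ref.nrow(), ny = ref.ncol();
  int fnx = flo.nrow(), fny = flo.ncol();
  int bs = 2 * half + 1, n = bs * bs;
  std::vector<double> ablk(n), bblk(n);
  std::vector<double> rows;
  for (int cy = half; cy + half < ny; cy += step) {
    for (int cx = half; cx + half < nx; cx += step) {
      int idx = 0;
      double asum = 0, asq = 0;
      for (int j = cy - half; j <= cy + half; ++j)
        for (int i = cx - half; i <= cx + half; ++i) {
          double v = ref(i, j);
          ablk[idx++] = v; asum += v; asq += v * v;
        }
      double amean = asum / n, avar = asq / n - amean * amean;
      if (avar < min_var) continue;
      double best = -2.0; int bdx = 0, bdy = 0;
      // cc on the (2s+1)^2 lattice kept for sub-pixel refinement
      int w = 2 * search + 1;
      std::vector<double> ccmap((size_t)w * w, -2.0);
      for (int dy = -search; dy <= search; ++dy) {
        int fy0 = cy + dy - half, fy1 = cy + dy + half;
        if (fy0 < 0 || fy1 >= fny) continue;
        for (int dx = -search; dx <= search; ++dx) {
          int fx0 = cx + dx - half, fx1 = cx + dx + half;
          if (fx0 < 0 || fx1 >= fnx) continue;
          int k = 0;
          for (int j = fy0; j <= fy1; ++j)
            for (int i = fx0; i <= fx1; ++i) bblk[k++] = flo(i, j);
          double cc = block_cc(ablk.data(), bblk.data(), n, amean, avar);
          ccmap[(size_t)(dx + search) + (size_t)w * (dy + search)] = cc;
          if (cc > best) { best = cc; bdx = dx; bdy = dy; }
        }
      }
      if (best < -1.5) continue;
      double sx = 0, sy = 0;
      if (bdx > -search && bdx < search) {
        double cm = ccmap[(size_t)(bdx - 1 + search) + (size_t)w * (bdy + search)];
        double cp = ccmap[(size_t)(bdx + 1 + search) + (size_t)w * (bdy + search)];
        if (cm > -1.5 && cp > -1.5) sx = subpix(cm, best, cp);
      }
      if (bdy > -search && bdy < search) {
        double cm = ccmap[(size_t)(bdx + search) + (size_t)w * (bdy - 1 + search)];
        double cp = ccmap[(size_t)(bdx + search) + (size_t)w * (bdy + 1 + search)];
        if (cm > -1.5 && cp > -1.5) sy = subpix(cm, best, cp);
      }
      rows.push_back(cx); rows.push_back(cy);
      rows.push_back(bdx + sx); rows.push_back(bdy + sy);
      rows.push_back(best);
    }
  }
  int nr = rows.size() / 5;
  NumericMatrix out(nr, 5);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < 5; ++c) out(r, c) = rows[(size_t)r * 5 + c];
  colnames(out) = CharacterVector::create("cx", "cy", "dx", "dy", "cc");
  return out;
}

// [[Rcpp::export(name = ".cpp_block_match_3d")]]
NumericMatrix cpp_block_match_3d(NumericVector ref, IntegerVector rdim,
                                 NumericVector flo, IntegerVector fdim,
                                 int half, int step, int search, double min_var) {
  int nx = rdim[0], ny = rdim[1], nz = rdim[2];
  int fx_ = fdim[0], fy_ = fdim[1], fz_ = fdim[2];
  const double *R = ref.begin(), *F = flo.begin();
  int bs = 2 * half + 1, n = bs * bs * bs;
  std::vector<double> ablk(n), bblk(n);
  std::vector<double> rows;
  int w = 2 * search + 1;
  std::vector<double> ccmap;
  for (int cz = half; cz + half < nz; cz += step)
    for (int cy = half; cy + half < ny; cy += step)
      for (int cx = half; cx + half < nx; cx += step) {
        int idx = 0; double asum = 0, asq = 0;
        for (int k = cz - half; k <= cz + half; ++k)
          for (int j = cy - half; j <= cy + half; ++j)
            for (int i = cx - half; i <= cx + half; ++i) {
              double v = R[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
              ablk[idx++] = v; asum += v; asq += v * v;
            }
        double amean = asum / n, avar = asq / n - amean * amean;
        if (avar < min_var) continue;
        double best = -2.0; int bdx = 0, bdy = 0, bdz = 0;
        ccmap.assign((size_t)w * w * w, -2.0);
        for (int dz = -search; dz <= search; ++dz) {
          if (cz + dz - half < 0 || cz + dz + half >= fz_) continue;
          for (int dy = -search; dy <= search; ++dy) {
            if (cy + dy - half < 0 || cy + dy + half >= fy_) continue;
            for (int dx = -search; dx <= search; ++dx) {
              if (cx + dx - half < 0 || cx + dx + half >= fx_) continue;
              int t = 0;
              for (int k = cz + dz - half; k <= cz + dz + half; ++k)
                for (int j = cy + dy - half; j <= cy + dy + half; ++j)
                  for (int i = cx + dx - half; i <= cx + dx + half; ++i)
                    bblk[t++] = F[i + (R_xlen_t)fx_ * (j + (R_xlen_t)fy_ * k)];
              double cc = block_cc(ablk.data(), bblk.data(), n, amean, avar);
              size_t ci = (size_t)(dx + search) +
                (size_t)w * ((size_t)(dy + search) + (size_t)w * (dz + search));
              ccmap[ci] = cc;
              if (cc > best) { best = cc; bdx = dx; bdy = dy; bdz = dz; }
            }
          }
        }
        if (best < -1.5) continue;
        double s3[3] = {0, 0, 0};
        int bd[3] = {bdx, bdy, bdz};
        for (int a = 0; a < 3; ++a) {
          if (bd[a] <= -search || bd[a] >= search) continue;
          int dm[3] = {bdx, bdy, bdz}, dp[3] = {bdx, bdy, bdz};
          dm[a] -= 1; dp[a] += 1;
          size_t im = (size_t)(dm[0] + search) +
            (size_t)w * ((size_t)(dm[1] + search) + (size_t)w * (dm[2] + search));
          size_t ip = (size_t)(dp[0] + search) +
            (size_t)w * ((size_t)(dp[1] + search) + (size_t)w * (dp[2] + search));
          if (ccmap[im] > -1.5 && ccmap[ip] > -1.5)
            s3[a] = subpix(ccmap[im], best, ccmap[ip]);
        }
        rows.push_back(cx); rows.push_back(cy); rows.push_back(cz);
        rows.push_back(bdx + s3[0]); rows.push_back(bdy + s3[1]);
        rows.push_back(bdz + s3[2]); rows.push_back(best);
      }
  int nr = rows.size() / 7;
  NumericMatrix out(nr, 7);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < 7; ++c) out(r, c) = rows[(size_t)r * 7 + c];
  colnames(out) = CharacterVector::create("cx", "cy", "cz", "dx", "dy", "dz", "cc");
  return out;
}
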