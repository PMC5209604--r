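#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voxel (i,j,k) (0-based) sits at origin + voxel * (i,j,k); arrays are in
// R/Fortran order with x fastest, matching both R arrays and the MRC layout.

static inline R_xlen_t lin_index(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
}

// Accumulate weighted Gaussian kernels onto a voxel grid.
// pos: N x 3 centers (Angstrom); w: N weights; sigma: N kernel sd (Angstrom);
// cutoff_mult: kernels truncated at cutoff_mult * sigma (<= 0: no truncation).
// [[Rcpp::export]]
NumericVector grid_accumulate(const NumericMatrix& pos,
                              const NumericVector& w,
                              const NumericVector& sigma,
                              const IntegerVector& dims,
                              double voxel,
                              const NumericVector& origin,
                              double cutoff_mult) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = pos.nrow();
  NumericVector out((R_xlen_t)nx * ny * nz);

  for (int a = 0; a < n; ++a) {
    const double cx = pos(a, 0), cy = pos(a, 1), cz = pos(a, 2);
    const double s2 = sigma[a] * sigma[a];
    const double wa = w[a];
    int i0 = 0, i1 = nx - 1, j0 = 0, j1 = ny - 1, k0 = 0, k1 = nz - 1;
    double r2max = R_PosInf;
    if (cutoff_mult > 0) {
      const double rad = cutoff_mult * sigma[a];
      r2max = rad * rad * (1.0 + 1e-12);  // keep the boundary shell inside
      i0 = std::max(0, (int)std::ceil((cx - rad - origin[0]) / voxel));
      i1 = std::min(nx - 1, (int)std::floor((cx + rad - origin[0]) / voxel));
      j0 = std::max(0, (int)std::ceil((cy - rad - origin[1]) / voxel));
      j1 = std::min(ny - 1, (int)std::floor((cy + rad - origin[1]) / voxel));
      k0 = std::max(0, (int)std::ceil((cz - rad - origin[2]) / voxel));
      k1 = std::min(nz - 1, (int)std::floor((cz + rad - origin[2]) / voxel));
    }
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + voxel * k - cz;
      const double dz2 = dz * dz;
      if (dz2 > r2max) continue;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + voxel * j - cy;
        const double dyz2 = dz2 + dy * dy;
        if (dyz2 > r2max) continue;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + voxel * i - cx;
          const double d2 = dyz2 + dx * dx;
          if (d2 > r2max) continue;
          out[lin_index(i, j, k, nx, ny)] += wa * std::exp(-d2 / (2.0 * s2));
        }
      }
    }
  }
  return out;
}

// Gradient of J = sum_j resid_j^2, resid = f - fhat (zero outside the mask),
// with respect to pseudoatom centers and weights:
//   dJ/dw_a  = -2 sum_j resid_j K_aj
//   dJ/dr_a  = -2 (w_a / sigma^2) sum_j resid_j K_aj (r_j - r_a)
// Truncation must match the renderer's so J and its gradient are consistent.
// [[Rcpp::export]]
List grid_gradient(const NumericMatrix& pos,
                   const NumericVector& w,
                   double sigma,
                   const IntegerVector& dims,
                   double voxel,
                   const NumericVector& origin,
                   const NumericVector& resid,
                   double cutoff_mult) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = pos.nrow();
  const double s2 = sigma * sigma;
  NumericMatrix gpos(n, 3);
  NumericVector gw(n);

  for (int a = 0; a < n; ++a) {
    const double cx = pos(a, 0), cy = pos(a, 1), cz = pos(a, 2);
    int i0 = 0, i1 = nx - 1, j0 = 0, j1 = ny - 1, k0 = 0, k1 = nz - 1;
    double r2max = R_PosInf;
    if (cutoff_mult > 0) {
      const double rad = cutoff_mult * sigma;
      r2max = rad * rad * (1.0 + 1e-12);
      i0 = std::max(0, (int)std::ceil((cx - rad - origin[0]) / voxel));
      i1 = std::min(nx - 1, (int)std::floor((cx + rad - origin[0]) / voxel));
      j0 = std::max(0, (int)std::ceil((cy - rad - origin[1]) / voxel));
      j1 = std::min(ny - 1, (int)std::floor((cy + rad - origin[1]) / voxel));
      k0 = std::max(0, (int)std::ceil((cz - rad - origin[2]) / voxel));
      k1 = std::min(nz - 1, (int)std::floor((cz + rad - origin[2]) / voxel));
    }
    double sw = 0.0, sx = 0.0, sy = 0.0, sz = 0.0;
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + voxel * k - cz;
      const double dz2 = dz * dz;
      if (dz2 > r2max) continue;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + voxel * j - cy;
        const double dyz2 = dz2 + dy * dy;
        if (dyz2 > r2max) continue;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + voxel * i - cx;
          const double d2 = dyz2 + dx * dx;
          if (d2 > r2max) continue;
          const double r = resid[lin_index(i, j, k, nx, ny)];
          if (r == 0.0) continue;
          const double kv = std::exp(-d2 / (2.0 * s2));
          const double rk = r * kv;
          sw += rk;
          sx += rk * dx;
          sy += rk * dy;
          sz += rk * dz;
        }
      }
    }
    gw[a] = -2.0 * sw;
    const double c = -2.0 * w[a] / s2;
    gpos(a, 0) = c * sx;
    gpos(a, 1) = c * sy;
    gpos(a, 2) = c * sz;
  }
  return List::create(Named("positions") = gpos, Named("weights") = gw);
}

// Greedy selection of candidate points (rows of cand, already sorted by
// priority) that keep a minimum separation from `existing` points and from
// every candidate accepted before them. Returns 1-based indices into cand.
// [[Rcpp::export]]
IntegerVector greedy_min_sep(const NumericMatrix& cand,
                             const NumericMatrix& existing,
                             double min_sep,
                             int max_accept) {
  const double d2min = min_sep * min_sep;
  std::vector<int> keep;
  std::vector<double> ax, ay, az;
  for (int e = 0; e < existing.nrow(); ++e) {
    ax.push_back(existing(e, 0));
    ay.push_back(existing(e, 1));
    az.push_back(existing(e, 2));
  }
  const size_t n_fixed = ax.size();
  for (int c = 0; c < cand.nrow(); ++c) {
    if ((int)keep.size() >= max_accept) break;
    const double x = cand(c, 0), y = cand(c, 1), z = cand(c, 2);
    bool ok = true;
    for (size_t a = 0; a < ax.size(); ++a) {
      const double dx = x - ax[a], dy = y - ay[a], dz = z - az[a];
      if (dx * dx + dy * dy + dz * dz < d2min) { ok = false; break; }
    }
    if (ok) {
      keep.push_back(c + 1);
      ax.push_back(x); ay.push_back(y); az.push_back(z);
    }
  }
  (void)n_fixed;
  return wrap(keep);
}
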