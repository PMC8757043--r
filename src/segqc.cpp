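#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Directed Hausdorff distance between two foreground point sets given as
// n x 3 matrices of voxel indices (any consistent origin), scaled per-axis
// by spacing (mm). Early-exit inner scan: once a candidate point's running
// minimum falls at or below the current maximum it cannot raise the
// supremum, so the inner loop breaks. Exact (no approximation).
static double directed_hd_sq(const NumericMatrix& A, const NumericMatrix& B,
                             const NumericVector& sp) {
  const int na = A.nrow(), nb = B.nrow();
  const double sx = sp[0], sy = sp[1], sz = sp[2];
  double cmax = 0.0;
  for (int i = 0; i < na; ++i) {
    double cmin = R_PosInf;
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < nb; ++j) {
      const double dx = (ax - B(j, 0)) * sx;
      const double dy = (ay - B(j, 1)) * sy;
      const double dz = (az - B(j, 2)) * sz;
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < cmin) {
        cmin = d;
        if (cmin <= cmax) break;
      }
    }
    if (cmin > cmax) cmax = cmin;
  }
  return cmax;
}

// [[Rcpp::export]]
double cpp_hausdorff_max(NumericMatrix a, NumericMatrix b, NumericVector spacing) {
  const double d1 = directed_hd_sq(a, b, spacing);
  const double d2 = directed_hd_sq(b, a, spacing);
  return std::sqrt(d1 > d2 ? d1 : d2);
}

// All nearest-neighbour distances from points of `a` to the set `b`
// (mm, spacing-scaled); used for percentile Hausdorff variants.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix a, NumericMatrix b, NumericVector spacing) {
  const int na = a.nrow(), nb = b.nrow();
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double cmin = R_PosInf;
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      const double dx = (ax - b(j, 0)) * sx;
      const double dy = (ay - b(j, 1)) * sy;
      const double dz = (az - b(j, 2)) * sz;
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < cmin) cmin = d;
    }
    out[i] = std::sqrt(cmin);
  }
  return out;
}

// 6-connected component labelling of a 3D binary volume (column-major,
// dims = c(nx, ny, nz)). Returns integer labels 0 (background), 1..K.
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      const R_xlen_t v = q.front(); q.pop();
      const int x = (int)(v % nx);
      const int y = (int)((v / nx) % ny);
      const int z = (int)(v / ((R_xlen_t)nx * ny));
      const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int k = 0; k < 6; ++k) {
        const int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        const R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] != 0 && lab[w] == 0) { lab[w] = next; q.push(w); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

static std::vector<std::array<int,3>> ball_offsets(double radius) {
  std::vector<std::array<int,3>> off;
  const int r = (int)std::floor(radius);
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if ((double)(dx*dx + dy*dy + dz*dz) <= radius * radius)
          off.push_back({dx, dy, dz});
  return off;
}

// Binary dilation by a Euclidean ball of `radius` voxels.
// [[Rcpp::export]]
IntegerVector cpp_dilate3d(IntegerVector mask, IntegerVector dims, double radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n, 0);
  const std::vector<std::array<int,3>> off = ball_offsets(radius);
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0) continue;
    const int x = (int)(s % nx);
    const int y = (int)((s / nx) % ny);
    const int z = (int)(s / ((R_xlen_t)nx * ny));
    for (size_t k = 0; k < off.size(); ++k) {
      const int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      out[(R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] = 1;
    }
  }
  return out;
}

// Binary erosion by a Euclidean ball; out-of-bounds counts as background,
// so structures touching the volume boundary erode from that side too.
// [[Rcpp::export]]
IntegerVector cpp_erode3d(IntegerVector mask, IntegerVector dims, double radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n, 0);
  const std::vector<std::array<int,3>> off = ball_offsets(radius);
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0) continue;
    const int x = (int)(s % nx);
    const int y = (int)((s / nx) % ny);
    const int z = (int)(s / ((R_xlen_t)nx * ny));
    bool keep = true;
    for (size_t k = 0; k < off.size() && keep; ++k) {
      const int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) { keep = false; break; }
      if (mask[(R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)] == 0) keep = false;
    }
    if (keep) out[s] = 1;
  }
  return out;
}
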