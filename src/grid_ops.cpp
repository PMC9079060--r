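// Geometric grid operations on scalar volumes stored as R arrays [X, Y, Z]
// (x fastest). Voxel centres sit at 0-based integer index coordinates.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sample_linear(const double* v, const int* d, double ux, double uy, double uz,
                                   double fill) {
  if (ux < -0.5 || uy < -0.5 || uz < -0.5 ||
      ux > d[0] - 0.5 || uy > d[1] - 0.5 || uz > d[2] - 0.5) return fill;
  int x0 = (int)std::floor(ux), y0 = (int)std::floor(uy), z0 = (int)std::floor(uz);
  double fx = ux - x0, fy = uy - y0, fz = uz - z0;
  int x1 = x0 + 1, y1 = y0 + 1, z1 = z0 + 1;
  // replicate the border half-voxel
  x0 = std::min(std::max(x0, 0), d[0] - 1); x1 = std::min(std::max(x1, 0), d[0] - 1);
  y0 = std::min(std::max(y0, 0), d[1] - 1); y1 = std::min(std::max(y1, 0), d[1] - 1);
  z0 = std::min(std::max(z0, 0), d[2] - 1); z1 = std::min(std::max(z1, 0), d[2] - 1);
  auto at = [&](int x, int y, int z) {
    return v[(size_t)x + (size_t)d[0] * (y + (size_t)d[1] * z)];
  };
  double c00 = at(x0, y0, z0) * (1 - fx) + at(x1, y0, z0) * fx;
  double c10 = at(x0, y1, z0) * (1 - fx) + at(x1, y1, z0) * fx;
  double c01 = at(x0, y0, z1) * (1 - fx) + at(x1, y0, z1) * fx;
  double c11 = at(x0, y1, z1) * (1 - fx) + at(x1, y1, z1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double sample_nearest(const double* v, const int* d, double ux, double uy, double uz,
                                    double fill) {
  int x = (int)std::lround(ux), y = (int)std::lround(uy), z = (int)std::lround(uz);
  if (x < 0 || y < 0 || z < 0 || x >= d[0] || y >= d[1] || z >= d[2]) return fill;
  return v[(size_t)x + (size_t)d[0] * (y + (size_t)d[1] * z)];
}

// Pull-back warp: output voxel o maps to input index coordinate
// u = A %*% o + t (+ disp[, o] if given); sampled linearly or nearest.
// [[Rcpp::export(name = ".cpp_warp_affine")]]
NumericVector cpp_warp_affine(const NumericVector& vol, const IntegerVector& in_dims,
                              const IntegerVector& out_dims, const arma::mat& A,
                              const arma::vec& t, const Nullable<NumericMatrix>& disp,
                              const std::string& method, double fill) {
  if (in_dims.size() != 3 || out_dims.size() != 3) stop("dims must have length 3");
  if (A.n_rows != 3 || A.n_cols != 3 || t.n_elem != 3) stop("affine must be 3x3 + 3");
  const int d[3] = {in_dims[0], in_dims[1], in_dims[2]};
  const size_t Nout = (size_t)out_dims[0] * out_dims[1] * out_dims[2];
  if ((size_t)vol.size() != (size_t)d[0] * d[1] * d[2]) stop("volume length does not match dims");
  const bool linear = (method == "linear");
  if (!linear && method != "nearest") stop("method must be 'linear' or 'nearest'");
  const double* dp = nullptr;
  if (disp.isNotNull()) {
    NumericMatrix dm(disp);
    if ((size_t)dm.ncol() != Nout || dm.nrow() != 3)
      stop("displacement field must be 3 x n_out_voxels");
    dp = REAL(dm);
  }
  NumericVector out(Nout);
  const double* v = REAL(vol);
  size_t j = 0;
  for (int z = 0; z < out_dims[2]; ++z)
    for (int y = 0; y < out_dims[1]; ++y)
      for (int x = 0; x < out_dims[0]; ++x, ++j) {
        double ux = A(0, 0) * x + A(0, 1) * y + A(0, 2) * z + t[0];
        double uy = A(1, 0) * x + A(1, 1) * y + A(1, 2) * z + t[1];
        double uz = A(2, 0) * x + A(2, 1) * y + A(2, 2) * z + t[2];
        if (dp) { ux += dp[3 * j]; uy += dp[3 * j + 1]; uz += dp[3 * j + 2]; }
        out[j] = linear ? sample_linear(v, d, ux, uy, uz, fill)
                        : sample_nearest(v, d, ux, uy, uz, fill);
      }
  out.attr("dim") = out_dims;
  return out;
}

// 26-connected component labelling of a {0,1} volume. Labels are assigned in
// raster-scan order (x fastest), so lower labels start at lexicographically
// smaller voxel indices.
// [[Rcpp::export(name = ".cpp_label_components")]]
List cpp_label_components(const IntegerVector& mask, const IntegerVector& dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const size_t N = (size_t)X * Y * Z;
  if ((size_t)mask.size() != N) stop("mask length does not match dims");
  IntegerVector labels(N, 0);
  std::vector<double> sizes;
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < N; ++s) {
    if (!mask[s] || labels[s]) continue;
    ++next;
    double sz = 0;
    stack.push_back(s);
    labels[s] = next;
    while (!stack.empty()) {
      size_t j = stack.back(); stack.pop_back();
      ++sz;
      const int x = (int)(j % X), y = (int)((j / X) % Y), z = (int)(j / ((size_t)X * Y));
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        const int nx = x + dx, ny = y + dy, nz = z + dz;
        if (nx < 0 || ny < 0 || nz < 0 || nx >= X || ny >= Y || nz >= Z) continue;
        const size_t nj = (size_t)nx + (size_t)X * (ny + (size_t)Y * nz);
        if (mask[nj] && !labels[nj]) { labels[nj] = next; stack.push_back(nj); }
      }
    }
    sizes.push_back(sz);
  }
  labels.attr("dim") = dims;
  return List::create(_["labels"] = labels, _["sizes"] = NumericVector(sizes.begin(), sizes.end()));
}

// Boundary voxels of a {0,1} mask: foreground voxels with at least one
// background 6-neighbour (out-of-grid counts as background).
// Returns an n x 3 matrix of 0-based voxel indices.
// [[Rcpp::export(name = ".cpp_boundary_voxels")]]
IntegerMatrix cpp_boundary_voxels(const IntegerVector& mask, const IntegerVector& dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  std::vector<int> ix, iy, iz;
  auto at = [&](int x, int y, int z) -> int {
    if (x < 0 || y < 0 || z < 0 || x >= X || y >= Y || z >= Z) return 0;
    return mask[(size_t)x + (size_t)X * (y + (size_t)Y * z)];
  };
  for (int z = 0; z < Z; ++z) for (int y = 0; y < Y; ++y) for (int x = 0; x < X; ++x) {
    if (!at(x, y, z)) continue;
    if (!at(x - 1, y, z) || !at(x + 1, y, z) || !at(x, y - 1, z) ||
        !at(x, y + 1, z) || !at(x, y, z - 1) || !at(x, y, z + 1)) {
      ix.push_back(x); iy.push_back(y); iz.push_back(z);
    }
  }
  IntegerMatrix out(ix.size(), 3);
  for (size_t i = 0; i < ix.size(); ++i) { out(i, 0) = ix[i]; out(i, 1) = iy[i]; out(i, 2) = iz[i]; }
  return out;
}

// For each point of A (n x 3, mm), the distance to the closest point of B.
// [[Rcpp::export(name = ".cpp_closest_point_dists")]]
NumericVector cpp_closest_point_dists(const NumericMatrix& A, const NumericMatrix& B) {
  const int nA = A.nrow(), nB = B.nrow();
  if (nA == 0 || nB == 0) stop("point sets must be non-empty");
  NumericVector out(nA);
  for (int i = 0; i < nA; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < nB; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
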