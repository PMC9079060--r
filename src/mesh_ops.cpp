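// Isosurface extraction and mesh utilities.
//
// The extractor marches tetrahedra: each cell of the voxel-centre lattice is
// split into 6 tetrahedra sharing the (0,0,0)-(1,1,1) diagonal, so shared cube
// faces are triangulated identically in neighbouring cells and the surface is
// watertight away from the grid boundary. Surface vertices lie on lattice
// edges and are welded through an edge-keyed map; triangle winding is fixed so
// normals point from inside (value >= level) to outside.
#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 6-tet decomposition of the unit cube, corners bit-coded (x | y<<1 | z<<2).
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};

struct EdgeKey {
  size_t a, b;
  bool operator==(const EdgeKey& o) const { return a == o.a && b == o.b; }
};
struct EdgeHash {
  size_t operator()(const EdgeKey& k) const {
    return std::hash<size_t>()(k.a * 1000003u ^ k.b);
  }
};

// [[Rcpp::export(name = ".cpp_march_tets")]]
List cpp_march_tets(const NumericVector& vol, const IntegerVector& dims, double level) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  if ((size_t)vol.size() != (size_t)X * Y * Z) stop("volume length does not match dims");
  const double* v = REAL(vol);
  auto lin = [&](int x, int y, int z) { return (size_t)x + (size_t)X * (y + (size_t)Y * z); };

  std::vector<double> vx, vy, vz;        // welded vertex coords (index space)
  std::vector<int> f0, f1, f2;           // 0-based face indices
  std::unordered_map<EdgeKey, int, EdgeHash> edge_vertex;

  auto vertex_on_edge = [&](size_t n1, size_t n2) -> int {
    EdgeKey k{std::min(n1, n2), std::max(n1, n2)};
    auto it = edge_vertex.find(k);
    if (it != edge_vertex.end()) return it->second;
    const size_t a = k.a, b = k.b;
    const double va = v[a], vb = v[b];
    double t = (vb == va) ? 0.5 : (level - va) / (vb - va);
    if (t < 0) t = 0; if (t > 1) t = 1;
    const double ax = (double)(a % X), ay = (double)((a / X) % Y), az = (double)(a / ((size_t)X * Y));
    const double bx = (double)(b % X), by = (double)((b / X) % Y), bz = (double)(b / ((size_t)X * Y));
    vx.push_back(ax + t * (bx - ax));
    vy.push_back(ay + t * (by - ay));
    vz.push_back(az + t * (bz - az));
    const int id = (int)vx.size() - 1;
    edge_vertex.emplace(k, id);
    return id;
  };

  // emit a triangle, flipping winding so the normal points away from `ref`
  auto emit = [&](int a, int b, int c, const double ref[3]) {
    const double e1[3] = {vx[b] - vx[a], vy[b] - vy[a], vz[b] - vz[a]};
    const double e2[3] = {vx[c] - vx[a], vy[c] - vy[a], vz[c] - vz[a]};
    const double n[3] = {e1[1] * e2[2] - e1[2] * e2[1],
                         e1[2] * e2[0] - e1[0] * e2[2],
                         e1[0] * e2[1] - e1[1] * e2[0]};
    const double cx = (vx[a] + vx[b] + vx[c]) / 3.0 - ref[0];
    const double cy = (vy[a] + vy[b] + vy[c]) / 3.0 - ref[1];
    const double cz = (vz[a] + vz[b] + vz[c]) / 3.0 - ref[2];
    if (n[0] * cx + n[1] * cy + n[2] * cz < 0) std::swap(b, c);
    f0.push_back(a); f1.push_back(b); f2.push_back(c);
  };

  for (int z = 0; z + 1 < Z; ++z) for (int y = 0; y + 1 < Y; ++y) for (int x = 0; x + 1 < X; ++x) {
    size_t corner[8];
    for (int c = 0; c < 8; ++c)
      corner[c] = lin(x + (c & 1), y + ((c >> 1) & 1), z + ((c >> 2) & 1));
    // skip uniform cells quickly
    bool any_in = false, any_out = false;
    for (int c = 0; c < 8; ++c) (v[corner[c]] >= level ? any_in : any_out) = true;
    if (!any_in || !any_out) continue;
    for (int tnum = 0; tnum < 6; ++tnum) {
      size_t n[4];
      bool in[4];
      int n_in = 0;
      for (int c = 0; c < 4; ++c) {
        n[c] = corner[TETS[tnum][c]];
        in[c] = v[n[c]] >= level;
        n_in += in[c];
      }
      if (n_in == 0 || n_in == 4) continue;
      // centroid of inside nodes = reference point behind the surface
      double ref[3] = {0, 0, 0};
      for (int c = 0; c < 4; ++c) if (in[c]) {
        ref[0] += (double)(n[c] % X);
        ref[1] += (double)((n[c] / X) % Y);
        ref[2] += (double)(n[c] / ((size_t)X * Y));
      }
      ref[0] /= n_in; ref[1] /= n_in; ref[2] /= n_in;
      int ins[4], outs[4], ni = 0, no = 0;
      for (int c = 0; c < 4; ++c) (in[c] ? ins[ni++] : outs[no++]) = c;
      if (n_in == 1) {
        const int a = vertex_on_edge(n[ins[0]], n[outs[0]]);
        const int b = vertex_on_edge(n[ins[0]], n[outs[1]]);
        const int c = vertex_on_edge(n[ins[0]], n[outs[2]]);
        emit(a, b, c, ref);
      } else if (n_in == 3) {
        const int a = vertex_on_edge(n[outs[0]], n[ins[0]]);
        const int b = vertex_on_edge(n[outs[0]], n[ins[1]]);
        const int c = vertex_on_edge(n[outs[0]], n[ins[2]]);
        emit(a, b, c, ref);
      } else { // 2 in, 2 out -> quad as two triangles
        const int a = vertex_on_edge(n[ins[0]], n[outs[0]]);
        const int b = vertex_on_edge(n[ins[0]], n[outs[1]]);
        const int c = vertex_on_edge(n[ins[1]], n[outs[1]]);
        const int d = vertex_on_edge(n[ins[1]], n[outs[0]]);
        emit(a, b, c, ref);
        emit(a, c, d, ref);
      }
    }
  }

  NumericMatrix verts(vx.size(), 3);
  for (size_t i = 0; i < vx.size(); ++i) { verts(i, 0) = vx[i]; verts(i, 1) = vy[i]; verts(i, 2) = vz[i]; }
  IntegerMatrix faces(f0.size(), 3);
  for (size_t i = 0; i < f0.size(); ++i) { faces(i, 0) = f0[i]; faces(i, 1) = f1[i]; faces(i, 2) = f2[i]; }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}

// Taubin lambda/mu smoothing with uniform (umbrella) Laplacian weights.
// Alternating positive/negative steps shrink far less than plain Laplacian
// smoothing, approximately preserving enclosed volume.
// [[Rcpp::export(name = ".cpp_smooth_taubin")]]
NumericMatrix cpp_smooth_taubin(const NumericMatrix& verts, const IntegerMatrix& faces,
                                int iterations, double lambda, double mu) {
  const int nv = verts.nrow(), nf = faces.nrow();
  std::vector<std::vector<int>> nbr(nv);
  auto add_edge = [&](int a, int b) {
    if (std::find(nbr[a].begin(), nbr[a].end(), b) == nbr[a].end()) nbr[a].push_back(b);
  };
  for (int i = 0; i < nf; ++i) {
    const int a = faces(i, 0), b = faces(i, 1), c = faces(i, 2);
    add_edge(a, b); add_edge(b, a); add_edge(b, c); add_edge(c, b); add_edge(a, c); add_edge(c, a);
  }
  arma::mat p(nv, 3);
  for (int i = 0; i < nv; ++i) for (int k = 0; k < 3; ++k) p(i, k) = verts(i, k);
  arma::mat q(nv, 3);
  for (int it = 0; it < 2 * iterations; ++it) {
    const double f = (it % 2 == 0) ? lambda : mu;
    for (int i = 0; i < nv; ++i) {
      if (nbr[i].empty()) { q.row(i) = p.row(i); continue; }
      arma::rowvec m(3, arma::fill::zeros);
      for (int j : nbr[i]) m += p.row(j);
      m /= (double)nbr[i].size();
      q.row(i) = p.row(i) + f * (m - p.row(i));
    }
    p = q;
  }
  NumericMatrix out(nv, 3);
  for (int i = 0; i < nv; ++i) for (int k = 0; k < 3; ++k) out(i, k) = p(i, k);
  return out;
}

// Closest point on triangle (Ericson, Real-Time Collision Detection).
static double point_tri_dist2(const double p[3], const double a[3], const double b[3],
                              const double c[3]) {
  auto sub = [](const double u[3], const double w[3], double r[3]) {
    r[0] = u[0] - w[0]; r[1] = u[1] - w[1]; r[2] = u[2] - w[2];
  };
  auto dot = [](const double u[3], const double w[3]) {
    return u[0] * w[0] + u[1] * w[1] + u[2] * w[2];
  };
  double ab[3], ac[3], ap[3];
  sub(b, a, ab); sub(c, a, ac); sub(p, a, ap);
  const double d1 = dot(ab, ap), d2 = dot(ac, ap);
  double q[3];
  if (d1 <= 0 && d2 <= 0) { q[0] = a[0]; q[1] = a[1]; q[2] = a[2]; }
  else {
    double bp[3]; sub(p, b, bp);
    const double d3 = dot(ab, bp), d4 = dot(ac, bp);
    if (d3 >= 0 && d4 <= d3) { q[0] = b[0]; q[1] = b[1]; q[2] = b[2]; }
    else {
      const double vc = d1 * d4 - d3 * d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        const double t = d1 / (d1 - d3);
        for (int k = 0; k < 3; ++k) q[k] = a[k] + t * ab[k];
      } else {
        double cp[3]; sub(p, c, cp);
        const double d5 = dot(ab, cp), d6 = dot(ac, cp);
        if (d6 >= 0 && d5 <= d6) { q[0] = c[0]; q[1] = c[1]; q[2] = c[2]; }
        else {
          const double vb = d5 * d2 - d1 * d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) {
            const double t = d2 / (d2 - d6);
            for (int k = 0; k < 3; ++k) q[k] = a[k] + t * ac[k];
          } else {
            const double va = d3 * d6 - d5 * d4;
            if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
              const double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int k = 0; k < 3; ++k) q[k] = b[k] + t * (c[k] - b[k]);
            } else {
              const double denom = 1.0 / (va + vb + vc);
              const double vv = vb * denom, ww = vc * denom;
              for (int k = 0; k < 3; ++k) q[k] = a[k] + ab[k] * vv + ac[k] * ww;
            }
          }
        }
      }
    }
  }
  double d[3]; sub(p, q, d);
  return dot(d, d);
}

// For each point, the distance to the closest point on the triangle surface.
// [[Rcpp::export(name = ".cpp_point_mesh_dists")]]
NumericVector cpp_point_mesh_dists(const NumericMatrix& pts, const NumericMatrix& verts,
                                   const IntegerMatrix& faces) {
  const int np = pts.nrow(), nf = faces.nrow();
  if (nf == 0) stop("mesh has no faces");
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    const double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < nf; ++j) {
      const int ia = faces(j, 0), ib = faces(j, 1), ic = faces(j, 2);
      const double a[3] = {verts(ia, 0), verts(ia, 1), verts(ia, 2)};
      const double b[3] = {verts(ib, 0), verts(ib, 1), verts(ib, 2)};
      const double c[3] = {verts(ic, 0), verts(ic, 1), verts(ic, 2)};
      const double d2 = point_tri_dist2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
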