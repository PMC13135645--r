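#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Distance from point p to capsule sweep of a polyline with per-point radii:
// min over segments of (distance to segment - lerped radius).
static inline double seg_capsule_dist(const double* p,
                                      const double* a, const double* b,
                                      double ra, double rb) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double denom = ab[0] * ab[0] + ab[1] * ab[1] + ab[2] * ab[2];
  double t = denom > 0 ? (ap[0] * ab[0] + ap[1] * ab[1] + ap[2] * ab[2]) / denom : 0.0;
  if (t < 0) t = 0; else if (t > 1) t = 1;
  double dx = ap[0] - t * ab[0], dy = ap[1] - t * ab[1], dz = ap[2] - t * ab[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz) - (ra + t * (rb - ra));
}

// [[Rcpp::export]]
NumericVector cpp_capsule_dist(NumericMatrix pts, NumericMatrix poly,
                               NumericVector radii) {
  const int n = pts.nrow(), m = poly.nrow();
  NumericVector out(n);
  std::vector<double> P(3 * m);
  for (int j = 0; j < m; ++j) {
    P[3 * j] = poly(j, 0); P[3 * j + 1] = poly(j, 1); P[3 * j + 2] = poly(j, 2);
  }
  for (int i = 0; i < n; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double best = R_PosInf;
    for (int j = 0; j + 1 < m; ++j) {
      double d = seg_capsule_dist(p, &P[3 * j], &P[3 * (j + 1)],
                                  radii[j], radii[j + 1]);
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// Signed distance of the union of capsule sweeps, evaluated on a regular
// grid (dims nodes per axis, spacing h, node 0 at origin). Values far from
// every sweep are left at +big (outside); each segment only updates nodes in
// its padded bounding box, which is exact within a band around the surface.
// [[Rcpp::export]]
NumericVector cpp_union_sdf_grid(List polylines, List radii,
                                 NumericVector origin, double h,
                                 IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double big = 1e6;
  NumericVector vals((R_xlen_t)nx * ny * nz, big);
  for (int s = 0; s < polylines.size(); ++s) {
    NumericMatrix poly = polylines[s];
    NumericVector rad = radii[s];
    const int m = poly.nrow();
    for (int j = 0; j + 1 < m; ++j) {
      double a[3] = {poly(j, 0), poly(j, 1), poly(j, 2)};
      double b[3] = {poly(j + 1, 0), poly(j + 1, 1), poly(j + 1, 2)};
      double rmax = std::max(rad[j], rad[j + 1]);
      double pad = rmax + 3.5 * h;
      int i0[3], i1[3];
      for (int d = 0; d < 3; ++d) {
        double lo = std::min(a[d], b[d]) - pad, hi = std::max(a[d], b[d]) + pad;
        i0[d] = std::max(0, (int)std::floor((lo - origin[d]) / h));
        i1[d] = std::min(dims[d] - 1, (int)std::ceil((hi - origin[d]) / h));
      }
      for (int k = i0[2]; k <= i1[2]; ++k) {
        double z = origin[2] + k * h;
        for (int jy = i0[1]; jy <= i1[1]; ++jy) {
          double y = origin[1] + jy * h;
          R_xlen_t base = ((R_xlen_t)k * ny + jy) * nx;
          for (int ix = i0[0]; ix <= i1[0]; ++ix) {
            double p[3] = {origin[0] + ix * h, y, z};
            double d = seg_capsule_dist(p, a, b, rad[j], rad[j + 1]);
            if (d < vals[base + ix]) vals[base + ix] = d;
          }
        }
      }
    }
  }
  return vals;
}

struct EdgeKey {
  uint64_t k;
  bool operator==(const EdgeKey& o) const { return k == o.k; }
};
struct EdgeHash {
  size_t operator()(const EdgeKey& e) const { return std::hash<uint64_t>()(e.k); }
};

// Marching tetrahedra on the Kuhn (6-tet, translation-consistent)
// subdivision of each grid cube. Zero isosurface of vals; negative = inside.
// Emits a shared-vertex triangle mesh; triangles are wound so normals point
// from negative (inside) to positive (outside).
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector vals, IntegerVector dims,
                       NumericVector origin, double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto gidx = [&](int i, int j, int k) -> uint64_t {
    return ((uint64_t)k * ny + j) * nx + i;
  };
  // Kuhn tets: vertex orders by coordinate permutation
  static const int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  std::unordered_map<EdgeKey, int, EdgeHash> edge_vertex;
  std::vector<double> verts;
  std::vector<int> tris;

  auto val_at = [&](uint64_t g) {
    double v = vals[g];
    if (std::fabs(v) < 1e-9) v = 1e-9;
    return v;
  };
  auto edge_point = [&](uint64_t ga, uint64_t gb) -> int {
    EdgeKey key{ga < gb ? (ga << 32 | gb) : (gb << 32 | ga)};
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double fa = val_at(ga), fb = val_at(gb);
    double t = fa / (fa - fb);
    int ia = (int)(ga % nx), ja = (int)((ga / nx) % ny), ka = (int)(ga / ((uint64_t)nx * ny));
    int ib = (int)(gb % nx), jb = (int)((gb / nx) % ny), kb = (int)(gb / ((uint64_t)nx * ny));
    double p[3] = {origin[0] + (ia + t * (ib - ia)) * h,
                   origin[1] + (ja + t * (jb - ja)) * h,
                   origin[2] + (ka + t * (kb - ka)) * h};
    int id = (int)(verts.size() / 3);
    verts.push_back(p[0]); verts.push_back(p[1]); verts.push_back(p[2]);
    edge_vertex.emplace(key, id);
    return id;
  };
  auto emit = [&](int v0, int v1, int v2, const double* ref) {
    // orient so normal . ref > 0 (ref points from inside to outside)
    double* A = &verts[3 * v0];
    double* B = &verts[3 * v1];
    double* C = &verts[3 * v2];
    double u[3] = {B[0]-A[0], B[1]-A[1], B[2]-A[2]};
    double w[3] = {C[0]-A[0], C[1]-A[1], C[2]-A[2]};
    double nvec[3] = {u[1]*w[2]-u[2]*w[1], u[2]*w[0]-u[0]*w[2], u[0]*w[1]-u[1]*w[0]};
    double dot = nvec[0]*ref[0] + nvec[1]*ref[1] + nvec[2]*ref[2];
    if (dot >= 0) { tris.push_back(v0); tris.push_back(v1); tris.push_back(v2); }
    else          { tris.push_back(v0); tris.push_back(v2); tris.push_back(v1); }
  };

  uint64_t tv[4];
  double tf[4];
  double tp[4][3];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        // quick reject: all 8 same sign
        double v000 = vals[gidx(i,j,k)];
        bool any_neg = false, any_pos = false;
        for (int c = 0; c < 8; ++c) {
          double v = vals[gidx(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1))];
          if (v < 0) any_neg = true; else any_pos = true;
        }
        (void)v000;
        if (!any_neg || !any_pos) continue;
        for (int t = 0; t < 6; ++t) {
          int ci = i, cj = j, ck = k;
          tv[0] = gidx(ci, cj, ck);
          int pos_xyz[3] = {0, 0, 0};
          for (int step = 0; step < 3; ++step) {
            pos_xyz[perms[t][step]] = 1;
            tv[step + 1] = gidx(i + pos_xyz[0], j + pos_xyz[1], k + pos_xyz[2]);
          }
          int neg[4], np = 0, pos[4], pp = 0;
          for (int c = 0; c < 4; ++c) {
            tf[c] = val_at(tv[c]);
            uint64_t g = tv[c];
            tp[c][0] = origin[0] + (double)(g % nx) * h;
            tp[c][1] = origin[1] + (double)((g / nx) % ny) * h;
            tp[c][2] = origin[2] + (double)(g / ((uint64_t)nx * ny)) * h;
            if (tf[c] < 0) neg[np++] = c; else pos[pp++] = c;
          }
          if (np == 0 || np == 4) continue;
          // reference direction: centroid(pos) - centroid(neg)
          double ref[3] = {0, 0, 0};
          for (int c = 0; c < pp; ++c)
            for (int d = 0; d < 3; ++d) ref[d] += tp[pos[c]][d] / pp;
          for (int c = 0; c < np; ++c)
            for (int d = 0; d < 3; ++d) ref[d] -= tp[neg[c]][d] / np;
          if (np == 1 || np == 3) {
            int apex = (np == 1) ? neg[0] : pos[0];
            int others[3], no = 0;
            for (int c = 0; c < 4; ++c) if (c != apex) others[no++] = c;
            int e0 = edge_point(tv[apex], tv[others[0]]);
            int e1 = edge_point(tv[apex], tv[others[1]]);
            int e2 = edge_point(tv[apex], tv[others[2]]);
            emit(e0, e1, e2, ref);
          } else {
            int a = neg[0], b = neg[1], c = pos[0], d = pos[1];
            int eac = edge_point(tv[a], tv[c]);
            int ead = edge_point(tv[a], tv[d]);
            int ebd = edge_point(tv[b], tv[d]);
            int ebc = edge_point(tv[b], tv[c]);
            emit(eac, ead, ebd, ref);
            emit(eac, ebd, ebc, ref);
          }
        }
      }

  int nv = (int)(verts.size() / 3), nf = (int)(tris.size() / 3);
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v)
    for (int d = 0; d < 3; ++d) V(v, d) = verts[3 * v + d];
  IntegerMatrix F(nf, 3);
  for (int f = 0; f < nf; ++f)
    for (int d = 0; d < 3; ++d) F(f, d) = tris[3 * f + d] + 1;
  return List::create(_["vertices"] = V, _["faces"] = F);
}
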