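#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Marching tetrahedra on a scalar field sampled at grid points.
// Each grid cell (cube) is split into six tetrahedra around the main
// diagonal; the iso-surface is interpolated on tetrahedron edges with
// vertices cached per grid edge, so the output is watertight and manifold
// by construction. Triangles are oriented with outward normals (pointing
// from field > iso towards field <= iso).
//
// field: length nx*ny*nz (column-major, x fastest), values at grid points.
// Returns vertices in grid-index coordinates (0-based, double) and 1-based
// triangle indices.

namespace {

struct Key {
  uint64_t v;
  bool operator==(const Key &o) const { return v == o.v; }
};
struct KeyHash {
  size_t operator()(const Key &k) const { return std::hash<uint64_t>()(k.v); }
};

} // namespace

// [[Rcpp::export(name = ".march_tets")]]
List march_tets(NumericVector field, IntegerVector dims, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t npts = (R_xlen_t)nx * ny * nz;
  if (field.size() != npts) stop("field length does not match dims");

  // cube corner offsets (classic ordering)
  static const int corner[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                                   {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  // six tetrahedra sharing the 0-6 diagonal
  static const int tets[6][4] = {{0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
                                 {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};

  std::unordered_map<Key, int, KeyHash> edge_cache;
  std::vector<double> verts; // x,y,z triples
  std::vector<int> faces;    // 0-based triples

  auto gidx = [&](int i, int j, int k) -> R_xlen_t {
    return (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
  };

  // vertex on grid edge (a,b): cached by sorted global endpoint ids
  auto edge_vertex = [&](R_xlen_t ga, R_xlen_t gb, const double *pa,
                         const double *pb, double va, double vb) -> int {
    R_xlen_t lo = ga < gb ? ga : gb, hi = ga < gb ? gb : ga;
    Key key{(uint64_t)lo * (uint64_t)npts + (uint64_t)hi};
    auto it = edge_cache.find(key);
    if (it != edge_cache.end()) return it->second;
    double t = (iso - va) / (vb - va);
    double p[3];
    for (int d = 0; d < 3; ++d) p[d] = pa[d] + t * (pb[d] - pa[d]);
    int id = (int)(verts.size() / 3);
    verts.insert(verts.end(), p, p + 3);
    edge_cache.emplace(key, id);
    return id;
  };

  // orient triangle (q0,q1,q2) so its normal points from `in_pt` (inside)
  // towards outside; swap if needed
  auto push_tri = [&](int a, int b, int c, const double *in_pt) {
    const double *p0 = &verts[3 * (size_t)a];
    const double *p1 = &verts[3 * (size_t)b];
    const double *p2 = &verts[3 * (size_t)c];
    double u[3], v[3], n[3], cen[3];
    for (int d = 0; d < 3; ++d) {
      u[d] = p1[d] - p0[d];
      v[d] = p2[d] - p0[d];
      cen[d] = (p0[d] + p1[d] + p2[d]) / 3.0;
    }
    n[0] = u[1] * v[2] - u[2] * v[1];
    n[1] = u[2] * v[0] - u[0] * v[2];
    n[2] = u[0] * v[1] - u[1] * v[0];
    double dot = 0;
    for (int d = 0; d < 3; ++d) dot += n[d] * (cen[d] - in_pt[d]);
    if (dot >= 0) {
      faces.push_back(a); faces.push_back(b); faces.push_back(c);
    } else {
      faces.push_back(a); faces.push_back(c); faces.push_back(b);
    }
  };

  double P[4][3], V[4];
  R_xlen_t G[4];

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        // gather cube values; skip empty/full cubes fast
        double cv[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          cv[c] = field[gidx(i + corner[c][0], j + corner[c][1], k + corner[c][2])];
          (cv[c] > iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int code = 0;
          for (int c = 0; c < 4; ++c) {
            int cc = tets[t][c];
            P[c][0] = i + corner[cc][0];
            P[c][1] = j + corner[cc][1];
            P[c][2] = k + corner[cc][2];
            G[c] = gidx((int)P[c][0], (int)P[c][1], (int)P[c][2]);
            V[c] = cv[cc];
            if (V[c] > iso) code |= (1 << c);
          }
          if (code == 0 || code == 15) continue;
          // inside/outside vertex lists
          int ins[4], outs[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c)
            (V[c] > iso) ? (ins[ni++] = c) : (outs[no++] = c);
          if (ni == 1 || ni == 3) {
            int apex = (ni == 1) ? ins[0] : outs[0];
            int oth[3], m = 0;
            for (int c = 0; c < 4; ++c)
              if (c != apex) oth[m++] = c;
            int e0 = edge_vertex(G[apex], G[oth[0]], P[apex], P[oth[0]], V[apex], V[oth[0]]);
            int e1 = edge_vertex(G[apex], G[oth[1]], P[apex], P[oth[1]], V[apex], V[oth[1]]);
            int e2 = edge_vertex(G[apex], G[oth[2]], P[apex], P[oth[2]], V[apex], V[oth[2]]);
            // inside reference point: centroid of inside vertices
            double ref[3];
            if (ni == 1) {
              for (int d = 0; d < 3; ++d) ref[d] = P[apex][d];
            } else {
              for (int d = 0; d < 3; ++d)
                ref[d] = (P[ins[0]][d] + P[ins[1]][d] + P[ins[2]][d]) / 3.0;
            }
            push_tri(e0, e1, e2, ref);
          } else { // 2-2 case: quad e(a,c) e(a,d) e(b,d) e(b,c)
            int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
            int q0 = edge_vertex(G[a], G[c], P[a], P[c], V[a], V[c]);
            int q1 = edge_vertex(G[a], G[d], P[a], P[d], V[a], V[d]);
            int q2 = edge_vertex(G[b], G[d], P[b], P[d], V[b], V[d]);
            int q3 = edge_vertex(G[b], G[c], P[b], P[c], V[b], V[c]);
            double ref[3];
            for (int dd = 0; dd < 3; ++dd) ref[dd] = (P[a][dd] + P[b][dd]) / 2.0;
            push_tri(q0, q1, q2, ref);
            push_tri(q0, q2, q3, ref);
          }
        }
      }

  size_t nv = verts.size() / 3, nf = faces.size() / 3;
  NumericMatrix Vout(nv, 3);
  for (size_t r = 0; r < nv; ++r)
    for (int d = 0; d < 3; ++d) Vout(r, d) = verts[3 * r + d];
  IntegerMatrix Fout(nf, 3);
  for (size_t r = 0; r < nf; ++r)
    for (int d = 0; d < 3; ++d) Fout(r, d) = faces[3 * r + d] + 1;
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}
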