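#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------- winding ---

// Generalized winding number of each query point w.r.t. a closed triangle
// mesh: sum of signed solid angles / 4*pi. ~0 outside, ~1 inside (robust to
// points near but not on the surface). Two-level evaluation: faces are
// grouped into spatial patches; far patches contribute their dipole
// (area-vector) approximation, near patches are summed exactly.
// [[Rcpp::export(name = ".winding_number")]]
NumericVector winding_number(NumericMatrix pts, NumericMatrix verts, IntegerMatrix faces) {
  const int np = pts.nrow(), nf = faces.nrow(), nv = verts.nrow();
  NumericVector out(np);
  std::vector<double> vx(nv), vy(nv), vz(nv);
  for (int i = 0; i < nv; ++i) {
    vx[i] = verts(i, 0); vy[i] = verts(i, 1); vz[i] = verts(i, 2);
  }
  std::vector<int> fa(nf), fb(nf), fc(nf);
  std::vector<double> fcx(nf), fcy(nf), fcz(nf);
  for (int f = 0; f < nf; ++f) {
    fa[f] = faces(f, 0) - 1; fb[f] = faces(f, 1) - 1; fc[f] = faces(f, 2) - 1;
    fcx[f] = (vx[fa[f]] + vx[fb[f]] + vx[fc[f]]) / 3.0;
    fcy[f] = (vy[fa[f]] + vy[fb[f]] + vy[fc[f]]) / 3.0;
    fcz[f] = (vz[fa[f]] + vz[fb[f]] + vz[fc[f]]) / 3.0;
  }

  // spatial patching on a uniform grid (target ~64 faces per patch)
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < nv; ++i) {
    lo[0] = std::min(lo[0], vx[i]); hi[0] = std::max(hi[0], vx[i]);
    lo[1] = std::min(lo[1], vy[i]); hi[1] = std::max(hi[1], vy[i]);
    lo[2] = std::min(lo[2], vz[i]); hi[2] = std::max(hi[2], vz[i]);
  }
  double ext = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-9});
  int nside = std::max(1, (int)std::floor(std::cbrt(nf / 12.0)));
  nside = std::min(nside, 64);
  double cell = ext / nside + 1e-12;
  int ng[3];
  for (int d = 0; d < 3; ++d)
    ng[d] = std::max(1, std::min(nside, (int)((hi[d] - lo[d]) / cell) + 1));
  auto patch_of = [&](double x, double y, double z) {
    int cx = std::min(ng[0] - 1, std::max(0, (int)((x - lo[0]) / cell)));
    int cy = std::min(ng[1] - 1, std::max(0, (int)((y - lo[1]) / cell)));
    int cz = std::min(ng[2] - 1, std::max(0, (int)((z - lo[2]) / cell)));
    return (cz * ng[1] + cy) * ng[0] + cx;
  };
  int npatch = ng[0] * ng[1] * ng[2];
  std::vector<std::vector<int>> members(npatch);
  for (int f = 0; f < nf; ++f) members[patch_of(fcx[f], fcy[f], fcz[f])].push_back(f);

  struct Patch { double cx, cy, cz, r2, anx, any, anz; };
  std::vector<Patch> patches;
  std::vector<const std::vector<int> *> patch_faces;
  for (int p = 0; p < npatch; ++p) {
    if (members[p].empty()) continue;
    Patch pa = {0, 0, 0, 0, 0, 0, 0};
    for (int f : members[p]) { pa.cx += fcx[f]; pa.cy += fcy[f]; pa.cz += fcz[f]; }
    double m = (double)members[p].size();
    pa.cx /= m; pa.cy /= m; pa.cz /= m;
    double r2 = 0;
    for (int f : members[p]) {
      // patch radius covers all face vertices
      int ids[3] = {fa[f], fb[f], fc[f]};
      for (int c = 0; c < 3; ++c) {
        double dx = vx[ids[c]] - pa.cx, dy = vy[ids[c]] - pa.cy,
               dz = vz[ids[c]] - pa.cz;
        r2 = std::max(r2, dx * dx + dy * dy + dz * dz);
      }
      // area vector 0.5 * (b-a) x (c-a)
      double ux = vx[fb[f]] - vx[fa[f]], uy = vy[fb[f]] - vy[fa[f]],
             uz = vz[fb[f]] - vz[fa[f]];
      double wx = vx[fc[f]] - vx[fa[f]], wy = vy[fc[f]] - vy[fa[f]],
             wz = vz[fc[f]] - vz[fa[f]];
      pa.anx += 0.5 * (uy * wz - uz * wy);
      pa.any += 0.5 * (uz * wx - ux * wz);
      pa.anz += 0.5 * (ux * wy - uy * wx);
    }
    pa.r2 = r2;
    patches.push_back(pa);
    patch_faces.push_back(&members[p]);
  }

  const double beta2 = 6.25; // (2.5 patch radii)^2 switches far/near field
  for (int p = 0; p < np; ++p) {
    const double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    double acc = 0.0;
    for (size_t q = 0; q < patches.size(); ++q) {
      const Patch &pa = patches[q];
      double dx = pa.cx - px, dy = pa.cy - py, dz = pa.cz - pz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > beta2 * pa.r2) {
        double d3 = d2 * std::sqrt(d2);
        acc += (pa.anx * dx + pa.any * dy + pa.anz * dz) / d3;
        continue;
      }
      for (int f : *patch_faces[q]) {
        double ax = vx[fa[f]] - px, ay = vy[fa[f]] - py, az = vz[fa[f]] - pz;
        double bx = vx[fb[f]] - px, by = vy[fb[f]] - py, bz = vz[fb[f]] - pz;
        double cx = vx[fc[f]] - px, cy = vy[fc[f]] - py, cz = vz[fc[f]] - pz;
        double la = std::sqrt(ax * ax + ay * ay + az * az);
        double lb = std::sqrt(bx * bx + by * by + bz * bz);
        double lc = std::sqrt(cx * cx + cy * cy + cz * cz);
        double det = ax * (by * cz - bz * cy) - ay * (bx * cz - bz * cx) +
                     az * (bx * cy - by * cx);
        double ab = ax * bx + ay * by + az * bz;
        double bc = bx * cx + by * cy + bz * cz;
        double ca = cx * ax + cy * ay + cz * az;
        double denom = la * lb * lc + ab * lc + bc * la + ca * lb;
        acc += 2.0 * std::atan2(det, denom);
      }
    }
    out[p] = acc / (4.0 * M_PI);
  }
  return out;
}

// ---------------------------------------------------------------- kd-tree ---

namespace {

struct KDTree {
  const double *pts; // n x 3 column-major
  int n;
  std::vector<int> idx;
  std::vector<int> left, right, axis;
  std::vector<int> pt_of_node;

  double coord(int i, int ax) const { return pts[(size_t)ax * n + i]; }

  int build(int lo, int hi, int depth) {
    if (lo >= hi) return -1;
    int ax = depth % 3;
    int mid = (lo + hi) / 2;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return coord(a, ax) < coord(b, ax); });
    int node = (int)pt_of_node.size();
    pt_of_node.push_back(idx[mid]);
    axis.push_back(ax);
    left.push_back(-1);
    right.push_back(-1);
    int l = build(lo, mid, depth + 1);
    int r = build(mid + 1, hi, depth + 1);
    left[node] = l;
    right[node] = r;
    return node;
  }

  void nearest(int node, const double q[3], int &best, double &bestd2) const {
    if (node < 0) return;
    int p = pt_of_node[node];
    double dx = coord(p, 0) - q[0], dy = coord(p, 1) - q[1], dz = coord(p, 2) - q[2];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < bestd2 || (d2 == bestd2 && p < best)) { bestd2 = d2; best = p; }
    int ax = axis[node];
    double diff = q[ax] - coord(p, ax);
    int near = diff < 0 ? left[node] : right[node];
    int far = diff < 0 ? right[node] : left[node];
    nearest(near, q, best, bestd2);
    if (diff * diff <= bestd2) nearest(far, q, best, bestd2);
  }
};

} // namespace

// For each query point, the index (1-based) of the nearest reference point
// and the distance. Ties broken toward the lowest index.
// [[Rcpp::export(name = ".nn_nearest")]]
List nn_nearest(NumericMatrix query, NumericMatrix ref) {
  KDTree tree;
  tree.pts = REAL(ref);
  tree.n = ref.nrow();
  tree.idx.resize(tree.n);
  for (int i = 0; i < tree.n; ++i) tree.idx[i] = i;
  int root = tree.build(0, tree.n, 0);
  const int m = query.nrow();
  IntegerVector nn(m);
  NumericVector dist(m);
  for (int i = 0; i < m; ++i) {
    double q[3] = {query(i, 0), query(i, 1), query(i, 2)};
    int best = -1;
    double bestd2 = R_PosInf;
    tree.nearest(root, q, best, bestd2);
    nn[i] = best + 1;
    dist[i] = std::sqrt(bestd2);
  }
  return List::create(_["index"] = nn, _["distance"] = dist);
}

// ---------------------------------------------- triangle-triangle overlap ---

namespace {

// Moller 1997 interval-based triangle-triangle intersection test.
inline void cross3(const double a[3], const double b[3], double r[3]) {
  r[0] = a[1] * b[2] - a[2] * b[1];
  r[1] = a[2] * b[0] - a[0] * b[2];
  r[2] = a[0] * b[1] - a[1] * b[0];
}
inline double dot3(const double a[3], const double b[3]) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
inline void sub3(const double a[3], const double b[3], double r[3]) {
  r[0] = a[0] - b[0]; r[1] = a[1] - b[1]; r[2] = a[2] - b[2];
}

bool point_in_tri_2d(double px, double py, double ax, double ay, double bx,
                     double by, double cx, double cy) {
  double d1 = (px - bx) * (ay - by) - (ax - bx) * (py - by);
  double d2 = (px - cx) * (by - cy) - (bx - cx) * (py - cy);
  double d3 = (px - ax) * (cy - ay) - (cx - ax) * (py - ay);
  bool neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
  bool pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
  return !(neg && pos);
}

bool seg_seg_2d(double p0x, double p0y, double p1x, double p1y, double q0x,
                double q0y, double q1x, double q1y) {
  double d1 = (q1x - q0x) * (p0y - q0y) - (q1y - q0y) * (p0x - q0x);
  double d2 = (q1x - q0x) * (p1y - q0y) - (q1y - q0y) * (p1x - q0x);
  double d3 = (p1x - p0x) * (q0y - p0y) - (p1y - p0y) * (q0x - p0x);
  double d4 = (p1x - p0x) * (q1y - p0y) - (p1y - p0y) * (q1x - p0x);
  return ((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0));
}

bool coplanar_tri_tri(const double n[3], const double *t1[3], const double *t2[3]) {
  // project to the dominant axis plane
  int i0, i1;
  double a[3] = {std::fabs(n[0]), std::fabs(n[1]), std::fabs(n[2])};
  if (a[0] > a[1] && a[0] > a[2]) { i0 = 1; i1 = 2; }
  else if (a[1] > a[2]) { i0 = 0; i1 = 2; }
  else { i0 = 0; i1 = 1; }
  for (int e = 0; e < 3; ++e) {
    int e2 = (e + 1) % 3;
    for (int f = 0; f < 3; ++f) {
      int f2 = (f + 1) % 3;
      if (seg_seg_2d(t1[e][i0], t1[e][i1], t1[e2][i0], t1[e2][i1],
                     t2[f][i0], t2[f][i1], t2[f2][i0], t2[f2][i1]))
        return true;
    }
  }
  // full containment
  if (point_in_tri_2d(t1[0][i0], t1[0][i1], t2[0][i0], t2[0][i1],
                      t2[1][i0], t2[1][i1], t2[2][i0], t2[2][i1]))
    return true;
  if (point_in_tri_2d(t2[0][i0], t2[0][i1], t1[0][i0], t1[0][i1],
                      t1[1][i0], t1[1][i1], t1[2][i0], t1[2][i1]))
    return true;
  return false;
}

bool tri_tri_overlap(const double *v0, const double *v1, const double *v2,
                     const double *u0, const double *u1, const double *u2,
                     double eps) {
  double e1[3], e2[3], n1[3];
  sub3(v1, v0, e1); sub3(v2, v0, e2); cross3(e1, e2, n1);
  double d1 = -dot3(n1, v0);
  double du0 = dot3(n1, u0) + d1, du1 = dot3(n1, u1) + d1, du2 = dot3(n1, u2) + d1;
  if (std::fabs(du0) < eps) du0 = 0;
  if (std::fabs(du1) < eps) du1 = 0;
  if (std::fabs(du2) < eps) du2 = 0;
  double du0du1 = du0 * du1, du0du2 = du0 * du2;
  if (du0du1 > 0 && du0du2 > 0) return false;

  double f1[3], f2[3], n2[3];
  sub3(u1, u0, f1); sub3(u2, u0, f2); cross3(f1, f2, n2);
  double d2 = -dot3(n2, u0);
  double dv0 = dot3(n2, v0) + d2, dv1 = dot3(n2, v1) + d2, dv2 = dot3(n2, v2) + d2;
  if (std::fabs(dv0) < eps) dv0 = 0;
  if (std::fabs(dv1) < eps) dv1 = 0;
  if (std::fabs(dv2) < eps) dv2 = 0;
  double dv0dv1 = dv0 * dv1, dv0dv2 = dv0 * dv2;
  if (dv0dv1 > 0 && dv0dv2 > 0) return false;

  double D[3];
  cross3(n1, n2, D);
  double maxc = std::fabs(D[0]);
  int index = 0;
  if (std::fabs(D[1]) > maxc) { maxc = std::fabs(D[1]); index = 1; }
  if (std::fabs(D[2]) > maxc) { maxc = std::fabs(D[2]); index = 2; }

  if (maxc < eps) { // coplanar
    const double *t1[3] = {v0, v1, v2};
    const double *t2[3] = {u0, u1, u2};
    return coplanar_tri_tri(n1, t1, t2);
  }

  auto interval = [&](const double *a, const double *b, const double *c,
                      double da, double db, double dc, double &t0,
                      double &t1v) -> bool {
    double pa = a[index], pb = b[index], pc = c[index];
    // arrange so that a,b on one side, c alone (or boundary)
    if (da * db > 0) { // c alone
      t0 = pa + (pc - pa) * da / (da - dc);
      t1v = pb + (pc - pb) * db / (db - dc);
    } else if (da * dc > 0) { // b alone
      t0 = pa + (pb - pa) * da / (da - db);
      t1v = pc + (pb - pc) * dc / (dc - db);
    } else if (db * dc > 0 || da != 0) { // a alone
      t0 = pb + (pa - pb) * db / (db - da);
      t1v = pc + (pa - pc) * dc / (dc - da);
    } else if (db != 0) {
      t0 = pa + (pb - pa) * da / (da - db);
      t1v = pc + (pb - pc) * dc / (dc - db);
    } else if (dc != 0) {
      t0 = pa + (pc - pa) * da / (da - dc);
      t1v = pb + (pc - pb) * db / (db - dc);
    } else {
      return false; // coplanar, handled elsewhere
    }
    if (t0 > t1v) std::swap(t0, t1v);
    return true;
  };

  double a0, a1, b0, b1;
  if (!interval(v0, v1, v2, dv0, dv1, dv2, a0, a1)) return false;
  if (!interval(u0, u1, u2, du0, du1, du2, b0, b1)) return false;
  return std::max(a0, b0) < std::min(a1, b1) - eps;
}

} // namespace

// All pairs of genuinely intersecting faces (excluding pairs sharing a
// vertex), found with a uniform-grid broad phase. Returns a 2-column matrix
// of 1-based face indices; limited to max_pairs rows.
// [[Rcpp::export(name = ".self_intersections")]]
IntegerMatrix self_intersections(NumericMatrix verts, IntegerMatrix faces,
                                 int max_pairs) {
  const int nf = faces.nrow();
  std::vector<double> lo(3, R_PosInf), hi(3, R_NegInf);
  for (int i = 0; i < verts.nrow(); ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], verts(i, d));
      hi[d] = std::max(hi[d], verts(i, d));
    }
  // cell size ~ mean face bbox extent
  double mean_ext = 0;
  std::vector<double> fmin(3 * nf), fmax(3 * nf);
  for (int f = 0; f < nf; ++f) {
    for (int d = 0; d < 3; ++d) {
      double a = verts(faces(f, 0) - 1, d), b = verts(faces(f, 1) - 1, d),
             c = verts(faces(f, 2) - 1, d);
      fmin[3 * f + d] = std::min(a, std::min(b, c));
      fmax[3 * f + d] = std::max(a, std::max(b, c));
      mean_ext += fmax[3 * f + d] - fmin[3 * f + d];
    }
  }
  mean_ext = std::max(mean_ext / (3.0 * nf), 1e-9);
  double cell = 2.0 * mean_ext;
  int ncell[3];
  for (int d = 0; d < 3; ++d)
    ncell[d] = std::max(1, std::min(128, (int)((hi[d] - lo[d]) / cell) + 1));

  auto cell_of = [&](double x, int d) {
    int c = (int)((x - lo[d]) / (hi[d] - lo[d] + 1e-12) * ncell[d]);
    return std::min(std::max(c, 0), ncell[d] - 1);
  };

  std::vector<std::vector<int>> buckets((size_t)ncell[0] * ncell[1] * ncell[2]);
  for (int f = 0; f < nf; ++f) {
    int c0[3], c1[3];
    for (int d = 0; d < 3; ++d) {
      c0[d] = cell_of(fmin[3 * f + d], d);
      c1[d] = cell_of(fmax[3 * f + d], d);
    }
    for (int z = c0[2]; z <= c1[2]; ++z)
      for (int y = c0[1]; y <= c1[1]; ++y)
        for (int x = c0[0]; x <= c1[0]; ++x)
          buckets[(size_t)z * ncell[0] * ncell[1] + (size_t)y * ncell[0] + x].push_back(f);
  }

  double scale = 0;
  for (int d = 0; d < 3; ++d) scale = std::max(scale, hi[d] - lo[d]);
  double eps = 1e-10 * std::max(scale, 1.0);

  std::vector<std::pair<int, int>> found;
  std::vector<char> seen((size_t)nf, 0);
  for (size_t b = 0; b < buckets.size() && (int)found.size() < max_pairs; ++b) {
    const std::vector<int> &fb = buckets[b];
    for (size_t i = 0; i < fb.size() && (int)found.size() < max_pairs; ++i) {
      for (size_t j = i + 1; j < fb.size(); ++j) {
        int f1 = fb[i], f2 = fb[j];
        // bbox overlap
        bool ov = true;
        for (int d = 0; d < 3; ++d)
          if (fmin[3 * f1 + d] > fmax[3 * f2 + d] ||
              fmin[3 * f2 + d] > fmax[3 * f1 + d]) {
            ov = false;
            break;
          }
        if (!ov) continue;
        // skip pairs sharing any vertex
        bool share = false;
        for (int a = 0; a < 3 && !share; ++a)
          for (int c = 0; c < 3; ++c)
            if (faces(f1, a) == faces(f2, c)) { share = true; break; }
        if (share) continue;
        double t1[3][3], t2[3][3];
        for (int c = 0; c < 3; ++c)
          for (int d = 0; d < 3; ++d) {
            t1[c][d] = verts(faces(f1, c) - 1, d);
            t2[c][d] = verts(faces(f2, c) - 1, d);
          }
        if (tri_tri_overlap(t1[0], t1[1], t1[2], t2[0], t2[1], t2[2], eps)) {
          int a = std::min(f1, f2), c = std::max(f1, f2);
          // de-duplicate pairs seen in multiple buckets
          bool dup = false;
          for (size_t q = 0; q < found.size(); ++q)
            if (found[q].first == a && found[q].second == c) { dup = true; break; }
          if (!dup) {
            found.push_back({a, c});
            if ((int)found.size() >= max_pairs) break;
          }
        }
      }
    }
  }
  (void)seen;
  IntegerMatrix out((int)found.size(), 2);
  for (size_t i = 0; i < found.size(); ++i) {
    out(i, 0) = found[i].first + 1;
    out(i, 1) = found[i].second + 1;
  }
  return out;
}
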