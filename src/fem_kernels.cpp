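#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Small-strain isotropic elasticity on 4-node (constant strain) and 10-node
// (quadratic, 4-point Gauss) tetrahedra. Straight-edged elements with exact
// edge midpoints are assumed, so the barycentric-to-physical map is affine
// and the corner geometry determines the gradients.

namespace {

const int EDGE[6][2] = {{0, 1}, {1, 2}, {2, 0}, {0, 3}, {1, 3}, {2, 3}};
// 4-point rule, barycentric (a,b,b,b) permutations, weight 1/4
const double QA = 0.585410196624968454;
const double QB = 0.138196601125010515;

struct ElemGeom {
  double gradL[4][3]; // gradients of barycentric coordinates
  double vol;
};

bool elem_geom(const double x[4][3], ElemGeom &g) {
  double M[3][3]; // columns x2-x1, x3-x1, x4-x1
  for (int d = 0; d < 3; ++d) {
    M[d][0] = x[1][d] - x[0][d];
    M[d][1] = x[2][d] - x[0][d];
    M[d][2] = x[3][d] - x[0][d];
  }
  double det = M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
               M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
               M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
  g.vol = det / 6.0;
  if (!(det > 0)) return false;
  double inv[3][3];
  inv[0][0] = (M[1][1] * M[2][2] - M[1][2] * M[2][1]) / det;
  inv[0][1] = (M[0][2] * M[2][1] - M[0][1] * M[2][2]) / det;
  inv[0][2] = (M[0][1] * M[1][2] - M[0][2] * M[1][1]) / det;
  inv[1][0] = (M[1][2] * M[2][0] - M[1][0] * M[2][2]) / det;
  inv[1][1] = (M[0][0] * M[2][2] - M[0][2] * M[2][0]) / det;
  inv[1][2] = (M[0][2] * M[1][0] - M[0][0] * M[1][2]) / det;
  inv[2][0] = (M[1][0] * M[2][1] - M[1][1] * M[2][0]) / det;
  inv[2][1] = (M[0][1] * M[2][0] - M[0][0] * M[2][1]) / det;
  inv[2][2] = (M[0][0] * M[1][1] - M[0][1] * M[1][0]) / det;
  // grad of L2,L3,L4 are the rows of inv; L1 = 1 - L2 - L3 - L4
  for (int d = 0; d < 3; ++d) {
    g.gradL[1][d] = inv[0][d];
    g.gradL[2][d] = inv[1][d];
    g.gradL[3][d] = inv[2][d];
    g.gradL[0][d] = -inv[0][d] - inv[1][d] - inv[2][d];
  }
  return true;
}

// shape-function spatial gradients for nn nodes at barycentric L
void shape_grads(const ElemGeom &g, const double L[4], int nn, double dN[10][3]) {
  for (int i = 0; i < 4; ++i)
    for (int d = 0; d < 3; ++d)
      dN[i][d] = (nn == 4) ? g.gradL[i][d] : (4.0 * L[i] - 1.0) * g.gradL[i][d];
  if (nn == 10) {
    for (int e = 0; e < 6; ++e) {
      int a = EDGE[e][0], b = EDGE[e][1];
      for (int d = 0; d < 3; ++d)
        dN[4 + e][d] = 4.0 * (L[a] * g.gradL[b][d] + L[b] * g.gradL[a][d]);
    }
  }
}

void dmatrix(double E, double nu, double D[6][6]) {
  double lam = E * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
  double mu = E / (2.0 * (1.0 + nu));
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) D[i][j] = 0.0;
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) D[i][j] = lam;
    D[i][i] = lam + 2.0 * mu;
    D[3 + i][3 + i] = mu;
  }
}

// strain order: (exx, eyy, ezz, gxy, gyz, gzx)
inline void fill_B(const double dN[10][3], int nn, std::vector<double> &B) {
  std::fill(B.begin(), B.end(), 0.0);
  int ncol = 3 * nn;
  for (int i = 0; i < nn; ++i) {
    double dx = dN[i][0], dy = dN[i][1], dz = dN[i][2];
    B[0 * ncol + 3 * i + 0] = dx;
    B[1 * ncol + 3 * i + 1] = dy;
    B[2 * ncol + 3 * i + 2] = dz;
    B[3 * ncol + 3 * i + 0] = dy;
    B[3 * ncol + 3 * i + 1] = dx;
    B[4 * ncol + 3 * i + 1] = dz;
    B[4 * ncol + 3 * i + 2] = dy;
    B[5 * ncol + 3 * i + 0] = dz;
    B[5 * ncol + 3 * i + 2] = dx;
  }
}

} // namespace

// Returns triplets (i, j, x) with 1-based dof indices (dof = 3*(node-1)+c)
// for Matrix::sparseMatrix. elems: 1-based, E x 4 or E x 10.
// [[Rcpp::export(name = ".assemble_tet_stiffness")]]
List assemble_tet_stiffness(NumericMatrix nodes, IntegerMatrix elems, double E,
                            double nu) {
  const int ne = elems.nrow(), nn = elems.ncol();
  if (nn != 4 && nn != 10) stop("elements must have 4 or 10 nodes");
  const int ndof = 3 * nn;
  double D[6][6];
  dmatrix(E, nu, D);

  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve((size_t)ne * ndof * ndof);
  tj.reserve((size_t)ne * ndof * ndof);
  tx.reserve((size_t)ne * ndof * ndof);

  std::vector<double> B(6 * ndof), DB(6 * ndof), ke(ndof * ndof);
  double dN[10][3], L[4];

  for (int e = 0; e < ne; ++e) {
    double x[4][3];
    for (int c = 0; c < 4; ++c)
      for (int d = 0; d < 3; ++d) x[c][d] = nodes(elems(e, c) - 1, d);
    ElemGeom g;
    if (!elem_geom(x, g))
      stop("element %d has non-positive volume (inverted element)", e + 1);
    std::fill(ke.begin(), ke.end(), 0.0);
    int nq = (nn == 4) ? 1 : 4;
    for (int q = 0; q < nq; ++q) {
      if (nn == 4) {
        L[0] = L[1] = L[2] = L[3] = 0.25;
      } else {
        for (int c = 0; c < 4; ++c) L[c] = QB;
        L[q] = QA;
      }
      double w = g.vol / nq;
      shape_grads(g, L, nn, dN);
      fill_B(dN, nn, B);
      for (int r = 0; r < 6; ++r)
        for (int c = 0; c < ndof; ++c) {
          double s = 0;
          for (int k = 0; k < 6; ++k) s += D[r][k] * B[k * ndof + c];
          DB[r * ndof + c] = s;
        }
      for (int r = 0; r < ndof; ++r)
        for (int c = 0; c < ndof; ++c) {
          double s = 0;
          for (int k = 0; k < 6; ++k) s += B[k * ndof + r] * DB[k * ndof + c];
          ke[r * ndof + c] += w * s;
        }
    }
    for (int r = 0; r < ndof; ++r) {
      int gi = 3 * (elems(e, r / 3) - 1) + (r % 3) + 1;
      for (int c = 0; c < ndof; ++c) {
        int gj = 3 * (elems(e, c / 3) - 1) + (c % 3) + 1;
        ti.push_back(gi);
        tj.push_back(gj);
        tx.push_back(ke[r * ndof + c]);
      }
    }
  }
  return List::create(_["i"] = IntegerVector(ti.begin(), ti.end()),
                      _["j"] = IntegerVector(tj.begin(), tj.end()),
                      _["x"] = NumericVector(tx.begin(), tx.end()));
}

// Per-element quadrature-averaged stress (sxx, syy, szz, sxy, syz, szx)
// from the nodal displacement vector u (length 3 * n_nodes).
// [[Rcpp::export(name = ".tet_element_stress")]]
NumericMatrix tet_element_stress(NumericMatrix nodes, IntegerMatrix elems,
                                 NumericVector u, double E, double nu) {
  const int ne = elems.nrow(), nn = elems.ncol();
  if (nn != 4 && nn != 10) stop("elements must have 4 or 10 nodes");
  double D[6][6];
  dmatrix(E, nu, D);
  NumericMatrix out(ne, 6);
  double dN[10][3], L[4];
  for (int e = 0; e < ne; ++e) {
    double x[4][3];
    for (int c = 0; c < 4; ++c)
      for (int d = 0; d < 3; ++d) x[c][d] = nodes(elems(e, c) - 1, d);
    ElemGeom g;
    if (!elem_geom(x, g))
      stop("element %d has non-positive volume (inverted element)", e + 1);
    double ue[30];
    for (int c = 0; c < nn; ++c)
      for (int d = 0; d < 3; ++d) ue[3 * c + d] = u[3 * (elems(e, c) - 1) + d];
    int nq = (nn == 4) ? 1 : 4;
    double sig[6] = {0, 0, 0, 0, 0, 0};
    for (int q = 0; q < nq; ++q) {
      if (nn == 4) {
        L[0] = L[1] = L[2] = L[3] = 0.25;
      } else {
        for (int c = 0; c < 4; ++c) L[c] = QB;
        L[q] = QA;
      }
      shape_grads(g, L, nn, dN);
      double eps[6] = {0, 0, 0, 0, 0, 0};
      for (int c = 0; c < nn; ++c) {
        double ux = ue[3 * c], uy = ue[3 * c + 1], uz = ue[3 * c + 2];
        eps[0] += dN[c][0] * ux;
        eps[1] += dN[c][1] * uy;
        eps[2] += dN[c][2] * uz;
        eps[3] += dN[c][1] * ux + dN[c][0] * uy;
        eps[4] += dN[c][2] * uy + dN[c][1] * uz;
        eps[5] += dN[c][2] * ux + dN[c][0] * uz;
      }
      for (int r = 0; r < 6; ++r) {
        double s = 0;
        for (int k = 0; k < 6; ++k) s += D[r][k] * eps[k];
        sig[r] += s / nq;
      }
    }
    for (int r = 0; r < 6; ++r) out(e, r) = sig[r];
  }
  return out;
}
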