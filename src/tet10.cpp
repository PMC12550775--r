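// TET10 isoparametric small-strain elasticity kernels.
// Quadratic tetrahedra in VTK node ordering: corners 0-3, midside nodes
// 4=(0,1), 5=(1,2), 6=(0,2), 7=(0,3), 8=(1,3), 9=(2,3).
// 4-point Gauss rule (degree 2, exact for the affine-geometry elements
// produced by the structured mesher).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double GA = 0.5854101966249685; // (5+3*sqrt(5))/20
static const double GB = 0.1381966011250105; // (5-sqrt(5))/20

// shape function derivatives wrt (xi, eta, zeta) at barycentric point
// L = (1-xi-eta-zeta, xi, eta, zeta)
static void dshape(double xi, double eta, double zeta, arma::mat &dN) {
  double L0 = 1.0 - xi - eta - zeta, L1 = xi, L2 = eta, L3 = zeta;
  // dL/d(xi,eta,zeta): L0 -> (-1,-1,-1), L1 -> (1,0,0), L2 -> (0,1,0),
  // L3 -> (0,0,1)
  double dL[4][3] = {{-1, -1, -1}, {1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  double L[4] = {L0, L1, L2, L3};
  // corners: Ni = Li (2 Li - 1)
  for (int i = 0; i < 4; ++i)
    for (int d = 0; d < 3; ++d)
      dN(i, d) = (4.0 * L[i] - 1.0) * dL[i][d];
  // edges: N = 4 Li Lj
  int ed[6][2] = {{0, 1}, {1, 2}, {0, 2}, {0, 3}, {1, 3}, {2, 3}};
  for (int e = 0; e < 6; ++e) {
    int i = ed[e][0], j = ed[e][1];
    for (int d = 0; d < 3; ++d)
      dN(4 + e, d) = 4.0 * (dL[i][d] * L[j] + L[i] * dL[j][d]);
  }
}

static void elasticity_D(double E, double nu, arma::mat &D) {
  double lam = E * nu / ((1.0 + nu) * (1.0 - 2.0 * nu));
  double mu = E / (2.0 * (1.0 + nu));
  D.zeros(6, 6);
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) D(i, j) = lam;
    D(i, i) = lam + 2.0 * mu;
    D(3 + i, 3 + i) = mu;
  }
}

// Assemble the global stiffness as symmetric upper-triangle triplets.
// nodes: n x 3, conn: ne x 10 (1-based), E, nu: per element.
// [[Rcpp::export]]
List tet10_stiffness_triplets(const arma::mat &nodes,
                              const arma::imat &conn,
                              const arma::vec &E, const arma::vec &nu) {
  const int ne = conn.n_rows;
  const double gp[4][3] = {{GB, GB, GB}, {GA, GB, GB},
                           {GB, GA, GB}, {GB, GB, GA}};
  const double wq = 1.0 / 24.0; // weight x reference volume factor

  // upper-triangle entries per 30x30 element matrix: 30*31/2 = 465
  const int per = 465;
  std::vector<int> iv; iv.reserve((size_t)ne * per);
  std::vector<int> jv; jv.reserve((size_t)ne * per);
  std::vector<double> xv; xv.reserve((size_t)ne * per);

  arma::mat X(10, 3), J(3, 3), Jinv(3, 3), dNdx(10, 3);
  arma::mat B(6, 30), D(6, 6), ke(30, 30), DB(6, 30);
  // reference shape derivatives are element-independent
  std::vector<arma::mat> dNq(4, arma::mat(10, 3));
  for (int q = 0; q < 4; ++q) dshape(gp[q][0], gp[q][1], gp[q][2], dNq[q]);

  for (int e = 0; e < ne; ++e) {
    if (E(e) <= 0.0)
      stop("zero or negative modulus on element %d", e + 1);
    for (int a = 0; a < 10; ++a) {
      int n = conn(e, a) - 1;
      X(a, 0) = nodes(n, 0); X(a, 1) = nodes(n, 1); X(a, 2) = nodes(n, 2);
    }
    elasticity_D(E(e), nu(e), D);
    ke.zeros();
    for (int q = 0; q < 4; ++q) {
      J = X.t() * dNq[q];           // 3x3, dx/dxi
      double detJ = arma::det(J);
      if (detJ <= 0.0)
        stop("non-positive Jacobian in element %d", e + 1);
      Jinv = arma::inv(J);
      dNdx = dNq[q] * Jinv;         // 10x3 spatial derivatives
      B.zeros();
      for (int a = 0; a < 10; ++a) {
        double bx = dNdx(a, 0), by = dNdx(a, 1), bz = dNdx(a, 2);
        int c = 3 * a;
        B(0, c) = bx; B(1, c + 1) = by; B(2, c + 2) = bz;
        B(3, c) = by; B(3, c + 1) = bx;           // gamma_xy
        B(4, c + 1) = bz; B(4, c + 2) = by;       // gamma_yz
        B(5, c) = bz; B(5, c + 2) = bx;           // gamma_zx
      }
      DB = D * B;
      ke += (wq * detJ) * (B.t() * DB);
    }
    // scatter upper triangle of ke into global dof triplets
    int dof[30];
    for (int a = 0; a < 10; ++a) {
      int n = conn(e, a) - 1;
      dof[3 * a] = 3 * n; dof[3 * a + 1] = 3 * n + 1;
      dof[3 * a + 2] = 3 * n + 2;
    }
    for (int r = 0; r < 30; ++r)
      for (int c = 0; c < 30; ++c) {
        int gi = dof[r], gj = dof[c];
        if (gi <= gj) {
          iv.push_back(gi + 1);
          jv.push_back(gj + 1);
          xv.push_back(ke(r, c));
        }
      }
  }
  return List::create(_["i"] = wrap(iv), _["j"] = wrap(jv),
                      _["x"] = wrap(xv));
}

// Volume-averaged element strain tensors from a displacement field.
// Returns ne x 6: exx, eyy, ezz, exy, eyz, exz (tensor shear components).
// [[Rcpp::export]]
arma::mat tet10_strains(const arma::mat &nodes, const arma::imat &conn,
                        const arma::vec &u) {
  const int ne = conn.n_rows;
  const double gp[4][3] = {{GB, GB, GB}, {GA, GB, GB},
                           {GB, GA, GB}, {GB, GB, GA}};
  arma::mat out(ne, 6, arma::fill::zeros);
  arma::mat X(10, 3), J(3, 3), dNdx(10, 3), ue(10, 3);
  std::vector<arma::mat> dNq(4, arma::mat(10, 3));
  for (int q = 0; q < 4; ++q) dshape(gp[q][0], gp[q][1], gp[q][2], dNq[q]);
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 10; ++a) {
      int n = conn(e, a) - 1;
      X(a, 0) = nodes(n, 0); X(a, 1) = nodes(n, 1); X(a, 2) = nodes(n, 2);
      ue(a, 0) = u(3 * n); ue(a, 1) = u(3 * n + 1); ue(a, 2) = u(3 * n + 2);
    }
    double wsum = 0.0;
    arma::vec acc(6, arma::fill::zeros);
    for (int q = 0; q < 4; ++q) {
      J = X.t() * dNq[q];
      double detJ = arma::det(J);
      dNdx = dNq[q] * arma::inv(J);
      arma::mat g = ue.t() * dNdx;   // displacement gradient du_i/dx_j
      double w = detJ / 24.0;
      acc(0) += w * g(0, 0);
      acc(1) += w * g(1, 1);
      acc(2) += w * g(2, 2);
      acc(3) += w * 0.5 * (g(0, 1) + g(1, 0));
      acc(4) += w * 0.5 * (g(1, 2) + g(2, 1));
      acc(5) += w * 0.5 * (g(0, 2) + g(2, 0));
      wsum += w;
    }
    for (int c = 0; c < 6; ++c) out(e, c) = acc(c) / wsum;
  }
  return out;
}

// Principal values of symmetric 3x3 tensors given as n x 6 rows
// (xx, yy, zz, xy, yz, xz); returns n x 3 sorted descending.
// [[Rcpp::export]]
arma::mat sym3_eigenvalues(const arma::mat &t6) {
  const int n = t6.n_rows;
  arma::mat out(n, 3);
  arma::mat33 A;
  arma::vec3 ev;
  for (int k = 0; k < n; ++k) {
    A(0, 0) = t6(k, 0); A(1, 1) = t6(k, 1); A(2, 2) = t6(k, 2);
    A(0, 1) = A(1, 0) = t6(k, 3);
    A(1, 2) = A(2, 1) = t6(k, 4);
    A(0, 2) = A(2, 0) = t6(k, 5);
    arma::eig_sym(ev, A);           // ascending
    out(k, 0) = ev(2); out(k, 1) = ev(1); out(k, 2) = ev(0);
  }
  return out;
}
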