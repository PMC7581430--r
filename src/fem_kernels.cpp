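// Element kernels for plane-strain elasticity on 6-node (quadratic,
// isoparametric) triangles with Saint Venant-Kirchhoff material:
//   E = (F'F - I)/2,  S = lambda tr(E) I + 2 mu E  (total Lagrangian)
// A small-strain path (E = sym grad u, no geometric stiffness) is kept for
// verification against closed-form linear solutions.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 6-point degree-4 rule; full integration avoids the spurious modes the
// minimal 3-point rule admits at finite strain
static const int NQ = 6;
static const double QA = 0.445948490915965;
static const double QB = 0.091576213509771;
static const double QP[6][2] = {
  {QA, QA}, {QA, 1.0 - 2.0 * QA}, {1.0 - 2.0 * QA, QA},
  {QB, QB}, {QB, 1.0 - 2.0 * QB}, {1.0 - 2.0 * QB, QB}};
static const double QWV[6] = {
  0.111690794839005, 0.111690794839005, 0.111690794839005,
  0.054975871827661, 0.054975871827661, 0.054975871827661};

// shape function derivatives wrt (xi, eta); node order: corners 1-3 CCW,
// then midsides (1-2), (2-3), (3-1) -- VTK quadratic-triangle ordering
static void tri6_dN(double xi, double eta, double dN[6][2]) {
  dN[0][0] = -3.0 + 4.0 * xi + 4.0 * eta; dN[0][1] = -3.0 + 4.0 * xi + 4.0 * eta;
  dN[1][0] = 4.0 * xi - 1.0;              dN[1][1] = 0.0;
  dN[2][0] = 0.0;                         dN[2][1] = 4.0 * eta - 1.0;
  dN[3][0] = 4.0 * (1.0 - 2.0 * xi - eta); dN[3][1] = -4.0 * xi;
  dN[4][0] = 4.0 * eta;                   dN[4][1] = 4.0 * xi;
  dN[5][0] = -4.0 * eta;                  dN[5][1] = 4.0 * (1.0 - xi - 2.0 * eta);
}

// Assemble tangent stiffness (COO triplets) and internal force vector.
// nodes: n x 2 reference coordinates; tris: m x 6 (1-based); u: n x 2;
// lambda, mu: per-element Lame constants. Returns min det(F) over all
// quadrature points for inversion checks.
// [[Rcpp::export]]
List fem_tri6_system_cpp(NumericMatrix nodes, IntegerMatrix tris,
                         NumericMatrix u, NumericVector lambda,
                         NumericVector mu, bool small_strain) {
  const int m = tris.nrow();
  const int nn = nodes.nrow();
  const int ntrip = m * 144;
  IntegerVector I(ntrip), J(ntrip);
  NumericVector V(ntrip);
  NumericVector fint(2 * nn);
  double mindetF = R_PosInf;

  double dN[6][2];
  for (int e = 0; e < m; ++e) {
    int nd[6];
    double X[6][2], U[6][2];
    for (int a = 0; a < 6; ++a) {
      nd[a] = tris(e, a) - 1;
      X[a][0] = nodes(nd[a], 0); X[a][1] = nodes(nd[a], 1);
      U[a][0] = u(nd[a], 0);     U[a][1] = u(nd[a], 1);
    }
    const double lam = lambda[e], muv = mu[e];
    const double C00 = lam + 2.0 * muv, C01 = lam, C22 = muv;

    double Ke[12][12] = {{0.0}};
    double fe[12] = {0.0};

    for (int q = 0; q < NQ; ++q) {
      tri6_dN(QP[q][0], QP[q][1], dN);
      // Jacobian J_ij = dx_i/dxi_j
      double Jm[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
      for (int a = 0; a < 6; ++a)
        for (int i = 0; i < 2; ++i)
          for (int j = 0; j < 2; ++j) Jm[i][j] += X[a][i] * dN[a][j];
      const double detJ = Jm[0][0] * Jm[1][1] - Jm[0][1] * Jm[1][0];
      const double iJ[2][2] = {{Jm[1][1] / detJ, -Jm[0][1] / detJ},
                               {-Jm[1][0] / detJ, Jm[0][0] / detJ}};
      double G[6][2];  // dN_a/dX_i
      for (int a = 0; a < 6; ++a) {
        G[a][0] = dN[a][0] * iJ[0][0] + dN[a][1] * iJ[1][0];
        G[a][1] = dN[a][0] * iJ[0][1] + dN[a][1] * iJ[1][1];
      }
      // deformation gradient
      double F[2][2] = {{1.0, 0.0}, {0.0, 1.0}};
      if (!small_strain) {
        for (int a = 0; a < 6; ++a) {
          F[0][0] += U[a][0] * G[a][0]; F[0][1] += U[a][0] * G[a][1];
          F[1][0] += U[a][1] * G[a][0]; F[1][1] += U[a][1] * G[a][1];
        }
        const double detF = F[0][0] * F[1][1] - F[0][1] * F[1][0];
        if (detF < mindetF) mindetF = detF;
      }
      // strain (Green-Lagrange or linearised), Voigt (E11, E22, 2E12)
      double E11, E22, G12;
      if (small_strain) {
        double H[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
        for (int a = 0; a < 6; ++a) {
          H[0][0] += U[a][0] * G[a][0]; H[0][1] += U[a][0] * G[a][1];
          H[1][0] += U[a][1] * G[a][0]; H[1][1] += U[a][1] * G[a][1];
        }
        E11 = H[0][0]; E22 = H[1][1]; G12 = H[0][1] + H[1][0];
      } else {
        E11 = 0.5 * (F[0][0] * F[0][0] + F[1][0] * F[1][0] - 1.0);
        E22 = 0.5 * (F[0][1] * F[0][1] + F[1][1] * F[1][1] - 1.0);
        G12 = F[0][0] * F[0][1] + F[1][0] * F[1][1];
      }
      const double S11 = C00 * E11 + C01 * E22;
      const double S22 = C01 * E11 + C00 * E22;
      const double S12 = C22 * G12;
      const double w = QWV[q] * detJ;  // thickness = 1 mm

      // B_a (3 x 2): rows dE11, dE22, d(2E12) per unit nodal displacement
      double B[6][3][2];
      for (int a = 0; a < 6; ++a) {
        B[a][0][0] = F[0][0] * G[a][0]; B[a][0][1] = F[1][0] * G[a][0];
        B[a][1][0] = F[0][1] * G[a][1]; B[a][1][1] = F[1][1] * G[a][1];
        B[a][2][0] = F[0][0] * G[a][1] + F[0][1] * G[a][0];
        B[a][2][1] = F[1][0] * G[a][1] + F[1][1] * G[a][0];
      }
      for (int a = 0; a < 6; ++a)
        for (int i = 0; i < 2; ++i)
          fe[2 * a + i] += w * (B[a][0][i] * S11 + B[a][1][i] * S22 +
                                B[a][2][i] * S12);

      for (int a = 0; a < 6; ++a) {
        for (int b = 0; b < 6; ++b) {
          // geometric part: (G_a . S G_b) I2 (zero for small strain)
          double geo = 0.0;
          if (!small_strain)
            geo = G[a][0] * (S11 * G[b][0] + S12 * G[b][1]) +
                  G[a][1] * (S12 * G[b][0] + S22 * G[b][1]);
          for (int i = 0; i < 2; ++i) {
            // CB_b column j precomputed inline
            for (int j = 0; j < 2; ++j) {
              const double CB0 = C00 * B[b][0][j] + C01 * B[b][1][j];
              const double CB1 = C01 * B[b][0][j] + C00 * B[b][1][j];
              const double CB2 = C22 * B[b][2][j];
              double kij = B[a][0][i] * CB0 + B[a][1][i] * CB1 +
                           B[a][2][i] * CB2;
              if (i == j) kij += geo;
              Ke[2 * a + i][2 * b + j] += w * kij;
            }
          }
        }
      }
    }

    const int base = e * 144;
    int c = 0;
    for (int a = 0; a < 6; ++a)
      for (int i = 0; i < 2; ++i) {
        const int gi = 2 * nd[a] + i;  // 0-based dof
        fint[gi] += fe[2 * a + i];
        for (int b = 0; b < 6; ++b)
          for (int j = 0; j < 2; ++j) {
            I[base + c] = gi + 1;
            J[base + c] = 2 * nd[b] + j + 1;
            V[base + c] = Ke[2 * a + i][2 * b + j];
            ++c;
          }
      }
  }
  if (small_strain) mindetF = 1.0;
  return List::create(_["i"] = I, _["j"] = J, _["v"] = V, _["fint"] = fint,
                      _["min_detF"] = mindetF);
}

// Consistent nodal forces of a pressure acting on quadratic boundary edges.
// edges: k x 3 (1-based: end a, end b, midside), ordered so the domain lies
// to the LEFT when walking a -> b (CCW boundary). pnod: k x 3 pressure at
// (a, b, mid). If follower, the traction acts on the deformed surface.
// [[Rcpp::export]]
NumericVector fem_edge_pressure_cpp(NumericMatrix nodes, IntegerMatrix edges,
                                    NumericMatrix pnod, NumericMatrix u,
                                    bool follower) {
  const int k = edges.nrow(), nn = nodes.nrow();
  NumericVector f(2 * nn);
  // 3-point Gauss on [0, 1]
  const double g = 0.5 * std::sqrt(3.0 / 5.0);
  const double xis[3] = {0.5 - g, 0.5, 0.5 + g};
  const double ws[3] = {5.0 / 18.0, 8.0 / 18.0, 5.0 / 18.0};
  for (int e = 0; e < k; ++e) {
    int nd[3] = {edges(e, 0) - 1, edges(e, 1) - 1, edges(e, 2) - 1};
    double X[3][2];
    for (int a = 0; a < 3; ++a) {
      X[a][0] = nodes(nd[a], 0) + (follower ? u(nd[a], 0) : 0.0);
      X[a][1] = nodes(nd[a], 1) + (follower ? u(nd[a], 1) : 0.0);
    }
    for (int q = 0; q < 3; ++q) {
      const double xi = xis[q];
      const double N[3] = {(1.0 - xi) * (1.0 - 2.0 * xi),
                           xi * (2.0 * xi - 1.0), 4.0 * xi * (1.0 - xi)};
      const double dN[3] = {-3.0 + 4.0 * xi, 4.0 * xi - 1.0, 4.0 - 8.0 * xi};
      double tx = 0.0, ty = 0.0, p = 0.0;
      for (int a = 0; a < 3; ++a) {
        tx += dN[a] * X[a][0];
        ty += dN[a] * X[a][1];
        p += N[a] * pnod(e, a);
      }
      // outward normal times |t| dxi = (ty, -tx) dxi; traction = -p n
      for (int a = 0; a < 3; ++a) {
        f[2 * nd[a]] += ws[q] * N[a] * (-p) * ty;
        f[2 * nd[a] + 1] += ws[q] * N[a] * (-p) * (-tx);
      }
    }
  }
  return f;
}

// Per-element quadrature-averaged 2nd Piola-Kirchhoff stress, reference
// area and reference centroid. Returns m x 4 stresses (S11, S22, S12, S33),
// with S33 = lambda (E11 + E22) from the plane-strain constraint E33 = 0.
// [[Rcpp::export]]
List tri6_stress_cpp(NumericMatrix nodes, IntegerMatrix tris, NumericMatrix u,
                     NumericVector lambda, NumericVector mu,
                     bool small_strain) {
  const int m = tris.nrow();
  NumericMatrix S(m, 4);
  NumericVector area(m);
  NumericMatrix cen(m, 2);
  double dN[6][2];
  for (int e = 0; e < m; ++e) {
    int nd[6];
    double X[6][2], U[6][2];
    for (int a = 0; a < 6; ++a) {
      nd[a] = tris(e, a) - 1;
      X[a][0] = nodes(nd[a], 0); X[a][1] = nodes(nd[a], 1);
      U[a][0] = u(nd[a], 0);     U[a][1] = u(nd[a], 1);
    }
    const double lam = lambda[e], muv = mu[e];
    double s11 = 0, s22 = 0, s12 = 0, s33 = 0, ar = 0, wsum = 0;
    for (int q = 0; q < NQ; ++q) {
      tri6_dN(QP[q][0], QP[q][1], dN);
      double Jm[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
      for (int a = 0; a < 6; ++a)
        for (int i = 0; i < 2; ++i)
          for (int j = 0; j < 2; ++j) Jm[i][j] += X[a][i] * dN[a][j];
      const double detJ = Jm[0][0] * Jm[1][1] - Jm[0][1] * Jm[1][0];
      const double iJ[2][2] = {{Jm[1][1] / detJ, -Jm[0][1] / detJ},
                               {-Jm[1][0] / detJ, Jm[0][0] / detJ}};
      double H[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
      for (int a = 0; a < 6; ++a) {
        const double g0 = dN[a][0] * iJ[0][0] + dN[a][1] * iJ[1][0];
        const double g1 = dN[a][0] * iJ[0][1] + dN[a][1] * iJ[1][1];
        H[0][0] += U[a][0] * g0; H[0][1] += U[a][0] * g1;
        H[1][0] += U[a][1] * g0; H[1][1] += U[a][1] * g1;
      }
      double E11, E22, E12;
      if (small_strain) {
        E11 = H[0][0]; E22 = H[1][1]; E12 = 0.5 * (H[0][1] + H[1][0]);
      } else {
        const double F[2][2] = {{1.0 + H[0][0], H[0][1]},
                                {H[1][0], 1.0 + H[1][1]}};
        E11 = 0.5 * (F[0][0] * F[0][0] + F[1][0] * F[1][0] - 1.0);
        E22 = 0.5 * (F[0][1] * F[0][1] + F[1][1] * F[1][1] - 1.0);
        E12 = 0.5 * (F[0][0] * F[0][1] + F[1][0] * F[1][1]);
      }
      const double tr = E11 + E22;
      const double w = QWV[q] * detJ;
      s11 += w * (lam * tr + 2.0 * muv * E11);
      s22 += w * (lam * tr + 2.0 * muv * E22);
      s12 += w * (2.0 * muv * E12);
      s33 += w * (lam * tr);
      ar += w;
      wsum += w;
    }
    S(e, 0) = s11 / wsum; S(e, 1) = s22 / wsum;
    S(e, 2) = s12 / wsum; S(e, 3) = s33 / wsum;
    area[e] = ar;
    cen(e, 0) = (X[0][0] + X[1][0] + X[2][0]) / 3.0;
    cen(e, 1) = (X[0][1] + X[1][1] + X[2][1]) / 3.0;
  }
  return List::create(_["S"] = S, _["area"] = area, _["centroid"] = cen);
}
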