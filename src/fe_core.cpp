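// Axisymmetric finite-strain element kernels for the pipette-aspiration model.
//
// Total-Lagrangian formulation on 6-node quadratic triangles (displacement)
// with a continuous linear pressure field (Taylor-Hood) to handle near
// incompressibility.  Constitutive laws: (0) nearly-incompressible
// neo-Hookean with decoupled deviatoric energy  W = mu/2 (J^{-2/3} I1 - 3),
// (1) "linear" stress-strain (St. Venant-Kirchhoff deviator) for the
// linear-elastic comparison models.  The volumetric response enters through
// the mixed field:  W_vol = p (J - 1) - p^2 / (2 kappa).
//
// Element tangents are assembled by forward differencing of the exact
// residual; with quadratic elements and smooth laws this preserves Newton
// convergence while keeping the kernels simple to audit.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double TWOPI = 6.283185307179586476925286766559;

// 7-point degree-5 quadrature on the unit triangle (weights sum to 1)
static const int NGP = 7;
static const double GW[NGP] = {0.225,
  0.132394152788506, 0.132394152788506, 0.132394152788506,
  0.125939180544827, 0.125939180544827, 0.125939180544827};
static const double GA[NGP] = {1.0 / 3.0,
  0.059715871789770, 0.470142064105115, 0.470142064105115,
  0.797426985353087, 0.101286507323456, 0.101286507323456};
static const double GB[NGP] = {1.0 / 3.0,
  0.470142064105115, 0.059715871789770, 0.470142064105115,
  0.101286507323456, 0.797426985353087, 0.101286507323456};

// T6 shape functions in barycentric coordinates (l1, l2, l3)
static inline void t6_shape(double l1, double l2, double l3, double *N) {
  N[0] = l1 * (2 * l1 - 1); N[1] = l2 * (2 * l2 - 1); N[2] = l3 * (2 * l3 - 1);
  N[3] = 4 * l1 * l2;       N[4] = 4 * l2 * l3;       N[5] = 4 * l3 * l1;
}

// derivatives wrt (l1, l2) with l3 = 1 - l1 - l2 dependent
static inline void t6_dshape(double l1, double l2, double l3,
                             double *d1, double *d2) {
  d1[0] = 4 * l1 - 1; d1[1] = 0;          d1[2] = -(4 * l3 - 1);
  d1[3] = 4 * l2;     d1[4] = -4 * l2;    d1[5] = 4 * (l3 - l1);
  d2[0] = 0;          d2[1] = 4 * l2 - 1; d2[2] = -(4 * l3 - 1);
  d2[3] = 4 * l1;     d2[4] = 4 * (l3 - l2); d2[5] = -4 * l1;
}

struct ElemGeom {
  double N[NGP][6];
  double dNdX[NGP][6][2];
  double R[NGP];        // reference radius at gauss point
  double wJ[NGP];       // GW * detJ/2 * 2*pi  (radius applied separately)
  double l1[NGP], l2[NGP], l3[NGP];
};

// build per-element geometry data; mapping is affine (straight-sided T6)
static bool elem_geom(const double *Xe /*6x2 row-major*/, ElemGeom &G) {
  const double x1 = Xe[0], y1 = Xe[1], x2 = Xe[2], y2 = Xe[3],
               x3 = Xe[4], y3 = Xe[5];
  // Jm columns: dX/dl1 = X1 - X3, dX/dl2 = X2 - X3
  const double a = x1 - x3, b = x2 - x3, c = y1 - y3, d = y2 - y3;
  const double det = a * d - b * c;
  if (det <= 0) return false;
  // Jinv = [[d, -b], [-c, a]] / det ; dl/dX rows
  const double i11 = d / det, i12 = -b / det, i21 = -c / det, i22 = a / det;
  double d1[6], d2[6];
  for (int g = 0; g < NGP; ++g) {
    const double l1 = GA[g], l2 = GB[g], l3 = 1 - l1 - l2;
    G.l1[g] = l1; G.l2[g] = l2; G.l3[g] = l3;
    t6_shape(l1, l2, l3, G.N[g]);
    t6_dshape(l1, l2, l3, d1, d2);
    for (int k = 0; k < 6; ++k) {
      G.dNdX[g][k][0] = d1[k] * i11 + d2[k] * i21;
      G.dNdX[g][k][1] = d1[k] * i12 + d2[k] * i22;
    }
    G.R[g] = l1 * x1 + l2 * x2 + l3 * x3;
    G.wJ[g] = GW[g] * 0.5 * det * TWOPI;
  }
  return true;
}

// element residual: 12 displacement dofs then 3 pressure dofs.
// returns false on local inversion (J <= 0).
static bool elem_residual(const ElemGeom &G, const double *de,
                          double mu, double kappa, int model, double *out) {
  for (int k = 0; k < 15; ++k) out[k] = 0;
  for (int g = 0; g < NGP; ++g) {
    const double *N = G.N[g];
    double g00 = 0, g01 = 0, g10 = 0, g11 = 0, ur = 0;
    for (int a = 0; a < 6; ++a) {
      const double uar = de[2 * a], uaz = de[2 * a + 1];
      const double dx = G.dNdX[g][a][0], dz = G.dNdX[g][a][1];
      g00 += uar * dx; g01 += uar * dz;
      g10 += uaz * dx; g11 += uaz * dz;
      ur += uar * N[a];
    }
    const double R = G.R[g];
    const double F11 = 1 + g00, F12 = g01, F21 = g10, F22 = 1 + g11;
    const double Fth = 1 + ur / R;
    const double detF2 = F11 * F22 - F12 * F21;
    const double J = detF2 * Fth;
    if (J <= 0 || Fth <= 0) return false;
    const double iT11 = F22 / detF2, iT12 = -F21 / detF2,
                 iT21 = -F12 / detF2, iT22 = F11 / detF2, iTth = 1.0 / Fth;
    const double p = G.l1[g] * de[12] + G.l2[g] * de[13] + G.l3[g] * de[14];
    double P11, P12, P21, P22, Pth;
    if (model == 0) {
      const double I1 = F11 * F11 + F12 * F12 + F21 * F21 + F22 * F22 + Fth * Fth;
      const double cc = mu * std::pow(J, -2.0 / 3.0);
      const double dd = I1 / 3.0;
      P11 = cc * (F11 - dd * iT11); P12 = cc * (F12 - dd * iT12);
      P21 = cc * (F21 - dd * iT21); P22 = cc * (F22 - dd * iT22);
      Pth = cc * (Fth - dd * iTth);
    } else {
      const double C11 = F11 * F11 + F21 * F21;
      const double C12 = F11 * F12 + F21 * F22;
      const double C22 = F12 * F12 + F22 * F22;
      const double Cth = Fth * Fth;
      const double E11 = 0.5 * (C11 - 1), E12 = 0.5 * C12,
                   E22 = 0.5 * (C22 - 1), Eth = 0.5 * (Cth - 1);
      const double trE3 = (E11 + E22 + Eth) / 3.0;
      const double S11 = 2 * mu * (E11 - trE3), S12 = 2 * mu * E12,
                   S22 = 2 * mu * (E22 - trE3), Sth = 2 * mu * (Eth - trE3);
      P11 = F11 * S11 + F12 * S12; P12 = F11 * S12 + F12 * S22;
      P21 = F21 * S11 + F22 * S12; P22 = F21 * S12 + F22 * S22;
      Pth = Fth * Sth;
    }
    const double pJ = p * J;
    P11 += pJ * iT11; P12 += pJ * iT12;
    P21 += pJ * iT21; P22 += pJ * iT22; Pth += pJ * iTth;
    const double w = G.wJ[g] * R;
    for (int a = 0; a < 6; ++a) {
      out[2 * a] += w * (P11 * G.dNdX[g][a][0] + P12 * G.dNdX[g][a][1] +
                         Pth * N[a] / R);
      out[2 * a + 1] += w * (P21 * G.dNdX[g][a][0] + P22 * G.dNdX[g][a][1]);
    }
    const double pres = (J - 1.0) - p / kappa;
    out[12] += w * pres * G.l1[g];
    out[13] += w * pres * G.l2[g];
    out[14] += w * pres * G.l3[g];
  }
  return true;
}

// 3-point Gauss on [-1, 1]
static const double LXI[3] = {-0.774596669241483, 0.0, 0.774596669241483};
static const double LW[3] = {5.0 / 9.0, 8.0 / 9.0, 5.0 / 9.0};

// consistent nodal force of the aspiration pressure on one quadratic edge
// (nodes ordered low-r end, midside, high-r end); suction pulls along the
// outward normal of the (deformed, if follower) top surface.
static void bele_force(const double *X /*3x2*/, const double *u /*6*/,
                       double pload, bool follower, double *f) {
  for (int k = 0; k < 6; ++k) f[k] = 0;
  for (int g = 0; g < 3; ++g) {
    const double xi = LXI[g];
    const double N[3] = {0.5 * xi * (xi - 1), 1 - xi * xi, 0.5 * xi * (xi + 1)};
    const double dN[3] = {xi - 0.5, -2 * xi, xi + 0.5};
    double xr = 0, drd = 0, dzd = 0;
    for (int a = 0; a < 3; ++a) {
      double cr = X[2 * a], cz = X[2 * a + 1];
      if (follower) { cr += u[2 * a]; cz += u[2 * a + 1]; }
      xr += N[a] * cr;
      drd += dN[a] * cr;
      dzd += dN[a] * cz;
    }
    const double w = LW[g] * pload * TWOPI * xr;
    for (int a = 0; a < 3; ++a) {
      f[2 * a] += w * (-dzd) * N[a];
      f[2 * a + 1] += w * drd * N[a];
    }
  }
}

// Assemble global residual (internal - external), external force vector and,
// optionally, tangent triplets.  Dof layout: u of node n at 2n-1, 2n
// (1-based), pressure of corner node n at 2*nn + pmap[n].
// `sele`/`skv`: quadratic surface edges carrying a vertical elastic
// foundation with nodally interpolated stiffness per unit area (the graded
// roller over the pipette edge fillet), assembled consistently.
// [[Rcpp::export]]
List fe_system(NumericMatrix nodes, IntegerMatrix tri,
               NumericVector mu_e, NumericVector ka_e, int model,
               IntegerVector pmap, int np, NumericVector sol,
               IntegerMatrix bele, double pload, bool follower,
               IntegerMatrix sele, NumericMatrix skv, NumericVector skh,
               bool wantK) {
  const int nn = nodes.nrow(), ne = tri.nrow(), nbe = bele.nrow();
  const int ndof = 2 * nn + np;
  NumericVector res(ndof), fext(ndof);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (wantK) {
    const size_t cap = (size_t)ne * 225 + (size_t)nbe * 36;
    ti.reserve(cap); tj.reserve(cap); tx.reserve(cap);
  }
  const double h = 1e-7;
  double Xe[12], de[15], de2[15], r0[15], r2[15];
  int gd[15];
  bool ok = true;

  for (int e = 0; e < ne && ok; ++e) {
    for (int a = 0; a < 6; ++a) {
      const int n = tri(e, a) - 1;
      Xe[2 * a] = nodes(n, 0); Xe[2 * a + 1] = nodes(n, 1);
      gd[2 * a] = 2 * n; gd[2 * a + 1] = 2 * n + 1;
      de[2 * a] = sol[2 * n]; de[2 * a + 1] = sol[2 * n + 1];
    }
    for (int c = 0; c < 3; ++c) {
      const int n = tri(e, c) - 1;
      gd[12 + c] = 2 * nn + pmap[n] - 1;
      de[12 + c] = sol[gd[12 + c]];
    }
    ElemGeom G;
    if (!elem_geom(Xe, G)) { ok = false; break; }
    const double mu = mu_e[e], ka = ka_e[e];
    if (!elem_residual(G, de, mu, ka, model, r0)) { ok = false; break; }
    for (int k = 0; k < 15; ++k) res[gd[k]] += r0[k];
    if (wantK) {
      for (int k = 0; k < 15; ++k) {
        std::copy(de, de + 15, de2);
        de2[k] += h;
        if (!elem_residual(G, de2, mu, ka, model, r2)) { ok = false; break; }
        const double ih = 1.0 / h;
        for (int r = 0; r < 15; ++r) {
          ti.push_back(gd[r] + 1);
          tj.push_back(gd[k] + 1);
          tx.push_back((r2[r] - r0[r]) * ih);
        }
      }
    }
  }

  if (ok) {
    double Xb[6], ub[6], ub2[6], f0[6], f2[6];
    int gb[6];
    for (int e = 0; e < nbe; ++e) {
      for (int a = 0; a < 3; ++a) {
        const int n = bele(e, a) - 1;
        Xb[2 * a] = nodes(n, 0); Xb[2 * a + 1] = nodes(n, 1);
        gb[2 * a] = 2 * n; gb[2 * a + 1] = 2 * n + 1;
        ub[2 * a] = sol[2 * n]; ub[2 * a + 1] = sol[2 * n + 1];
      }
      bele_force(Xb, ub, pload, follower, f0);
      for (int k = 0; k < 6; ++k) {
        fext[gb[k]] += f0[k];
        res[gb[k]] -= f0[k];
      }
      if (wantK && follower) {
        for (int k = 0; k < 6; ++k) {
          std::copy(ub, ub + 6, ub2);
          ub2[k] += h;
          bele_force(Xb, ub2, pload, follower, f2);
          const double ih = 1.0 / h;
          for (int r = 0; r < 6; ++r) {
            ti.push_back(gb[r] + 1);
            tj.push_back(gb[k] + 1);
            tx.push_back(-(f2[r] - f0[r]) * ih);
          }
        }
      }
    }
  }

  // consistent vertical foundation on the fillet-span surface edges:
  // K_ab = int N_a N_b k(r) 2*pi*r dl over the reference edge
  for (int e = 0; e < sele.nrow(); ++e) {
    double Ks[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    double Xs[6], uzs[3], kc[3];
    int gz[3];
    for (int a = 0; a < 3; ++a) {
      const int n = sele(e, a) - 1;
      Xs[2 * a] = nodes(n, 0); Xs[2 * a + 1] = nodes(n, 1);
      gz[a] = 2 * n + 1;
      uzs[a] = sol[gz[a]];
      kc[a] = skv(e, a);
    }
    for (int g = 0; g < 3; ++g) {
      const double xi = LXI[g];
      const double N[3] = {0.5 * xi * (xi - 1), 1 - xi * xi,
                           0.5 * xi * (xi + 1)};
      const double dN[3] = {xi - 0.5, -2 * xi, xi + 0.5};
      double r = 0, kg = 0, drd = 0, dzd = 0;
      for (int a = 0; a < 3; ++a) {
        r += N[a] * Xs[2 * a];
        kg += N[a] * kc[a];
        drd += dN[a] * Xs[2 * a];
        dzd += dN[a] * Xs[2 * a + 1];
      }
      if (kg < 0) kg = 0;
      const double w = LW[g] * kg * TWOPI * r * std::sqrt(drd * drd + dzd * dzd);
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          Ks[a][b] += w * N[a] * N[b];
    }
    for (int a = 0; a < 3; ++a) {
      double fa = 0;
      for (int b = 0; b < 3; ++b) fa += Ks[a][b] * uzs[b];
      res[gz[a]] += fa;
      if (wantK) {
        for (int b = 0; b < 3; ++b) {
          ti.push_back(gz[a] + 1);
          tj.push_back(gz[b] + 1);
          tx.push_back(Ks[a][b]);
        }
      }
    }
    // penalty on the midside node's tangential (radial) deviation from the
    // linear interpolant of its corners: suppresses a spurious local slip
    // mode of the quadratic surface edge without stiffening smooth fields
    if (e < skh.size() && skh[e] > 0) {
      const double gvec[3] = {-0.5, 1.0, -0.5};
      for (int a = 0; a < 3; ++a) {
        const int ga = gz[a] - 1;  // radial dof of the same node
        double fa = 0;
        for (int b = 0; b < 3; ++b)
          fa += skh[e] * gvec[a] * gvec[b] * sol[gz[b] - 1];
        res[ga] += fa;
        if (wantK) {
          for (int b = 0; b < 3; ++b) {
            ti.push_back(ga + 1);
            tj.push_back(gz[b]);  // (gz[b]-1)+1
            tx.push_back(skh[e] * gvec[a] * gvec[b]);
          }
        }
      }
    }
  }

  List out = List::create(_["res"] = res, _["fext"] = fext, _["ok"] = ok);
  if (wantK) {
    out["ti"] = IntegerVector(ti.begin(), ti.end());
    out["tj"] = IntegerVector(tj.begin(), tj.end());
    out["tx"] = NumericVector(tx.begin(), tx.end());
  }
  return out;
}

// deformation gradient components (F_rr, F_rz, F_zr, F_zz, F_thth) at a
// barycentric point of one element; R on the axis uses the l'Hopital limit
// F_thth -> F_rr.
// [[Rcpp::export]]
NumericVector fe_defgrad(NumericMatrix nodes, IntegerMatrix tri, int elem,
                         double l1, double l2, NumericVector sol) {
  double Xe[12], d1[6], d2[6], N[6];
  const int e = elem - 1;
  for (int a = 0; a < 6; ++a) {
    const int n = tri(e, a) - 1;
    Xe[2 * a] = nodes(n, 0); Xe[2 * a + 1] = nodes(n, 1);
  }
  const double x1 = Xe[0], y1 = Xe[1], x2 = Xe[2], y2 = Xe[3],
               x3 = Xe[4], y3 = Xe[5];
  const double a_ = x1 - x3, b_ = x2 - x3, c_ = y1 - y3, d_ = y2 - y3;
  const double det = a_ * d_ - b_ * c_;
  const double i11 = d_ / det, i12 = -b_ / det, i21 = -c_ / det, i22 = a_ / det;
  const double l3 = 1 - l1 - l2;
  t6_shape(l1, l2, l3, N);
  t6_dshape(l1, l2, l3, d1, d2);
  double g00 = 0, g01 = 0, g10 = 0, g11 = 0, ur = 0;
  for (int a = 0; a < 6; ++a) {
    const int n = tri(e, a) - 1;
    const double uar = sol[2 * n], uaz = sol[2 * n + 1];
    const double dx = d1[a] * i11 + d2[a] * i21;
    const double dz = d1[a] * i12 + d2[a] * i22;
    g00 += uar * dx; g01 += uar * dz;
    g10 += uaz * dx; g11 += uaz * dz;
    ur += uar * N[a];
  }
  const double R = l1 * x1 + l2 * x2 + l3 * x3;
  const double Frr = 1 + g00;
  const double Fth = (R > 1e-9) ? 1 + ur / R : Frr;
  return NumericVector::create(Frr, g01, g10, 1 + g11, Fth);
}
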