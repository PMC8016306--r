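// Finite-element core: axisymmetric / plane-strain 4-node quadrilaterals with a
// compressible Neo-Hookean law, Psi = C10*(I1bar - 3) + (1/D1)*(J - 1)^2.
//
// Volumetric locking at near-incompressibility is relieved by an F-bar
// (centroid-Jacobian) treatment: the isochoric term is integrated at the 2x2
// Gauss points with the local deformation gradient, while the volumetric term
// uses the element-centroid Jacobian over the element reference volume.  The
// nodal force below is the exact gradient of that discrete energy, so the
// discrete system is conservative (external work equals stored energy along
// any equilibrium path).
//
// Units: mm - kPa - mN (1 kPa * mm^2 = 1 mN); axisymmetric integrals carry the
// full 2*pi*r measure.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double GPT = 0.5773502691896258; // 1/sqrt(3)
static const double XA[4] = {-1.0, 1.0, 1.0, -1.0};
static const double EA[4] = {-1.0, -1.0, 1.0, 1.0};
static const double TWO_PI = 6.283185307179586;

struct ShapeData {
  double N[4];
  double dNdX[4][2];
  double detJ;
  double r0;
};

static bool shape_at(const double xe[4][2], double xi, double eta, ShapeData &g) {
  double dN[4][2];
  for (int a = 0; a < 4; ++a) {
    g.N[a]    = 0.25 * (1.0 + XA[a] * xi) * (1.0 + EA[a] * eta);
    dN[a][0]  = 0.25 * XA[a] * (1.0 + EA[a] * eta);
    dN[a][1]  = 0.25 * EA[a] * (1.0 + XA[a] * xi);
  }
  double J11 = 0, J12 = 0, J21 = 0, J22 = 0; // J[i][j] = d x_i / d xi_j
  for (int a = 0; a < 4; ++a) {
    J11 += xe[a][0] * dN[a][0];  J12 += xe[a][0] * dN[a][1];
    J21 += xe[a][1] * dN[a][0];  J22 += xe[a][1] * dN[a][1];
  }
  double det = J11 * J22 - J12 * J21;
  if (!(det > 1e-12)) return false;
  g.detJ = det;
  double i00 =  J22 / det, i01 = -J12 / det, i10 = -J21 / det, i11 = J11 / det;
  for (int a = 0; a < 4; ++a) {
    g.dNdX[a][0] = dN[a][0] * i00 + dN[a][1] * i10;
    g.dNdX[a][1] = dN[a][0] * i01 + dN[a][1] * i11;
  }
  g.r0 = 0.0;
  for (int a = 0; a < 4; ++a) g.r0 += g.N[a] * xe[a][0];
  return true;
}

struct KinData {
  double F2[2][2];
  double lam;     // out-of-plane stretch (hoop for axisym, 1 for plane strain)
  double detF2;
  double J;       // detF2 * lam
  double I1;      // 3-D first invariant tr(F^T F)
};

static bool kinematics(const ShapeData &g, const double ue[4][2], bool axisym,
                       KinData &k) {
  k.F2[0][0] = 1; k.F2[0][1] = 0; k.F2[1][0] = 0; k.F2[1][1] = 1;
  for (int a = 0; a < 4; ++a) {
    k.F2[0][0] += ue[a][0] * g.dNdX[a][0];
    k.F2[0][1] += ue[a][0] * g.dNdX[a][1];
    k.F2[1][0] += ue[a][1] * g.dNdX[a][0];
    k.F2[1][1] += ue[a][1] * g.dNdX[a][1];
  }
  k.lam = 1.0;
  if (axisym) {
    if (g.r0 > 1e-12) {
      double ur = 0;
      for (int a = 0; a < 4; ++a) ur += g.N[a] * ue[a][0];
      k.lam = 1.0 + ur / g.r0;
    } else {
      k.lam = k.F2[0][0]; // limit on the symmetry axis
    }
  }
  k.detF2 = k.F2[0][0] * k.F2[1][1] - k.F2[0][1] * k.F2[1][0];
  k.J = k.detF2 * k.lam;
  if (!(k.detF2 > 1e-10) || !(k.lam > 1e-10)) return false;
  k.I1 = k.F2[0][0] * k.F2[0][0] + k.F2[0][1] * k.F2[0][1] +
         k.F2[1][0] * k.F2[1][0] + k.F2[1][1] * k.F2[1][1] + k.lam * k.lam;
  return true;
}

// dJ/du and dI1/du at a point; dJ[8], dI1[8] in local dof order (a,comp)
static void kin_derivs(const ShapeData &g, const KinData &k, bool axisym,
                       double dJ[8], double dI1[8]) {
  // inv(F2)^T entries
  double fiT00 =  k.F2[1][1] / k.detF2, fiT01 = -k.F2[1][0] / k.detF2;
  double fiT10 = -k.F2[0][1] / k.detF2, fiT11 =  k.F2[0][0] / k.detF2;
  for (int a = 0; a < 4; ++a) {
    double g0 = g.dNdX[a][0], g1 = g.dNdX[a][1];
    // i = 0 (radial / x)
    dI1[2 * a]     = 2.0 * (k.F2[0][0] * g0 + k.F2[0][1] * g1);
    dJ[2 * a]      = k.lam * k.detF2 * (fiT00 * g0 + fiT01 * g1);
    // i = 1 (axial / y)
    dI1[2 * a + 1] = 2.0 * (k.F2[1][0] * g0 + k.F2[1][1] * g1);
    dJ[2 * a + 1]  = k.lam * k.detF2 * (fiT10 * g0 + fiT11 * g1);
    if (axisym && g.r0 > 1e-12) {
      double nr = g.N[a] / g.r0;
      dI1[2 * a] += 2.0 * k.lam * nr;
      dJ[2 * a]  += k.detF2 * nr;
    }
  }
}

// Energy and (exact) force of one element. Returns false on inverted mapping.
static bool elem_force_energy(const double xe[4][2], const double ue[4][2],
                              double c10, double d1, bool axisym,
                              double *energy, double fe[8], bool want_force) {
  ShapeData gc;
  KinData kc;
  if (!shape_at(xe, 0.0, 0.0, gc)) return false;
  if (!kinematics(gc, ue, axisym, kc)) return false;
  double Jc = kc.J;

  double Ve = 0.0, Edev = 0.0;
  if (want_force) for (int q = 0; q < 8; ++q) fe[q] = 0.0;

  for (int gx = 0; gx < 2; ++gx) {
    for (int gy = 0; gy < 2; ++gy) {
      ShapeData g;
      KinData k;
      double xi = (gx == 0 ? -GPT : GPT), eta = (gy == 0 ? -GPT : GPT);
      if (!shape_at(xe, xi, eta, g)) return false;
      if (!kinematics(g, ue, axisym, k)) return false;
      double w = g.detJ * (axisym ? TWO_PI * g.r0 : 1.0); // gauss weights = 1
      double J23 = std::pow(k.J, -2.0 / 3.0);
      Ve   += w;
      Edev += w * c10 * (J23 * k.I1 - 3.0);
      if (want_force) {
        double dJ[8], dI1[8];
        kin_derivs(g, k, axisym, dJ, dI1);
        double cI = w * c10 * J23;
        double cJ = -w * c10 * (2.0 / 3.0) * J23 * k.I1 / k.J;
        for (int q = 0; q < 8; ++q) fe[q] += cI * dI1[q] + cJ * dJ[q];
      }
    }
  }
  *energy = Edev + Ve * (1.0 / d1) * (Jc - 1.0) * (Jc - 1.0);
  if (want_force) {
    double dJc[8], dI1c[8];
    kin_derivs(gc, kc, axisym, dJc, dI1c);
    double cv = Ve * (2.0 / d1) * (Jc - 1.0);
    for (int q = 0; q < 8; ++q) fe[q] += cv * dJc[q];
  }
  return true;
}

static void gather_elem(const NumericMatrix &nodes, const IntegerMatrix &elems,
                        const NumericVector &u, int e, int id[4],
                        double xe[4][2], double ue[4][2]) {
  for (int a = 0; a < 4; ++a) {
    id[a] = elems(e, a) - 1;
    xe[a][0] = nodes(id[a], 0);
    xe[a][1] = nodes(id[a], 1);
    ue[a][0] = u[2 * id[a]];
    ue[a][1] = u[2 * id[a] + 1];
  }
}

// [[Rcpp::export]]
List fe_assemble(NumericMatrix nodes, IntegerMatrix elems, NumericVector u,
                 NumericVector c10, NumericVector d1, bool axisym,
                 bool want_force = true) {
  int m = elems.nrow(), n = nodes.nrow();
  NumericVector force(want_force ? 2 * n : 1);
  double energy = 0.0;
  bool ok = true;
  for (int e = 0; e < m; ++e) {
    int id[4];
    double xe[4][2], ue[4][2], fe[8], ee = 0.0;
    gather_elem(nodes, elems, u, e, id, xe, ue);
    if (!elem_force_energy(xe, ue, c10[e], d1[e], axisym, &ee, fe, want_force)) {
      ok = false;
      break;
    }
    energy += ee;
    if (want_force) {
      for (int a = 0; a < 4; ++a) {
        force[2 * id[a]]     += fe[2 * a];
        force[2 * id[a] + 1] += fe[2 * a + 1];
      }
    }
  }
  return List::create(_["ok"] = ok, _["energy"] = energy, _["force"] = force);
}

// Element tangents by central difference of the exact element force.
// Returns COO triplets (1-based global dof indices).
// [[Rcpp::export]]
List fe_stiffness_triplets(NumericMatrix nodes, IntegerMatrix elems,
                           NumericVector u, NumericVector c10, NumericVector d1,
                           bool axisym, double h = 1e-6) {
  int m = elems.nrow();
  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve(m * 64); tj.reserve(m * 64); tx.reserve(m * 64);
  bool ok = true;
  for (int e = 0; e < m && ok; ++e) {
    int id[4];
    double xe[4][2], ue[4][2];
    gather_elem(nodes, elems, u, e, id, xe, ue);
    double Kl[8][8];
    double fp[8], fm[8], ee;
    for (int q = 0; q < 8 && ok; ++q) {
      int a = q / 2, i = q % 2;
      double keep = ue[a][i];
      ue[a][i] = keep + h;
      if (!elem_force_energy(xe, ue, c10[e], d1[e], axisym, &ee, fp, true)) ok = false;
      ue[a][i] = keep - h;
      if (ok && !elem_force_energy(xe, ue, c10[e], d1[e], axisym, &ee, fm, true)) ok = false;
      ue[a][i] = keep;
      if (!ok) break;
      for (int p = 0; p < 8; ++p) Kl[p][q] = (fp[p] - fm[p]) / (2.0 * h);
    }
    if (!ok) break;
    for (int p = 0; p < 8; ++p) {
      int gp = 2 * id[p / 2] + (p % 2) + 1;
      for (int q = 0; q < 8; ++q) {
        int gq = 2 * id[q / 2] + (q % 2) + 1;
        ti.push_back(gp);
        tj.push_back(gq);
        tx.push_back(Kl[p][q]);
      }
    }
  }
  return List::create(_["ok"] = ok, _["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tx));
}

// Per-element centroid fields (F-bar consistent: at the centroid the local and
// F-bar gradients coincide). Columns: s_rr, s_zz, s_rz, s_tt, von Mises, SED, J.
// [[Rcpp::export]]
NumericMatrix fe_element_fields(NumericMatrix nodes, IntegerMatrix elems,
                                NumericVector u, NumericVector c10,
                                NumericVector d1, bool axisym) {
  int m = elems.nrow();
  NumericMatrix out(m, 7);
  colnames(out) = CharacterVector::create("s_rr", "s_zz", "s_rz", "s_tt",
                                          "von_mises", "sed", "J");
  for (int e = 0; e < m; ++e) {
    int id[4];
    double xe[4][2], ue[4][2];
    gather_elem(nodes, elems, u, e, id, xe, ue);
    ShapeData g;
    KinData k;
    if (!shape_at(xe, 0.0, 0.0, g) || !kinematics(g, ue, axisym, k)) {
      for (int c = 0; c < 7; ++c) out(e, c) = NA_REAL;
      continue;
    }
    double J = k.J;
    // B = F F^T (in-plane block) and hoop component
    double B00 = k.F2[0][0] * k.F2[0][0] + k.F2[0][1] * k.F2[0][1];
    double B01 = k.F2[0][0] * k.F2[1][0] + k.F2[0][1] * k.F2[1][1];
    double B11 = k.F2[1][0] * k.F2[1][0] + k.F2[1][1] * k.F2[1][1];
    double Btt = k.lam * k.lam;
    double trB = B00 + B11 + Btt;
    double ciso = 2.0 * c10[e] * std::pow(J, -5.0 / 3.0);
    double p = (2.0 / d1[e]) * (J - 1.0);
    double s00 = ciso * (B00 - trB / 3.0) + p;
    double s11 = ciso * (B11 - trB / 3.0) + p;
    double stt = ciso * (Btt - trB / 3.0) + p;
    double s01 = ciso * B01;
    double sm = (s00 + s11 + stt) / 3.0;
    double vm = std::sqrt(1.5 * ((s00 - sm) * (s00 - sm) +
                                 (s11 - sm) * (s11 - sm) +
                                 (stt - sm) * (stt - sm) + 2.0 * s01 * s01));
    double sed = c10[e] * (std::pow(J, -2.0 / 3.0) * k.I1 - 3.0) +
                 (1.0 / d1[e]) * (J - 1.0) * (J - 1.0);
    out(e, 0) = s00;
    out(e, 1) = s11;
    out(e, 2) = s01;
    out(e, 3) = stt;
    out(e, 4) = vm;
    out(e, 5) = sed;
    out(e, 6) = J;
  }
  return out;
}

// 8-connected component labelling of a logical mask (row-major R matrix).
// Returns an integer matrix, 0 = background, components numbered from 1.
// [[Rcpp::export]]
IntegerMatrix cc_label(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (mask(qi, qj) && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
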