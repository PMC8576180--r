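// Element-level kernels for the membrane IFEA framework.
//
// Conventions: units mm / kPa / mN (1 kPa = 1 mN/mm^2). Each element carries
// a reference local frame (ex, ey, ez) with ez the outward normal; in-plane
// kinematics are expressed in reference local coordinates, nodal quantities
// in global coordinates. C2d is the in-plane right Cauchy-Green tensor.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Compressible Mooney-Rivlin, plane-stress condensed
// ---------------------------------------------------------------------------

// S33 (through-thickness 2nd PK stress) for block-diagonal C = [C2d, c33].
static double mr_s33(double c11, double c22, double c12, double c33,
                     double C10, double C01, double D1) {
  double i1 = c11 + c22 + c33;
  double trC2 = c11 * c11 + 2.0 * c12 * c12 + c22 * c22 + c33 * c33;
  double i2 = 0.5 * (i1 * i1 - trC2);
  double det2 = c11 * c22 - c12 * c12;
  double J2 = det2 * c33;
  double J = std::sqrt(J2);
  double J23 = std::pow(J, -2.0 / 3.0);
  double J43 = J23 * J23;
  return 2.0 * (C10 * J23 * (1.0 - i1 / (3.0 * c33)) +
                C01 * J43 * (i1 - c33 - 2.0 * i2 / (3.0 * c33)) +
                J * (J - 1.0) / (D1 * c33));
}

// Solve S33(c33) = 0 by safeguarded Newton within an expanding bracket.
static double mr_solve_c33(double c11, double c22, double c12,
                           double C10, double C01, double D1,
                           int elem_for_error) {
  double det2 = c11 * c22 - c12 * c12;
  if (det2 <= 0.0)
    stop("element %d: in-plane Jacobian <= 0 (element inversion)",
         elem_for_error + 1);
  // bracket: S33 -> -inf as c33 -> 0+, grows positive for large c33
  double lo = 1e-6, hi = 4.0;
  double glo = mr_s33(c11, c22, c12, lo, C10, C01, D1);
  double ghi = mr_s33(c11, c22, c12, hi, C10, C01, D1);
  int expand = 0;
  while (glo * ghi > 0.0 && expand < 40) {
    if (std::abs(glo) < std::abs(ghi)) { lo *= 0.25; glo = mr_s33(c11, c22, c12, lo, C10, C01, D1); }
    else { hi *= 2.0; ghi = mr_s33(c11, c22, c12, hi, C10, C01, D1); }
    ++expand;
  }
  if (glo * ghi > 0.0)
    stop("element %d: plane-stress root find failed to bracket (C = [%g %g %g])",
         elem_for_error + 1, c11, c22, c12);
  double x = 1.0 / det2;             // incompressible guess, usually close
  if (x <= lo || x >= hi) x = 0.5 * (lo + hi);
  double g = mr_s33(c11, c22, c12, x, C10, C01, D1);
  for (int it = 0; it < 100; ++it) {
    if (g > 0.0) { hi = x; ghi = g; } else { lo = x; glo = g; }
    double h = 1e-7 * x;
    double gp = (mr_s33(c11, c22, c12, x + h, C10, C01, D1) -
                 mr_s33(c11, c22, c12, x - h, C10, C01, D1)) / (2.0 * h);
    double xn = (gp != 0.0) ? x - g / gp : 0.5 * (lo + hi);
    if (!(xn > lo && xn < hi)) xn = 0.5 * (lo + hi);
    if (std::abs(xn - x) < 1e-12 * x) { x = xn; break; }
    x = xn;
    g = mr_s33(c11, c22, c12, x, C10, C01, D1);
    if (std::abs(g) < 1e-12 * (C10 + C01 + 1.0 / D1)) break;
  }
  return x;
}

// W and condensed in-plane S for Mooney-Rivlin; c33 solved internally.
static void mr_eval(const double C2d[3], double C10, double C01, double D1,
                    double S2d[3], double* W, double* lambda3,
                    int elem_for_error) {
  double c11 = C2d[0], c22 = C2d[1], c12 = C2d[2];
  double c33 = mr_solve_c33(c11, c22, c12, C10, C01, D1, elem_for_error);
  double i1 = c11 + c22 + c33;
  double trC2 = c11 * c11 + 2.0 * c12 * c12 + c22 * c22 + c33 * c33;
  double i2 = 0.5 * (i1 * i1 - trC2);
  double det2 = c11 * c22 - c12 * c12;
  double J = std::sqrt(det2 * c33);
  double J23 = std::pow(J, -2.0 / 3.0);
  double J43 = J23 * J23;
  // inv of in-plane block
  double v11 = c22 / det2, v22 = c11 / det2, v12 = -c12 / det2;
  double a = C10 * J23, b = C01 * J43, c = J * (J - 1.0) / D1;
  S2d[0] = 2.0 * (a * (1.0 - i1 / 3.0 * v11) + b * (i1 - c11 - 2.0 * i2 / 3.0 * v11) + c * v11);
  S2d[1] = 2.0 * (a * (1.0 - i1 / 3.0 * v22) + b * (i1 - c22 - 2.0 * i2 / 3.0 * v22) + c * v22);
  S2d[2] = 2.0 * (a * (-i1 / 3.0 * v12) + b * (-c12 - 2.0 * i2 / 3.0 * v12) + c * v12);
  *W = C10 * (J23 * i1 - 3.0) + C01 * (J43 * i2 - 3.0) + (J - 1.0) * (J - 1.0) / D1;
  *lambda3 = std::sqrt(c33);
}

// ---------------------------------------------------------------------------
// Holzapfel-Gasser-Ogden membrane with J = 1 thickness condensation
// ---------------------------------------------------------------------------

// (exp(x) - 1)/x with a series guard near x = 0 (k2 -> 0 limit of W_aniso).
static double expm1_over_x(double x) {
  if (std::abs(x) < 1e-8) return 1.0 + 0.5 * x;
  return std::expm1(x) / x;
}

static void hgo_eval(const double C2d[3], double C10, double k1, double k2,
                     double kappa, const double a0[2],
                     double S2d[3], double* W, double* lambda3,
                     int elem_for_error) {
  double c11 = C2d[0], c22 = C2d[1], c12 = C2d[2];
  double det2 = c11 * c22 - c12 * c12;
  if (det2 <= 0.0)
    stop("element %d: in-plane Jacobian <= 0 (element inversion)",
         elem_for_error + 1);
  double c33 = 1.0 / det2;                 // J = 1
  double i1 = c11 + c22 + c33;
  double i4 = a0[0] * a0[0] * c11 + 2.0 * a0[0] * a0[1] * c12 + a0[1] * a0[1] * c22;
  double Ef = kappa * (i1 - 3.0) + (1.0 - 3.0 * kappa) * (i4 - 1.0);
  double v11 = c22 / det2, v22 = c11 / det2, v12 = -c12 / det2;
  // dI1/dC2d with c33 = 1/det2 eliminated: I - (1/det2) C2d^{-1}
  double d1_11 = 1.0 - c33 * v11, d1_22 = 1.0 - c33 * v22, d1_12 = -c33 * v12;
  double Wiso = C10 * (i1 - 3.0);          // volumetric term vanishes at J = 1
  double Waniso = 0.0, dWa = 0.0;
  if (Ef > 0.0 && k1 > 0.0) {              // tension-only fiber contribution
    double x = k2 * Ef * Ef;
    Waniso = 0.5 * k1 * Ef * Ef * expm1_over_x(x);
    dWa = k1 * Ef * std::exp(x);
  }
  double g11 = C10 * d1_11, g22 = C10 * d1_22, g12 = C10 * d1_12;
  if (dWa != 0.0) {
    g11 += dWa * (kappa * d1_11 + (1.0 - 3.0 * kappa) * a0[0] * a0[0]);
    g22 += dWa * (kappa * d1_22 + (1.0 - 3.0 * kappa) * a0[1] * a0[1]);
    g12 += dWa * (kappa * d1_12 + (1.0 - 3.0 * kappa) * a0[0] * a0[1]);
  }
  S2d[0] = 2.0 * g11; S2d[1] = 2.0 * g22; S2d[2] = 2.0 * g12;
  *W = Wiso + Waniso;
  *lambda3 = std::sqrt(c33);
}

// ---------------------------------------------------------------------------
// Single-state evaluation (exposed for the constitutive-law API and tests)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List mr_eval_cpp(NumericVector C2d, double C10, double C01, double D1) {
  double Cc[3] = {C2d[0], C2d[1], C2d[2]};
  double S[3], W, lam3;
  mr_eval(Cc, C10, C01, D1, S, &W, &lam3, -1);
  return List::create(_["W"] = W, _["S"] = NumericVector::create(S[0], S[1], S[2]),
                      _["lambda3"] = lam3);
}

// [[Rcpp::export]]
List hgo_eval_cpp(NumericVector C2d, double C10, double k1, double k2,
                  double kappa, NumericVector a0) {
  double Cc[3] = {C2d[0], C2d[1], C2d[2]};
  double a[2] = {a0[0], a0[1]};
  double S[3], W, lam3;
  hgo_eval(Cc, C10, k1, k2, kappa, a, S, &W, &lam3, -1);
  return List::create(_["W"] = W, _["S"] = NumericVector::create(S[0], S[1], S[2]),
                      _["lambda3"] = lam3);
}

// ---------------------------------------------------------------------------
// Element residual (internal minus follower-pressure force)
// ---------------------------------------------------------------------------

struct ElemGeom {
  arma::vec3 X0, X1, X2;      // reference nodes
  double B[4];                // inv(Dm), row-major
  double area;                // reference area
};

// element force (9-vector, global dofs) at elemental displacement ue (9)
static void elem_force(const ElemGeom& g, const double* ue,
                       int mat_case, const double* mp, const double* a0,
                       double thickness, double pressure,
                       double* f, double* Wout, int e) {
  arma::vec3 x0 = g.X0, x1 = g.X1, x2 = g.X2;
  for (int c = 0; c < 3; ++c) {
    x0[c] += ue[c]; x1[c] += ue[3 + c]; x2[c] += ue[6 + c];
  }
  arma::vec3 e1 = x1 - x0, e2 = x2 - x0;
  // F32 = P * B, P = [e1 e2]
  arma::vec3 F1 = e1 * g.B[0] + e2 * g.B[2];
  arma::vec3 F2 = e1 * g.B[1] + e2 * g.B[3];
  double C2d[3] = {arma::dot(F1, F1), arma::dot(F2, F2), arma::dot(F1, F2)};
  double S[3], W, lam3;
  if (mat_case == 0) mr_eval(C2d, mp[0], mp[1], mp[2], S, &W, &lam3, e);
  else               hgo_eval(C2d, mp[0], mp[2], mp[3], mp[4], a0, S, &W, &lam3, e);
  // M = P * B * S * B^T (3x2); internal force cols: node1 <- M[,1], node2 <- M[,2]
  // BSBt = B * S * B^T (2x2 symmetric)
  double S11 = S[0], S22 = S[1], S12 = S[2];
  double b11 = g.B[0], b12 = g.B[1], b21 = g.B[2], b22 = g.B[3];
  // (B S) rows
  double t11 = b11 * S11 + b12 * S12, t12 = b11 * S12 + b12 * S22;
  double t21 = b21 * S11 + b22 * S12, t22 = b21 * S12 + b22 * S22;
  double q11 = t11 * b11 + t12 * b12, q12 = t11 * b21 + t12 * b22;
  double q21 = t21 * b11 + t22 * b12, q22 = t21 * b21 + t22 * b22;
  double At = g.area * thickness;
  arma::vec3 fi1 = At * (e1 * q11 + e2 * q21);
  arma::vec3 fi2 = At * (e1 * q12 + e2 * q22);
  // follower pressure on current configuration
  arma::vec3 n = 0.5 * arma::cross(e1, e2);
  arma::vec3 fp = (pressure / 3.0) * n;
  for (int c = 0; c < 3; ++c) {
    f[c]     = -(fi1[c] + fi2[c]) - fp[c];
    f[3 + c] = fi1[c] - fp[c];
    f[6 + c] = fi2[c] - fp[c];
  }
  *Wout = W * g.area * thickness;
}

static ElemGeom make_geom(const arma::mat& nodes, const arma::imat& tris,
                          const arma::mat& ex, const arma::mat& ey, int e) {
  ElemGeom g;
  int i0 = tris(e, 0), i1 = tris(e, 1), i2 = tris(e, 2);
  g.X0 = nodes.row(i0).t(); g.X1 = nodes.row(i1).t(); g.X2 = nodes.row(i2).t();
  arma::vec3 ax = ex.row(e).t(), ay = ey.row(e).t();
  arma::vec3 d1 = g.X1 - g.X0, d2 = g.X2 - g.X0;
  double m11 = arma::dot(ax, d1), m12 = arma::dot(ax, d2);
  double m21 = arma::dot(ay, d1), m22 = arma::dot(ay, d2);
  double det = m11 * m22 - m12 * m21;
  if (det <= 0.0)
    stop("element %d: non-positive reference area in local frame", e + 1);
  g.area = 0.5 * det;
  g.B[0] = m22 / det;  g.B[1] = -m12 / det;
  g.B[2] = -m21 / det; g.B[3] = m11 / det;
  return g;
}

// Assemble global residual (internal - external) and optionally the tangent
// by central finite differencing of the exact element force (captures
// material, geometric and follower-pressure stiffness).
// mat_params: n_elem x 5 (MR uses cols 0..2 as C10,C01,D1; HGO cols
// 0..4 as C10,D,k1,k2,kappa), fiber: n_elem x 2 local fiber direction.
// [[Rcpp::export]]
List membrane_assemble_cpp(const arma::mat& nodes, const arma::imat& tris,
                           const arma::vec& u, double thickness,
                           int mat_case, const arma::mat& mat_params,
                           const arma::mat& fiber,
                           double pressure,
                           const arma::mat& ex, const arma::mat& ey,
                           bool want_tangent) {
  int ne = tris.n_rows, nn = nodes.n_rows;
  arma::vec R(3 * nn, arma::fill::zeros);
  double Wtot = 0.0;
  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (want_tangent) { ti.reserve(ne * 81); tj.reserve(ne * 81); tx.reserve(ne * 81); }
  double f[9], fp[9], fm[9], Wdum;
  for (int e = 0; e < ne; ++e) {
    ElemGeom g = make_geom(nodes, tris, ex, ey, e);
    int idx[3] = {(int)tris(e, 0), (int)tris(e, 1), (int)tris(e, 2)};
    double ue[9];
    for (int a = 0; a < 3; ++a)
      for (int c = 0; c < 3; ++c) ue[3 * a + c] = u[3 * idx[a] + c];
    const double* mp = mat_params.colptr(0) + 0; // column-major; index manually
    double mpe[5], a0e[2];
    for (int j = 0; j < 5; ++j) mpe[j] = mat_params(e, j);
    a0e[0] = fiber(e, 0); a0e[1] = fiber(e, 1);
    (void)mp;
    double We;
    elem_force(g, ue, mat_case, mpe, a0e, thickness, pressure, f, &We, e);
    Wtot += We;
    for (int a = 0; a < 3; ++a)
      for (int c = 0; c < 3; ++c) R[3 * idx[a] + c] += f[3 * a + c];
    if (want_tangent) {
      double h = 1e-6 * std::sqrt(g.area);
      double Ke[81];
      double up[9];
      for (int d = 0; d < 9; ++d) {
        std::memcpy(up, ue, sizeof(up));
        up[d] = ue[d] + h;
        elem_force(g, up, mat_case, mpe, a0e, thickness, pressure, fp, &Wdum, e);
        up[d] = ue[d] - h;
        elem_force(g, up, mat_case, mpe, a0e, thickness, pressure, fm, &Wdum, e);
        for (int r = 0; r < 9; ++r) Ke[9 * r + d] = (fp[r] - fm[r]) / (2.0 * h);
      }
      for (int ra = 0; ra < 3; ++ra)
        for (int rc = 0; rc < 3; ++rc)
          for (int ca = 0; ca < 3; ++ca)
            for (int cc = 0; cc < 3; ++cc) {
              ti.push_back(3 * idx[ra] + rc + 1);
              tj.push_back(3 * idx[ca] + cc + 1);
              tx.push_back(Ke[9 * (3 * ra + rc) + (3 * ca + cc)]);
            }
    }
  }
  List out = List::create(_["residual"] = R, _["energy"] = Wtot);
  if (want_tangent) {
    // assemble the sparse tangent here (batch insertion with duplicate
    // accumulation) to avoid R-side triplet handling on every iteration
    arma::umat loc(2, ti.size());
    arma::vec vals(tx.size());
    for (size_t q = 0; q < ti.size(); ++q) {
      loc(0, q) = ti[q] - 1;
      loc(1, q) = tj[q] - 1;
      vals[q] = tx[q];
    }
    arma::sp_mat K(true, loc, vals, 3 * nn, 3 * nn);
    out["tangent"] = K;
  }
  return out;
}

// Per-element deformation fields at a given displacement: C2d components,
// thickness stretch, energy density, in-plane 2nd PK stress, principal
// technical strains with global direction vectors, principal Cauchy stresses.
// [[Rcpp::export]]
List element_fields_cpp(const arma::mat& nodes, const arma::imat& tris,
                        const arma::vec& u, double thickness,
                        int mat_case, const arma::mat& mat_params,
                        const arma::mat& fiber,
                        const arma::mat& ex, const arma::mat& ey) {
  int ne = tris.n_rows;
  arma::mat C2dout(ne, 3), Sout(ne, 3), dir_major(ne, 3), dir_minor(ne, 3),
      sig_p(ne, 2);
  arma::vec lam3(ne), Wv(ne), eps_major(ne), eps_minor(ne);
  for (int e = 0; e < ne; ++e) {
    ElemGeom g = make_geom(nodes, tris, ex, ey, e);
    int idx[3] = {(int)tris(e, 0), (int)tris(e, 1), (int)tris(e, 2)};
    arma::vec3 x0 = g.X0, x1 = g.X1, x2 = g.X2;
    for (int c = 0; c < 3; ++c) {
      x0[c] += u[3 * idx[0] + c];
      x1[c] += u[3 * idx[1] + c];
      x2[c] += u[3 * idx[2] + c];
    }
    arma::vec3 e1 = x1 - x0, e2 = x2 - x0;
    arma::vec3 F1 = e1 * g.B[0] + e2 * g.B[2];
    arma::vec3 F2 = e1 * g.B[1] + e2 * g.B[3];
    double C2d[3] = {arma::dot(F1, F1), arma::dot(F2, F2), arma::dot(F1, F2)};
    double S[3], W, l3;
    if (mat_case == 0) {
      double mp[3] = {mat_params(e, 0), mat_params(e, 1), mat_params(e, 2)};
      mr_eval(C2d, mp[0], mp[1], mp[2], S, &W, &l3, e);
    } else if (mat_case == 1) {
      double a0e[2] = {fiber(e, 0), fiber(e, 1)};
      hgo_eval(C2d, mat_params(e, 0), mat_params(e, 2), mat_params(e, 3),
               mat_params(e, 4), a0e, S, &W, &l3, e);
    } else {
      S[0] = S[1] = S[2] = 0.0; W = 0.0; l3 = 1.0;
    }
    C2dout(e, 0) = C2d[0]; C2dout(e, 1) = C2d[1]; C2dout(e, 2) = C2d[2];
    Sout(e, 0) = S[0]; Sout(e, 1) = S[1]; Sout(e, 2) = S[2];
    lam3[e] = l3; Wv[e] = W;
    // principal stretches of C2d (closed-form symmetric 2x2 eigensolve)
    double tr = C2d[0] + C2d[1];
    double dd = std::sqrt(std::max(0.0, 0.25 * (C2d[0] - C2d[1]) * (C2d[0] - C2d[1]) + C2d[2] * C2d[2]));
    double cmax = 0.5 * tr + dd, cmin = 0.5 * tr - dd;
    eps_major[e] = std::sqrt(std::max(cmax, 0.0)) - 1.0;
    eps_minor[e] = std::sqrt(std::max(cmin, 0.0)) - 1.0;
    double v1, v2;  // eigvec of cmax in local 2D
    if (dd < 1e-14) { v1 = 1.0; v2 = 0.0; }
    else if (std::abs(C2d[2]) > 1e-14 * std::abs(tr)) { v1 = C2d[2]; v2 = cmax - C2d[0]; }
    else if (C2d[0] >= C2d[1]) { v1 = 1.0; v2 = 0.0; }
    else { v1 = 0.0; v2 = 1.0; }
    double nv = std::sqrt(v1 * v1 + v2 * v2);
    v1 /= nv; v2 /= nv;
    arma::vec3 ax = ex.row(e).t(), ay = ey.row(e).t();
    arma::vec3 dM = v1 * ax + v2 * ay, dm = -v2 * ax + v1 * ay;
    for (int c = 0; c < 3; ++c) { dir_major(e, c) = dM[c]; dir_minor(e, c) = dm[c]; }
    // principal in-plane Cauchy stress: sigma = (1/J) F S F^T, J = sqrt(det2)*l3
    double det2 = C2d[0] * C2d[1] - C2d[2] * C2d[2];
    double J = std::sqrt(std::max(det2, 0.0)) * l3;
    arma::mat33 sig;
    sig.zeros();
    if (J > 0) {
      sig = (S[0] * F1 * F1.t() + S[1] * F2 * F2.t() +
             S[2] * (F1 * F2.t() + F2 * F1.t())) / J;
    }
    arma::vec3 eval;
    arma::mat33 evec;
    arma::eig_sym(eval, evec, sig);
    sig_p(e, 0) = eval[2]; sig_p(e, 1) = eval[1]; // two in-plane values
    // smallest-magnitude eigenvalue is the (zero) normal one for rank-2 sig;
    // order: eval ascending; pick the two of largest magnitude, keep order
    double cand[3] = {eval[0], eval[1], eval[2]};
    int drop = 0;
    for (int q = 1; q < 3; ++q) if (std::abs(cand[q]) < std::abs(cand[drop])) drop = q;
    std::vector<double> keep;
    for (int q = 0; q < 3; ++q) if (q != drop) keep.push_back(cand[q]);
    sig_p(e, 0) = std::max(keep[0], keep[1]);
    sig_p(e, 1) = std::min(keep[0], keep[1]);
  }
  return List::create(_["C2d"] = C2dout, _["S"] = Sout, _["lambda3"] = lam3,
                      _["W"] = Wv, _["eps_major"] = eps_major,
                      _["eps_minor"] = eps_minor, _["dir_major"] = dir_major,
                      _["dir_minor"] = dir_minor, _["sigma_principal"] = sig_p);
}

// ---------------------------------------------------------------------------
// Heterogeneous isotropic linear-elastic membrane stiffness
// ---------------------------------------------------------------------------

// CST membrane element matrices in the reference local frame, mapped to
// global dofs. Returns triplets for K and, on request, per-element gradient
// accumulations for the adjoint method.
// [[Rcpp::export]]
List linear_stiffness_cpp(const arma::mat& nodes, const arma::imat& tris,
                          double thickness,
                          const arma::vec& E, const arma::vec& nu,
                          const arma::mat& ex, const arma::mat& ey) {
  int ne = tris.n_rows;
  IntegerVector ti(ne * 81), tj(ne * 81);
  NumericVector tx(ne * 81);
  int pos = 0;
  for (int e = 0; e < ne; ++e) {
    ElemGeom g = make_geom(nodes, tris, ex, ey, e);
    int idx[3] = {(int)tris(e, 0), (int)tris(e, 1), (int)tris(e, 2)};
    arma::vec3 ax = ex.row(e).t(), ay = ey.row(e).t();
    // local 2D node coords
    double px[3], py[3];
    px[0] = 0; py[0] = 0;
    arma::vec3 d1 = g.X1 - g.X0, d2 = g.X2 - g.X0;
    px[1] = arma::dot(ax, d1); py[1] = arma::dot(ay, d1);
    px[2] = arma::dot(ax, d2); py[2] = arma::dot(ay, d2);
    double A2 = 2.0 * g.area;
    double bb[3] = {py[1] - py[2], py[2] - py[0], py[0] - py[1]};
    double cc[3] = {px[2] - px[1], px[0] - px[2], px[1] - px[0]};
    arma::mat B(3, 6, arma::fill::zeros);
    for (int a = 0; a < 3; ++a) {
      B(0, 2 * a) = bb[a] / A2;
      B(1, 2 * a + 1) = cc[a] / A2;
      B(2, 2 * a) = cc[a] / A2;
      B(2, 2 * a + 1) = bb[a] / A2;
    }
    double f = E[e] / (1.0 - nu[e] * nu[e]);
    arma::mat33 D = {{f, f * nu[e], 0}, {f * nu[e], f, 0}, {0, 0, f * (1.0 - nu[e]) / 2.0}};
    arma::mat T(6, 9, arma::fill::zeros);
    for (int a = 0; a < 3; ++a)
      for (int c = 0; c < 3; ++c) {
        T(2 * a, 3 * a + c) = ax[c];
        T(2 * a + 1, 3 * a + c) = ay[c];
      }
    arma::mat Ke = g.area * thickness * T.t() * B.t() * D * B * T;
    for (int ra = 0; ra < 3; ++ra)
      for (int rc = 0; rc < 3; ++rc)
        for (int ca = 0; ca < 3; ++ca)
          for (int cc2 = 0; cc2 < 3; ++cc2) {
            ti[pos] = 3 * idx[ra] + rc + 1;
            tj[pos] = 3 * idx[ca] + cc2 + 1;
            tx[pos] = Ke(3 * ra + rc, 3 * ca + cc2);
            ++pos;
          }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx);
}

// Adjoint gradient accumulations: for each element e,
//   grad_E[e]  = -sum_s lam_s^T (dK/dE_e)  u_s = -sum_s lam_e^T (K_e/E_e) u_e
//   grad_nu[e] = -sum_s lam_s^T (dK/dnu_e) u_s
// U and Lam are 3n x nstage matrices (Lam zero at constrained dofs).
// [[Rcpp::export]]
List linear_grad_terms_cpp(const arma::mat& nodes, const arma::imat& tris,
                           double thickness,
                           const arma::vec& E, const arma::vec& nu,
                           const arma::mat& ex, const arma::mat& ey,
                           const arma::mat& U, const arma::mat& Lam) {
  int ne = tris.n_rows, ns = U.n_cols;
  arma::vec gE(ne, arma::fill::zeros), gnu(ne, arma::fill::zeros);
  for (int e = 0; e < ne; ++e) {
    ElemGeom g = make_geom(nodes, tris, ex, ey, e);
    int idx[3] = {(int)tris(e, 0), (int)tris(e, 1), (int)tris(e, 2)};
    arma::vec3 ax = ex.row(e).t(), ay = ey.row(e).t();
    double px[3], py[3];
    px[0] = 0; py[0] = 0;
    arma::vec3 d1 = g.X1 - g.X0, d2 = g.X2 - g.X0;
    px[1] = arma::dot(ax, d1); py[1] = arma::dot(ay, d1);
    px[2] = arma::dot(ax, d2); py[2] = arma::dot(ay, d2);
    double A2 = 2.0 * g.area;
    double bb[3] = {py[1] - py[2], py[2] - py[0], py[0] - py[1]};
    double cc[3] = {px[2] - px[1], px[0] - px[2], px[1] - px[0]};
    arma::mat B(3, 6, arma::fill::zeros);
    for (int a = 0; a < 3; ++a) {
      B(0, 2 * a) = bb[a] / A2;
      B(1, 2 * a + 1) = cc[a] / A2;
      B(2, 2 * a) = cc[a] / A2;
      B(2, 2 * a + 1) = bb[a] / A2;
    }
    double om = 1.0 - nu[e] * nu[e];
    double f = E[e] / om;
    arma::mat33 M1 = {{1, nu[e], 0}, {nu[e], 1, 0}, {0, 0, (1.0 - nu[e]) / 2.0}};
    arma::mat33 dM1 = {{0, 1, 0}, {1, 0, 0}, {0, 0, -0.5}};
    arma::mat33 D = f * M1;
    arma::mat33 dDnu = E[e] * (2.0 * nu[e] / (om * om) * M1 + dM1 / om);
    arma::mat T(6, 9, arma::fill::zeros);
    for (int a = 0; a < 3; ++a)
      for (int c = 0; c < 3; ++c) {
        T(2 * a, 3 * a + c) = ax[c];
        T(2 * a + 1, 3 * a + c) = ay[c];
      }
    arma::mat G = g.area * thickness * (B * T);   // 3x9 strain operator
    for (int s = 0; s < ns; ++s) {
      arma::vec ue(9), le(9);
      for (int a = 0; a < 3; ++a)
        for (int c = 0; c < 3; ++c) {
          ue[3 * a + c] = U(3 * idx[a] + c, s);
          le[3 * a + c] = Lam(3 * idx[a] + c, s);
        }
      arma::vec3 eps_u = (B * T) * ue;
      arma::vec3 eps_l = (B * T) * le;
      double common = g.area * thickness;
      gE[e]  -= common * arma::dot(eps_l, (D / E[e]) * eps_u);
      gnu[e] -= common * arma::dot(eps_l, dDnu * eps_u);
    }
    (void)G;
  }
  return List::create(_["grad_E"] = gE, _["grad_nu"] = gnu);
}

// Reference-configuration pressure load (consistent with the geometrically
// linear heterogeneous model): p/3 of each element's reference normal.
// [[Rcpp::export]]
arma::vec reference_pressure_load_cpp(const arma::mat& nodes,
                                      const arma::imat& tris,
                                      double pressure) {
  int nn = nodes.n_rows, ne = tris.n_rows;
  arma::vec f(3 * nn, arma::fill::zeros);
  for (int e = 0; e < ne; ++e) {
    int i0 = tris(e, 0), i1 = tris(e, 1), i2 = tris(e, 2);
    arma::vec3 d1 = nodes.row(i1).t() - nodes.row(i0).t();
    arma::vec3 d2 = nodes.row(i2).t() - nodes.row(i0).t();
    arma::vec3 n = 0.5 * arma::cross(d1, d2);
    for (int c = 0; c < 3; ++c) {
      f[3 * i0 + c] += pressure * n[c] / 3.0;
      f[3 * i1 + c] += pressure * n[c] / 3.0;
      f[3 * i2 + c] += pressure * n[c] / 3.0;
    }
  }
  return f;
}

// ---------------------------------------------------------------------------
// Brute-force k-nearest neighbors (ties broken by reference index order)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix knn_cpp(const arma::mat& ref, const arma::mat& query, int k) {
  int N = ref.n_rows, Q = query.n_rows;
  if (k < 1 || k > N) stop("k must be between 1 and the number of reference points");
  IntegerMatrix out(Q, k);
  std::vector<std::pair<double, int> > d(N);
  for (int q = 0; q < Q; ++q) {
    for (int i = 0; i < N; ++i) {
      double dx = ref(i, 0) - query(q, 0);
      double dy = ref(i, 1) - query(q, 1);
      double dz = ref(i, 2) - query(q, 2);
      d[i] = std::make_pair(dx * dx + dy * dy + dz * dz, i);
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int j = 0; j < k; ++j) out(q, j) = d[j].second + 1;
  }
  return out;
}
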