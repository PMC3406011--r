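// Core numerics: transversely isotropic hyperelastic constitutive law with a
// rank-one active fiber stress, and total-Lagrangian assembly of the
// axisymmetric (r, phi, z) finite-element equations on 9-node biquadratic
// meridional elements.  Kinematics: a material point (R, Theta, Z) maps to
// (r(R,Z), Theta + phi(R,Z), z(R,Z)); in the rotating cylindrical bases the
// deformation gradient is
//   F = [ r_R      0     r_Z  ]
//       [ r phi_R  r/R   r phi_Z ]
//       [ z_R      0     z_Z  ]
// which also carries rigid rotations about the axis into the identity, so the
// constitutive law sees an objective strain.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

static const double GP3x[3] = {-0.7745966692414834, 0.0, 0.7745966692414834};
static const double GP3w[3] = {5.0 / 9.0, 8.0 / 9.0, 5.0 / 9.0};
static const double GP2x[2] = {-0.5773502691896257, 0.5773502691896257};
static const double GP2w[2] = {1.0, 1.0};

static inline void shape1(double x, double* N, double* dN) {
  N[0] = x * (x - 1.0) / 2.0; N[1] = 1.0 - x * x; N[2] = x * (x + 1.0) / 2.0;
  dN[0] = x - 0.5; dN[1] = -2.0 * x; dN[2] = x + 0.5;
}

// 9-node shape functions, local order: xi (transmural) fastest, then eta.
static inline void shape9(double xi, double eta, double* N,
                          double* dNxi, double* dNeta) {
  double nx[3], dnx[3], ny[3], dny[3];
  shape1(xi, nx, dnx); shape1(eta, ny, dny);
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i) {
      N[j * 3 + i] = nx[i] * ny[j];
      dNxi[j * 3 + i] = dnx[i] * ny[j];
      dNeta[j * 3 + i] = nx[i] * dny[j];
    }
}

struct Material {
  double a0, a1, af0, af1, kappa;
  double vol_stab;  // fraction of the penalty integrated at the full rule
};

static Material mat_from(const vec& p) {
  Material m;
  m.a0 = p[0]; m.a1 = p[1]; m.af0 = p[2]; m.af1 = p[3]; m.kappa = p[4];
  m.vol_stab = p.n_elem > 5 ? p[5] : 0.0;
  return m;
}

// Deviatoric/fiber part of the 2nd Piola-Kirchhoff stress (no volumetric
// penalty; that part is integrated separately, reduced, to avoid locking).
// The active fiber Cauchy stress sigma_a is evaluated from the *current*
// fiber stretch through the series-elastic element:
//   sigma_a = max(0, amp * (lambda_f ls0 - l_c) / lse0),
// where amp = T0 f_iso(l_c) f_twitch(t_a, l_s) and l_c are held fixed
// during a solve.  Keeping the stretch dependence implicit puts the (stiff)
// SE compliance into the tangent, which is essential for stable coupling.
static double sigma_active(const mat& C, const vec& ef0, double amp,
                           double lc, double ls0, double lse0,
                           double& lf2) {
  lf2 = arma::as_scalar(ef0.t() * C * ef0);
  if (amp <= 0.0) return 0.0;
  double ls = std::sqrt(lf2) * ls0;
  double sa = amp * (ls - lc) / lse0;
  return sa > 0.0 ? sa : 0.0;
}

static void S_dev(const mat& E, const vec& ef0, const Material& mp,
                  double amp, double lc, double ls0, double lse0, mat& S) {
  double trE2 = arma::accu(E % E);
  double Ef = arma::as_scalar(ef0.t() * E * ef0);
  S = 2.0 * mp.a0 * mp.a1 * std::exp(mp.a1 * trE2) * E;
  double cf = 2.0 * mp.af0 * mp.af1 * Ef * std::exp(mp.af1 * Ef * Ef);
  S += cf * (ef0 * ef0.t());
  mat C = 2.0 * E + arma::eye(3, 3);
  double lf2;
  double sa = sigma_active(C, ef0, amp, lc, ls0, lse0, lf2);
  if (sa > 0.0) {
    double J = std::sqrt(std::max(0.0, arma::det(C)));
    S += (sa * J / lf2) * (ef0 * ef0.t());
  }
}

// Volumetric penalty stress S_vol = kappa (J - 1) J C^{-1}
static void S_vol(const mat& E, const Material& mp, mat& S) {
  mat C = 2.0 * E + arma::eye(3, 3);
  double detC = arma::det(C);
  if (detC <= 0.0) { S = arma::zeros(3, 3); return; }
  double J = std::sqrt(detC);
  S = mp.kappa * (J - 1.0) * J * arma::inv_sympd(arma::symmatu(C));
}

// [[Rcpp::export]]
double cpp_passive_energy(const arma::mat& E, const arma::vec& ef0,
                          const arma::vec& pas) {
  Material mp = mat_from(pas);
  double trE2 = arma::accu(E % E);
  double Ef = arma::as_scalar(ef0.t() * E * ef0);
  mat C = 2.0 * E + arma::eye(3, 3);
  double J = std::sqrt(std::max(0.0, arma::det(C)));
  return mp.a0 * (std::exp(mp.a1 * trE2) - 1.0) +
         mp.af0 * (std::exp(mp.af1 * Ef * Ef) - 1.0) +
         0.5 * mp.kappa * (J - 1.0) * (J - 1.0);
}

// [[Rcpp::export]]
arma::mat cpp_S_pk2(const arma::mat& E, const arma::vec& ef0,
                    const arma::vec& pas, double sigma_a) {
  Material mp = mat_from(pas);
  mat Sd, Sv;
  S_dev(E, ef0, mp, 0.0, 0.0, 1.0, 1.0, Sd);
  S_vol(E, mp, Sv);
  if (sigma_a != 0.0) {
    mat C = 2.0 * E + arma::eye(3, 3);
    double J = std::sqrt(std::max(0.0, arma::det(C)));
    double lf2 = arma::as_scalar(ef0.t() * C * ef0);
    Sd += (sigma_a * J / lf2) * (ef0 * ef0.t());
  }
  return Sd + Sv;
}

// [[Rcpp::export]]
arma::mat cpp_cauchy(const arma::mat& F, const arma::vec& ef0,
                     const arma::vec& pas, double sigma_a) {
  double J = arma::det(F);
  if (J <= 0.0) stop("inverted deformation state: det F <= 0");
  mat E = 0.5 * (F.t() * F - arma::eye(3, 3));
  mat S = cpp_S_pk2(E, ef0, pas, sigma_a);
  return F * S * F.t() / J;
}

// ---------------------------------------------------------------------------
// Element kinematics helpers

struct GpGeom {
  double N[9], NR[9], NZ[9];  // shape fns and derivatives wrt (R, Z)
  double R, detJ0, w;         // reference radius, Jacobian, quadrature weight
};

// Precompute reference-geometry data for one element at a quadrature rule.
static void element_gps(const mat& xy, int nq, const double* qx,
                        const double* qw, std::vector<GpGeom>& gps) {
  gps.clear();
  double N[9], dxi[9], deta[9];
  for (int q2 = 0; q2 < nq; ++q2)
    for (int q1 = 0; q1 < nq; ++q1) {
      shape9(qx[q1], qx[q2], N, dxi, deta);
      double J00 = 0, J01 = 0, J10 = 0, J11 = 0, R = 0;
      for (int a = 0; a < 9; ++a) {
        J00 += dxi[a] * xy(a, 0);  J01 += dxi[a] * xy(a, 1);
        J10 += deta[a] * xy(a, 0); J11 += deta[a] * xy(a, 1);
        R += N[a] * xy(a, 0);
      }
      double det = J00 * J11 - J01 * J10;
      GpGeom g;
      double i00 = J11 / det, i01 = -J01 / det, i10 = -J10 / det, i11 = J00 / det;
      for (int a = 0; a < 9; ++a) {
        g.N[a] = N[a];
        g.NR[a] = dxi[a] * i00 + deta[a] * i10;
        g.NZ[a] = dxi[a] * i01 + deta[a] * i11;
      }
      g.R = R; g.detJ0 = det; g.w = qw[q1] * qw[q2];
      gps.push_back(g);
    }
}

// Deformation gradient at a quadrature point from element DOFs
// d (27: per node u_r, phi, u_z).  Returns false if R is (numerically) on
// the axis and the 0/0 limit had to be used for F(1,1).
static void gp_F(const GpGeom& g, const double* d, mat& F, double& r,
                 double& phR, double& phZ) {
  double ur = 0, urR = 0, urZ = 0, uzR = 0, uzZ = 0;
  phR = 0; phZ = 0;
  for (int a = 0; a < 9; ++a) {
    ur += g.N[a] * d[3 * a];
    urR += g.NR[a] * d[3 * a];  urZ += g.NZ[a] * d[3 * a];
    phR += g.NR[a] * d[3 * a + 1]; phZ += g.NZ[a] * d[3 * a + 1];
    uzR += g.NR[a] * d[3 * a + 2]; uzZ += g.NZ[a] * d[3 * a + 2];
  }
  r = g.R + ur;
  F.zeros(3, 3);
  F(0, 0) = 1.0 + urR; F(0, 2) = urZ;
  F(1, 0) = r * phR;   F(1, 2) = r * phZ;
  F(1, 1) = (g.R > 1e-9) ? r / g.R : 1.0 + urR;
  F(2, 0) = uzR;       F(2, 2) = 1.0 + uzZ;
}

// Internal-force contribution of one quadrature point: f_a += (F S) : dF_a,
// with dF_a the derivative of F wrt nodal DOF a:
//   du_a: [[NR,0,NZ],[N phR, N/R, N phZ],[0,0,0]]
//   dphi_a: [[0,0,0],[r NR, 0, r NZ],[0,0,0]]
//   duz_a: [[0,0,0],[0,0,0],[NR,0,NZ]]
static inline void add_fint(const GpGeom& g, const mat& F, const mat& S,
                            double r, double phR, double phZ,
                            double scale, double* fe) {
  mat G = F * S;  // 3x3
  double invR = (g.R > 1e-9) ? 1.0 / g.R : 0.0;
  for (int a = 0; a < 9; ++a) {
    fe[3 * a] += scale * (G(0, 0) * g.NR[a] + G(0, 2) * g.NZ[a] +
                          g.N[a] * (G(1, 0) * phR + G(1, 2) * phZ +
                                    G(1, 1) * invR));
    fe[3 * a + 1] += scale * (G(1, 0) * r * g.NR[a] + G(1, 2) * r * g.NZ[a]);
    fe[3 * a + 2] += scale * (G(2, 0) * g.NR[a] + G(2, 2) * g.NZ[a]);
  }
}

// Residual (internal forces) of one element; d has 27 entries.
// sig_act: active fiber Cauchy stress at the 3x3 quadrature points.
// fib: 9x3 nodal fiber vectors (r, c, z components).
// ---- scalar (allocation-free) versions for the assembly hot loop --------
// 3x3 matrices as double[9], row-major.

static inline double det3(const double* A) {
  return A[0] * (A[4] * A[8] - A[5] * A[7]) -
         A[1] * (A[3] * A[8] - A[5] * A[6]) +
         A[2] * (A[3] * A[7] - A[4] * A[6]);
}

// symmetric inverse of a symmetric 3x3 (row-major), given its determinant
static inline void inv3_sym(const double* A, double det, double* Y) {
  double id = 1.0 / det;
  Y[0] = (A[4] * A[8] - A[5] * A[7]) * id;
  Y[1] = (A[2] * A[7] - A[1] * A[8]) * id;
  Y[2] = (A[1] * A[5] - A[2] * A[4]) * id;
  Y[3] = Y[1];
  Y[4] = (A[0] * A[8] - A[2] * A[6]) * id;
  Y[5] = (A[2] * A[3] - A[0] * A[5]) * id;
  Y[6] = Y[2];
  Y[7] = Y[5];
  Y[8] = (A[0] * A[4] - A[1] * A[3]) * id;
}

struct GpF {
  double F[9];      // row-major deformation gradient
  double r, phR, phZ;
};

static inline void gp_F_raw(const GpGeom& g, const double* d, GpF& o) {
  double ur = 0, urR = 0, urZ = 0, uzR = 0, uzZ = 0, phR = 0, phZ = 0;
  for (int a = 0; a < 9; ++a) {
    ur += g.N[a] * d[3 * a];
    urR += g.NR[a] * d[3 * a];  urZ += g.NZ[a] * d[3 * a];
    phR += g.NR[a] * d[3 * a + 1]; phZ += g.NZ[a] * d[3 * a + 1];
    uzR += g.NR[a] * d[3 * a + 2]; uzZ += g.NZ[a] * d[3 * a + 2];
  }
  double r = g.R + ur;
  o.r = r; o.phR = phR; o.phZ = phZ;
  o.F[0] = 1.0 + urR; o.F[1] = 0.0;                        o.F[2] = urZ;
  o.F[3] = r * phR;   o.F[4] = (g.R > 1e-9) ? r / g.R : 1.0 + urR;
  o.F[5] = r * phZ;
  o.F[6] = uzR;       o.F[7] = 0.0;                        o.F[8] = 1.0 + uzZ;
}

// f_a += (F S) : dF_a at one quadrature point (S symmetric, row-major)
static inline void add_fint_raw(const GpGeom& g, const GpF& k,
                                const double* S, double scale, double* fe) {
  const double* F = k.F;
  double G[9];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      G[3 * i + j] = F[3 * i] * S[j] + F[3 * i + 1] * S[3 + j] +
                     F[3 * i + 2] * S[6 + j];
  double invR = (g.R > 1e-9) ? 1.0 / g.R : 0.0;
  double c_u = G[3] * k.phR + G[5] * k.phZ + G[4] * invR;
  for (int a = 0; a < 9; ++a) {
    fe[3 * a] += scale * (G[0] * g.NR[a] + G[2] * g.NZ[a] + g.N[a] * c_u);
    fe[3 * a + 1] += scale * (G[3] * k.r * g.NR[a] + G[5] * k.r * g.NZ[a]);
    fe[3 * a + 2] += scale * (G[6] * g.NR[a] + G[8] * g.NZ[a]);
  }
}

static bool element_fint(const std::vector<GpGeom>& gps_full,
                         const std::vector<GpGeom>& gps_red,
                         const mat& fib, const vec& amp, const vec& lc,
                         double ls0, double lse0,
                         const Material& mp, const double* d, double* fe) {
  GpF k;
  double C[9], E[9], S[9], Ci[9], ef[3];
  for (int a = 0; a < 27; ++a) fe[a] = 0.0;
  // deviatoric + fiber + active at full 3x3 quadrature, plus the
  // stabilizing fraction of the volumetric penalty
  for (size_t q = 0; q < gps_full.size(); ++q) {
    const GpGeom& g = gps_full[q];
    gp_F_raw(g, d, k);
    double detF = det3(k.F);
    if (detF <= 0.0 || !std::isfinite(detF)) return false;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double cij = k.F[i] * k.F[j] + k.F[3 + i] * k.F[3 + j] +
                     k.F[6 + i] * k.F[6 + j];
        C[3 * i + j] = cij;
        E[3 * i + j] = 0.5 * (cij - (i == j ? 1.0 : 0.0));
      }
    ef[0] = ef[1] = ef[2] = 0.0;
    for (int a = 0; a < 9; ++a)
      for (int c = 0; c < 3; ++c) ef[c] += g.N[a] * fib(a, c);
    double nrm = std::sqrt(ef[0] * ef[0] + ef[1] * ef[1] + ef[2] * ef[2]);
    ef[0] /= nrm; ef[1] /= nrm; ef[2] /= nrm;
    double trE2 = 0.0, Ef = 0.0;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        trE2 += E[3 * i + j] * E[3 * i + j];
        Ef += ef[i] * E[3 * i + j] * ef[j];
      }
    double c_iso = 2.0 * mp.a0 * mp.a1 * std::exp(mp.a1 * trE2);
    double c_fib = 2.0 * mp.af0 * mp.af1 * Ef * std::exp(mp.af1 * Ef * Ef);
    // active series-elastic stress from the current fiber stretch
    if (amp[q] > 0.0) {
      double lf2 = 0.0;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) lf2 += ef[i] * C[3 * i + j] * ef[j];
      double sa = amp[q] * (std::sqrt(lf2) * ls0 - lc[q]) / lse0;
      if (sa > 0.0) c_fib += sa * detF / lf2;
    }
    for (int i = 0; i < 9; ++i) S[i] = c_iso * E[i];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) S[3 * i + j] += c_fib * ef[i] * ef[j];
    if (mp.vol_stab > 0.0) {
      double detC = detF * detF;
      inv3_sym(C, detC, Ci);
      double cv = mp.vol_stab * mp.kappa * (detF - 1.0) * detF;
      for (int i = 0; i < 9; ++i) S[i] += cv * Ci[i];
    }
    double scale = g.w * g.detJ0 * 2.0 * M_PI * g.R;
    add_fint_raw(g, k, S, scale, fe);
  }
  // main volumetric penalty at reduced 2x2 quadrature (avoids locking)
  for (size_t q = 0; q < gps_red.size(); ++q) {
    const GpGeom& g = gps_red[q];
    gp_F_raw(g, d, k);
    double detF = det3(k.F);
    if (detF <= 0.0 || !std::isfinite(detF)) return false;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        C[3 * i + j] = k.F[i] * k.F[j] + k.F[3 + i] * k.F[3 + j] +
                       k.F[6 + i] * k.F[6 + j];
    double detC = detF * detF;
    inv3_sym(C, detC, Ci);
    double cv = (1.0 - mp.vol_stab) * mp.kappa * (detF - 1.0) * detF;
    for (int i = 0; i < 9; ++i) S[i] = cv * Ci[i];
    double scale = g.w * g.detJ0 * 2.0 * M_PI * g.R;
    add_fint_raw(g, k, S, scale, fe);
  }
  return true;
}

// Pressure load on one endocardial edge (3 nodes, apex -> base order).
// Follower load of a uniform cavity pressure p on the revolved deformed
// surface: f[u_a] = 2 pi p int N_a r z' dxi, f[w_a] = -2 pi p int N_a r r' dxi.
// No circumferential force (pressure exerts no axial torque).
static void edge_load(const double* Re, const double* Ze, const double* d,
                      double p, double* fe) {
  for (int a = 0; a < 9; ++a) fe[a] = 0.0;
  double N[3], dN[3];
  for (int q = 0; q < 3; ++q) {
    shape1(GP3x[q], N, dN);
    double r = 0, rp = 0, zp = 0;
    for (int a = 0; a < 3; ++a) {
      double ra = Re[a] + d[3 * a], za = Ze[a] + d[3 * a + 2];
      r += N[a] * ra; rp += dN[a] * ra; zp += dN[a] * za;
    }
    for (int a = 0; a < 3; ++a) {
      fe[3 * a] += GP3w[q] * 2.0 * M_PI * p * N[a] * r * zp;
      fe[3 * a + 2] -= GP3w[q] * 2.0 * M_PI * p * N[a] * r * rp;
    }
  }
}

// [[Rcpp::export]]
List cpp_assemble(const arma::mat& nodes, const arma::imat& conn0,
                  const arma::vec& u, const arma::mat& fib,
                  const arma::mat& act_amp, const arma::mat& act_lc,
                  const arma::vec& actv, const arma::vec& pas,
                  double p_lv, const arma::imat& endo0, bool want_K) {
  Material mp = mat_from(pas);
  int nel = conn0.n_rows, nn = nodes.n_rows, ndof = 3 * nn;
  vec res(ndof, arma::fill::zeros);
  std::vector<int> Ki, Kj; std::vector<double> Kx;
  if (want_K) { Ki.reserve(nel * 729); Kj.reserve(nel * 729); Kx.reserve(nel * 729); }
  std::vector<GpGeom> gpf, gpr;
  mat xy(9, 2), fibe(9, 3);
  double d[27], fe[27], fep[27];
  bool ok = true;

  for (int e = 0; e < nel && ok; ++e) {
    for (int a = 0; a < 9; ++a) {
      int n = conn0(e, a);
      xy(a, 0) = nodes(n, 0); xy(a, 1) = nodes(n, 1);
      for (int k = 0; k < 3; ++k) fibe(a, k) = fib(n, k);
      for (int c = 0; c < 3; ++c) d[3 * a + c] = u[3 * n + c];
    }
    element_gps(xy, 3, GP3x, GP3w, gpf);
    element_gps(xy, 2, GP2x, GP2w, gpr);
    vec am = act_amp.row(e).t(), lc = act_lc.row(e).t();
    if (!element_fint(gpf, gpr, fibe, am, lc, actv[0], actv[1], mp, d, fe)) {
      ok = false; break;
    }
    for (int a = 0; a < 9; ++a) {
      int n = conn0(e, a);
      for (int c = 0; c < 3; ++c) res[3 * n + c] += fe[3 * a + c];
    }
    if (want_K) {
      for (int pdof = 0; pdof < 27; ++pdof) {
        double h = 1e-7 * std::max(1.0, std::abs(d[pdof]));
        double keep = d[pdof];
        d[pdof] = keep + h;
        if (!element_fint(gpf, gpr, fibe, am, lc, actv[0], actv[1], mp, d,
                          fep)) { ok = false; break; }
        d[pdof] = keep;
        int nb = conn0(e, pdof / 3), cb = pdof % 3;
        for (int a = 0; a < 27; ++a) {
          int na = conn0(e, a / 3), ca = a % 3;
          Ki.push_back(3 * na + ca);
          Kj.push_back(3 * nb + cb);
          Kx.push_back((fep[a] - fe[a]) / h);
        }
      }
    }
  }
  if (!ok) return List::create(Named("ok") = false);

  // pressure follower load on the endocardium (subtracted from the residual)
  int nedge = endo0.n_rows;
  double Re[3], Ze[3], de[9], fe9[9], fp9[9];
  for (int ie = 0; ie < nedge; ++ie) {
    for (int a = 0; a < 3; ++a) {
      int n = endo0(ie, a);
      Re[a] = nodes(n, 0); Ze[a] = nodes(n, 1);
      for (int c = 0; c < 3; ++c) de[3 * a + c] = u[3 * n + c];
    }
    edge_load(Re, Ze, de, p_lv, fe9);
    for (int a = 0; a < 3; ++a) {
      int n = endo0(ie, a);
      for (int c = 0; c < 3; ++c) res[3 * n + c] -= fe9[3 * a + c];
    }
    if (want_K && p_lv != 0.0) {
      for (int pdof = 0; pdof < 9; ++pdof) {
        if (pdof % 3 == 1) continue;  // no phi dependence
        double h = 1e-7 * std::max(1.0, std::abs(de[pdof]));
        double keep = de[pdof];
        de[pdof] = keep + h;
        edge_load(Re, Ze, de, p_lv, fp9);
        de[pdof] = keep;
        int nb = endo0(ie, pdof / 3), cb = pdof % 3;
        for (int a = 0; a < 9; ++a) {
          int na = endo0(ie, a / 3), ca = a % 3;
          Ki.push_back(3 * na + ca);
          Kj.push_back(3 * nb + cb);
          Kx.push_back(-(fp9[a] - fe9[a]) / h);
        }
      }
    }
  }

  List out = List::create(Named("ok") = true, Named("res") = res);
  if (want_K) {
    out["Ki"] = IntegerVector(Ki.begin(), Ki.end());
    out["Kj"] = IntegerVector(Kj.begin(), Kj.end());
    out["Kx"] = NumericVector(Kx.begin(), Kx.end());
  }
  return out;
}

// Deformed cavity volume: pi * int r^2 dz along the endocardial curve
// (apex -> base), in mm^3.
// [[Rcpp::export]]
double cpp_cavity_volume(const arma::mat& nodes, const arma::vec& u,
                         const arma::imat& endo0) {
  double V = 0.0, N[3], dN[3];
  for (unsigned ie = 0; ie < endo0.n_rows; ++ie) {
    for (int q = 0; q < 3; ++q) {
      shape1(GP3x[q], N, dN);
      double r = 0, zp = 0;
      for (int a = 0; a < 3; ++a) {
        int n = endo0(ie, a);
        r += N[a] * (nodes(n, 0) + u[3 * n]);
        zp += dN[a] * (nodes(n, 1) + u[3 * n + 2]);
      }
      V += GP3w[q] * M_PI * r * r * zp;
    }
  }
  return V;
}

// External load vector of a unit cavity pressure on the deformed
// endocardium (follower load evaluated at displacement u).
// [[Rcpp::export]]
arma::vec cpp_pressure_load(const arma::mat& nodes, const arma::vec& u,
                            const arma::imat& endo0) {
  vec L(u.n_elem, arma::fill::zeros);
  double Re[3], Ze[3], de[9], fe9[9];
  for (unsigned ie = 0; ie < endo0.n_rows; ++ie) {
    for (int a = 0; a < 3; ++a) {
      int n = endo0(ie, a);
      Re[a] = nodes(n, 0); Ze[a] = nodes(n, 1);
      for (int c = 0; c < 3; ++c) de[3 * a + c] = u[3 * n + c];
    }
    edge_load(Re, Ze, de, 1.0, fe9);
    for (int a = 0; a < 3; ++a) {
      int n = endo0(ie, a);
      for (int c = 0; c < 3; ++c) L[3 * n + c] += fe9[3 * a + c];
    }
  }
  return L;
}

// Gradient of the deformed cavity volume wrt nodal displacements:
// V = pi int r^2 z' dxi  ->  dV/du_r,a = 2 pi int r N_a z' dxi,
//                            dV/du_z,a = pi int r^2 N_a' dxi.
// [[Rcpp::export]]
arma::vec cpp_cavity_gradient(const arma::mat& nodes, const arma::vec& u,
                              const arma::imat& endo0) {
  vec g(u.n_elem, arma::fill::zeros);
  double N[3], dN[3];
  for (unsigned ie = 0; ie < endo0.n_rows; ++ie) {
    for (int q = 0; q < 3; ++q) {
      shape1(GP3x[q], N, dN);
      double r = 0, zp = 0;
      for (int a = 0; a < 3; ++a) {
        int n = endo0(ie, a);
        r += N[a] * (nodes(n, 0) + u[3 * n]);
        zp += dN[a] * (nodes(n, 1) + u[3 * n + 2]);
      }
      for (int a = 0; a < 3; ++a) {
        int n = endo0(ie, a);
        g[3 * n] += GP3w[q] * 2.0 * M_PI * r * N[a] * zp;
        g[3 * n + 2] += GP3w[q] * M_PI * r * r * dN[a];
      }
    }
  }
  return g;
}

// Per-quadrature-point state for postprocessing: deformation gradient,
// fiber stretch, det F, fiber Cauchy stress (passive+active along fiber).
// [[Rcpp::export]]
List cpp_gp_state(const arma::mat& nodes, const arma::imat& conn0,
                  const arma::vec& u, const arma::mat& fib,
                  const arma::mat& act_amp, const arma::mat& act_lc,
                  const arma::vec& actv, const arma::vec& pas) {
  Material mp = mat_from(pas);
  int nel = conn0.n_rows, ngp = 9;
  mat lambda(nel, ngp), Jdet(nel, ngp), sigf(nel, ngp), siga(nel, ngp);
  mat Fout(nel, ngp * 9);
  std::vector<GpGeom> gpf;
  mat xy(9, 2), fibe(9, 3), F(3, 3), E(3, 3), S(3, 3);
  double d[27], r, phR, phZ;
  for (int e = 0; e < nel; ++e) {
    for (int a = 0; a < 9; ++a) {
      int n = conn0(e, a);
      xy(a, 0) = nodes(n, 0); xy(a, 1) = nodes(n, 1);
      for (int k = 0; k < 3; ++k) fibe(a, k) = fib(n, k);
      for (int c = 0; c < 3; ++c) d[3 * a + c] = u[3 * n + c];
    }
    element_gps(xy, 3, GP3x, GP3w, gpf);
    for (int q = 0; q < ngp; ++q) {
      const GpGeom& g = gpf[q];
      gp_F(g, d, F, r, phR, phZ);
      double J = arma::det(F);
      E = 0.5 * (F.t() * F - arma::eye(3, 3));
      vec ef(3, arma::fill::zeros);
      for (int a = 0; a < 9; ++a)
        for (int k = 0; k < 3; ++k) ef[k] += g.N[a] * fibe(a, k);
      ef /= arma::norm(ef);
      vec Fe = F * ef;
      double lf = arma::norm(Fe);
      mat Sd, Sv;
      S_dev(E, ef, mp, act_amp(e, q), act_lc(e, q), actv[0], actv[1], Sd);
      S_vol(E, mp, Sv);
      mat sig = F * (Sd + Sv) * F.t() / J;
      vec efc = Fe / lf;
      mat C = 2.0 * E + arma::eye(3, 3);
      double lf2;
      siga(e, q) = sigma_active(C, ef, act_amp(e, q), act_lc(e, q),
                                actv[0], actv[1], lf2);
      lambda(e, q) = lf;
      Jdet(e, q) = J;
      sigf(e, q) = arma::as_scalar(efc.t() * sig * efc);
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          Fout(e, q * 9 + i * 3 + j) = F(i, j);
    }
  }
  return List::create(Named("lambda_f") = lambda, Named("J") = Jdet,
                      Named("sigma_f") = sigf, Named("sigma_a") = siga,
                      Named("F") = Fout);
}

// Deformation gradient evaluated at the element-local nodes, averaged over
// the elements sharing each node.  Returns an n x 9 matrix (row-major F).
// [[Rcpp::export]]
arma::mat cpp_F_at_nodes(const arma::mat& nodes, const arma::imat& conn0,
                         const arma::vec& u) {
  int nel = conn0.n_rows, nn = nodes.n_rows;
  mat Fsum(nn, 9, arma::fill::zeros);
  vec cnt(nn, arma::fill::zeros);
  static const double locs[3] = {-1.0, 0.0, 1.0};
  mat xy(9, 2), F(3, 3);
  double d[27], r, phR, phZ;
  for (int e = 0; e < nel; ++e) {
    for (int a = 0; a < 9; ++a) {
      int n = conn0(e, a);
      xy(a, 0) = nodes(n, 0); xy(a, 1) = nodes(n, 1);
      for (int c = 0; c < 3; ++c) d[3 * a + c] = u[3 * n + c];
    }
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i) {
        int a_loc = j * 3 + i;
        // geometry data at the nodal local coordinates
        double N[9], dxi[9], deta[9];
        shape9(locs[i], locs[j], N, dxi, deta);
        double J00 = 0, J01 = 0, J10 = 0, J11 = 0, R = 0;
        for (int a = 0; a < 9; ++a) {
          J00 += dxi[a] * xy(a, 0);  J01 += dxi[a] * xy(a, 1);
          J10 += deta[a] * xy(a, 0); J11 += deta[a] * xy(a, 1);
          R += N[a] * xy(a, 0);
        }
        double det = J00 * J11 - J01 * J10;
        GpGeom g;
        double i00 = J11 / det, i01 = -J01 / det, i10 = -J10 / det, i11 = J00 / det;
        for (int a = 0; a < 9; ++a) {
          g.N[a] = N[a];
          g.NR[a] = dxi[a] * i00 + deta[a] * i10;
          g.NZ[a] = dxi[a] * i01 + deta[a] * i11;
        }
        g.R = R;
        gp_F(g, d, F, r, phR, phZ);
        int n = conn0(e, a_loc);
        for (int ii = 0; ii < 3; ++ii)
          for (int jj = 0; jj < 3; ++jj)
            Fsum(n, ii * 3 + jj) += F(ii, jj);
        cnt[n] += 1.0;
      }
  }
  for (int n = 0; n < nn; ++n) Fsum.row(n) /= cnt[n];
  return Fsum;
}
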