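// Axisymmetric finite-deformation core: hyperelastic material point
// evaluation and element/global assembly for bilinear quadrilaterals with
// selective reduced integration of the volumetric response.
//
// Conventions
//   * local/global frame is (r, theta, z); tensors are stored row-major 3x3
//   * stresses in MPa, lengths in mm, forces in N (MPa * mm^2)
//   * material row encodings (first entry is the type code):
//       0  GOH annulus:          [0, C10, D, k1, k2, kappa, alpha_rad]
//       1  Mooney-Rivlin:        [1, C10n, C01n, D]
//       2  neo-Hookean (E, nu):  [2, mu, lambda]
//     GOH and Mooney-Rivlin use the volumetric energy
//     U = (1/D) ((J^2-1)/2 - ln J), so D = 2/K.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double det3(const double* A) {
  return A[0]*(A[4]*A[8]-A[5]*A[7])
       - A[1]*(A[3]*A[8]-A[5]*A[6])
       + A[2]*(A[3]*A[7]-A[4]*A[6]);
}

static inline void inv3(const double* A, double detA, double* Ai) {
  const double id = 1.0/detA;
  Ai[0]=(A[4]*A[8]-A[5]*A[7])*id; Ai[1]=(A[2]*A[7]-A[1]*A[8])*id; Ai[2]=(A[1]*A[5]-A[2]*A[4])*id;
  Ai[3]=(A[5]*A[6]-A[3]*A[8])*id; Ai[4]=(A[0]*A[8]-A[2]*A[6])*id; Ai[5]=(A[2]*A[3]-A[0]*A[5])*id;
  Ai[6]=(A[3]*A[7]-A[4]*A[6])*id; Ai[7]=(A[1]*A[6]-A[0]*A[7])*id; Ai[8]=(A[0]*A[4]-A[1]*A[3])*id;
}

struct MatOut {
  double psi;          // strain-energy density (MPa)
  double sig_iso[9];   // Cauchy stress minus the volumetric pressure part
  double p;            // volumetric pressure dU/dJ
  bool ok;
};

// Material point evaluation. The stress is split into an "isochoric" part
// and a pressure p so the element can integrate the two with different
// quadrature rules (selective reduced integration).
static void mat_eval(const double* F, const double* m, MatOut& o) {
  o.ok = true;
  const double J = det3(F);
  if (!(J > 1e-10)) { o.ok = false; return; }

  double b[9]; // left Cauchy-Green F F^T
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) {
      double s = 0;
      for (int k = 0; k < 3; k++) s += F[3*i+k]*F[3*j+k];
      b[3*i+j] = s;
    }

  const int type = (int)(m[0] + 0.5);

  if (type == 2) { // compressible neo-Hookean for bone / PMMA
    const double mu = m[1], la = m[2], lnJ = std::log(J);
    const double trb = b[0] + b[4] + b[8];
    for (int i = 0; i < 9; i++) o.sig_iso[i] = mu/J*b[i];
    o.sig_iso[0] -= mu/J; o.sig_iso[4] -= mu/J; o.sig_iso[8] -= mu/J;
    o.p   = la*lnJ/J;
    o.psi = 0.5*mu*(trb - 3.0) - mu*lnJ + 0.5*la*lnJ*lnJ;
    return;
  }

  const double Jm23 = std::pow(J, -2.0/3.0);
  double bb[9];
  for (int i = 0; i < 9; i++) bb[i] = Jm23*b[i];
  const double I1b = bb[0] + bb[4] + bb[8];

  double psi_iso = 0.0;
  double coef1   = 0.0;   // multiplies dev(bbar) in the Cauchy stress
  double extra[9] = {0,0,0,0,0,0,0,0,0};
  double Dvol;

  if (type == 0) { // GOH: isotropic ground matrix + two exponential fibre families
    const double C10 = m[1]; Dvol = m[2];
    const double k1 = m[3], k2 = m[4], kap = m[5], al = m[6];
    coef1   = C10;
    psi_iso = C10*(I1b - 3.0);
    const double ca = std::cos(al), sa = std::sin(al);
    const double Jm13 = std::pow(J, -1.0/3.0);
    for (int f = 0; f < 2; f++) {
      const double a[3] = {0.0, ca, (f == 0 ? sa : -sa)};
      double g[3]; // isochoric push-forward of the fibre direction
      for (int i = 0; i < 3; i++)
        g[i] = Jm13*(F[3*i+0]*a[0] + F[3*i+1]*a[1] + F[3*i+2]*a[2]);
      const double I4b = g[0]*g[0] + g[1]*g[1] + g[2]*g[2];
      // tension-only: a family contributes only when its isochoric stretch
      // exceeds one
      if (I4b > 1.0 && k1 > 0.0) {
        const double E = kap*(I1b - 3.0) + (1.0 - 3.0*kap)*(I4b - 1.0);
        if (E > 0.0) {
          const double ex = std::exp(k2*E*E);
          const double q  = k1*E*ex;
          psi_iso += k1/(2.0*k2)*(ex - 1.0);
          coef1   += kap*q;
          const double c4 = (1.0 - 3.0*kap)*q;
          const double tr3 = I4b/3.0;
          for (int i = 0; i < 3; i++)
            for (int j = 0; j < 3; j++)
              extra[3*i+j] += c4*(g[i]*g[j] - (i == j ? tr3 : 0.0));
        }
      }
    }
  } else { // Mooney-Rivlin (nucleus)
    const double c10 = m[1], c01 = m[2]; Dvol = m[3];
    double bb2[9];
    for (int i = 0; i < 3; i++)
      for (int j = 0; j < 3; j++) {
        double s = 0;
        for (int k = 0; k < 3; k++) s += bb[3*i+k]*bb[3*k+j];
        bb2[3*i+j] = s;
      }
    const double trbb2 = bb2[0] + bb2[4] + bb2[8];
    const double I2b = 0.5*(I1b*I1b - trbb2);
    psi_iso = c10*(I1b - 3.0) + c01*(I2b - 3.0);
    coef1   = c10 + c01*I1b;
    for (int i = 0; i < 3; i++)
      for (int j = 0; j < 3; j++)
        extra[3*i+j] = -c01*(bb2[3*i+j] - (i == j ? trbb2/3.0 : 0.0));
  }

  const double tr3 = I1b/3.0;
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++)
      o.sig_iso[3*i+j] = 2.0/J*(coef1*(bb[3*i+j] - (i == j ? tr3 : 0.0)) + extra[3*i+j]);
  o.p   = (J - 1.0/J)/Dvol;
  o.psi = psi_iso + ((J*J - 1.0)*0.5 - std::log(J))/Dvol;
}

//' @noRd
// [[Rcpp::export(name = ".mat_energy_cpp")]]
double mat_energy_cpp(NumericMatrix F, NumericVector m) {
  double Fc[9];
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) Fc[3*i+j] = F(i, j);
  double mc[8] = {0,0,0,0,0,0,0,0};
  for (int j = 0; j < m.size() && j < 8; j++) mc[j] = m[j];
  MatOut o;
  mat_eval(Fc, mc, o);
  if (!o.ok) stop("invalid deformation: det(F) <= 0");
  return o.psi;
}

//' @noRd
// [[Rcpp::export(name = ".mat_cauchy_cpp")]]
NumericMatrix mat_cauchy_cpp(NumericMatrix F, NumericVector m) {
  double Fc[9];
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++) Fc[3*i+j] = F(i, j);
  double mc[8] = {0,0,0,0,0,0,0,0};
  for (int j = 0; j < m.size() && j < 8; j++) mc[j] = m[j];
  MatOut o;
  mat_eval(Fc, mc, o);
  if (!o.ok) stop("invalid deformation: det(F) <= 0");
  NumericMatrix S(3, 3);
  for (int i = 0; i < 3; i++)
    for (int j = 0; j < 3; j++)
      S(i, j) = o.sig_iso[3*i+j] + (i == j ? o.p : 0.0);
  return S;
}

// Element internal force for a 4-node axisymmetric quadrilateral.
// 2x2 Gauss quadrature for the isochoric part, single centroid point for
// the volumetric part. Nodal dofs are (u_r, u_z) per node, CCW ordering.
static bool elem_fint(const double* Xr, const double* Xz, const double* ue,
                      const double* m, double* fe) {
  for (int i = 0; i < 8; i++) fe[i] = 0.0;
  const double g1 = 0.5773502691896258;
  const double XI[5] = {-g1,  g1, g1, -g1, 0.0};
  const double ET[5] = {-g1, -g1, g1,  g1, 0.0};
  const double W[5]  = {1.0, 1.0, 1.0, 1.0, 4.0};
  const double TWO_PI = 6.283185307179586476925287;

  for (int k = 0; k < 5; k++) {
    const bool vol = (k == 4);
    const double xi = XI[k], et = ET[k];
    const double N[4]   = {0.25*(1-xi)*(1-et), 0.25*(1+xi)*(1-et),
                           0.25*(1+xi)*(1+et), 0.25*(1-xi)*(1+et)};
    const double dNx[4] = {-0.25*(1-et),  0.25*(1-et), 0.25*(1+et), -0.25*(1+et)};
    const double dNe[4] = {-0.25*(1-xi), -0.25*(1+xi), 0.25*(1+xi),  0.25*(1-xi)};

    double a = 0, bj = 0, c = 0, d = 0; // dR/dxi, dZ/dxi, dR/deta, dZ/deta
    for (int i = 0; i < 4; i++) {
      a  += dNx[i]*Xr[i]; bj += dNx[i]*Xz[i];
      c  += dNe[i]*Xr[i]; d  += dNe[i]*Xz[i];
    }
    const double det2 = a*d - bj*c;
    if (!(det2 > 0)) return false;
    double dNR[4], dNZ[4];
    for (int i = 0; i < 4; i++) {
      dNR[i] = ( d*dNx[i] - bj*dNe[i])/det2;
      dNZ[i] = (-c*dNx[i] +  a*dNe[i])/det2;
    }

    double R = 0, ur = 0;
    for (int i = 0; i < 4; i++) { R += N[i]*Xr[i]; ur += N[i]*ue[2*i]; }
    if (!(R > 1e-12)) return false; // quadrature points of valid meshes stay off-axis

    double F[9] = {1,0,0, 0,1,0, 0,0,1};
    for (int i = 0; i < 4; i++) {
      F[0] += dNR[i]*ue[2*i];     F[2] += dNZ[i]*ue[2*i];
      F[6] += dNR[i]*ue[2*i+1];   F[8] += dNZ[i]*ue[2*i+1];
    }
    F[4] = 1.0 + ur/R;

    MatOut mo;
    mat_eval(F, m, mo);
    if (!mo.ok) return false;
    const double J = det3(F);
    double Fi[9];
    inv3(F, J, Fi);

    // first Piola-Kirchhoff P = J sigma F^{-T} of the part integrated here
    double P[9];
    if (!vol) {
      for (int i = 0; i < 3; i++)
        for (int j = 0; j < 3; j++) {
          double s = 0;
          for (int kk = 0; kk < 3; kk++) s += mo.sig_iso[3*i+kk]*Fi[3*j+kk];
          P[3*i+j] = J*s;
        }
    } else {
      for (int i = 0; i < 3; i++)
        for (int j = 0; j < 3; j++)
          P[3*i+j] = J*mo.p*Fi[3*j+i];
    }

    const double w = W[k]*det2*TWO_PI*R;
    for (int i = 0; i < 4; i++) {
      fe[2*i]   += w*(P[0]*dNR[i] + P[2]*dNZ[i] + P[4]*N[i]/R);
      fe[2*i+1] += w*(P[6]*dNR[i] + P[8]*dNZ[i]);
    }
  }
  return true;
}

//' @noRd
// [[Rcpp::export(name = ".fe_assemble_cpp")]]
List fe_assemble(NumericMatrix coords, IntegerMatrix conn, IntegerVector matid,
                 NumericMatrix mats, NumericVector u, bool want_K) {
  const int nn = coords.nrow(), ne = conn.nrow(), ndof = 2*nn;
  NumericVector fint(ndof);
  std::vector<int> Ki, Kj;
  std::vector<double> Kx;
  if (want_K) {
    Ki.reserve(64*ne); Kj.reserve(64*ne); Kx.reserve(64*ne);
  }
  const double h = 1e-6; // perturbation (mm) for the numerical element tangent

  for (int e = 0; e < ne; e++) {
    double Xr[4], Xz[4], ue[8];
    int nd[4];
    for (int i = 0; i < 4; i++) {
      nd[i] = conn(e, i) - 1;
      Xr[i] = coords(nd[i], 0); Xz[i] = coords(nd[i], 1);
      ue[2*i] = u[2*nd[i]]; ue[2*i+1] = u[2*nd[i]+1];
    }
    const int mi = matid[e] - 1;
    double m[8] = {0,0,0,0,0,0,0,0};
    for (int j = 0; j < mats.ncol() && j < 8; j++) m[j] = mats(mi, j);

    double fe[8];
    if (!elem_fint(Xr, Xz, ue, m, fe))
      return List::create(_["ok"] = false);
    for (int i = 0; i < 4; i++) {
      fint[2*nd[i]]   += fe[2*i];
      fint[2*nd[i]+1] += fe[2*i+1];
    }
    if (want_K) {
      double up[8], fp[8];
      for (int j = 0; j < 8; j++) {
        for (int q = 0; q < 8; q++) up[q] = ue[q];
        up[j] += h;
        if (!elem_fint(Xr, Xz, up, m, fp))
          return List::create(_["ok"] = false);
        const int gj = 2*nd[j/2] + (j % 2);
        for (int i = 0; i < 8; i++) {
          const int gi = 2*nd[i/2] + (i % 2);
          Ki.push_back(gi + 1);
          Kj.push_back(gj + 1);
          Kx.push_back((fp[i] - fe[i])/h);
        }
      }
    }
  }
  if (want_K)
    return List::create(_["ok"] = true, _["fint"] = fint,
                        _["Ki"] = wrap(Ki), _["Kj"] = wrap(Kj),
                        _["Kx"] = wrap(Kx), _["ndof"] = ndof);
  return List::create(_["ok"] = true, _["fint"] = fint);
}
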