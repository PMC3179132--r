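// Compiled core: pair-potential kernels, Ewald summation, interaction grids,
// and the three Monte Carlo engines (dimer annealing, NPT liquid, GCMC
// adsorption). Internal units throughout: Angstrom, kJ/mol, elementary
// charge, Kelvin. All randomness comes from R's RNG (seed with set.seed()).
#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <complex>
#include <unordered_set>
using namespace Rcpp;

static const double COULK = 1389.35457644382; // kJ A / (mol e^2)
static const double KB = 0.008314462618;      // kJ / (mol K)
static const double PI = 3.14159265358979323846;

inline double mimg(double d, double L) {
  if (L > 0.0) d -= L * std::nearbyint(d / L);
  return d;
}

inline double lj_pair(double eps, double sig, double r2) {
  if (eps == 0.0 || sig == 0.0) return 0.0;
  double sr2 = sig * sig / r2;
  double sr6 = sr2 * sr2 * sr2;
  return 4.0 * eps * (sr6 * sr6 - sr6);
}

// Damped shifted-force Coulomb (Fennell-Gezelter): energy and force both
// vanish at rc; reduces to the undamped shifted-force form as alpha -> 0.
struct Dsf {
  double rc, alpha, eshift, fshift;
  Dsf(double rc_ = 10.6, double a_ = 0.2) { set(rc_, a_); }
  void set(double rc_, double a_) {
    rc = rc_; alpha = a_;
    double er = std::erfc(alpha * rc);
    eshift = er / rc;
    fshift = er / (rc * rc) + 2.0 * alpha / std::sqrt(PI) * std::exp(-alpha * alpha * rc * rc) / rc;
  }
  inline double u(double qq, double r) const {
    if (r >= rc) return 0.0;
    return COULK * qq * (std::erfc(alpha * r) / r - eshift + fshift * (r - rc));
  }
};

// Coulomb method selector: 0 none, 1 truncated bare, 2 DSF, 3 full (no cutoff)
inline double coul_pair(int method, const Dsf& dsf, double qq, double r, double rc) {
  if (qq == 0.0) return 0.0;
  switch (method) {
  case 0: return 0.0;
  case 1: return (r < rc) ? COULK * qq / r : 0.0;
  case 2: return dsf.u(qq, r);
  default: return COULK * qq / r;
  }
}

// ------------------------------------------------------------------
// species / system containers built from R lists
// ------------------------------------------------------------------
struct RotBond {
  int a, b;                  // axis atoms (0-based local)
  std::vector<int> moving;   // atoms rotated with the bond
  int d1, d2, d3, d4;        // dihedral quadruple
  double c1, c2, c3;         // cosine series coefficients
};

struct Species {
  int n = 0;
  bool rigid = true;
  std::vector<double> sig, eps, q, mass;
  std::vector<char> excl;    // n*n, 1 = excluded intramolecular pair
  std::vector<RotBond> rots;
  bool excluded(int i, int j) const { return excl[i * n + j] != 0; }
};

static Species species_from_list(const List& sp) {
  Species s;
  NumericVector sig = sp["sigma"], eps = sp["epsilon"], q = sp["charge"], m = sp["mass"];
  s.n = sig.size();
  s.rigid = as<bool>(sp["rigid"]);
  s.sig.assign(sig.begin(), sig.end());
  s.eps.assign(eps.begin(), eps.end());
  s.q.assign(q.begin(), q.end());
  s.mass.assign(m.begin(), m.end());
  IntegerMatrix ex = sp["excl"];
  s.excl.assign(s.n * s.n, 0);
  for (int i = 0; i < s.n; ++i)
    for (int j = 0; j < s.n; ++j)
      s.excl[i * s.n + j] = (char)ex(i, j);
  if (sp.containsElementNamed("rotatable")) {
    List rl = sp["rotatable"];
    for (int k = 0; k < rl.size(); ++k) {
      List r = rl[k];
      RotBond rb;
      IntegerVector ax = r["axis"], mv = r["moving"], dh = r["dihedral"];
      NumericVector cc = r["c"];
      rb.a = ax[0] - 1; rb.b = ax[1] - 1;
      for (int t = 0; t < mv.size(); ++t) rb.moving.push_back(mv[t] - 1);
      rb.d1 = dh[0] - 1; rb.d2 = dh[1] - 1; rb.d3 = dh[2] - 1; rb.d4 = dh[3] - 1;
      rb.c1 = cc[0]; rb.c2 = cc[1]; rb.c3 = cc[2];
      s.rots.push_back(rb);
    }
  }
  return s;
}

typedef std::array<double, 3> V3;

inline double dihedral_angle(const std::vector<V3>& x, int i, int j, int k, int l) {
  double b1[3], b2[3], b3[3];
  for (int t = 0; t < 3; ++t) {
    b1[t] = x[j][t] - x[i][t];
    b2[t] = x[k][t] - x[j][t];
    b3[t] = x[l][t] - x[k][t];
  }
  double n1[3] = { b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2], b1[0]*b2[1]-b1[1]*b2[0] };
  double n2[3] = { b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2], b2[0]*b3[1]-b2[1]*b3[0] };
  double m1[3];
  double b2n = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
  m1[0] = (n1[1]*b2[2]-n1[2]*b2[1]) / b2n;
  m1[1] = (n1[2]*b2[0]-n1[0]*b2[2]) / b2n;
  m1[2] = (n1[0]*b2[1]-n1[1]*b2[0]) / b2n;
  double xx = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
  double yy = m1[0]*n2[0]+m1[1]*n2[1]+m1[2]*n2[2];
  return std::atan2(yy, xx);
}

inline double torsion_u(const RotBond& rb, double phi) {
  return 0.5 * rb.c1 * (1.0 + std::cos(phi)) +
         0.5 * rb.c2 * (1.0 - std::cos(2.0 * phi)) +
         0.5 * rb.c3 * (1.0 + std::cos(3.0 * phi));
}

// intramolecular energy of one molecule: torsions + nonbonded pairs beyond
// the exclusion rule (full-range LJ + bare Coulomb, a molecular-scale sum)
static double intra_energy(const Species& s, const std::vector<V3>& x) {
  double u = 0.0;
  for (size_t r = 0; r < s.rots.size(); ++r) {
    const RotBond& rb = s.rots[r];
    u += torsion_u(rb, dihedral_angle(x, rb.d1, rb.d2, rb.d3, rb.d4));
  }
  for (int i = 0; i < s.n; ++i)
    for (int j = i + 1; j < s.n; ++j) {
      if (s.excluded(i, j)) continue;
      double dx = x[i][0]-x[j][0], dy = x[i][1]-x[j][1], dz = x[i][2]-x[j][2];
      double r2 = dx*dx + dy*dy + dz*dz;
      double sij = 0.5 * (s.sig[i] + s.sig[j]);
      double eij = std::sqrt(s.eps[i] * s.eps[j]);
      u += lj_pair(eij, sij, r2);
      double qq = s.q[i] * s.q[j];
      if (qq != 0.0) u += COULK * qq / std::sqrt(r2);
    }
  return u;
}

// random rotation matrix from a uniform quaternion
static void rand_rotation(double R[3][3]) {
  double q[4];
  double n2 = 0.0;
  for (int i = 0; i < 4; ++i) { q[i] = R::norm_rand(); n2 += q[i]*q[i]; }
  double n = std::sqrt(n2);
  for (int i = 0; i < 4; ++i) q[i] /= n;
  double w=q[0], x=q[1], y=q[2], z=q[3];
  R[0][0]=1-2*(y*y+z*z); R[0][1]=2*(x*y-w*z);   R[0][2]=2*(x*z+w*y);
  R[1][0]=2*(x*y+w*z);   R[1][1]=1-2*(x*x+z*z); R[1][2]=2*(y*z-w*x);
  R[2][0]=2*(x*z-w*y);   R[2][1]=2*(y*z+w*x);   R[2][2]=1-2*(x*x+y*y);
}

static void axis_angle(double ux, double uy, double uz, double th, double R[3][3]) {
  double c = std::cos(th), s = std::sin(th), t = 1.0 - c;
  R[0][0]=c+ux*ux*t;    R[0][1]=ux*uy*t-uz*s; R[0][2]=ux*uz*t+uy*s;
  R[1][0]=ux*uy*t+uz*s; R[1][1]=c+uy*uy*t;    R[1][2]=uy*uz*t-ux*s;
  R[2][0]=ux*uz*t-uy*s; R[2][1]=uy*uz*t+ux*s; R[2][2]=c+uz*uz*t;
}

static void rand_unit(double& x, double& y, double& z) {
  double n2;
  do {
    x = 2.0*R::unif_rand()-1.0; y = 2.0*R::unif_rand()-1.0; z = 2.0*R::unif_rand()-1.0;
    n2 = x*x+y*y+z*z;
  } while (n2 > 1.0 || n2 < 1e-12);
  double n = std::sqrt(n2);
  x/=n; y/=n; z/=n;
}

// ------------------------------------------------------------------
// flat pairwise energy over an arbitrary configuration
// ------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_energy(NumericMatrix xyz, NumericVector sig, NumericVector eps,
                NumericVector q, IntegerVector mol,
                IntegerVector excl_i, IntegerVector excl_j,
                double box, double rc_lj, double rc_coul,
                int coul_method, double alpha, bool tail) {
  int n = xyz.nrow();
  Dsf dsf(rc_coul, alpha);
  std::unordered_set<long long> ex;
  for (int k = 0; k < excl_i.size(); ++k) {
    long long a = excl_i[k] - 1, b = excl_j[k] - 1;
    if (a > b) std::swap(a, b);
    ex.insert(a * (long long)n + b);
  }
  double ulj = 0.0, uc = 0.0;
  double rc2 = rc_lj * rc_lj;
  bool nocut = (box <= 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (mol[i] == mol[j] && ex.count((long long)i * n + j)) continue;
      double dx = mimg(xyz(i,0)-xyz(j,0), box);
      double dy = mimg(xyz(i,1)-xyz(j,1), box);
      double dz = mimg(xyz(i,2)-xyz(j,2), box);
      double r2 = dx*dx+dy*dy+dz*dz;
      if (r2 < 1e-12) stop("overlapping atoms at zero distance");
      if (nocut || r2 < rc2) {
        double sij = 0.5*(sig[i]+sig[j]);
        double eij = std::sqrt(eps[i]*eps[j]);
        ulj += lj_pair(eij, sij, r2);
      }
      double qq = q[i]*q[j];
      if (qq != 0.0) {
        double r = std::sqrt(r2);
        uc += coul_pair(nocut && coul_method != 0 ? 3 : coul_method, dsf, qq, r, rc_coul);
      }
    }
  }
  double utail = 0.0;
  if (tail && box > 0.0) {
    double s12 = 0.0, s6 = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (mol[i] == mol[j] && ex.count((long long)i * n + j)) continue;
        double sij = 0.5*(sig[i]+sig[j]);
        double eij = std::sqrt(eps[i]*eps[j]);
        if (eij == 0.0 || sij == 0.0) continue;
        double s3 = sij*sij*sij, s6i = s3*s3;
        s12 += eij * s6i * s6i;
        s6  += eij * s6i;
      }
    double V = box*box*box;
    double rc3 = rc_lj*rc_lj*rc_lj, rc9 = rc3*rc3*rc3;
    utail = (8.0*PI/(3.0*V)) * (s12/(3.0*rc9) - s6/rc3);
  }
  return List::create(_["lj"] = ulj, _["coul"] = uc, _["tail"] = utail,
                      _["total"] = ulj + uc + utail);
}

// cross-interaction energy between a group of atoms and the rest
// [[Rcpp::export]]
List cpp_group_energy(NumericMatrix xyz, NumericVector sig, NumericVector eps,
                      NumericVector q, LogicalVector group, double box,
                      double rc_lj, double rc_coul, int coul_method, double alpha) {
  int n = xyz.nrow();
  Dsf dsf(rc_coul, alpha);
  double ulj = 0.0, uc = 0.0;
  double rc2 = rc_lj * rc_lj;
  bool nocut = (box <= 0.0);
  for (int i = 0; i < n; ++i) {
    if (!group[i]) continue;
    for (int j = 0; j < n; ++j) {
      if (group[j]) continue;
      double dx = mimg(xyz(i,0)-xyz(j,0), box);
      double dy = mimg(xyz(i,1)-xyz(j,1), box);
      double dz = mimg(xyz(i,2)-xyz(j,2), box);
      double r2 = dx*dx+dy*dy+dz*dz;
      if (nocut || r2 < rc2) {
        double sij = 0.5*(sig[i]+sig[j]);
        double eij = std::sqrt(eps[i]*eps[j]);
        ulj += lj_pair(eij, sij, r2);
      }
      double qq = q[i]*q[j];
      if (qq != 0.0) {
        double r = std::sqrt(r2);
        uc += coul_pair(nocut && coul_method != 0 ? 3 : coul_method, dsf, qq, r, rc_coul);
      }
    }
  }
  return List::create(_["lj"] = ulj, _["coul"] = uc, _["total"] = ulj + uc);
}

// ------------------------------------------------------------------
// Ewald summation (cubic periodic box)
// ------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_ewald_energy(NumericMatrix xyz, NumericVector q, double box,
                      IntegerVector mol, IntegerVector excl_i, IntegerVector excl_j,
                      double alpha, double rcut, int kmax) {
  int n = xyz.nrow();
  double V = box*box*box;
  std::unordered_set<long long> ex;
  for (int k = 0; k < excl_i.size(); ++k) {
    long long a = excl_i[k]-1, b = excl_j[k]-1;
    if (a > b) std::swap(a, b);
    ex.insert(a*(long long)n + b);
  }
  // real space + exclusion correction
  double ureal = 0.0, uexcl = 0.0;
  double rc2 = rcut*rcut;
  for (int i = 0; i < n; ++i)
    for (int j = i+1; j < n; ++j) {
      double qq = q[i]*q[j];
      if (qq == 0.0) continue;
      double dx = mimg(xyz(i,0)-xyz(j,0), box);
      double dy = mimg(xyz(i,1)-xyz(j,1), box);
      double dz = mimg(xyz(i,2)-xyz(j,2), box);
      double r2 = dx*dx+dy*dy+dz*dz;
      double r = std::sqrt(r2);
      bool excl = (mol[i] == mol[j]) && ex.count((long long)i*n+j);
      if (excl) {
        uexcl -= COULK * qq * std::erf(alpha*r) / r;
      } else if (r2 < rc2) {
        ureal += COULK * qq * std::erfc(alpha*r) / r;
      }
    }
  // reciprocal space with per-axis phase recursion
  int nk = 2*kmax + 1;
  std::vector<std::complex<double>> ph(3 * n * nk);
  double twopiL = 2.0*PI/box;
  for (int ax = 0; ax < 3; ++ax)
    for (int i = 0; i < n; ++i) {
      std::complex<double> e1 = std::polar(1.0, twopiL * xyz(i, ax));
      std::complex<double> cur(1.0, 0.0);
      // fill m = 0..kmax then negatives by conjugation
      for (int m = 0; m <= kmax; ++m) {
        ph[(ax*n + i)*nk + (kmax + m)] = cur;
        cur *= e1;
      }
      for (int m = 1; m <= kmax; ++m)
        ph[(ax*n + i)*nk + (kmax - m)] = std::conj(ph[(ax*n + i)*nk + (kmax + m)]);
    }
  double urec = 0.0;
  double k2max = (twopiL * kmax) * (twopiL * kmax) + 1e-9;
  for (int mx = -kmax; mx <= kmax; ++mx)
    for (int my = -kmax; my <= kmax; ++my)
      for (int mz = -kmax; mz <= kmax; ++mz) {
        if (mx == 0 && my == 0 && mz == 0) continue;
        double kx = twopiL*mx, ky = twopiL*my, kz = twopiL*mz;
        double k2 = kx*kx+ky*ky+kz*kz;
        if (k2 > k2max) continue;
        std::complex<double> S(0.0, 0.0);
        for (int i = 0; i < n; ++i) {
          if (q[i] == 0.0) continue;
          S += q[i] * ph[(0*n+i)*nk + (kmax+mx)]
                     * ph[(1*n+i)*nk + (kmax+my)]
                     * ph[(2*n+i)*nk + (kmax+mz)];
        }
        urec += std::exp(-k2/(4.0*alpha*alpha))/k2 * std::norm(S);
      }
  urec *= COULK * 2.0*PI/V;
  double q2 = 0.0, qt = 0.0;
  for (int i = 0; i < n; ++i) { q2 += q[i]*q[i]; qt += q[i]; }
  double uself = -COULK * alpha/std::sqrt(PI) * q2;
  double ubg = -COULK * PI/(2.0*alpha*alpha*V) * qt*qt;
  return List::create(_["real"] = ureal, _["recip"] = urec, _["self"] = uself,
                      _["excl"] = uexcl, _["background"] = ubg,
                      _["total"] = ureal + urec + uself + uexcl + ubg,
                      _["net_charge"] = qt);
}

// Ewald electrostatic potential (per unit probe charge) on a regular grid
// [[Rcpp::export]]
NumericVector cpp_ewald_potential_grid(NumericMatrix xyz, NumericVector q, double box,
                                       int ngrid, double alpha, double rcut, int kmax) {
  int n = xyz.nrow();
  double V = box*box*box;
  double h = box / ngrid;
  long ntot = (long)ngrid*ngrid*ngrid;
  std::vector<double> phi(ntot, 0.0);
  // real-space: atoms outer, affected nodes inner (rcut <= box/2 required)
  if (rcut > box / 2.0) rcut = box / 2.0;
  int reach = (int)std::ceil(rcut / h);
  double rc2 = rcut*rcut;
  for (int a = 0; a < n; ++a) {
    if (q[a] == 0.0) continue;
    double ax = xyz(a,0), ay = xyz(a,1), az = xyz(a,2);
    int ix = (int)std::floor(ax/h), iy = (int)std::floor(ay/h), iz = (int)std::floor(az/h);
    for (int dx = -reach; dx <= reach; ++dx)
      for (int dy = -reach; dy <= reach; ++dy)
        for (int dz = -reach; dz <= reach; ++dz) {
          int gx = ix+dx, gy = iy+dy, gz = iz+dz;
          double px = gx*h - ax, py = gy*h - ay, pz = gz*h - az;
          px = mimg(px, box); py = mimg(py, box); pz = mimg(pz, box);
          double r2 = px*px+py*py+pz*pz;
          if (r2 >= rc2) continue;
          double r = std::sqrt(r2);
          if (r < 1e-6) r = 1e-6;
          int wx = ((gx % ngrid) + ngrid) % ngrid;
          int wy = ((gy % ngrid) + ngrid) % ngrid;
          int wz = ((gz % ngrid) + ngrid) % ngrid;
          phi[(long)wz*ngrid*ngrid + (long)wy*ngrid + wx] += COULK*q[a]*std::erfc(alpha*r)/r;
        }
  }
  // reciprocal part via separable partial sums
  double twopiL = 2.0*PI/box;
  int nk = 2*kmax+1;
  // S(k) structure factors
  std::vector<std::complex<double>> ph1(3 * n * nk);
  for (int ax = 0; ax < 3; ++ax)
    for (int i = 0; i < n; ++i) {
      std::complex<double> e1 = std::polar(1.0, twopiL * xyz(i, ax));
      std::complex<double> cur(1.0, 0.0);
      for (int m = 0; m <= kmax; ++m) { ph1[(ax*n+i)*nk + (kmax+m)] = cur; cur *= e1; }
      for (int m = 1; m <= kmax; ++m)
        ph1[(ax*n+i)*nk + (kmax-m)] = std::conj(ph1[(ax*n+i)*nk + (kmax+m)]);
    }
  double k2max = (twopiL*kmax)*(twopiL*kmax) + 1e-9;
  std::vector<std::complex<double>> coef((size_t)nk*nk*nk, std::complex<double>(0.0,0.0));
  for (int mx = -kmax; mx <= kmax; ++mx)
    for (int my = -kmax; my <= kmax; ++my)
      for (int mz = -kmax; mz <= kmax; ++mz) {
        if (mx==0 && my==0 && mz==0) continue;
        double kx = twopiL*mx, ky = twopiL*my, kz = twopiL*mz;
        double k2 = kx*kx+ky*ky+kz*kz;
        if (k2 > k2max) continue;
        std::complex<double> S(0.0,0.0);
        for (int i = 0; i < n; ++i) {
          if (q[i]==0.0) continue;
          S += q[i]*ph1[(0*n+i)*nk+(kmax+mx)]*ph1[(1*n+i)*nk+(kmax+my)]*ph1[(2*n+i)*nk+(kmax+mz)];
        }
        // phi_k(r) = COULK * 4 pi / (V k^2) exp(-k^2/4a^2) Re[S * exp(-i k r)]
        coef[((size_t)(kmax+mx)*nk + (kmax+my))*nk + (kmax+mz)] =
          COULK * 4.0*PI/V * std::exp(-k2/(4.0*alpha*alpha))/k2 * S;
      }
  // node phases exp(-i k x) for grid coordinates x = g h
  std::vector<std::complex<double>> nodeph((size_t)ngrid*nk);
  for (int g = 0; g < ngrid; ++g)
    for (int m = -kmax; m <= kmax; ++m)
      nodeph[(size_t)g*nk + (kmax+m)] = std::polar(1.0, -twopiL*m*g*h);
  // sum over kz -> (kx, ky, gz), then ky -> (kx, gy, gz), then kx
  std::vector<std::complex<double>> s1((size_t)nk*nk*ngrid, std::complex<double>(0,0));
  for (int mx = 0; mx < nk; ++mx)
    for (int my = 0; my < nk; ++my)
      for (int gz = 0; gz < ngrid; ++gz) {
        std::complex<double> acc(0,0);
        for (int mz = 0; mz < nk; ++mz)
          acc += coef[((size_t)mx*nk+my)*nk+mz] * nodeph[(size_t)gz*nk+mz];
        s1[((size_t)mx*nk+my)*ngrid+gz] = acc;
      }
  std::vector<std::complex<double>> s2((size_t)nk*ngrid*ngrid, std::complex<double>(0,0));
  for (int mx = 0; mx < nk; ++mx)
    for (int gy = 0; gy < ngrid; ++gy)
      for (int gz = 0; gz < ngrid; ++gz) {
        std::complex<double> acc(0,0);
        for (int my = 0; my < nk; ++my)
          acc += s1[((size_t)mx*nk+my)*ngrid+gz] * nodeph[(size_t)gy*nk+my];
        s2[((size_t)mx*ngrid+gy)*ngrid+gz] = acc;
      }
  double qt = 0.0; for (int i = 0; i < n; ++i) qt += q[i];
  double phibg = -COULK * PI/(alpha*alpha*V) * qt;
  for (int gx = 0; gx < ngrid; ++gx)
    for (int gy = 0; gy < ngrid; ++gy)
      for (int gz = 0; gz < ngrid; ++gz) {
        std::complex<double> acc(0,0);
        for (int mx = 0; mx < nk; ++mx)
          acc += s2[((size_t)mx*ngrid+gy)*ngrid+gz] * nodeph[(size_t)gx*nk+mx];
        phi[(long)gz*ngrid*ngrid + (long)gy*ngrid + gx] += acc.real() + phibg;
      }
  NumericVector out(phi.begin(), phi.end());
  out.attr("dim") = IntegerVector::create(ngrid, ngrid, ngrid);
  return out;
}

// LJ interaction grid for one probe atom type against a frozen set of atoms
// [[Rcpp::export]]
NumericVector cpp_lj_grid(NumericMatrix xyz, NumericVector sig, NumericVector eps,
                          double box, int ngrid, double probe_sig, double probe_eps,
                          double rc, double cap) {
  int n = xyz.nrow();
  double h = box / ngrid;
  long ntot = (long)ngrid*ngrid*ngrid;
  std::vector<double> g(ntot, 0.0);
  if (rc > box / 2.0) rc = box / 2.0;  // minimum image, no double counting
  int reach = (int)std::ceil(rc / h);
  double rc2 = rc*rc;
  for (int a = 0; a < n; ++a) {
    double eij = std::sqrt(eps[a]*probe_eps);
    double sij = 0.5*(sig[a]+probe_sig);
    if (eij == 0.0 || sij == 0.0) continue;
    double ax = xyz(a,0), ay = xyz(a,1), az = xyz(a,2);
    int ix = (int)std::floor(ax/h), iy = (int)std::floor(ay/h), iz = (int)std::floor(az/h);
    for (int dx = -reach; dx <= reach; ++dx)
      for (int dy = -reach; dy <= reach; ++dy)
        for (int dz = -reach; dz <= reach; ++dz) {
          int gx = ix+dx, gy = iy+dy, gz = iz+dz;
          double px = mimg(gx*h - ax, box), py = mimg(gy*h - ay, box), pz = mimg(gz*h - az, box);
          double r2 = px*px+py*py+pz*pz;
          if (r2 >= rc2) continue;
          if (r2 < 0.01) r2 = 0.01;
          int wx = ((gx % ngrid)+ngrid)%ngrid, wy = ((gy % ngrid)+ngrid)%ngrid, wz = ((gz % ngrid)+ngrid)%ngrid;
          g[(long)wz*ngrid*ngrid + (long)wy*ngrid + wx] += lj_pair(eij, sij, r2);
        }
  }
  for (long i = 0; i < ntot; ++i) if (g[i] > cap) g[i] = cap;
  NumericVector out(g.begin(), g.end());
  out.attr("dim") = IntegerVector::create(ngrid, ngrid, ngrid);
  return out;
}

// periodic trilinear interpolation; grid indexed [x + ng*y + ng^2*z]
inline double interp3(const double* g, int ng, double h, double box,
                      double x, double y, double z) {
  x -= box*std::floor(x/box); y -= box*std::floor(y/box); z -= box*std::floor(z/box);
  double fx = x/h, fy = y/h, fz = z/h;
  int ix = (int)std::floor(fx), iy = (int)std::floor(fy), iz = (int)std::floor(fz);
  double tx = fx-ix, ty = fy-iy, tz = fz-iz;
  int ix1 = (ix+1)%ng, iy1 = (iy+1)%ng, iz1 = (iz+1)%ng;
  ix %= ng; iy %= ng; iz %= ng;
  double c000 = g[ix +ng*(iy +ng*iz )], c100 = g[ix1+ng*(iy +ng*iz )];
  double c010 = g[ix +ng*(iy1+ng*iz )], c110 = g[ix1+ng*(iy1+ng*iz )];
  double c001 = g[ix +ng*(iy +ng*iz1)], c101 = g[ix1+ng*(iy +ng*iz1)];
  double c011 = g[ix +ng*(iy1+ng*iz1)], c111 = g[ix1+ng*(iy1+ng*iz1)];
  double c00 = c000*(1-tx)+c100*tx, c10 = c010*(1-tx)+c110*tx;
  double c01 = c001*(1-tx)+c101*tx, c11 = c011*(1-tx)+c111*tx;
  double c0 = c00*(1-ty)+c10*ty, c1 = c01*(1-ty)+c11*ty;
  return c0*(1-tz)+c1*tz;
}

// [[Rcpp::export]]
NumericVector cpp_interp_grid(NumericVector grid, double box, NumericMatrix pts) {
  IntegerVector dim = grid.attr("dim");
  int ng = dim[0];
  double h = box/ng;
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = interp3(grid.begin(), ng, h, box, pts(i,0), pts(i,1), pts(i,2));
  return out;
}

// ------------------------------------------------------------------
// simulated annealing of an isolated dimer
// ------------------------------------------------------------------

static double inter_energy_dimer(const Species& st, const Species& sp,
                                 const std::vector<V3>& xt, const std::vector<V3>& xp,
                                 double* lj_out = nullptr, double* coul_out = nullptr) {
  double ul = 0.0, uc = 0.0;
  for (int i = 0; i < st.n; ++i)
    for (int j = 0; j < sp.n; ++j) {
      double dx = xt[i][0]-xp[j][0], dy = xt[i][1]-xp[j][1], dz = xt[i][2]-xp[j][2];
      double r2 = dx*dx+dy*dy+dz*dz;
      double sij = 0.5*(st.sig[i]+sp.sig[j]);
      double eij = std::sqrt(st.eps[i]*sp.eps[j]);
      ul += lj_pair(eij, sij, r2);
      double qq = st.q[i]*sp.q[j];
      if (qq != 0.0) uc += COULK*qq/std::sqrt(r2);
    }
  if (lj_out) *lj_out = ul;
  if (coul_out) *coul_out = uc;
  return ul + uc;
}

static void com_of(const Species& s, const std::vector<V3>& x, double c[3]) {
  double M = 0.0; c[0]=c[1]=c[2]=0.0;
  for (int i = 0; i < s.n; ++i) {
    M += s.mass[i];
    for (int t = 0; t < 3; ++t) c[t] += s.mass[i]*x[i][t];
  }
  for (int t = 0; t < 3; ++t) c[t] /= M;
}

static void rotate_about(std::vector<V3>& x, const std::vector<int>& idx,
                         const double ctr[3], const double R[3][3]) {
  for (size_t k = 0; k < idx.size(); ++k) {
    int i = idx[k];
    double v[3] = { x[i][0]-ctr[0], x[i][1]-ctr[1], x[i][2]-ctr[2] };
    x[i][0] = ctr[0] + R[0][0]*v[0]+R[0][1]*v[1]+R[0][2]*v[2];
    x[i][1] = ctr[1] + R[1][0]*v[0]+R[1][1]*v[1]+R[1][2]*v[2];
    x[i][2] = ctr[2] + R[2][0]*v[0]+R[2][1]*v[1]+R[2][2]*v[2];
  }
}

// [[Rcpp::export]]
List cpp_anneal(List sp_template, List sp_partner,
                NumericMatrix xyz_t, NumericMatrix xyz_p,
                NumericMatrix schedule, // columns: T, nmoves, step_tr, step_rot, step_tor
                double tether) {
  Species st = species_from_list(sp_template);
  Species sp = species_from_list(sp_partner);
  std::vector<V3> xt(st.n), xp(sp.n);
  for (int i = 0; i < st.n; ++i) { xt[i] = { xyz_t(i,0), xyz_t(i,1), xyz_t(i,2) }; }
  for (int i = 0; i < sp.n; ++i) { xp[i] = { xyz_p(i,0), xyz_p(i,1), xyz_p(i,2) }; }
  std::vector<int> all_t(st.n), all_p(sp.n);
  for (int i = 0; i < st.n; ++i) all_t[i] = i;
  for (int i = 0; i < sp.n; ++i) all_p[i] = i;

  double u_inter = inter_energy_dimer(st, sp, xt, xp);
  double u_intra = sp.rigid ? 0.0 : intra_energy(sp, xp);
  double best_inter = u_inter;
  std::vector<V3> best_t = xt, best_p = xp;
  long nacc = 0, ntot = 0;

  int nstage = schedule.nrow();
  for (int s = 0; s < nstage; ++s) {
    double T = schedule(s,0);
    long nm = (long)schedule(s,1);
    double dtr = schedule(s,2), drot = schedule(s,3), dtor = schedule(s,4);
    double beta = 1.0/(KB*T);
    for (long m = 0; m < nm; ++m) {
      ++ntot;
      int ntypes = sp.rigid ? 3 : 4; // translate-p, rotate-p, rotate-t, torsion-p
      int mt = (int)(R::unif_rand()*ntypes);
      std::vector<V3> xp_new = xp;
      std::vector<V3> xt_new = xt;
      double du_intra = 0.0;
      if (mt == 0) {
        double dsh[3];
        for (int t = 0; t < 3; ++t) dsh[t] = dtr*(2.0*R::unif_rand()-1.0);
        for (int i = 0; i < sp.n; ++i)
          for (int t = 0; t < 3; ++t) xp_new[i][t] += dsh[t];
      } else if (mt == 1) {
        double c[3]; com_of(sp, xp, c);
        double ux,uy,uz; rand_unit(ux,uy,uz);
        double R3[3][3]; axis_angle(ux,uy,uz, drot*(2.0*R::unif_rand()-1.0), R3);
        rotate_about(xp_new, all_p, c, R3);
      } else if (mt == 2) {
        double c[3]; com_of(st, xt, c);
        double ux,uy,uz; rand_unit(ux,uy,uz);
        double R3[3][3]; axis_angle(ux,uy,uz, drot*(2.0*R::unif_rand()-1.0), R3);
        rotate_about(xt_new, all_t, c, R3);
      } else {
        int rb = (int)(R::unif_rand()*sp.rots.size());
        const RotBond& r = sp.rots[rb];
        double ax[3] = { xp[r.b][0]-xp[r.a][0], xp[r.b][1]-xp[r.a][1], xp[r.b][2]-xp[r.a][2] };
        double an = std::sqrt(ax[0]*ax[0]+ax[1]*ax[1]+ax[2]*ax[2]);
        double ctr[3] = { xp[r.a][0], xp[r.a][1], xp[r.a][2] };
        double R3[3][3]; axis_angle(ax[0]/an, ax[1]/an, ax[2]/an, dtor*(2.0*R::unif_rand()-1.0), R3);
        rotate_about(xp_new, r.moving, ctr, R3);
        du_intra = intra_energy(sp, xp_new) - u_intra;
      }
      // tether on COM separation keeps the pair associated at high T
      double ct[3], cp[3];
      com_of(st, xt_new, ct); com_of(sp, xp_new, cp);
      double dd = 0.0;
      for (int t = 0; t < 3; ++t) dd += (ct[t]-cp[t])*(ct[t]-cp[t]);
      if (dd > tether*tether) continue;
      double u_inter_new = inter_energy_dimer(st, sp, xt_new, xp_new);
      double du = (u_inter_new - u_inter) + du_intra;
      if (du <= 0.0 || R::unif_rand() < std::exp(-beta*du)) {
        xt = xt_new; xp = xp_new;
        u_inter = u_inter_new; u_intra += du_intra;
        ++nacc;
        if (u_inter < best_inter) { best_inter = u_inter; best_t = xt; best_p = xp; }
      }
    }
  }
  double blj, bcoul, flj, fcoul;
  inter_energy_dimer(st, sp, best_t, best_p, &blj, &bcoul);
  inter_energy_dimer(st, sp, xt, xp, &flj, &fcoul);
  NumericMatrix out_t(st.n, 3), out_p(sp.n, 3), fin_t(st.n, 3), fin_p(sp.n, 3);
  for (int i = 0; i < st.n; ++i) for (int t = 0; t < 3; ++t) out_t(i,t) = best_t[i][t];
  for (int i = 0; i < sp.n; ++i) for (int t = 0; t < 3; ++t) out_p(i,t) = best_p[i][t];
  for (int i = 0; i < st.n; ++i) for (int t = 0; t < 3; ++t) fin_t(i,t) = xt[i][t];
  for (int i = 0; i < sp.n; ++i) for (int t = 0; t < 3; ++t) fin_p(i,t) = xp[i][t];
  return List::create(_["xyz_template"] = out_t, _["xyz_partner"] = out_p,
                      _["e_lj"] = blj, _["e_coul"] = bcoul, _["e_total"] = blj + bcoul,
                      _["final_xyz_template"] = fin_t, _["final_xyz_partner"] = fin_p,
                      _["final_lj"] = flj, _["final_coul"] = fcoul,
                      _["final_total"] = flj + fcoul,
                      _["acceptance"] = (double)nacc/(double)ntot);
}

// ------------------------------------------------------------------
// NPT Monte Carlo of the liquid mixture (DSF electrostatics)
// ------------------------------------------------------------------
struct NptSys {
  double L;
  std::vector<Species> sp;
  std::vector<int> msp, mstart, mn;     // per molecule
  std::vector<double> x, y, z;          // flat atom coords
  std::vector<double> sig, eps, q, mass;
  std::vector<int> mol;
  int natoms = 0, nmol = 0;
  double rc_lj, rc_c;
  Dsf dsf;
  double tailC = 0.0;                   // U_tail = tailC / V
  // tabulated DSF radial factor S(r) with u = qq * S(r): avoids erfc in
  // the inner loop; linear interpolation on a dense grid
  std::vector<double> dsf_tab;
  double dsf_dr = 0.0;
  void build_dsf_table(int nbin = 16384) {
    dsf_tab.resize(nbin + 2);
    dsf_dr = rc_c / nbin;
    for (int i = 0; i <= nbin + 1; ++i) {
      double r = std::max(1e-4, i * dsf_dr);
      dsf_tab[i] = (r >= rc_c) ? 0.0 : dsf.u(1.0, r);
    }
  }
  inline double dsf_u(double qq, double r) const {
    double f = r / dsf_dr;
    int i = (int)f;
    double t = f - i;
    return qq * (dsf_tab[i] * (1.0 - t) + dsf_tab[i + 1] * t);
  }

  NptSys() : dsf(10.6, 0.2) {}

  // cached molecule-pair interaction energies: a molecule move computes
  // only its new row; the old row comes from the cache
  std::vector<double> upair;            // nmol * nmol, symmetric

  // per-molecule interactions of molecule m (trial coordinates given);
  // fills row[k] for k != m; returns false on hard overlap
  bool mol_inter_row(int m, const std::vector<double>& cx,
                     const std::vector<double>& cy,
                     const std::vector<double>& cz,
                     std::vector<double>& row) const {
    std::fill(row.begin(), row.end(), 0.0);
    double rc2l = rc_lj*rc_lj, rc2c = rc_c*rc_c;
    int a0 = mstart[m], a1 = mstart[m] + mn[m];
    for (int a = a0; a < a1; ++a) {
      double xa = cx[a-a0], ya = cy[a-a0], za = cz[a-a0];
      double sa = sig[a], ea = eps[a], qa = q[a];
      for (int b = 0; b < natoms; ++b) {
        int mb = mol[b];
        if (mb == m) continue;
        double dx = mimg(xa - x[b], L), dy = mimg(ya - y[b], L), dz = mimg(za - z[b], L);
        double r2 = dx*dx+dy*dy+dz*dz;
        if (r2 < rc2l) {
          if (r2 < 1e-4) return false;
          double sij = 0.5*(sa+sig[b]);
          double eij = std::sqrt(ea*eps[b]);
          row[mb] += lj_pair(eij, sij, r2);
        }
        double qq = qa*q[b];
        if (qq != 0.0 && r2 < rc2c)
          row[mb] += dsf_u(qq, std::sqrt(r2));
      }
    }
    return true;
  }

  // rebuild the whole pair matrix (after volume moves); returns total U
  double refresh_pairs() {
    std::fill(upair.begin(), upair.end(), 0.0);
    double rc2l = rc_lj*rc_lj, rc2c = rc_c*rc_c;
    for (int a = 0; a < natoms; ++a) {
      int ma = mol[a];
      for (int b = a+1; b < natoms; ++b) {
        int mb = mol[b];
        if (ma == mb) continue;
        double dx = mimg(x[a]-x[b], L), dy = mimg(y[a]-y[b], L), dz = mimg(z[a]-z[b], L);
        double r2 = dx*dx+dy*dy+dz*dz;
        double u = 0.0;
        if (r2 < rc2l) {
          double sij = 0.5*(sig[a]+sig[b]);
          double eij = std::sqrt(eps[a]*eps[b]);
          u += lj_pair(eij, sij, r2);
        }
        double qq = q[a]*q[b];
        if (qq != 0.0 && r2 < rc2c) u += dsf_u(qq, std::sqrt(r2));
        if (u != 0.0) {
          upair[(size_t)ma*nmol + mb] += u;
          upair[(size_t)mb*nmol + ma] += u;
        }
      }
    }
    double tot = 0.0;
    for (int m1 = 0; m1 < nmol; ++m1)
      for (int m2 = m1+1; m2 < nmol; ++m2)
        tot += upair[(size_t)m1*nmol + m2];
    return tot;
  }

  double full_inter() {
    if (upair.size() != (size_t)nmol*nmol) upair.assign((size_t)nmol*nmol, 0.0);
    return refresh_pairs();
  }

  double mol_intra(int m) const {
    const Species& s = sp[msp[m]];
    if (s.rigid) return 0.0;
    std::vector<V3> xm(s.n);
    for (int i = 0; i < s.n; ++i) xm[i] = { x[mstart[m]+i], y[mstart[m]+i], z[mstart[m]+i] };
    return intra_energy(s, xm);
  }
};

// [[Rcpp::export]]
List cpp_npt(NumericMatrix xyz, List species_info, IntegerVector mol_species,
             double box, double T, double P, // P in kJ/mol/A^3
             double nmoves_d, int vol_every, double rc_lj, double rc_c, double alpha,
             double step_tr, double step_rot, double step_tor, double step_lnv,
             double ntune_d, int sample_every, bool ideal_gas) {
  long nmoves = (long)nmoves_d, ntune = (long)ntune_d;
  NptSys S;
  S.L = box; S.rc_lj = rc_lj; S.rc_c = rc_c; S.dsf.set(rc_c, alpha);
  S.build_dsf_table();
  for (int k = 0; k < species_info.size(); ++k)
    S.sp.push_back(species_from_list(species_info[k]));
  S.nmol = mol_species.size();
  for (int m = 0; m < S.nmol; ++m) {
    int si = mol_species[m];
    S.msp.push_back(si);
    S.mstart.push_back(S.natoms);
    S.mn.push_back(S.sp[si].n);
    for (int i = 0; i < S.sp[si].n; ++i) {
      S.x.push_back(xyz(S.natoms+i, 0));
      S.y.push_back(xyz(S.natoms+i, 1));
      S.z.push_back(xyz(S.natoms+i, 2));
      S.sig.push_back(ideal_gas ? 0.0 : S.sp[si].sig[i]);
      S.eps.push_back(ideal_gas ? 0.0 : S.sp[si].eps[i]);
      S.q.push_back(ideal_gas ? 0.0 : S.sp[si].q[i]);
      S.mass.push_back(S.sp[si].mass[i]);
      S.mol.push_back(m);
    }
    S.natoms += S.sp[si].n;
  }
  // tail-correction coefficient over non-excluded pairs
  if (!ideal_gas) {
    double s12 = 0.0, s6 = 0.0;
    for (int a = 0; a < S.natoms; ++a)
      for (int b = a+1; b < S.natoms; ++b) {
        if (S.mol[a] == S.mol[b]) continue; // no tail for intramolecular pairs
        double sij = 0.5*(S.sig[a]+S.sig[b]);
        double eij = std::sqrt(S.eps[a]*S.eps[b]);
        if (eij == 0.0 || sij == 0.0) continue;
        double s3 = sij*sij*sij, s6i = s3*s3;
        s12 += eij*s6i*s6i; s6 += eij*s6i;
      }
    double rc3 = rc_lj*rc_lj*rc_lj, rc9 = rc3*rc3*rc3;
    S.tailC = (8.0*PI/3.0) * (s12/(3.0*rc9) - s6/rc3);
  }

  double beta = 1.0/(KB*T);
  double U = ideal_gas ? 0.0 : S.full_inter();
  std::vector<double> vtrace, utrace;
  long acc_tr = 0, try_tr = 0, acc_rot = 0, try_rot = 0;
  long acc_tor = 0, try_tor = 0, acc_vol = 0, try_vol = 0;
  long since_tune = 0;

  std::vector<double> cx, cy, cz, row((size_t)S.nmol, 0.0);
  for (long mv = 1; mv <= nmoves; ++mv) {
    if (vol_every > 0 && (mv % vol_every) == 0) {
      // volume move in ln V
      ++try_vol;
      double V = S.L*S.L*S.L;
      double lnV = std::log(V) + step_lnv*(2.0*R::unif_rand()-1.0);
      double Vn = std::exp(lnV);
      double Ln = std::cbrt(Vn);
      if (Ln < 2.0*S.rc_lj && Ln < S.L) {
        // refuse to shrink below twice the cutoff
      } else {
        double sf = Ln/S.L;
        std::vector<double> nx = S.x, ny = S.y, nz = S.z;
        for (int m = 0; m < S.nmol; ++m) {
          double M = 0.0, c0 = 0.0, c1 = 0.0, c2 = 0.0;
          for (int i = S.mstart[m]; i < S.mstart[m]+S.mn[m]; ++i) {
            M += S.mass[i]; c0 += S.mass[i]*S.x[i]; c1 += S.mass[i]*S.y[i]; c2 += S.mass[i]*S.z[i];
          }
          c0/=M; c1/=M; c2/=M;
          double d0 = (sf-1.0)*c0, d1 = (sf-1.0)*c1, d2 = (sf-1.0)*c2;
          for (int i = S.mstart[m]; i < S.mstart[m]+S.mn[m]; ++i) { nx[i]+=d0; ny[i]+=d1; nz[i]+=d2; }
        }
        double Lold = S.L;
        std::vector<double> upair_old = S.upair;
        std::swap(S.x, nx); std::swap(S.y, ny); std::swap(S.z, nz);
        S.L = Ln;
        double Un = ideal_gas ? 0.0 : S.full_inter();
        double dU = (Un - U) + S.tailC*(1.0/Vn - 1.0/V);
        double argv = -beta*(dU + P*(Vn-V)) + (S.nmol+1)*std::log(Vn/V);
        if (argv >= 0.0 || R::unif_rand() < std::exp(argv)) {
          U = Un; ++acc_vol;
        } else {
          std::swap(S.x, nx); std::swap(S.y, ny); std::swap(S.z, nz);
          S.L = Lold;
          S.upair = upair_old;
        }
      }
    } else {
      int m = (int)(R::unif_rand()*S.nmol);
      const Species& ssp = S.sp[S.msp[m]];
      int na = S.mn[m], a0 = S.mstart[m];
      cx.assign(na, 0.0); cy.assign(na, 0.0); cz.assign(na, 0.0);
      for (int i = 0; i < na; ++i) { cx[i]=S.x[a0+i]; cy[i]=S.y[a0+i]; cz[i]=S.z[a0+i]; }
      int mt;
      if (ssp.rigid || ssp.rots.empty()) mt = (R::unif_rand() < 0.5) ? 0 : 1;
      else { double u3 = R::unif_rand(); mt = (u3 < 1.0/3) ? 0 : (u3 < 2.0/3 ? 1 : 2); }
      double du_intra = 0.0;
      double u_old = 0.0;
      if (!ideal_gas)
        for (int k = 0; k < S.nmol; ++k) u_old += S.upair[(size_t)m*S.nmol + k];
      if (mt == 0) {
        ++try_tr;
        double d0 = step_tr*(2.0*R::unif_rand()-1.0);
        double d1 = step_tr*(2.0*R::unif_rand()-1.0);
        double d2 = step_tr*(2.0*R::unif_rand()-1.0);
        for (int i = 0; i < na; ++i) { cx[i]+=d0; cy[i]+=d1; cz[i]+=d2; }
      } else if (mt == 1) {
        ++try_rot;
        double M = 0.0, c0=0,c1=0,c2=0;
        for (int i = 0; i < na; ++i) { M += ssp.mass[i]; c0+=ssp.mass[i]*cx[i]; c1+=ssp.mass[i]*cy[i]; c2+=ssp.mass[i]*cz[i]; }
        c0/=M; c1/=M; c2/=M;
        double ux,uy,uz; rand_unit(ux,uy,uz);
        double R3[3][3]; axis_angle(ux,uy,uz, step_rot*(2.0*R::unif_rand()-1.0), R3);
        for (int i = 0; i < na; ++i) {
          double v0=cx[i]-c0, v1=cy[i]-c1, v2=cz[i]-c2;
          cx[i]=c0+R3[0][0]*v0+R3[0][1]*v1+R3[0][2]*v2;
          cy[i]=c1+R3[1][0]*v0+R3[1][1]*v1+R3[1][2]*v2;
          cz[i]=c2+R3[2][0]*v0+R3[2][1]*v1+R3[2][2]*v2;
        }
      } else {
        ++try_tor;
        int rb = (int)(R::unif_rand()*ssp.rots.size());
        const RotBond& r = ssp.rots[rb];
        double ax0 = cx[r.b]-cx[r.a], ax1 = cy[r.b]-cy[r.a], ax2 = cz[r.b]-cz[r.a];
        double an = std::sqrt(ax0*ax0+ax1*ax1+ax2*ax2);
        double R3[3][3]; axis_angle(ax0/an, ax1/an, ax2/an, step_tor*(2.0*R::unif_rand()-1.0), R3);
        double ctr0 = cx[r.a], ctr1 = cy[r.a], ctr2 = cz[r.a];
        std::vector<V3> before(na), after(na);
        for (int i = 0; i < na; ++i) before[i] = { cx[i], cy[i], cz[i] };
        for (size_t kk = 0; kk < r.moving.size(); ++kk) {
          int i = r.moving[kk];
          double v0=cx[i]-ctr0, v1=cy[i]-ctr1, v2=cz[i]-ctr2;
          cx[i]=ctr0+R3[0][0]*v0+R3[0][1]*v1+R3[0][2]*v2;
          cy[i]=ctr1+R3[1][0]*v0+R3[1][1]*v1+R3[1][2]*v2;
          cz[i]=ctr2+R3[2][0]*v0+R3[2][1]*v1+R3[2][2]*v2;
        }
        if (!ideal_gas) {
          for (int i = 0; i < na; ++i) after[i] = { cx[i], cy[i], cz[i] };
          du_intra = intra_energy(ssp, after) - intra_energy(ssp, before);
        }
      }
      double u_new = 0.0;
      bool overlap = false;
      if (!ideal_gas) {
        overlap = !S.mol_inter_row(m, cx, cy, cz, row);
        if (!overlap) for (int k = 0; k < S.nmol; ++k) u_new += row[k];
      }
      double du = (u_new - u_old) + du_intra;
      bool acc = !overlap &&
        ((du <= 0.0) || (R::unif_rand() < std::exp(-beta*du)));
      if (acc) {
        for (int i = 0; i < na; ++i) { S.x[a0+i]=cx[i]; S.y[a0+i]=cy[i]; S.z[a0+i]=cz[i]; }
        if (!ideal_gas)
          for (int k = 0; k < S.nmol; ++k) {
            S.upair[(size_t)m*S.nmol + k] = row[k];
            S.upair[(size_t)k*S.nmol + m] = row[k];
          }
        U += (u_new - u_old);
        if (mt == 0) ++acc_tr; else if (mt == 1) ++acc_rot; else ++acc_tor;
      }
    }
    // step-size tuning during the tuning window only
    if (++since_tune >= 2000 && mv <= ntune) {
      since_tune = 0;
      if (try_tr > 200) { double r = (double)acc_tr/try_tr;
        if (r < 0.3) step_tr *= 0.9; else if (r > 0.5) step_tr *= 1.1;
        step_tr = std::min(step_tr, S.L/4.0); acc_tr = try_tr = 0; }
      if (try_rot > 200) { double r = (double)acc_rot/try_rot;
        if (r < 0.3) step_rot *= 0.9; else if (r > 0.5) step_rot *= 1.1;
        step_rot = std::min(step_rot, PI); acc_rot = try_rot = 0; }
      if (try_tor > 200) { double r = (double)acc_tor/try_tor;
        if (r < 0.3) step_tor *= 0.9; else if (r > 0.5) step_tor *= 1.1;
        step_tor = std::min(step_tor, PI); acc_tor = try_tor = 0; }
      if (try_vol > 50) { double r = (double)acc_vol/try_vol;
        if (r < 0.3) step_lnv *= 0.9; else if (r > 0.5) step_lnv *= 1.1;
        acc_vol = try_vol = 0; }
    }
    if ((mv % sample_every) == 0) {
      vtrace.push_back(S.L*S.L*S.L);
      utrace.push_back(U + (S.tailC != 0.0 ? S.tailC/(S.L*S.L*S.L) : 0.0));
    }
  }
  NumericMatrix out(S.natoms, 3);
  for (int i = 0; i < S.natoms; ++i) { out(i,0)=S.x[i]; out(i,1)=S.y[i]; out(i,2)=S.z[i]; }
  return List::create(_["xyz"] = out, _["box"] = S.L,
                      _["v_trace"] = NumericVector(vtrace.begin(), vtrace.end()),
                      _["u_trace"] = NumericVector(utrace.begin(), utrace.end()),
                      _["steps"] = NumericVector::create(step_tr, step_rot, step_tor, step_lnv),
                      _["acc"] = NumericVector::create(
                        try_tr ? (double)acc_tr/try_tr : NA_REAL,
                        try_rot ? (double)acc_rot/try_rot : NA_REAL,
                        try_tor ? (double)acc_tor/try_tor : NA_REAL,
                        try_vol ? (double)acc_vol/try_vol : NA_REAL));
}

// ------------------------------------------------------------------
// grand canonical Monte Carlo with energy-biased insertion
// ------------------------------------------------------------------

struct GcmcAds {
  // one rigid adsorbate molecule: absolute atom coordinates
  std::vector<double> ax, ay, az;
  double cx, cy, cz; // center used for bias bookkeeping (geometric center)
};

// [[Rcpp::export]]
List cpp_gcmc(List lj_grids, IntegerVector type_of_atom, NumericVector phi_grid,
              double box, NumericMatrix ads_local, NumericVector ads_sig,
              NumericVector ads_eps, NumericVector ads_q,
              double T, double zz, // zz = f/(kB_SI T) in 1/A^3 (ideal-gas density)
              double ntrials_d, double rc_aa, double alpha,
              NumericVector bias_cum, int ncub, double bias_vcell, NumericVector bias_p,
              bool lj_only, double step_tr, double step_rot,
              int sample_every, int nsnap, NumericMatrix init_xyz, int init_nmol) {
  long ntrials = (long)ntrials_d;
  int na = ads_local.nrow();
  int ngrids = lj_grids.size();
  std::vector<const double*> G(ngrids);
  int ng = 0;
  for (int g = 0; g < ngrids; ++g) {
    NumericVector gv = lj_grids[g];
    G[g] = REAL(gv);
    IntegerVector dim = gv.attr("dim");
    ng = dim[0];
  }
  const double* PHI = phi_grid.size() > 1 ? REAL(phi_grid) : nullptr;
  double h = box/ng;
  Dsf dsf(rc_aa, alpha);
  double beta = 1.0/(KB*T);
  double V = box*box*box;
  bool biased = bias_cum.size() > 1;

  std::vector<GcmcAds> mols;
  // rebuild warm-start molecules from init_xyz (groups of na rows)
  for (int m = 0; m < init_nmol; ++m) {
    GcmcAds A; A.ax.resize(na); A.ay.resize(na); A.az.resize(na);
    A.cx = A.cy = A.cz = 0.0;
    for (int i = 0; i < na; ++i) {
      A.ax[i] = init_xyz(m*na+i, 0); A.ay[i] = init_xyz(m*na+i, 1); A.az[i] = init_xyz(m*na+i, 2);
      A.cx += A.ax[i]/na; A.cy += A.ay[i]/na; A.cz += A.az[i]/na;
    }
    mols.push_back(A);
  }

  // energy of one molecule with the frozen matrix via the maps
  auto map_energy = [&](const GcmcAds& A, double* lj_out, double* coul_out) {
    double ul = 0.0, uc = 0.0;
    for (int i = 0; i < na; ++i) {
      ul += interp3(G[type_of_atom[i]], ng, h, box, A.ax[i], A.ay[i], A.az[i]);
      if (!lj_only && PHI && ads_q[i] != 0.0)
        uc += ads_q[i]*interp3(PHI, ng, h, box, A.ax[i], A.ay[i], A.az[i]);
    }
    *lj_out = ul; *coul_out = uc;
    return ul + uc;
  };
  // adsorbate-adsorbate interaction of molecule A with others (skip index)
  auto aa_energy = [&](const GcmcAds& A, int skip) {
    double u = 0.0;
    double rc2 = rc_aa*rc_aa;
    for (size_t m = 0; m < mols.size(); ++m) {
      if ((int)m == skip) continue;
      const GcmcAds& B = mols[m];
      for (int i = 0; i < na; ++i)
        for (int j = 0; j < na; ++j) {
          double dx = mimg(A.ax[i]-B.ax[j], box);
          double dy = mimg(A.ay[i]-B.ay[j], box);
          double dz = mimg(A.az[i]-B.az[j], box);
          double r2 = dx*dx+dy*dy+dz*dz;
          if (r2 >= rc2) continue;
          if (r2 < 1e-4) return 1e12;
          double sij = 0.5*(ads_sig[i]+ads_sig[j]);
          double eij = std::sqrt(ads_eps[i]*ads_eps[j]);
          u += lj_pair(eij, sij, r2);
          if (!lj_only) {
            double qq = ads_q[i]*ads_q[j];
            if (qq != 0.0) u += dsf.u(qq, std::sqrt(r2));
          }
        }
    }
    return u;
  };
  auto mol_energy = [&](const GcmcAds& A, int skip) {
    double ul, uc;
    double um = map_energy(A, &ul, &uc);
    return um + aa_energy(A, skip);
  };
  // bias sampling density at a point (per A^3); uniform = 1/V
  auto pdens = [&](double px, double py, double pz) {
    if (!biased) return 1.0/V;
    double hb = box/ncub;
    px -= box*std::floor(px/box); py -= box*std::floor(py/box); pz -= box*std::floor(pz/box);
    int ix = std::min((int)(px/hb), ncub-1);
    int iy = std::min((int)(py/hb), ncub-1);
    int iz = std::min((int)(pz/hb), ncub-1);
    long c = (long)iz*ncub*ncub + (long)iy*ncub + ix;
    return bias_p[c] / bias_vcell;
  };

  long nacc_ins=0, ntry_ins=0, nacc_del=0, ntry_del=0, nacc_tr=0, ntry_tr=0, nacc_rot=0, ntry_rot=0;
  double sumN = 0.0, sumN2 = 0.0;
  long ncount = 0;
  std::vector<double> ntrace;
  std::vector<double> samp_lj, samp_coul; // per-molecule adsorbate-matrix components
  List snapshots(nsnap > 0 ? nsnap : 0);
  int snap_taken = 0;
  long snap_every = (nsnap > 0) ? std::max((long)1, ntrials/2/nsnap) : 0;
  long half = ntrials/2;

  for (long t = 1; t <= ntrials; ++t) {
    double u4 = R::unif_rand();
    if (u4 < 0.25) {
      // insertion
      ++ntry_ins;
      GcmcAds A; A.ax.resize(na); A.ay.resize(na); A.az.resize(na);
      double px, py, pz;
      if (biased) {
        double u = R::unif_rand();
        // binary search in cumulative weights
        long lo = 0, hi = bias_cum.size()-1;
        while (lo < hi) { long mid = (lo+hi)/2; if (bias_cum[mid] < u) lo = mid+1; else hi = mid; }
        long c = lo;
        int ix = c % ncub; int iy = (c/ncub) % ncub; int iz = c/(ncub*ncub);
        double hb = box/ncub;
        px = (ix + R::unif_rand())*hb; py = (iy + R::unif_rand())*hb; pz = (iz + R::unif_rand())*hb;
      } else {
        px = R::unif_rand()*box; py = R::unif_rand()*box; pz = R::unif_rand()*box;
      }
      double R3[3][3]; rand_rotation(R3);
      for (int i = 0; i < na; ++i) {
        double v0 = ads_local(i,0), v1 = ads_local(i,1), v2 = ads_local(i,2);
        A.ax[i] = px + R3[0][0]*v0+R3[0][1]*v1+R3[0][2]*v2;
        A.ay[i] = py + R3[1][0]*v0+R3[1][1]*v1+R3[1][2]*v2;
        A.az[i] = pz + R3[2][0]*v0+R3[2][1]*v1+R3[2][2]*v2;
      }
      A.cx = px; A.cy = py; A.cz = pz;
      double uN = mol_energy(A, -1);
      double acc = zz/((mols.size()+1.0)*pdens(px,py,pz)) * std::exp(-beta*uN);
      if (uN < 1e11 && R::unif_rand() < acc) { mols.push_back(A); ++nacc_ins; }
    } else if (u4 < 0.5) {
      // deletion
      ++ntry_del;
      if (!mols.empty()) {
        int m = (int)(R::unif_rand()*mols.size());
        double uO = mol_energy(mols[m], m);
        double acc = mols.size()*pdens(mols[m].cx, mols[m].cy, mols[m].cz)/zz * std::exp(beta*uO);
        if (R::unif_rand() < acc) {
          mols[m] = mols.back(); mols.pop_back(); ++nacc_del;
        }
      }
    } else if (u4 < 0.75) {
      // translation
      ++ntry_tr;
      if (!mols.empty()) {
        int m = (int)(R::unif_rand()*mols.size());
        GcmcAds A = mols[m];
        double d0 = step_tr*(2.0*R::unif_rand()-1.0);
        double d1 = step_tr*(2.0*R::unif_rand()-1.0);
        double d2 = step_tr*(2.0*R::unif_rand()-1.0);
        for (int i = 0; i < na; ++i) { A.ax[i]+=d0; A.ay[i]+=d1; A.az[i]+=d2; }
        A.cx+=d0; A.cy+=d1; A.cz+=d2;
        double du = mol_energy(A, m) - mol_energy(mols[m], m);
        if (du <= 0.0 || R::unif_rand() < std::exp(-beta*du)) { mols[m] = A; ++nacc_tr; }
      }
    } else {
      // rotation
      ++ntry_rot;
      if (!mols.empty()) {
        int m = (int)(R::unif_rand()*mols.size());
        GcmcAds A = mols[m];
        double ux,uy,uz; rand_unit(ux,uy,uz);
        double R3[3][3]; axis_angle(ux,uy,uz, step_rot*(2.0*R::unif_rand()-1.0), R3);
        for (int i = 0; i < na; ++i) {
          double v0=A.ax[i]-A.cx, v1=A.ay[i]-A.cy, v2=A.az[i]-A.cz;
          A.ax[i]=A.cx+R3[0][0]*v0+R3[0][1]*v1+R3[0][2]*v2;
          A.ay[i]=A.cy+R3[1][0]*v0+R3[1][1]*v1+R3[1][2]*v2;
          A.az[i]=A.cz+R3[2][0]*v0+R3[2][1]*v1+R3[2][2]*v2;
        }
        double du = mol_energy(A, m) - mol_energy(mols[m], m);
        if (du <= 0.0 || R::unif_rand() < std::exp(-beta*du)) { mols[m] = A; ++nacc_rot; }
      }
    }
    if (t > half) {
      sumN += mols.size(); sumN2 += (double)mols.size()*mols.size(); ++ncount;
      if ((t % sample_every) == 0) {
        ntrace.push_back((double)mols.size());
        for (size_t m = 0; m < mols.size(); ++m) {
          double ul, uc;
          map_energy(mols[m], &ul, &uc);
          samp_lj.push_back(ul); samp_coul.push_back(uc);
        }
      }
      if (nsnap > 0 && snap_taken < nsnap && ((t - half) % snap_every) == 0) {
        NumericMatrix sm(mols.size()*na, 3);
        for (size_t m = 0; m < mols.size(); ++m)
          for (int i = 0; i < na; ++i) {
            sm(m*na+i, 0) = mols[m].ax[i]; sm(m*na+i, 1) = mols[m].ay[i]; sm(m*na+i, 2) = mols[m].az[i];
          }
        snapshots[snap_taken++] = sm;
      }
    }
  }
  NumericMatrix fin(mols.size()*na, 3);
  for (size_t m = 0; m < mols.size(); ++m)
    for (int i = 0; i < na; ++i) {
      fin(m*na+i,0)=mols[m].ax[i]; fin(m*na+i,1)=mols[m].ay[i]; fin(m*na+i,2)=mols[m].az[i];
    }
  double avgN = ncount ? sumN/ncount : 0.0;
  double varN = ncount ? sumN2/ncount - avgN*avgN : 0.0;
  if (snap_taken < (int)snapshots.size()) {
    List trimmed(snap_taken);
    for (int i = 0; i < snap_taken; ++i) trimmed[i] = snapshots[i];
    snapshots = trimmed;
  }
  return List::create(_["avg_N"] = avgN, _["var_N"] = varN,
                      _["n_trace"] = NumericVector(ntrace.begin(), ntrace.end()),
                      _["sample_lj"] = NumericVector(samp_lj.begin(), samp_lj.end()),
                      _["sample_coul"] = NumericVector(samp_coul.begin(), samp_coul.end()),
                      _["snapshots"] = snapshots,
                      _["final_xyz"] = fin, _["final_nmol"] = (int)mols.size(),
                      _["acc"] = NumericVector::create(
                        ntry_ins ? (double)nacc_ins/ntry_ins : NA_REAL,
                        ntry_del ? (double)nacc_del/ntry_del : NA_REAL,
                        ntry_tr ? (double)nacc_tr/ntry_tr : NA_REAL,
                        ntry_rot ? (double)nacc_rot/ntry_rot : NA_REAL));
}
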