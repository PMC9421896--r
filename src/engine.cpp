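// Coarse-grained simulation engine: Go-type background potential,
// redox-tunable double-well disulfide term, triplet repulsion,
// flat-bottom breaking restraint, FIRE-style minimizer and a BAOAB
// Langevin integrator with constant-velocity pulling.
//
// Internal units: kcal/mol, Angstrom, fs.  Mass is stored in
// kcal mol^-1 fs^2 A^-2 (1 amu = 1e7/4184 of those).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double KB = 0.0019872041; // kcal/mol/K

// ---------------------------------------------------------------------------
// Deterministic fast RNG: xoshiro256++ seeded via splitmix64, polar normals.
// ---------------------------------------------------------------------------
struct XRng {
  uint64_t s[4];
  bool have;
  double cached;
  explicit XRng(uint64_t seed) : have(false), cached(0.0) {
    uint64_t z = seed;
    for (int i = 0; i < 4; i++) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline double norm() {
    if (have) { have = false; return cached; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(s2) / s2);
    cached = v * f; have = true;
    return u * f;
  }
};

// ---------------------------------------------------------------------------
// System description parsed once from an R list.
// ---------------------------------------------------------------------------
struct PairTerm { int i, j; double a, b; }; // generic pair with 2 parameters
struct Dihedral { int i, j, k, l; double phi0, kd; };
struct Tether   { int bead; double p[3]; double k; };

struct DynPar  { double A, Db, rb, sb, Dc, rc, sc; };
struct TriPar  { double a, b, c, d; };
struct RestPar { double k, r1, r2, r3; };

struct System {
  int n;
  std::vector<double> mass;              // internal mass units
  std::vector<PairTerm> bonds;           // a = b0, b = k   (U = 0.5 k (r-b0)^2)
  std::vector<PairTerm> contacts;        // a = r0, b = eps (12-10 well)
  std::vector<PairTerm> ev;              // a = sigma, b = k (quartic)
  std::vector<Dihedral> dihedrals;
  int ssMode;                            // 0 none, 1 dynamic, 2 static, 3 restraint
  std::vector<PairTerm> ssPairs;         // dynamic double-well pairs (a,b unused)
  std::vector<int> cysBeads;             // side-center beads of cysteines
  std::vector<PairTerm> restPairs;       // flat-bottom restrained pairs
  DynPar dyn; TriPar tri; RestPar rest;
  std::vector<Tether> tethers;
  // moving tether (pulling); kMove <= 0 disables
  int moveBead; double moveP0[3], moveDir[3], moveSpeed, moveK;
  // monitored anchors (backbone beads) for extension
  int anchorA, anchorB; double nativeDist;
};

static void parsePairs(const NumericMatrix& m, std::vector<PairTerm>& out) {
  out.clear();
  for (int r = 0; r < m.nrow(); r++) {
    PairTerm p;
    p.i = (int)m(r, 0); p.j = (int)m(r, 1);
    p.a = m.ncol() > 2 ? m(r, 2) : 0.0;
    p.b = m.ncol() > 3 ? m(r, 3) : 0.0;
    out.push_back(p);
  }
}

static System parseSystem(const List& sys) {
  System S;
  NumericVector mass = sys["mass"];
  S.n = mass.size();
  S.mass.assign(mass.begin(), mass.end());
  parsePairs(as<NumericMatrix>(sys["bonds"]), S.bonds);
  parsePairs(as<NumericMatrix>(sys["contacts"]), S.contacts);
  parsePairs(as<NumericMatrix>(sys["evPairs"]), S.ev);
  NumericMatrix dih = sys["dihedrals"];
  S.dihedrals.clear();
  for (int r = 0; r < dih.nrow(); r++) {
    Dihedral d;
    d.i = (int)dih(r, 0); d.j = (int)dih(r, 1);
    d.k = (int)dih(r, 2); d.l = (int)dih(r, 3);
    d.phi0 = dih(r, 4); d.kd = dih(r, 5);
    S.dihedrals.push_back(d);
  }
  S.ssMode = as<int>(sys["ssMode"]);
  parsePairs(as<NumericMatrix>(sys["ssPairs"]), S.ssPairs);
  IntegerVector cb = sys["cysBeads"];
  S.cysBeads.assign(cb.begin(), cb.end());
  parsePairs(as<NumericMatrix>(sys["restPairs"]), S.restPairs);
  NumericVector dp = sys["dynPar"];   // A, Db, rb, sb, Dc, rc, sc
  S.dyn = { dp[0], dp[1], dp[2], dp[3], dp[4], dp[5], dp[6] };
  NumericVector tp = sys["tripletPar"];
  S.tri = { tp[0], tp[1], tp[2], tp[3] };
  NumericVector rp = sys["restPar"];
  S.rest = { rp[0], rp[1], rp[2], rp[3] };
  NumericMatrix te = sys["tethers"];
  S.tethers.clear();
  for (int r = 0; r < te.nrow(); r++) {
    Tether t;
    t.bead = (int)te(r, 0);
    t.p[0] = te(r, 1); t.p[1] = te(r, 2); t.p[2] = te(r, 3);
    t.k = te(r, 4);
    S.tethers.push_back(t);
  }
  S.moveK = 0.0; S.moveBead = -1; S.moveSpeed = 0.0;
  if (sys.containsElementNamed("moving") && !Rf_isNull(sys["moving"])) {
    List mv = sys["moving"];
    S.moveBead = as<int>(mv["bead"]);
    NumericVector p0 = mv["p0"], dir = mv["dir"];
    for (int k = 0; k < 3; k++) { S.moveP0[k] = p0[k]; S.moveDir[k] = dir[k]; }
    S.moveSpeed = as<double>(mv["speed"]);
    S.moveK = as<double>(mv["k"]);
  }
  S.anchorA = as<int>(sys["anchorA"]);
  S.anchorB = as<int>(sys["anchorB"]);
  S.nativeDist = as<double>(sys["nativeDist"]);
  return S;
}

// ---------------------------------------------------------------------------
// Scalar potential pieces (shared with the R-level uDynSS/uFlatBottom via
// exported evaluators at the bottom).
// ---------------------------------------------------------------------------
static inline void dynSS(double r, const DynPar& p, double& u, double& dudr) {
  double inv = 1.0 / r;
  double i6 = inv * inv * inv; i6 *= i6;          // r^-6
  double i12 = i6 * i6;                           // r^-12
  double gb = std::exp(-0.5 * (r - p.rb) * (r - p.rb) / (p.sb * p.sb));
  double gc = std::exp(-0.5 * (r - p.rc) * (r - p.rc) / (p.sc * p.sc));
  u = p.A * i12 - p.Db * gb - p.Dc * gc;
  dudr = -12.0 * p.A * i12 * inv
       + p.Db * gb * (r - p.rb) / (p.sb * p.sb)
       + p.Dc * gc * (r - p.rc) / (p.sc * p.sc);
}

static inline double tripSwitch(double r, const TriPar& p, double& ds) {
  double e = std::exp((r - p.c) / p.d);
  double s = 1.0 / (1.0 + e);
  ds = -s * s * e / p.d;
  return s;
}

// U = a * (s(r1) s(r2))^b
static inline void tripEnergy(double r1, double r2, const TriPar& p,
                              double& u, double& du1, double& du2) {
  double ds1, ds2;
  double s1 = tripSwitch(r1, p, ds1);
  double s2 = tripSwitch(r2, p, ds2);
  double prod = s1 * s2;
  if (prod <= 0.0) { u = 0.0; du1 = 0.0; du2 = 0.0; return; }
  double pb = std::pow(prod, p.b);
  u = p.a * pb;
  double fac = p.a * p.b * pb / prod;
  du1 = fac * ds1 * s2;
  du2 = fac * s1 * ds2;
}

static inline void flatBottom(double r, const RestPar& p, double& u, double& dudr) {
  if (r < p.r1) {
    u = p.k * (r - p.r1) * (r - p.r1);
    dudr = 2.0 * p.k * (r - p.r1);
  } else if (r <= p.r2) {
    u = 0.0; dudr = 0.0;
  } else if (r <= p.r3) {
    u = p.k * (r - p.r2) * (r - p.r2);
    dudr = 2.0 * p.k * (r - p.r2);
  } else {
    double w = p.r3 - p.r2;
    u = p.k * w * w + 2.0 * p.k * w * (r - p.r3);
    dudr = 2.0 * p.k * w;
  }
}

// ---------------------------------------------------------------------------
// Full energy + forces.  coords and forces are length 3n arrays (xyz packed).
// ---------------------------------------------------------------------------
struct Energy {
  double total, go, ss;
  std::vector<double> ssPairE; // per dynamic/restraint pair
};

static inline double dist3(const double* x, int i, int j, double* d) {
  d[0] = x[3 * i] - x[3 * j];
  d[1] = x[3 * i + 1] - x[3 * j + 1];
  d[2] = x[3 * i + 2] - x[3 * j + 2];
  return std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
}

static inline void addPairForce(double* f, int i, int j, const double* d,
                                double r, double dudr) {
  // force on i = -dU/dr * (xi-xj)/r
  double g = -dudr / r;
  f[3 * i] += g * d[0]; f[3 * i + 1] += g * d[1]; f[3 * i + 2] += g * d[2];
  f[3 * j] -= g * d[0]; f[3 * j + 1] -= g * d[1]; f[3 * j + 2] -= g * d[2];
}

static Energy evalEnergy(const System& S, const double* x, double* f,
                         double tNow) {
  Energy E;
  E.total = 0.0; E.go = 0.0; E.ss = 0.0;
  std::fill(f, f + 3 * S.n, 0.0);
  double d[3];

  // bonds
  for (size_t b = 0; b < S.bonds.size(); b++) {
    const PairTerm& p = S.bonds[b];
    double r = dist3(x, p.i, p.j, d);
    if (r < 1e-8) stop("overlapping bonded beads %d and %d", p.i, p.j);
    double dr = r - p.a;
    E.go += 0.5 * p.b * dr * dr;
    addPairForce(f, p.i, p.j, d, r, p.b * dr);
  }
  // 12-10 native contacts
  for (size_t c = 0; c < S.contacts.size(); c++) {
    const PairTerm& p = S.contacts[c];
    double r = dist3(x, p.i, p.j, d);
    if (r < 0.1) stop("overlapping beads %d and %d (r < 0.1 A)", p.i, p.j);
    double q = p.a / r;
    double q2 = q * q, q10 = q2 * q2 * q2 * q2 * q2, q12 = q10 * q2;
    E.go += p.b * (5.0 * q12 - 6.0 * q10);
    double dudr = (60.0 * p.b / r) * (q10 - q12);
    addPairForce(f, p.i, p.j, d, r, dudr);
  }
  // quartic excluded volume
  for (size_t c = 0; c < S.ev.size(); c++) {
    const PairTerm& p = S.ev[c];
    double dx0 = x[3 * p.i] - x[3 * p.j];
    double dx1 = x[3 * p.i + 1] - x[3 * p.j + 1];
    double dx2 = x[3 * p.i + 2] - x[3 * p.j + 2];
    double r2 = dx0 * dx0 + dx1 * dx1 + dx2 * dx2;
    if (r2 >= p.a * p.a) continue;
    double r = std::sqrt(r2);
    if (r < 0.1) stop("overlapping beads %d and %d (r < 0.1 A)", p.i, p.j);
    double s = p.a - r;
    E.go += p.b * s * s * s * s;
    d[0] = dx0; d[1] = dx1; d[2] = dx2;
    addPairForce(f, p.i, p.j, d, r, -4.0 * p.b * s * s * s);
  }
  // pseudo-dihedrals: U = kd (1 - cos(phi - phi0))
  for (size_t c = 0; c < S.dihedrals.size(); c++) {
    const Dihedral& dh = S.dihedrals[c];
    double b1[3], b2[3], b3[3];
    for (int k = 0; k < 3; k++) {
      b1[k] = x[3 * dh.j + k] - x[3 * dh.i + k];
      b2[k] = x[3 * dh.k + k] - x[3 * dh.j + k];
      b3[k] = x[3 * dh.l + k] - x[3 * dh.k + k];
    }
    double n1[3] = { b1[1] * b2[2] - b1[2] * b2[1],
                     b1[2] * b2[0] - b1[0] * b2[2],
                     b1[0] * b2[1] - b1[1] * b2[0] };
    double n2[3] = { b2[1] * b3[2] - b2[2] * b3[1],
                     b2[2] * b3[0] - b2[0] * b3[2],
                     b2[0] * b3[1] - b2[1] * b3[0] };
    double n1sq = n1[0] * n1[0] + n1[1] * n1[1] + n1[2] * n1[2];
    double n2sq = n2[0] * n2[0] + n2[1] * n2[1] + n2[2] * n2[2];
    double b2len = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
    if (n1sq < 1e-12 || n2sq < 1e-12 || b2len < 1e-8) continue; // collinear
    double m[3] = { n1[1] * n2[2] - n1[2] * n2[1],
                    n1[2] * n2[0] - n1[0] * n2[2],
                    n1[0] * n2[1] - n1[1] * n2[0] };
    double y = (m[0] * b2[0] + m[1] * b2[1] + m[2] * b2[2]) / b2len;
    double xdot = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
    double phi = std::atan2(y, xdot);
    E.go += dh.kd * (1.0 - std::cos(phi - dh.phi0));
    double dU = dh.kd * std::sin(phi - dh.phi0); // dU/dphi
    double A[3], B[3];
    for (int k = 0; k < 3; k++) {
      A[k] = -b2len / n1sq * n1[k]; // dphi/dri
      B[k] =  b2len / n2sq * n2[k]; // dphi/drl
    }
    double c1 = (b1[0] * b2[0] + b1[1] * b2[1] + b1[2] * b2[2]) / (b2len * b2len);
    double c2 = (b3[0] * b2[0] + b3[1] * b2[1] + b3[2] * b2[2]) / (b2len * b2len);
    for (int k = 0; k < 3; k++) {
      double dri = A[k];
      double drl = B[k];
      double drj = (-1.0 - c1) * A[k] + c2 * B[k];
      double drk = c1 * A[k] + (-1.0 - c2) * B[k];
      f[3 * dh.i + k] -= dU * dri;
      f[3 * dh.j + k] -= dU * drj;
      f[3 * dh.k + k] -= dU * drk;
      f[3 * dh.l + k] -= dU * drl;
    }
  }

  // disulfide terms
  size_t npair = (S.ssMode == 1) ? S.ssPairs.size()
               : (S.ssMode == 3) ? S.restPairs.size() : 0;
  E.ssPairE.assign(npair, 0.0);
  if (S.ssMode == 1) {
    // double-well over all cysteine pairs + triplet repulsion
    size_t nc = S.cysBeads.size();
    std::vector<double> rp(S.ssPairs.size());
    std::vector<std::vector<int> > byCys(nc);
    // pair order must match R: all pairs (ci, cj), ci < cj by list order
    size_t q = 0;
    for (size_t a = 0; a < nc; a++)
      for (size_t b = a + 1; b < nc; b++) {
        byCys[a].push_back((int)q);
        byCys[b].push_back((int)q);
        q++;
      }
    for (size_t c = 0; c < S.ssPairs.size(); c++) {
      const PairTerm& p = S.ssPairs[c];
      double r = dist3(x, p.i, p.j, d);
      double u, dudr;
      dynSS(r, S.dyn, u, dudr);
      E.ss += u; E.ssPairE[c] = u;
      addPairForce(f, p.i, p.j, d, r, dudr);
      rp[c] = r;
    }
    // triplet repulsion: for each cysteine, every pair of its partners
    for (size_t a = 0; a < nc; a++) {
      const std::vector<int>& idx = byCys[a];
      for (size_t u1 = 0; u1 < idx.size(); u1++)
        for (size_t u2 = u1 + 1; u2 < idx.size(); u2++) {
          int q1 = idx[u1], q2 = idx[u2];
          double uE, du1, du2;
          tripEnergy(rp[q1], rp[q2], S.tri, uE, du1, du2);
          if (uE <= 1e-12) continue;
          E.ss += uE;
          const PairTerm& p1 = S.ssPairs[q1];
          double r1 = dist3(x, p1.i, p1.j, d);
          addPairForce(f, p1.i, p1.j, d, r1, du1);
          const PairTerm& p2 = S.ssPairs[q2];
          double r2 = dist3(x, p2.i, p2.j, d);
          addPairForce(f, p2.i, p2.j, d, r2, du2);
        }
    }
  } else if (S.ssMode == 3) {
    for (size_t c = 0; c < S.restPairs.size(); c++) {
      const PairTerm& p = S.restPairs[c];
      double r = dist3(x, p.i, p.j, d);
      double u, dudr;
      flatBottom(r, S.rest, u, dudr);
      E.ss += u; E.ssPairE[c] = u;
      addPairForce(f, p.i, p.j, d, r, dudr);
    }
  }
  // mode 2 (static): crosslinks are plain harmonic bonds, already in S.bonds.

  // tethers
  for (size_t c = 0; c < S.tethers.size(); c++) {
    const Tether& t = S.tethers[c];
    double dx0 = x[3 * t.bead] - t.p[0];
    double dx1 = x[3 * t.bead + 1] - t.p[1];
    double dx2 = x[3 * t.bead + 2] - t.p[2];
    E.go += 0.5 * t.k * (dx0 * dx0 + dx1 * dx1 + dx2 * dx2);
    f[3 * t.bead]     -= t.k * dx0;
    f[3 * t.bead + 1] -= t.k * dx1;
    f[3 * t.bead + 2] -= t.k * dx2;
  }
  // moving tether
  if (S.moveK > 0.0 && S.moveBead >= 0) {
    double p[3];
    for (int k = 0; k < 3; k++)
      p[k] = S.moveP0[k] + S.moveDir[k] * S.moveSpeed * tNow;
    double dx0 = x[3 * S.moveBead] - p[0];
    double dx1 = x[3 * S.moveBead + 1] - p[1];
    double dx2 = x[3 * S.moveBead + 2] - p[2];
    E.go += 0.5 * S.moveK * (dx0 * dx0 + dx1 * dx1 + dx2 * dx2);
    f[3 * S.moveBead]     -= S.moveK * dx0;
    f[3 * S.moveBead + 1] -= S.moveK * dx1;
    f[3 * S.moveBead + 2] -= S.moveK * dx2;
  }
  E.total = E.go + E.ss;
  return E;
}

// signed spring force along the pulling axis, kcal/mol/A
static inline double springForce(const System& S, const double* x, double tNow) {
  if (S.moveK <= 0.0 || S.moveBead < 0) return 0.0;
  double p[3], dx[3];
  for (int k = 0; k < 3; k++) {
    p[k] = S.moveP0[k] + S.moveDir[k] * S.moveSpeed * tNow;
    dx[k] = p[k] - x[3 * S.moveBead + k];
  }
  return S.moveK * (dx[0] * S.moveDir[0] + dx[1] * S.moveDir[1] +
                    dx[2] * S.moveDir[2]);
}

static inline double extension(const System& S, const double* x) {
  double d[3];
  double r = dist3(x, S.anchorB, S.anchorA, d);
  return r - S.nativeDist;
}

// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List engineEnergy(List sys, NumericMatrix coords) {
  System S = parseSystem(sys);
  if (coords.nrow() != S.n) stop("coordinate/mass size mismatch");
  std::vector<double> x(3 * S.n), f(3 * S.n);
  for (int i = 0; i < S.n; i++)
    for (int k = 0; k < 3; k++) x[3 * i + k] = coords(i, k);
  Energy E = evalEnergy(S, x.data(), f.data(), 0.0);
  NumericMatrix fm(S.n, 3);
  for (int i = 0; i < S.n; i++)
    for (int k = 0; k < 3; k++) fm(i, k) = f[3 * i + k];
  return List::create(_["energy"] = E.total, _["go"] = E.go, _["ss"] = E.ss,
                      _["forces"] = fm, _["ssPairEnergies"] = wrap(E.ssPairE));
}

// FIRE (fast inertial relaxation engine) minimizer with unit fictitious
// masses; deterministic.  Returns relaxed coordinates and the largest
// gradient component.
// [[Rcpp::export]]
List engineMinimize(List sys, NumericMatrix coords, int maxSteps = 2000,
                    double fTol = 1e-4, double step0 = 5e-3) {
  System S = parseSystem(sys);
  const int nd = 3 * S.n;
  std::vector<double> x(nd), f(nd), v(nd, 0.0);
  for (int i = 0; i < S.n; i++)
    for (int k = 0; k < 3; k++) x[3 * i + k] = coords(i, k);
  Energy E = evalEnergy(S, x.data(), f.data(), 0.0);
  double dt = step0, dtMax = 20.0 * step0, alpha = 0.1, gmax = 0.0;
  int nPos = 0, it = 0;
  const double dxCap = 0.1; // per-coordinate displacement cap, A
  for (; it < maxSteps; it++) {
    gmax = 0.0;
    for (int q = 0; q < nd; q++) gmax = std::max(gmax, std::fabs(f[q]));
    if (gmax < fTol) break;
    double P = 0.0, vn = 0.0, fn2 = 0.0;
    for (int q = 0; q < nd; q++) {
      P += f[q] * v[q];
      vn += v[q] * v[q];
      fn2 += f[q] * f[q];
    }
    if (P > 0.0) {
      double mix = alpha * std::sqrt(vn / std::max(fn2, 1e-300));
      for (int q = 0; q < nd; q++)
        v[q] = (1.0 - alpha) * v[q] + mix * f[q];
      if (++nPos > 5) { dt = std::min(dt * 1.1, dtMax); alpha *= 0.99; }
    } else {
      std::fill(v.begin(), v.end(), 0.0);
      dt *= 0.5; alpha = 0.1; nPos = 0;
    }
    for (int q = 0; q < nd; q++) {
      v[q] += dt * f[q];
      double dxq = dt * v[q];
      if (dxq > dxCap) dxq = dxCap;
      if (dxq < -dxCap) dxq = -dxCap;
      x[q] += dxq;
    }
    E = evalEnergy(S, x.data(), f.data(), 0.0);
  }
  NumericMatrix xm(S.n, 3);
  for (int i = 0; i < S.n; i++)
    for (int k = 0; k < 3; k++) xm(i, k) = x[3 * i + k];
  return List::create(_["coords"] = xm, _["energy"] = E.total,
                      _["gradMax"] = gmax, _["iterations"] = it);
}

// ---------------------------------------------------------------------------
// BAOAB Langevin integrator.  gamma in fs^-1; temperature in K.  With
// gamma = 0 the O-step is the identity and the scheme reduces to velocity
// Verlet (NVE).  logPairs: bead-index pairs whose distances are recorded at
// every saved frame (cysteine side-center pairs).
// [[Rcpp::export]]
List engineRun(List sys, NumericMatrix coords, Nullable<NumericMatrix> vel0,
               double dt, int nSteps = 0, int saveEvery = 200,
               double temperature = 300.0, double gamma = 5e-5,
               double seed = 1, bool saveCoords = true,
               IntegerMatrix logPairs = IntegerMatrix(0, 2),
               double tOffset = 0.0) {
  System S = parseSystem(sys);
  if (coords.nrow() != S.n) stop("coordinate/mass size mismatch");
  XRng rng((uint64_t)(seed < 0 ? -seed : seed) + 0x5DEECE66DULL);
  std::vector<double> x(3 * S.n), v(3 * S.n, 0.0), f(3 * S.n);
  for (int i = 0; i < S.n; i++)
    for (int k = 0; k < 3; k++) x[3 * i + k] = coords(i, k);
  if (vel0.isNotNull()) {
    NumericMatrix vm(vel0);
    for (int i = 0; i < S.n; i++)
      for (int k = 0; k < 3; k++) v[3 * i + k] = vm(i, k);
  } else if (temperature > 0.0) {
    for (int i = 0; i < S.n; i++) {
      double sd = std::sqrt(KB * temperature / S.mass[i]);
      for (int k = 0; k < 3; k++) v[3 * i + k] = sd * rng.norm();
    }
  }
  double c1 = (gamma > 0.0) ? std::exp(-gamma * dt) : 1.0;
  double cT = (gamma > 0.0) ? std::sqrt((1.0 - c1 * c1) * KB * temperature) : 0.0;

  int nFrames = nSteps / saveEvery + 1;
  int nLog = logPairs.nrow();
  NumericMatrix logM(nFrames, 6); // step, time, extension, springF, epot, ekin
  NumericMatrix pd(nFrames, nLog);
  NumericVector coordsOut;
  std::vector<double> trajCoords;
  if (saveCoords) trajCoords.reserve((size_t)nFrames * 3 * S.n);

  double tNow = tOffset;
  Energy E = evalEnergy(S, x.data(), f.data(), tNow);
  double dtime = dt;
  int frame = 0;
  double dvec[3];
  auto record = [&](int stepIdx) {
    double ekin = 0.0;
    for (int i = 0; i < S.n; i++) {
      double vv = v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                  v[3 * i + 2] * v[3 * i + 2];
      ekin += 0.5 * S.mass[i] * vv;
    }
    logM(frame, 0) = stepIdx;
    logM(frame, 1) = tNow;
    logM(frame, 2) = extension(S, x.data());
    logM(frame, 3) = springForce(S, x.data(), tNow);
    logM(frame, 4) = E.total;
    logM(frame, 5) = ekin;
    for (int q = 0; q < nLog; q++)
      pd(frame, q) = dist3(x.data(), logPairs(q, 0), logPairs(q, 1), dvec);
    if (saveCoords)
      for (int q = 0; q < 3 * S.n; q++) trajCoords.push_back(x[q]);
    frame++;
  };
  record(0);

  for (int step = 1; step <= nSteps; step++) {
    // B: half kick
    for (int i = 0; i < S.n; i++) {
      double im = dtime * 0.5 / S.mass[i];
      for (int k = 0; k < 3; k++) v[3 * i + k] += im * f[3 * i + k];
    }
    // A: half drift
    for (int q = 0; q < 3 * S.n; q++) x[q] += 0.5 * dtime * v[q];
    // O
    if (gamma > 0.0) {
      for (int i = 0; i < S.n; i++) {
        double sd = cT / std::sqrt(S.mass[i]);
        for (int k = 0; k < 3; k++)
          v[3 * i + k] = c1 * v[3 * i + k] + sd * rng.norm();
      }
    }
    // A: half drift
    for (int q = 0; q < 3 * S.n; q++) x[q] += 0.5 * dtime * v[q];
    tNow += dtime;
    E = evalEnergy(S, x.data(), f.data(), tNow);
    // B: half kick
    for (int i = 0; i < S.n; i++) {
      double im = dtime * 0.5 / S.mass[i];
      for (int k = 0; k < 3; k++) v[3 * i + k] += im * f[3 * i + k];
    }
    if (step % saveEvery == 0) {
      for (int q = 0; q < 3 * S.n; q++)
        if (std::fabs(x[q]) > 1e6)
          stop("numeric blow-up at step %d (|coordinate| > 1e6 A)", step);
      record(step);
    }
  }

  NumericMatrix vOut(S.n, 3), xOut(S.n, 3);
  for (int i = 0; i < S.n; i++)
    for (int k = 0; k < 3; k++) {
      vOut(i, k) = v[3 * i + k];
      xOut(i, k) = x[3 * i + k];
    }
  List out = List::create(
      _["log"] = logM, _["pairDist"] = pd, _["finalCoords"] = xOut,
      _["finalVel"] = vOut, _["tEnd"] = tNow, _["nFrames"] = frame);
  if (saveCoords) {
    NumericVector tc(trajCoords.begin(), trajCoords.end());
    tc.attr("dim") = IntegerVector::create(3, S.n, frame);
    out["coords"] = tc;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Scalar evaluators used by the R-level potential functions.
// [[Rcpp::export]]
NumericMatrix evalDynSS(NumericVector r, NumericVector par) {
  DynPar p = { par[0], par[1], par[2], par[3], par[4], par[5], par[6] };
  NumericMatrix out(r.size(), 2);
  for (int i = 0; i < r.size(); i++) {
    double u, dudr;
    dynSS(r[i], p, u, dudr);
    out(i, 0) = u; out(i, 1) = -dudr; // radial force = -dU/dr
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix evalFlatBottom(NumericVector r, NumericVector par) {
  RestPar p = { par[0], par[1], par[2], par[3] };
  NumericMatrix out(r.size(), 2);
  for (int i = 0; i < r.size(); i++) {
    double u, dudr;
    flatBottom(r[i], p, u, dudr);
    out(i, 0) = u; out(i, 1) = -dudr;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector evalTriplet(NumericVector rki, NumericVector rkj, NumericVector par) {
  TriPar p = { par[0], par[1], par[2], par[3] };
  NumericVector out(rki.size());
  for (int i = 0; i < rki.size(); i++) {
    double u, d1, d2;
    tripEnergy(rki[i], rkj[i], p, u, d1, d2);
    out[i] = u;
  }
  return out;
}
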