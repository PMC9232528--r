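// Coarse-grained bead-spring engine: cell-list nonbonded LJ/WCA, harmonic
// bonds/angles, cosine dihedrals, soft z-walls, BAOAB Langevin integration,
// streamed collective variables and on-the-fly well-tempered metadynamics
// over (z, mu). Single-threaded, seed-deterministic.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

static inline double wrap(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;
  return x;
}
static inline double fast_round(double x) {
  return (double)(long long)(x + (x >= 0 ? 0.5 : -0.5));
}
static inline double mindiff(double dx, double L) {
  dx -= L * fast_round(dx / L);
  return dx;
}

// ---------------------------------------------------------------------------
// Pair tables: per type-pair epsilon, sigma, cutoff, energy shift at cutoff.
struct PairTables {
  int ntypes;
  std::vector<double> eps, sig2, cut2, shift, cutskin2;
  double skin = 0.45;
  void init(const NumericMatrix& e, const NumericMatrix& s,
            const NumericMatrix& c) {
    ntypes = e.nrow();
    eps.resize(ntypes * ntypes);
    sig2.resize(ntypes * ntypes);
    cut2.resize(ntypes * ntypes);
    shift.resize(ntypes * ntypes);
    for (int a = 0; a < ntypes; ++a)
      for (int b = 0; b < ntypes; ++b) {
        int k = a * ntypes + b;
        eps[k] = e(a, b);
        sig2[k] = s(a, b) * s(a, b);
        cut2[k] = c(a, b) * c(a, b);
        double sr2 = sig2[k] / (c(a, b) * c(a, b));
        double sr6 = sr2 * sr2 * sr2;
        shift[k] = 4.0 * eps[k] * (sr6 * sr6 - sr6);
      }
    cutskin2.resize(ntypes * ntypes);
    for (int k = 0; k < ntypes * ntypes; ++k) {
      double rl = std::sqrt(cut2[k]) + skin;
      cutskin2[k] = rl * rl;
    }
  }
  double maxcut() const {
    double m = 0;
    for (double c : cut2) m = std::max(m, c);
    return std::sqrt(m);
  }
};

struct Bonded {
  // bonds: i j k r0 ; angles: i j k kth th0 ; dihedrals: i j k l kd n phi0
  NumericMatrix bonds, angles, dihedrals;
};

struct System {
  int N;
  std::vector<double> x, y, z, vx, vy, vz, mass;
  std::vector<int> type;
  double Lx, Ly, Lz;
  bool pbc_z;
};

struct Walls {
  bool on;
  double zlo, zhi, k;
};

// implicit-solvent solvophobic field: apolar beads pay a smooth energy
// penalty above the upper (and below the lower) head-group plane
struct HydroField {
  bool on = false;
  double eps = 0, w = 0.5, z_upper = 0, z_lower = 0;
  bool two_sided = true;
  std::vector<int> apolar;
};

struct CellList {
  int ncx, ncy, ncz;
  double cx, cy, cz, z0;
  std::vector<int> head, next;
  void build(const System& s, double rc) {
    ncx = std::max(1, (int)std::floor(s.Lx / rc));
    ncy = std::max(1, (int)std::floor(s.Ly / rc));
    // z binning covers the actual coordinate span (slab mode has no z wrap)
    double zmin, zmax;
    if (s.pbc_z) {
      zmin = 0; zmax = s.Lz;
    } else {
      zmin = *std::min_element(s.z.begin(), s.z.end()) - 1e-9;
      zmax = *std::max_element(s.z.begin(), s.z.end()) + 1e-9;
    }
    z0 = zmin;
    if (zmax - zmin > 100.0 * s.Lz)
      stop("integration diverged: coordinate span exploded");
    double span = std::max(zmax - zmin, rc);
    ncz = std::max(1, (int)std::floor(span / rc));
    cx = s.Lx / ncx; cy = s.Ly / ncy; cz = span / ncz;
    head.assign(ncx * ncy * ncz, -1);
    next.assign(s.N, -1);
    for (int i = 0; i < s.N; ++i) {
      int ix = std::min(ncx - 1, std::max(0, (int)(wrap(s.x[i], s.Lx) / cx)));
      int iy = std::min(ncy - 1, std::max(0, (int)(wrap(s.y[i], s.Ly) / cy)));
      int iz = std::min(ncz - 1, std::max(0, (int)((s.pbc_z ? wrap(s.z[i], s.Lz) : s.z[i] - z0) / cz)));
      int c = (iz * ncy + iy) * ncx + ix;
      next[i] = head[c];
      head[c] = i;
    }
  }
};

// metadynamics grid over 1 or 2 CVs, nodes include both endpoints
struct MetadGrid {
  int ncv;
  double mn[2], mx[2], d[2];
  int n[2];
  std::vector<double> V, g1, g2;
  void init(int ncv_, NumericVector mins, NumericVector maxs, IntegerVector ns) {
    ncv = ncv_;
    for (int c = 0; c < ncv; ++c) {
      mn[c] = mins[c]; mx[c] = maxs[c]; n[c] = ns[c];
      d[c] = (mx[c] - mn[c]) / (n[c] - 1);
    }
    int tot = n[0] * (ncv == 2 ? n[1] : 1);
    V.assign(tot, 0.0); g1.assign(tot, 0.0);
    if (ncv == 2) g2.assign(tot, 0.0); else g2.assign(1, 0.0);
  }
  void add_hill(const double* c, const double* s, double w) {
    int i0 = std::max(0, (int)std::ceil((c[0] - 6 * s[0] - mn[0]) / d[0]));
    int i1 = std::min(n[0] - 1, (int)std::floor((c[0] + 6 * s[0] - mn[0]) / d[0]));
    if (ncv == 1) {
      for (int i = i0; i <= i1; ++i) {
        double ds = mn[0] + i * d[0] - c[0];
        double e = w * std::exp(-0.5 * ds * ds / (s[0] * s[0]));
        V[i] += e;
        g1[i] += -ds / (s[0] * s[0]) * e;
      }
    } else {
      int j0 = std::max(0, (int)std::ceil((c[1] - 6 * s[1] - mn[1]) / d[1]));
      int j1 = std::min(n[1] - 1, (int)std::floor((c[1] + 6 * s[1] - mn[1]) / d[1]));
      for (int i = i0; i <= i1; ++i) {
        double ds0 = mn[0] + i * d[0] - c[0];
        double e0 = std::exp(-0.5 * ds0 * ds0 / (s[0] * s[0]));
        for (int j = j0; j <= j1; ++j) {
          double ds1 = mn[1] + j * d[1] - c[1];
          double e = w * e0 * std::exp(-0.5 * ds1 * ds1 / (s[1] * s[1]));
          int k = i * n[1] + j;
          V[k] += e;
          g1[k] += -ds0 / (s[0] * s[0]) * e;
          g2[k] += -ds1 / (s[1] * s[1]) * e;
        }
      }
    }
  }
  // bilinear interpolation of V and its gradient; s clamped to range
  void eval(const double* sraw, double& Vout, double* grad) const {
    double s[2];
    for (int c = 0; c < ncv; ++c)
      s[c] = std::min(mx[c], std::max(mn[c], sraw[c]));
    if (ncv == 1) {
      int i = std::min(n[0] - 2, (int)((s[0] - mn[0]) / d[0]));
      if (i < 0) i = 0;
      double f = (s[0] - (mn[0] + i * d[0])) / d[0];
      Vout = (1 - f) * V[i] + f * V[i + 1];
      grad[0] = (1 - f) * g1[i] + f * g1[i + 1];
    } else {
      int i = std::min(n[0] - 2, std::max(0, (int)((s[0] - mn[0]) / d[0])));
      int j = std::min(n[1] - 2, std::max(0, (int)((s[1] - mn[1]) / d[1])));
      double fx = (s[0] - (mn[0] + i * d[0])) / d[0];
      double fy = (s[1] - (mn[1] + j * d[1])) / d[1];
      int k00 = i * n[1] + j, k01 = k00 + 1, k10 = (i + 1) * n[1] + j, k11 = k10 + 1;
      double w00 = (1 - fx) * (1 - fy), w01 = (1 - fx) * fy,
             w10 = fx * (1 - fy), w11 = fx * fy;
      Vout = w00 * V[k00] + w01 * V[k01] + w10 * V[k10] + w11 * V[k11];
      grad[0] = w00 * g1[k00] + w01 * g1[k01] + w10 * g1[k10] + w11 * g1[k11];
      grad[1] = w00 * g2[k00] + w01 * g2[k01] + w10 * g2[k10] + w11 * g2[k11];
    }
  }
};

struct MetadSpec {
  bool on = false;
  int ncv = 0;          // 1 => (z), 2 => (z, mu)
  double omega0 = 0, sigma[2] = {0, 0}, gamma_wt = 0, kT = 1;
  int pace = 0;
  double wall_k = 0;    // CV-space containment beyond grid edges
  MetadGrid grid;
  std::vector<double> hills; // rows: time c1 c2 s1 s2 height walker
  double walker_id = 0;
  long nwall = 0;
};

struct CVSpec {
  bool on = false;
  std::vector<int> sol;     // solute bead indices
  std::vector<int> heads;   // reference head beads (may be empty)
  int e1 = -1, e2 = -1;     // end beads
  double Msol = 0;
};

struct Forces {
  std::vector<double> fx, fy, fz;
  double e_pair, e_bond, e_angle, e_dih, e_wall, e_tether, e_bias;
  void zero(int N) {
    fx.assign(N, 0.0); fy.assign(N, 0.0); fz.assign(N, 0.0);
    e_pair = e_bond = e_angle = e_dih = e_wall = e_tether = e_bias = 0;
  }
  double total() const {
    return e_pair + e_bond + e_angle + e_dih + e_wall + e_tether + e_bias;
  }
};

struct Tether {
  std::vector<int> idx;
  std::vector<double> k, x0, y0, z0;
};

struct Pull {
  std::vector<int> idx;
  std::vector<double> w; // per-bead weight (mass fraction)
  double fx = 0, fy = 0, fz = 0;
  bool on = false;
};

// Verlet neighbor list built by cell binning (brute force for small boxes),
// rebuilt when any bead has moved more than skin/2 since the last build.
struct NeighborList {
  std::vector<int> pi, pj;
  std::vector<double> sx, sy, sz;  // per-pair image shifts at build
  std::vector<double> peps, psig2, pcut2, pshift; // cached pair parameters
  std::vector<double> bx, by, bz;  // positions at build
  bool built = false;
  // positions are kept unwrapped between rebuilds, so raw differences are
  // valid displacement measures here
  bool needs_rebuild(const System& s, double skin) const {
    if (!built) return true;
    double lim = 0.25 * skin * skin;
    for (int i = 0; i < s.N; ++i) {
      double dx = s.x[i] - bx[i];
      double dy = s.y[i] - by[i];
      double dz = s.z[i] - bz[i];
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }
  void maybe_add(const System& s, const PairTables& pt,
                 const std::unordered_set<long long>& excl, int i, int j) {
    double dx = mindiff(s.x[i] - s.x[j], s.Lx);
    double dy = mindiff(s.y[i] - s.y[j], s.Ly);
    double dz = s.z[i] - s.z[j];
    if (s.pbc_z) dz = mindiff(dz, s.Lz);
    int k = s.type[i] * pt.ntypes + s.type[j];
    if (pt.eps[k] <= 0) return;
    if (dx * dx + dy * dy + dz * dz < pt.cutskin2[k]) {
      if (excl.count((long long)std::min(i, j) * s.N + std::max(i, j))) return;
      pi.push_back(i);
      pj.push_back(j);
      // freeze the periodic image shift; valid until the next rebuild
      sx.push_back(s.x[i] - s.x[j] - dx);
      sy.push_back(s.y[i] - s.y[j] - dy);
      sz.push_back(s.z[i] - s.z[j] - dz);
      peps.push_back(pt.eps[k]);
      psig2.push_back(pt.sig2[k]);
      pcut2.push_back(pt.cut2[k]);
      pshift.push_back(pt.shift[k]);
    }
  }
  void build(const System& s, const PairTables& pt,
             const std::unordered_set<long long>& excl, CellList& cl) {
    pi.clear();
    pj.clear();
    sx.clear();
    sy.clear();
    sz.clear();
    peps.clear();
    psig2.clear();
    pcut2.clear();
    pshift.clear();
    double rc = pt.maxcut() + pt.skin;
    if (s.Lx < 3.0 * rc || s.Ly < 3.0 * rc || (s.pbc_z && s.Lz < 3.0 * rc)) {
      for (int i = 0; i < s.N; ++i)
        for (int j = i + 1; j < s.N; ++j) maybe_add(s, pt, excl, i, j);
    } else {
      cl.build(s, rc);
      static const int off[13][3] = {
        {1,0,0},{0,1,0},{1,1,0},{-1,1,0},
        {0,0,1},{1,0,1},{-1,0,1},{0,1,1},{0,-1,1},
        {1,1,1},{-1,1,1},{1,-1,1},{-1,-1,1}};
      for (int ciz = 0; ciz < cl.ncz; ++ciz)
        for (int ciy = 0; ciy < cl.ncy; ++ciy)
          for (int cix = 0; cix < cl.ncx; ++cix) {
            int c = (ciz * cl.ncy + ciy) * cl.ncx + cix;
            for (int i = cl.head[c]; i >= 0; i = cl.next[i]) {
              for (int j = cl.next[i]; j >= 0; j = cl.next[j])
                maybe_add(s, pt, excl, i, j);
              for (int o = 0; o < 13; ++o) {
                int jx = cix + off[o][0], jy = ciy + off[o][1],
                    jz = ciz + off[o][2];
                int wjx = (jx % cl.ncx + cl.ncx) % cl.ncx;
                int wjy = (jy % cl.ncy + cl.ncy) % cl.ncy;
                int wjz;
                if (s.pbc_z) {
                  wjz = (jz % cl.ncz + cl.ncz) % cl.ncz;
                } else {
                  if (jz < 0 || jz >= cl.ncz) continue;
                  wjz = jz;
                }
                int c2 = (wjz * cl.ncy + wjy) * cl.ncx + wjx;
                if (c2 == c) continue;
                for (int j = cl.head[c2]; j >= 0; j = cl.next[j])
                  maybe_add(s, pt, excl, i, j);
              }
            }
          }
    }
    bx.assign(s.x.begin(), s.x.end());
    by.assign(s.y.begin(), s.y.end());
    bz.assign(s.z.begin(), s.z.end());
    built = true;
  }
};
static void pair_forces(const System& s, const PairTables& pt,
                        const std::unordered_set<long long>& excl,
                        CellList& cl, NeighborList& nl, Forces& F) {
  if (nl.needs_rebuild(s, pt.skin)) nl.build(s, pt, excl, cl);
  size_t np = nl.pi.size();
  for (size_t p = 0; p < np; ++p) {
    int i = nl.pi[p], j = nl.pj[p];
    double dx = s.x[i] - s.x[j] - nl.sx[p];
    double dy = s.y[i] - s.y[j] - nl.sy[p];
    double dz = s.z[i] - s.z[j] - nl.sz[p];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < nl.pcut2[p]) {
      double sr2 = nl.psig2[p] / r2;
      double sr6 = sr2 * sr2 * sr2;
      F.e_pair += 4.0 * nl.peps[p] * (sr6 * sr6 - sr6) - nl.pshift[p];
      double fr = 24.0 * nl.peps[p] * (2.0 * sr6 * sr6 - sr6) / r2;
      F.fx[i] += fr * dx; F.fy[i] += fr * dy; F.fz[i] += fr * dz;
      F.fx[j] -= fr * dx; F.fy[j] -= fr * dy; F.fz[j] -= fr * dz;
    }
  }
}

static void bonded_forces(const System& s, const Bonded& B, Forces& F) {
  // harmonic bonds U = k/2 (r - r0)^2
  for (int b = 0; b < B.bonds.nrow(); ++b) {
    int i = (int)B.bonds(b, 0), j = (int)B.bonds(b, 1);
    double k = B.bonds(b, 2), r0 = B.bonds(b, 3);
    double dx = mindiff(s.x[i] - s.x[j], s.Lx);
    double dy = mindiff(s.y[i] - s.y[j], s.Ly);
    double dz = s.z[i] - s.z[j];
    if (s.pbc_z) dz = mindiff(dz, s.Lz);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - r0;
    F.e_bond += 0.5 * k * dr * dr;
    double fr = -k * dr / std::max(r, 1e-12);
    F.fx[i] += fr * dx; F.fy[i] += fr * dy; F.fz[i] += fr * dz;
    F.fx[j] -= fr * dx; F.fy[j] -= fr * dy; F.fz[j] -= fr * dz;
  }
  // harmonic angles U = k/2 (theta - theta0)^2, sin(theta) clamped
  for (int a = 0; a < B.angles.nrow(); ++a) {
    int i = (int)B.angles(a, 0), j = (int)B.angles(a, 1), k = (int)B.angles(a, 2);
    double ka = B.angles(a, 3), th0 = B.angles(a, 4);
    double d1x = mindiff(s.x[i] - s.x[j], s.Lx);
    double d1y = mindiff(s.y[i] - s.y[j], s.Ly);
    double d1z = s.z[i] - s.z[j]; if (s.pbc_z) d1z = mindiff(d1z, s.Lz);
    double d2x = mindiff(s.x[k] - s.x[j], s.Lx);
    double d2y = mindiff(s.y[k] - s.y[j], s.Ly);
    double d2z = s.z[k] - s.z[j]; if (s.pbc_z) d2z = mindiff(d2z, s.Lz);
    double r1s = d1x * d1x + d1y * d1y + d1z * d1z;
    double r2s = d2x * d2x + d2y * d2y + d2z * d2z;
    double r1 = std::sqrt(r1s), r2 = std::sqrt(r2s);
    double c = (d1x * d2x + d1y * d2y + d1z * d2z) / (r1 * r2);
    c = std::min(1.0, std::max(-1.0, c));
    double th = std::acos(c);
    double sn = std::sqrt(std::max(1.0 - c * c, 1e-12));
    double dUdth = ka * (th - th0);
    F.e_angle += 0.5 * ka * (th - th0) * (th - th0);
    double aa = -dUdth / sn;      // dU/dc  with sign folded in: F = -dU/dr
    double a11 = aa * c / r1s, a12 = -aa / (r1 * r2), a22 = aa * c / r2s;
    double f1x = a11 * d1x + a12 * d2x, f1y = a11 * d1y + a12 * d2y, f1z = a11 * d1z + a12 * d2z;
    double f3x = a22 * d2x + a12 * d1x, f3y = a22 * d2y + a12 * d1y, f3z = a22 * d2z + a12 * d1z;
    F.fx[i] += f1x; F.fy[i] += f1y; F.fz[i] += f1z;
    F.fx[k] += f3x; F.fy[k] += f3y; F.fz[k] += f3z;
    F.fx[j] -= f1x + f3x; F.fy[j] -= f1y + f3y; F.fz[j] -= f1z + f3z;
  }
  // cosine dihedrals U = k (1 + cos(n phi - phi0))
  for (int d = 0; d < B.dihedrals.nrow(); ++d) {
    int i = (int)B.dihedrals(d, 0), j = (int)B.dihedrals(d, 1),
        k = (int)B.dihedrals(d, 2), l = (int)B.dihedrals(d, 3);
    double kd = B.dihedrals(d, 4); int mult = (int)B.dihedrals(d, 5);
    double phi0 = B.dihedrals(d, 6);
    double b1[3] = {mindiff(s.x[j] - s.x[i], s.Lx), mindiff(s.y[j] - s.y[i], s.Ly),
                    s.pbc_z ? mindiff(s.z[j] - s.z[i], s.Lz) : s.z[j] - s.z[i]};
    double b2[3] = {mindiff(s.x[k] - s.x[j], s.Lx), mindiff(s.y[k] - s.y[j], s.Ly),
                    s.pbc_z ? mindiff(s.z[k] - s.z[j], s.Lz) : s.z[k] - s.z[j]};
    double b3[3] = {mindiff(s.x[l] - s.x[k], s.Lx), mindiff(s.y[l] - s.y[k], s.Ly),
                    s.pbc_z ? mindiff(s.z[l] - s.z[k], s.Lz) : s.z[l] - s.z[k]};
    double n1[3] = {b1[1] * b2[2] - b1[2] * b2[1], b1[2] * b2[0] - b1[0] * b2[2],
                    b1[0] * b2[1] - b1[1] * b2[0]};
    double n2[3] = {b2[1] * b3[2] - b2[2] * b3[1], b2[2] * b3[0] - b2[0] * b3[2],
                    b2[0] * b3[1] - b2[1] * b3[0]};
    double n1s = n1[0] * n1[0] + n1[1] * n1[1] + n1[2] * n1[2];
    double n2s = n2[0] * n2[0] + n2[1] * n2[1] + n2[2] * n2[2];
    double b1s = b1[0] * b1[0] + b1[1] * b1[1] + b1[2] * b1[2];
    double b2s = b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2];
    double b3s = b3[0] * b3[0] + b3[1] * b3[1] + b3[2] * b3[2];
    // near-collinear chains: the torsion angle is ill-conditioned and its
    // gradient diverges; taper the term smoothly to zero approaching
    // straight geometries (smoothstep on sin^2 of the flanking angles)
    double s21 = n1s / (b1s * b2s), s22 = n2s / (b2s * b3s);
    auto smooth = [](double v) {
      double t = (v - 0.02) / 0.06;
      if (t <= 0) return 0.0;
      if (t >= 1) return 1.0;
      return t * t * (3 - 2 * t);
    };
    double taper = smooth(s21) * smooth(s22);
    if (taper <= 0) continue;
    double b2n = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
    double m1[3] = {n1[1] * n2[2] - n1[2] * n2[1], n1[2] * n2[0] - n1[0] * n2[2],
                    n1[0] * n2[1] - n1[1] * n2[0]};
    double sy = (m1[0] * b2[0] + m1[1] * b2[1] + m1[2] * b2[2]) / b2n;
    double cx = n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2];
    double phi = std::atan2(sy, cx);
    F.e_dih += taper * kd * (1.0 + std::cos(mult * phi - phi0));
    double dUdphi = -taper * kd * mult * std::sin(mult * phi - phi0);
    // dphi/dr (van Schaik): dphi/dr1 = -|b2|/|n1|^2 n1 ; dphi/dr4 = |b2|/|n2|^2 n2
    double dp1[3], dp4[3];
    for (int q = 0; q < 3; ++q) {
      dp1[q] = -b2n / n1s * n1[q];
      dp4[q] = b2n / n2s * n2[q];
    }
    double t12 = (b1[0] * b2[0] + b1[1] * b2[1] + b1[2] * b2[2]) / (b2n * b2n);
    double t32 = (b3[0] * b2[0] + b3[1] * b2[1] + b3[2] * b2[2]) / (b2n * b2n);
    for (int q = 0; q < 3; ++q) {
      double dp2 = -(1.0 + t12) * dp1[q] + t32 * dp4[q];
      double dp3 = t12 * dp1[q] - (1.0 + t32) * dp4[q];
      double f1 = -dUdphi * dp1[q], f2 = -dUdphi * dp2,
             f3 = -dUdphi * dp3, f4 = -dUdphi * dp4[q];
      if (q == 0) { F.fx[i] += f1; F.fx[j] += f2; F.fx[k] += f3; F.fx[l] += f4; }
      if (q == 1) { F.fy[i] += f1; F.fy[j] += f2; F.fy[k] += f3; F.fy[l] += f4; }
      if (q == 2) { F.fz[i] += f1; F.fz[j] += f2; F.fz[k] += f3; F.fz[l] += f4; }
    }
  }
}

static void field_forces(const System& s, const HydroField& h, Forces& F) {
  if (!h.on) return;
  for (int i = 0; i < s.N; ++i) {
    if (!h.apolar[i]) continue;
    double su = 1.0 / (1.0 + std::exp(-(s.z[i] - h.z_upper) / h.w));
    F.e_wall += h.eps * su;
    F.fz[i] -= h.eps / h.w * su * (1.0 - su);
    if (h.two_sided) {
      double sl = 1.0 / (1.0 + std::exp(-(h.z_lower - s.z[i]) / h.w));
      F.e_wall += h.eps * sl;
      F.fz[i] += h.eps / h.w * sl * (1.0 - sl);
    }
  }
}

static void wall_forces(const System& s, const Walls& w, Forces& F) {
  if (!w.on) return;
  for (int i = 0; i < s.N; ++i) {
    if (s.z[i] < w.zlo) {
      double d = s.z[i] - w.zlo;
      F.e_wall += 0.5 * w.k * d * d;
      F.fz[i] += -w.k * d;
    } else if (s.z[i] > w.zhi) {
      double d = s.z[i] - w.zhi;
      F.e_wall += 0.5 * w.k * d * d;
      F.fz[i] += -w.k * d;
    }
  }
}

static void tether_forces(const System& s, const Tether& t, Forces& F) {
  for (size_t a = 0; a < t.idx.size(); ++a) {
    int i = t.idx[a];
    double dx = s.x[i] - t.x0[a], dy = s.y[i] - t.y0[a], dz = s.z[i] - t.z0[a];
    F.e_tether += 0.5 * t.k[a] * (dx * dx + dy * dy + dz * dz);
    F.fx[i] -= t.k[a] * dx; F.fy[i] -= t.k[a] * dy; F.fz[i] -= t.k[a] * dz;
  }
}

static void pull_forces(const System& s, const Pull& p, Forces& F) {
  if (!p.on) return;
  for (size_t a = 0; a < p.idx.size(); ++a) {
    int i = p.idx[a];
    F.fx[i] += p.w[a] * p.fx;
    F.fy[i] += p.w[a] * p.fy;
    F.fz[i] += p.w[a] * p.fz;
  }
}

// compute CVs: returns z (COM z rel head plane), Ree, zee, mu
static void compute_cv(const System& s, const CVSpec& cv,
                       double& zrel, double& Ree, double& zee, double& mu) {
  double cz = 0;
  for (size_t a = 0; a < cv.sol.size(); ++a)
    cz += s.mass[cv.sol[a]] * s.z[cv.sol[a]];
  cz /= cv.Msol;
  double href = 0;
  if (!cv.heads.empty()) {
    for (int h : cv.heads) href += s.z[h];
    href /= cv.heads.size();
  }
  zrel = cz - href;
  if (cv.e1 >= 0) {
    // positions are unwrapped within a run and the molecule is contiguous,
    // so raw differences give the physical end-to-end vector
    double dx = s.x[cv.e2] - s.x[cv.e1];
    double dy = s.y[cv.e2] - s.y[cv.e1];
    double dz = s.z[cv.e2] - s.z[cv.e1];
    Ree = std::sqrt(dx * dx + dy * dy + dz * dz);
    zee = dz;
    mu = Ree > 0 ? std::min(1.0, std::fabs(dz) / Ree) : NA_REAL;
  } else {
    Ree = NA_REAL; zee = NA_REAL; mu = NA_REAL;
  }
}

// metadynamics bias force: V interpolated on grid; chain rule onto beads.
// z gradient spread mass-weighted over solute beads; mu gradient on end beads.
static void bias_forces(const System& s, const CVSpec& cv, MetadSpec& md, Forces& F) {
  if (!md.on) return;
  double zrel, Ree, zee, mu;
  compute_cv(s, cv, zrel, Ree, zee, mu);
  double sv[2] = {zrel, mu};
  double V, grad[2] = {0, 0};
  md.grid.eval(sv, V, grad);
  F.e_bias += V;
  // containment walls in CV space beyond grid edges
  for (int c = 0; c < md.ncv; ++c) {
    double lo = md.grid.mn[c], hi = md.grid.mx[c];
    if (sv[c] < lo) { F.e_bias += 0.5 * md.wall_k * (sv[c] - lo) * (sv[c] - lo);
      grad[c] += md.wall_k * (sv[c] - lo); md.nwall++; }
    if (sv[c] > hi) { F.e_bias += 0.5 * md.wall_k * (sv[c] - hi) * (sv[c] - hi);
      grad[c] += md.wall_k * (sv[c] - hi); md.nwall++; }
  }
  // dV/dz onto solute beads (mass-weighted COM gradient)
  for (size_t a = 0; a < cv.sol.size(); ++a) {
    int i = cv.sol[a];
    F.fz[i] -= grad[0] * s.mass[i] / cv.Msol;
  }
  if (md.ncv == 2 && Ree > 1e-9) {
    // mu = |zee|/Ree ; d = r(e2) - r(e1), raw differences (see compute_cv)
    double dx = s.x[cv.e2] - s.x[cv.e1];
    double dy = s.y[cv.e2] - s.y[cv.e1];
    double dz = zee;
    double sgn = dz >= 0 ? 1.0 : -1.0;
    double R3 = Ree * Ree * Ree;
    double dmu[3] = {-std::fabs(dz) * dx / R3,
                     -std::fabs(dz) * dy / R3,
                     sgn / Ree - std::fabs(dz) * dz / R3};
    F.fx[cv.e2] -= grad[1] * dmu[0]; F.fx[cv.e1] += grad[1] * dmu[0];
    F.fy[cv.e2] -= grad[1] * dmu[1]; F.fy[cv.e1] += grad[1] * dmu[1];
    F.fz[cv.e2] -= grad[1] * dmu[2]; F.fz[cv.e1] += grad[1] * dmu[2];
  }
}

static void all_forces(const System& s, const PairTables& pt, const Bonded& B,
                       const std::unordered_set<long long>& excl, CellList& cl,
                       NeighborList& nl, const Walls& w, const HydroField& hf,
                       const Tether& t, const Pull& p, const CVSpec& cv,
                       MetadSpec& md, Forces& F) {
  F.zero(s.N);
  pair_forces(s, pt, excl, cl, nl, F);
  bonded_forces(s, B, F);
  wall_forces(s, w, F);
  field_forces(s, hf, F);
  tether_forces(s, t, F);
  pull_forces(s, p, F);
  bias_forces(s, cv, md, F);
}

static System unpack_system(const NumericMatrix& pos, const NumericMatrix& vel,
                            const NumericVector& mass, const IntegerVector& type,
                            const NumericVector& box, bool pbc_z) {
  System s;
  s.N = pos.nrow();
  s.x.resize(s.N); s.y.resize(s.N); s.z.resize(s.N);
  s.vx.resize(s.N); s.vy.resize(s.N); s.vz.resize(s.N);
  s.mass.resize(s.N); s.type.resize(s.N);
  for (int i = 0; i < s.N; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
    s.vx[i] = vel(i, 0); s.vy[i] = vel(i, 1); s.vz[i] = vel(i, 2);
    s.mass[i] = mass[i]; s.type[i] = type[i];
  }
  s.Lx = box[0]; s.Ly = box[1]; s.Lz = box[2]; s.pbc_z = pbc_z;
  return s;
}

static HydroField unpack_field(List field, int N) {
  HydroField h;
  if (field.size() > 0 && as<bool>(field["enabled"])) {
    h.on = true;
    h.eps = as<double>(field["eps"]);
    h.w = as<double>(field["w"]);
    h.z_upper = as<double>(field["z_upper"]);
    h.z_lower = as<double>(field["z_lower"]);
    h.two_sided = as<bool>(field["two_sided"]);
    h.apolar = as<std::vector<int>>(field["apolar"]);
    if ((int)h.apolar.size() != N) stop("field apolar flags length mismatch");
  }
  return h;
}

static std::unordered_set<long long> unpack_excl(const IntegerMatrix& excl, int N) {
  std::unordered_set<long long> out;
  for (int r = 0; r < excl.nrow(); ++r) {
    int i = excl(r, 0), j = excl(r, 1);
    out.insert((long long)std::min(i, j) * N + std::max(i, j));
  }
  return out;
}

// [[Rcpp::export]]
List cpp_compute_forces(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                        IntegerVector type, NumericVector box, bool pbc_z,
                        NumericMatrix eps, NumericMatrix sig, NumericMatrix cut,
                        NumericMatrix bonds, NumericMatrix angles,
                        NumericMatrix dihedrals, IntegerMatrix excl,
                        List walls, List field) {
  System s = unpack_system(pos, vel, mass, type, box, pbc_z);
  PairTables pt; pt.init(eps, sig, cut);
  Bonded B{bonds, angles, dihedrals};
  auto ex = unpack_excl(excl, s.N);
  CellList cl;
  NeighborList nl;
  Walls w{as<bool>(walls["enabled"]), as<double>(walls["zlo"]),
          as<double>(walls["zhi"]), as<double>(walls["k"])};
  HydroField hf = unpack_field(field, s.N);
  Tether t; Pull p; CVSpec cv; MetadSpec md;
  Forces F;
  all_forces(s, pt, B, ex, cl, nl, w, hf, t, p, cv, md, F);
  NumericMatrix fout(s.N, 3);
  for (int i = 0; i < s.N; ++i) {
    fout(i, 0) = F.fx[i]; fout(i, 1) = F.fy[i]; fout(i, 2) = F.fz[i];
  }
  return List::create(
    _["forces"] = fout, _["energy"] = F.total(),
    _["terms"] = NumericVector::create(
      _["pair"] = F.e_pair, _["bond"] = F.e_bond, _["angle"] = F.e_angle,
      _["dihedral"] = F.e_dih, _["wall"] = F.e_wall, _["tether"] = F.e_tether,
      _["bias"] = F.e_bias));
}

// capped steepest-descent minimization (overlap relaxation after packing)
// [[Rcpp::export]]
List cpp_minimize(NumericMatrix pos, NumericVector mass, IntegerVector type,
                  NumericVector box, bool pbc_z,
                  NumericMatrix eps, NumericMatrix sig, NumericMatrix cut,
                  NumericMatrix bonds, NumericMatrix angles,
                  NumericMatrix dihedrals, IntegerMatrix excl, List walls,
                  List field, int max_iter, double fmax_tol, double max_disp) {
  NumericMatrix vel(pos.nrow(), 3);
  System s = unpack_system(pos, vel, mass, type, box, pbc_z);
  PairTables pt; pt.init(eps, sig, cut);
  Bonded B{bonds, angles, dihedrals};
  auto ex = unpack_excl(excl, s.N);
  CellList cl;
  NeighborList nl;
  Walls w{as<bool>(walls["enabled"]), as<double>(walls["zlo"]),
          as<double>(walls["zhi"]), as<double>(walls["k"])};
  HydroField hf = unpack_field(field, s.N);
  Tether t; Pull p; CVSpec cv; MetadSpec md;
  Forces F;
  double step = 0.1 * max_disp, fmax = 0, e_prev = R_PosInf;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    all_forces(s, pt, B, ex, cl, nl, w, hf, t, p, cv, md, F);
    fmax = 0;
    for (int i = 0; i < s.N; ++i) {
      double f = std::sqrt(F.fx[i] * F.fx[i] + F.fy[i] * F.fy[i] + F.fz[i] * F.fz[i]);
      fmax = std::max(fmax, f);
    }
    if (fmax < fmax_tol) break;
    double e = F.total();
    if (e < e_prev) step = std::min(step * 1.2, max_disp);
    else step *= 0.5;
    e_prev = e;
    double scale = step / std::max(fmax, 1e-12);
    for (int i = 0; i < s.N; ++i) {
      s.x[i] = wrap(s.x[i] + scale * F.fx[i], s.Lx);
      s.y[i] = wrap(s.y[i] + scale * F.fy[i], s.Ly);
      double nz = s.z[i] + scale * F.fz[i];
      s.z[i] = s.pbc_z ? wrap(nz, s.Lz) : nz;
    }
  }
  NumericMatrix pout(s.N, 3);
  for (int i = 0; i < s.N; ++i) {
    pout(i, 0) = s.x[i]; pout(i, 1) = s.y[i]; pout(i, 2) = s.z[i];
  }
  all_forces(s, pt, B, ex, cl, nl, w, hf, t, p, cv, md, F);
  return List::create(_["positions"] = pout, _["energy"] = F.total(),
                      _["fmax"] = fmax, _["iterations"] = it);
}

// BAOAB Langevin run with streamed reporters and optional metadynamics
// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
             IntegerVector type, NumericVector box, bool pbc_z,
             NumericMatrix eps, NumericMatrix sig, NumericMatrix cut,
             NumericMatrix bonds, NumericMatrix angles, NumericMatrix dihedrals,
             IntegerMatrix excl, List walls, List field, List tether,
             List pull, List integ, List cvspec, List metad, List report,
             double time0) {
  System s = unpack_system(pos, vel, mass, type, box, pbc_z);
  PairTables pt; pt.init(eps, sig, cut);
  Bonded B{bonds, angles, dihedrals};
  auto ex = unpack_excl(excl, s.N);
  CellList cl;
  NeighborList nl;
  Walls w{as<bool>(walls["enabled"]), as<double>(walls["zlo"]),
          as<double>(walls["zhi"]), as<double>(walls["k"])};
  HydroField hf = unpack_field(field, s.N);
  Tether t;
  if (tether.size() > 0 && as<bool>(tether["enabled"])) {
    t.idx = as<std::vector<int>>(tether["idx"]);
    t.k = as<std::vector<double>>(tether["k"]);
    NumericMatrix r0 = tether["ref"];
    for (int i = 0; i < r0.nrow(); ++i) {
      t.x0.push_back(r0(i, 0)); t.y0.push_back(r0(i, 1)); t.z0.push_back(r0(i, 2));
    }
  }
  Pull p;
  if (pull.size() > 0 && as<bool>(pull["enabled"])) {
    p.on = true;
    p.idx = as<std::vector<int>>(pull["idx"]);
    p.w = as<std::vector<double>>(pull["w"]);
    NumericVector f = pull["force"];
    p.fx = f[0]; p.fy = f[1]; p.fz = f[2];
  }
  CVSpec cv;
  if (cvspec.size() > 0 && as<bool>(cvspec["enabled"])) {
    cv.on = true;
    cv.sol = as<std::vector<int>>(cvspec["solute"]);
    cv.heads = as<std::vector<int>>(cvspec["heads"]);
    cv.e1 = as<int>(cvspec["e1"]); cv.e2 = as<int>(cvspec["e2"]);
    cv.Msol = 0;
    for (int i : cv.sol) cv.Msol += s.mass[i];
  }
  MetadSpec md;
  if (metad.size() > 0 && as<bool>(metad["enabled"])) {
    md.on = true;
    md.ncv = as<int>(metad["ncv"]);
    md.omega0 = as<double>(metad["omega0"]);
    NumericVector sg = metad["sigma"];
    md.sigma[0] = sg[0]; if (md.ncv == 2) md.sigma[1] = sg[1];
    md.gamma_wt = as<double>(metad["gamma_wt"]);
    md.kT = as<double>(metad["kT"]);
    md.pace = as<int>(metad["pace"]);
    md.wall_k = as<double>(metad["wall_k"]);
    md.walker_id = as<double>(metad["walker_id"]);
    md.grid.init(md.ncv, metad["grid_min"], metad["grid_max"], metad["grid_n"]);
    if (metad.containsElementNamed("V0")) {
      NumericVector V0 = metad["V0"], G1 = metad["G1"], G2 = metad["G2"];
      for (int i = 0; i < V0.size(); ++i) {
        md.grid.V[i] = V0[i]; md.grid.g1[i] = G1[i];
        if (md.ncv == 2) md.grid.g2[i] = G2[i];
      }
    }
  }
  double dt = as<double>(integ["dt"]), T = as<double>(integ["temperature"]);
  double gamma = as<double>(integ["gamma"]);
  long nsteps = as<double>(integ["n_steps"]);
  unsigned long seed = (unsigned long)as<double>(integ["seed"]);
  int com_interval = as<int>(integ["com_interval"]);
  int stride_x = as<int>(report["stride_frames"]);
  int stride_e = as<int>(report["stride_energy"]);
  int stride_cv = as<int>(report["stride_cv"]);

  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  double c1 = std::exp(-gamma * dt), c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  std::vector<double> ou_amp(s.N);
  for (int i = 0; i < s.N; ++i) ou_amp[i] = c2 * std::sqrt(T / s.mass[i]);

  Forces F;
  all_forces(s, pt, B, ex, cl, nl, w, hf, t, p, cv, md, F);

  std::vector<NumericMatrix> frames;
  std::vector<double> frame_t;
  std::vector<double> elog;   // step time Epot Ekin Tinst
  std::vector<double> cvlog;  // time z Ree zee mu comx comy comz(unwrapped)
  // unwrapped solute COM accumulation
  double comu[3] = {0, 0, 0};
  std::vector<double> prev_sol_x, prev_sol_y, prev_sol_z;
  if (cv.on) {
    double c0[3] = {0, 0, 0};
    for (int i : cv.sol) {
      c0[0] += s.mass[i] * s.x[i]; c0[1] += s.mass[i] * s.y[i]; c0[2] += s.mass[i] * s.z[i];
      prev_sol_x.push_back(s.x[i]); prev_sol_y.push_back(s.y[i]); prev_sol_z.push_back(s.z[i]);
    }
    comu[0] = c0[0] / cv.Msol; comu[1] = c0[1] / cv.Msol; comu[2] = c0[2] / cv.Msol;
  }
  auto record_cv = [&](double tm) {
    double zrel, Ree, zee, mu;
    compute_cv(s, cv, zrel, Ree, zee, mu);
    cvlog.push_back(tm); cvlog.push_back(zrel); cvlog.push_back(Ree);
    cvlog.push_back(zee); cvlog.push_back(mu);
    cvlog.push_back(comu[0]); cvlog.push_back(comu[1]); cvlog.push_back(comu[2]);
  };
  auto record_e = [&](long step, double tm) {
    double ke = 0;
    for (int i = 0; i < s.N; ++i)
      ke += 0.5 * s.mass[i] * (s.vx[i] * s.vx[i] + s.vy[i] * s.vy[i] + s.vz[i] * s.vz[i]);
    elog.push_back((double)step); elog.push_back(tm);
    elog.push_back(F.total()); elog.push_back(ke);
    elog.push_back(2.0 * ke / (3.0 * s.N));
  };
  auto record_frame = [&](double tm) {
    NumericMatrix fr(s.N, 3);
    for (int i = 0; i < s.N; ++i) { fr(i, 0) = s.x[i]; fr(i, 1) = s.y[i]; fr(i, 2) = s.z[i]; }
    frames.push_back(fr); frame_t.push_back(tm);
  };
  if (stride_e > 0) record_e(0, time0);
  if (stride_cv > 0 && cv.on) record_cv(time0);
  if (stride_x > 0) record_frame(time0);

  for (long step = 1; step <= nsteps; ++step) {
    // B
    for (int i = 0; i < s.N; ++i) {
      double im = dt * 0.5 / s.mass[i];
      s.vx[i] += im * F.fx[i]; s.vy[i] += im * F.fy[i]; s.vz[i] += im * F.fz[i];
    }
    // A
    for (int i = 0; i < s.N; ++i) {
      s.x[i] += 0.5 * dt * s.vx[i]; s.y[i] += 0.5 * dt * s.vy[i]; s.z[i] += 0.5 * dt * s.vz[i];
    }
    // O
    if (gamma > 0) {
      for (int i = 0; i < s.N; ++i) {
        double a = ou_amp[i];
        s.vx[i] = c1 * s.vx[i] + a * gauss(rng);
        s.vy[i] = c1 * s.vy[i] + a * gauss(rng);
        s.vz[i] = c1 * s.vz[i] + a * gauss(rng);
      }
    }
    // A (positions unwrapped; the neighbor list carries image shifts)
    for (int i = 0; i < s.N; ++i) {
      s.x[i] += 0.5 * dt * s.vx[i];
      s.y[i] += 0.5 * dt * s.vy[i];
      s.z[i] += 0.5 * dt * s.vz[i];
    }
    // metadynamics deposition before force recompute so the new hill acts
    if (md.on && md.pace > 0 && step % md.pace == 0) {
      double zrel, Ree, zee, mu;
      compute_cv(s, cv, zrel, Ree, zee, mu);
      double sv[2] = {zrel, mu};
      if (!std::isfinite(sv[0]) || (md.ncv == 2 && !std::isfinite(sv[1])))
        stop("non-finite CV at metadynamics deposition (step %ld)", step);
      double V, g[2];
      md.grid.eval(sv, V, g);
      double h = md.omega0 * std::exp(-V / (md.kT * (md.gamma_wt - 1.0)));
      double cc[2] = {std::min(md.grid.mx[0], std::max(md.grid.mn[0], sv[0])), 0};
      if (md.ncv == 2) cc[1] = std::min(md.grid.mx[1], std::max(md.grid.mn[1], sv[1]));
      md.grid.add_hill(cc, md.sigma, h);
      md.hills.push_back(time0 + step * dt);
      md.hills.push_back(cc[0]);
      md.hills.push_back(md.ncv == 2 ? cc[1] : NA_REAL);
      md.hills.push_back(md.sigma[0]);
      md.hills.push_back(md.ncv == 2 ? md.sigma[1] : NA_REAL);
      md.hills.push_back(h);
      md.hills.push_back(md.walker_id);
    }
    // B with fresh forces
    all_forces(s, pt, B, ex, cl, nl, w, hf, t, p, cv, md, F);
    for (int i = 0; i < s.N; ++i) {
      double im = dt * 0.5 / s.mass[i];
      s.vx[i] += im * F.fx[i]; s.vy[i] += im * F.fy[i]; s.vz[i] += im * F.fz[i];
    }
    for (int i = 0; i < s.N; ++i)
      if (!std::isfinite(s.x[i]) || !std::isfinite(s.y[i]) ||
          !std::isfinite(s.z[i]) ||
          std::fabs(s.x[i]) + std::fabs(s.y[i]) + std::fabs(s.z[i]) > 1e7)
        stop("integration diverged at step %ld (runaway position, bead %d)",
             step, i + 1);
    if (com_interval > 0 && gamma > 0 && step % com_interval == 0) {
      double px = 0, py = 0, pz = 0, M = 0;
      for (int i = 0; i < s.N; ++i) {
        px += s.mass[i] * s.vx[i]; py += s.mass[i] * s.vy[i]; pz += s.mass[i] * s.vz[i];
        M += s.mass[i];
      }
      for (int i = 0; i < s.N; ++i) {
        s.vx[i] -= px / M; s.vy[i] -= py / M; s.vz[i] -= pz / M;
      }
    }
    // unwrapped solute COM via min-image increments
    if (cv.on) {
      double dxs = 0, dys = 0, dzs = 0;
      for (size_t a = 0; a < cv.sol.size(); ++a) {
        int i = cv.sol[a];
        dxs += s.mass[i] * mindiff(s.x[i] - prev_sol_x[a], s.Lx);
        dys += s.mass[i] * mindiff(s.y[i] - prev_sol_y[a], s.Ly);
        double dz = s.z[i] - prev_sol_z[a];
        if (s.pbc_z) dz = mindiff(dz, s.Lz);
        dzs += s.mass[i] * dz;
        prev_sol_x[a] = s.x[i]; prev_sol_y[a] = s.y[i]; prev_sol_z[a] = s.z[i];
      }
      comu[0] += dxs / cv.Msol; comu[1] += dys / cv.Msol; comu[2] += dzs / cv.Msol;
    }
    double tm = time0 + step * dt;
    if (stride_e > 0 && step % stride_e == 0) record_e(step, tm);
    if (stride_cv > 0 && cv.on && step % stride_cv == 0) record_cv(tm);
    if (stride_x > 0 && step % stride_x == 0) record_frame(tm);
  }

  NumericMatrix pout(s.N, 3), vout(s.N, 3);
  for (int i = 0; i < s.N; ++i) {
    pout(i, 0) = s.x[i]; pout(i, 1) = s.y[i]; pout(i, 2) = s.z[i];
    vout(i, 0) = s.vx[i]; vout(i, 1) = s.vy[i]; vout(i, 2) = s.vz[i];
  }
  int ne = elog.size() / 5;
  NumericMatrix emat(ne, 5);
  for (int r = 0; r < ne; ++r)
    for (int c = 0; c < 5; ++c) emat(r, c) = elog[r * 5 + c];
  colnames(emat) = CharacterVector::create("step", "time", "e_pot", "e_kin", "t_inst");
  int ncv_rows = cvlog.size() / 8;
  NumericMatrix cvmat(ncv_rows, 8);
  for (int r = 0; r < ncv_rows; ++r)
    for (int c = 0; c < 8; ++c) cvmat(r, c) = cvlog[r * 8 + c];
  colnames(cvmat) = CharacterVector::create("time", "z", "r_ee", "z_ee", "mu",
                                            "com_x", "com_y", "com_z");
  int nh = md.hills.size() / 7;
  NumericMatrix hmat(nh, 7);
  for (int r = 0; r < nh; ++r)
    for (int c = 0; c < 7; ++c) hmat(r, c) = md.hills[r * 7 + c];
  colnames(hmat) = CharacterVector::create("time", "c1", "c2", "sigma1", "sigma2",
                                           "height", "walker");
  List out = List::create(
    _["positions"] = pout, _["velocities"] = vout,
    _["time"] = time0 + nsteps * dt,
    _["frames"] = wrap(frames), _["frame_times"] = wrap(frame_t),
    _["energy"] = emat, _["cv"] = cvmat, _["hills"] = hmat,
    _["n_cv_wall_events"] = (double)md.nwall);
  if (md.on) {
    out["V"] = wrap(md.grid.V);
    out["G1"] = wrap(md.grid.g1);
    out["G2"] = wrap(md.grid.g2);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Overdamped Langevin sampler on analytic double-well potentials with
// optional well-tempered metadynamics; oracle-scale tool for FES recovery.
// potential: U = h1 ((x/a1)^2 - 1)^2 [+ h2 ((y/a2)^2 - 1)^2]
// [[Rcpp::export]]
List cpp_toy_metad(int dim, NumericVector h, NumericVector a, NumericVector x0,
                   double dt, double kT, double mobility_gamma, double n_steps,
                   double seed, int stride,
                   bool metad_on, double omega0, NumericVector sigma, int pace,
                   double gamma_wt, NumericVector grid_min, NumericVector grid_max,
                   IntegerVector grid_n, double wall_k) {
  std::mt19937_64 rng((unsigned long)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  double x[2] = {x0[0], dim == 2 ? x0[1] : 0.0};
  double D = kT / mobility_gamma;          // mass = 1
  double noise = std::sqrt(2.0 * D * dt);
  MetadGrid grid;
  std::vector<double> hills;
  if (metad_on) grid.init(dim, grid_min, grid_max, grid_n);
  long ns = (long)n_steps;
  std::vector<double> traj;
  long nwall = 0;
  for (long step = 1; step <= ns; ++step) {
    double f[2] = {0, 0};
    for (int c = 0; c < dim; ++c) {
      double u = x[c] / a[c];
      f[c] = -4.0 * h[c] * u * (u * u - 1.0) / a[c];
    }
    if (metad_on) {
      double V, g[2] = {0, 0};
      grid.eval(x, V, g);
      for (int c = 0; c < dim; ++c) {
        f[c] -= g[c];
        if (x[c] < grid.mn[c]) { f[c] -= wall_k * (x[c] - grid.mn[c]); nwall++; }
        if (x[c] > grid.mx[c]) { f[c] -= wall_k * (x[c] - grid.mx[c]); nwall++; }
      }
      if (pace > 0 && step % pace == 0) {
        double Vh, gh[2];
        grid.eval(x, Vh, gh);
        double hgt = omega0 * std::exp(-Vh / (kT * (gamma_wt - 1.0)));
        double cc[2];
        for (int c = 0; c < dim; ++c)
          cc[c] = std::min(grid.mx[c], std::max(grid.mn[c], x[c]));
        grid.add_hill(cc, &sigma[0], hgt);
        hills.push_back(step * dt); hills.push_back(cc[0]);
        hills.push_back(dim == 2 ? cc[1] : NA_REAL);
        hills.push_back(sigma[0]);
        hills.push_back(dim == 2 ? sigma[1] : NA_REAL);
        hills.push_back(hgt); hills.push_back(1.0);
      }
    }
    for (int c = 0; c < dim; ++c)
      x[c] += f[c] * dt / mobility_gamma + noise * gauss(rng);
    if (!std::isfinite(x[0]) || (dim == 2 && !std::isfinite(x[1])))
      stop("toy sampler diverged at step %ld", step);
    if (stride > 0 && step % stride == 0) {
      traj.push_back(step * dt); traj.push_back(x[0]);
      if (dim == 2) traj.push_back(x[1]);
    }
  }
  int ncol = 1 + dim;
  int nrow = traj.size() / ncol;
  NumericMatrix tmat(nrow, ncol);
  for (int r = 0; r < nrow; ++r)
    for (int c = 0; c < ncol; ++c) tmat(r, c) = traj[r * ncol + c];
  int nh = hills.size() / 7;
  NumericMatrix hmat(nh, 7);
  for (int r = 0; r < nh; ++r)
    for (int c = 0; c < 7; ++c) hmat(r, c) = hills[r * 7 + c];
  colnames(hmat) = CharacterVector::create("time", "c1", "c2", "sigma1", "sigma2",
                                           "height", "walker");
  List out = List::create(_["trajectory"] = tmat, _["hills"] = hmat,
                          _["n_cv_wall_events"] = (double)nwall);
  if (metad_on) out["V"] = wrap(grid.V);
  return out;
}

// evaluate a set of Gaussian hills on a grid (multiwalker merge & FES path)
// [[Rcpp::export]]
List cpp_hills_to_grid(NumericMatrix hills, int ncv, NumericVector grid_min,
                       NumericVector grid_max, IntegerVector grid_n) {
  MetadGrid grid;
  grid.init(ncv, grid_min, grid_max, grid_n);
  for (int r = 0; r < hills.nrow(); ++r) {
    double c[2] = {hills(r, 1), ncv == 2 ? hills(r, 2) : 0.0};
    double s[2] = {hills(r, 3), ncv == 2 ? hills(r, 4) : 1.0};
    grid.add_hill(c, s, hills(r, 5));
  }
  return List::create(_["V"] = wrap(grid.V), _["G1"] = wrap(grid.g1),
                      _["G2"] = wrap(grid.g2));
}

// minimum nonbonded pair distance (excluded pairs skipped)
// [[Rcpp::export]]
double cpp_min_distance(NumericMatrix pos, NumericVector box, bool pbc_z,
                        IntegerMatrix excl) {
  int N = pos.nrow();
  std::unordered_set<long long> ex;
  for (int r = 0; r < excl.nrow(); ++r) {
    int i = excl(r, 0), j = excl(r, 1);
    ex.insert((long long)std::min(i, j) * N + std::max(i, j));
  }
  double best = R_PosInf;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      if (ex.count((long long)i * N + j)) continue;
      double dx = mindiff(pos(i, 0) - pos(j, 0), box[0]);
      double dy = mindiff(pos(i, 1) - pos(j, 1), box[1]);
      double dz = pos(i, 2) - pos(j, 2);
      if (pbc_z) dz = mindiff(dz, box[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) best = r2;
    }
  return std::sqrt(best);
}
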