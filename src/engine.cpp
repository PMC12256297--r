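// HPS coarse-grained engine: Ashbaugh-Hatch + Debye-Hueckel nonbonded
// terms over Verlet neighbour lists built from sorted cell grids,
// harmonic bonds, BAOAB Langevin integration in a periodic box with
// optional linear box compression. Units: Angstrom, ps, amu, kcal/mol,
// Kelvin, elementary charge.
//
// Layout notes: beads are re-indexed in cell order at every list
// rebuild and coordinates packed AoS (x,y,z contiguous per bead) so
// the pair loop streams memory; each pair record carries the bead
// type-pair index and the periodic image shift (valid between
// rebuilds because displacements are bounded by the skin) in one
// integer, keeping the force inner loop branch-free.
#include <Rcpp.h>
#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3", "unroll-loops")
#endif
#include <cmath>
#include <cstdint>
#include <vector>
#define RESTRICT __restrict__
using namespace Rcpp;

// 1 kcal/mol = 418.4 amu A^2/ps^2
static const double KCAL2AKMA = 418.4;
static const double KB = 0.0019872041; // kcal/mol/K

// splitmix64-seeded xoshiro256+ with a Marsaglia-Tsang ziggurat for
// normals; self-contained so trajectories are reproducible for a
// given seed independent of the C++ standard library.
struct Rng {
  uint64_t s[4];
  uint32_t kn[128];
  double wn[128], fn[128];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
    // ziggurat tables (Marsaglia & Tsang)
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double gauss() {
    for (;;) {
      int32_t hz = (int32_t)(uint32_t)(next() >> 32);
      uint32_t iz = hz & 127;
      if ((uint32_t)std::abs(hz) < kn[iz]) return hz * wn[iz];
      // tail / wedge rejection
      if (iz == 0) {
        const double r = 3.442619855899;
        double xx, yy;
        do {
          xx = -std::log(unif()) / r;
          yy = -std::log(unif());
        } while (yy + yy < xx * xx);
        return hz > 0 ? r + xx : -r - xx;
      }
      double xv = hz * wn[iz];
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * xv * xv))
        return xv;
    }
  }
};

static inline double wrap0(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x = 0.0; // guard against floor rounding
  return x;
}

struct System {
  int n, nt;
  std::vector<double> x, y, z, vx, vy, vz, fx, fy, fz;
  std::vector<double> mass, invm, charge;
  std::vector<int> type, chain;
  std::vector<int> bi, bj; std::vector<double> br0;
  double k_bond;
  double box[3];
  const double *sig2, *lam, *ahshift; // nt*nt tables
  double eps, rc_ah, rc_dh, kappa, coulfac, dh_shift_fac, skin;

  // AH Verlet list in sorted (cell-order) space
  std::vector<double> ps;        // 3n packed sorted coords
  std::vector<double> fs;        // 3n packed sorted forces
  std::vector<int> s2o;          // sorted -> original index
  std::vector<int> pi_s, pj_s, pcode;
  // DH list in original space (charged beads only)
  std::vector<int> di, dj;
  std::vector<int> charged_ids;
  std::vector<double> x0, y0, z0; // positions at last build
  long n_rebuilds = 0;

  // scratch for the cell build
  std::vector<int> cellof, cnt, cstart, order;

  void sort_cells(const std::vector<int> &ids, double rlist, int *dims) {
    for (int a = 0; a < 3; ++a) {
      dims[a] = (int)std::floor(box[a] / rlist);
      if (dims[a] < 1) dims[a] = 1;
    }
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int ncell = nx * ny * nz;
    cellof.resize(ids.size());
    cnt.assign(ncell, 0);
    for (size_t k = 0; k < ids.size(); ++k) {
      int i = ids[k];
      int cx = (int)(x[i] / box[0] * nx); if (cx >= nx) cx = nx - 1; if (cx < 0) cx = 0;
      int cy = (int)(y[i] / box[1] * ny); if (cy >= ny) cy = ny - 1; if (cy < 0) cy = 0;
      int cz = (int)(z[i] / box[2] * nz); if (cz >= nz) cz = nz - 1; if (cz < 0) cz = 0;
      int c = (cz * ny + cy) * nx + cx;
      cellof[k] = c; cnt[c]++;
    }
    cstart.assign(ncell + 1, 0);
    for (int c = 0; c < ncell; ++c) cstart[c + 1] = cstart[c] + cnt[c];
    order.resize(ids.size());
    std::vector<int> fill(cstart.begin(), cstart.end() - 1);
    for (size_t k = 0; k < ids.size(); ++k) order[fill[cellof[k]]++] = ids[k];
  }

  // forward-neighbour cells of c (id >= c), deduplicated
  static void fwd_cells(int cx, int cy, int cz, const int *dims,
                        std::vector<int> &out) {
    out.clear();
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    int c = (cz * ny + cy) * nx + cx;
    for (int oz = -1; oz <= 1; ++oz) for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox) {
        int ax = (cx + ox + nx) % nx, ay = (cy + oy + ny) % ny,
            az = (cz + oz + nz) % nz;
        int cc = (az * ny + ay) * nx + ax;
        if (cc >= c) out.push_back(cc);
      }
    std::sort(out.begin(), out.end());
    out.erase(std::unique(out.begin(), out.end()), out.end());
  }

  void build_ah_list() {
    const double rlist = rc_ah + skin, r2max = rlist * rlist;
    int dims[3];
    std::vector<int> all(n);
    for (int i = 0; i < n; ++i) all[i] = i;
    sort_cells(all, rlist, dims);
    s2o = order;
    ps.resize(3 * n); fs.assign(3 * n, 0.0);
    for (int k = 0; k < n; ++k) {
      int io = s2o[k];
      ps[3 * k] = x[io]; ps[3 * k + 1] = y[io]; ps[3 * k + 2] = z[io];
    }
    pi_s.clear(); pj_s.clear(); pcode.clear();
    const double Lx = box[0], Ly = box[1], Lz = box[2];
    const double hx = 0.5 * Lx, hy = 0.5 * Ly, hz = 0.5 * Lz;
    std::vector<int> nbr;
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    for (int cz = 0; cz < nz; ++cz) for (int cy = 0; cy < ny; ++cy)
      for (int cx = 0; cx < nx; ++cx) {
        const int c = (cz * ny + cy) * nx + cx;
        if (cstart[c + 1] == cstart[c]) continue;
        fwd_cells(cx, cy, cz, dims, nbr);
        for (int cc : nbr) {
          for (int a = cstart[c]; a < cstart[c + 1]; ++a) {
            const double xi = ps[3 * a], yi = ps[3 * a + 1], zi = ps[3 * a + 2];
            const int b0 = (cc == c) ? a + 1 : cstart[cc];
            for (int b = b0; b < cstart[cc + 1]; ++b) {
              double dx = xi - ps[3 * b];
              double dy = yi - ps[3 * b + 1];
              double dz = zi - ps[3 * b + 2];
              int sxi = 1, syi = 1, szi = 1; // image shift + 1
              if (dx > hx) { dx -= Lx; sxi = 0; } else if (dx < -hx) { dx += Lx; sxi = 2; }
              if (dy > hy) { dy -= Ly; syi = 0; } else if (dy < -hy) { dy += Ly; syi = 2; }
              if (dz > hz) { dz -= Lz; szi = 0; } else if (dz < -hz) { dz += Lz; szi = 2; }
              if (dx * dx + dy * dy + dz * dz >= r2max) continue;
              const int io = s2o[a], jo = s2o[b];
              if (chain[io] == chain[jo] && (io - jo == 1 || jo - io == 1))
                continue;
              pi_s.push_back(a); pj_s.push_back(b);
              pcode.push_back((type[io] * nt + type[jo]) |
                              (sxi << 10) | (syi << 12) | (szi << 14));
            }
          }
        }
      }
  }

  void build_dh_list() {
    di.clear(); dj.clear();
    if (charged_ids.empty()) return;
    const double rlist = rc_dh + skin, r2max = rlist * rlist;
    int dims[3];
    sort_cells(charged_ids, rlist, dims);
    const double Lx = box[0], Ly = box[1], Lz = box[2];
    const double hx = 0.5 * Lx, hy = 0.5 * Ly, hz = 0.5 * Lz;
    std::vector<int> nbr;
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    for (int cz = 0; cz < nz; ++cz) for (int cy = 0; cy < ny; ++cy)
      for (int cx = 0; cx < nx; ++cx) {
        const int c = (cz * ny + cy) * nx + cx;
        if (cstart[c + 1] == cstart[c]) continue;
        fwd_cells(cx, cy, cz, dims, nbr);
        for (int cc : nbr) {
          for (int a = cstart[c]; a < cstart[c + 1]; ++a) {
            const int i = order[a];
            const int b0 = (cc == c) ? a + 1 : cstart[cc];
            for (int b = b0; b < cstart[cc + 1]; ++b) {
              const int j = order[b];
              if (chain[i] == chain[j] && (i - j == 1 || j - i == 1))
                continue;
              double dx = x[i] - x[j]; if (dx > hx) dx -= Lx; else if (dx < -hx) dx += Lx;
              double dy = y[i] - y[j]; if (dy > hy) dy -= Ly; else if (dy < -hy) dy += Ly;
              double dz = z[i] - z[j]; if (dz > hz) dz -= Lz; else if (dz < -hz) dz += Lz;
              if (dx * dx + dy * dy + dz * dz < r2max) {
                di.push_back(i); dj.push_back(j);
              }
            }
          }
        }
      }
  }

  void build_lists() {
    for (int i = 0; i < n; ++i) {
      x[i] = wrap0(x[i], box[0]);
      y[i] = wrap0(y[i], box[1]);
      z[i] = wrap0(z[i], box[2]);
    }
    build_ah_list();
    build_dh_list();
    x0 = x; y0 = y; z0 = z;
    n_rebuilds++;
  }

  bool needs_rebuild() const {
    const double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      const double dx = x[i] - x0[i], dy = y[i] - y0[i],
                   dz = z[i] - z0[i];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }

  void forces(double &e_bond, double &e_ah, double &e_dh) {
    e_bond = e_ah = e_dh = 0.0;
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    std::fill(fs.begin(), fs.end(), 0.0);
    // refresh packed sorted coordinates
    for (int k = 0; k < n; ++k) {
      const int io = s2o[k];
      ps[3 * k] = x[io]; ps[3 * k + 1] = y[io]; ps[3 * k + 2] = z[io];
    }
    const double Lx = box[0], Ly = box[1], Lz = box[2];
    const double rc2_ah = rc_ah * rc_ah, rc2_dh = rc_dh * rc_dh;
    const size_t na = pi_s.size();
    const int *RESTRICT pii = pi_s.data();
    const int *RESTRICT pjj = pj_s.data();
    const int *RESTRICT pcc = pcode.data();
    double *RESTRICT P = ps.data();
    double *RESTRICT F = fs.data();
    const double *RESTRICT SIG2 = sig2, *RESTRICT LAM = lam,
                 *RESTRICT SHIFT = ahshift;
    for (size_t k = 0; k < na; ++k) {
      const int a = pii[k], b = pjj[k], code = pcc[k];
      const double dx = P[3 * a] - P[3 * b] + (((code >> 10) & 3) - 1) * Lx;
      const double dy = P[3 * a + 1] - P[3 * b + 1] + (((code >> 12) & 3) - 1) * Ly;
      const double dz = P[3 * a + 2] - P[3 * b + 2] + (((code >> 14) & 3) - 1) * Lz;
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2_ah) continue;
      const int t = code & 1023;
      const double s2 = SIG2[t] / r2;
      const double s6 = s2 * s2 * s2, s12 = s6 * s6;
      const double lm = LAM[t];
      const double phi = 4.0 * eps * (s12 - s6);
      const double fr_lj = 24.0 * eps * (2.0 * s12 - s6) / r2;
      double e, fr;
      if (s6 > 0.5) { // r < 2^(1/6) sigma
        e = phi + (1.0 - lm) * eps - SHIFT[t];
        fr = fr_lj;
      } else {
        e = lm * phi - SHIFT[t];
        fr = lm * fr_lj;
      }
      e_ah += e;
      F[3 * a] += fr * dx; F[3 * b] -= fr * dx;
      F[3 * a + 1] += fr * dy; F[3 * b + 1] -= fr * dy;
      F[3 * a + 2] += fr * dz; F[3 * b + 2] -= fr * dz;
    }
    for (int k = 0; k < n; ++k) {
      const int io = s2o[k];
      fx[io] += F[3 * k]; fy[io] += F[3 * k + 1]; fz[io] += F[3 * k + 2];
    }
    const double hx = 0.5 * Lx, hy = 0.5 * Ly, hz = 0.5 * Lz;
    const size_t nd = di.size();
    for (size_t k = 0; k < nd; ++k) {
      const int i = di[k], j = dj[k];
      double dx = x[i] - x[j]; if (dx > hx) dx -= Lx; else if (dx < -hx) dx += Lx;
      double dy = y[i] - y[j]; if (dy > hy) dy -= Ly; else if (dy < -hy) dy += Ly;
      double dz = z[i] - z[j]; if (dz > hz) dz -= Lz; else if (dz < -hz) dz += Lz;
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2_dh) continue;
      const double r = std::sqrt(r2);
      const double qq = coulfac * charge[i] * charge[j];
      const double ex = std::exp(-kappa * r);
      e_dh += qq * (ex / r - dh_shift_fac);
      const double fr = qq * ex * (kappa * r + 1.0) / (r2 * r);
      fx[i] += fr * dx; fx[j] -= fr * dx;
      fy[i] += fr * dy; fy[j] -= fr * dy;
      fz[i] += fr * dz; fz[j] -= fr * dz;
    }
    for (size_t k = 0; k < bi.size(); ++k) {
      const int i = bi[k], j = bj[k];
      double dx = x[i] - x[j]; if (dx > hx) dx -= Lx; else if (dx < -hx) dx += Lx;
      double dy = y[i] - y[j]; if (dy > hy) dy -= Ly; else if (dy < -hy) dy += Ly;
      double dz = z[i] - z[j]; if (dz > hz) dz -= Lz; else if (dz < -hz) dz += Lz;
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double d = r - br0[k];
      e_bond += 0.5 * k_bond * d * d;
      const double fr = -k_bond * d / r;
      fx[i] += fr * dx; fx[j] -= fr * dx;
      fy[i] += fr * dy; fy[j] -= fr * dy;
      fz[i] += fr * dz; fz[j] -= fr * dz;
    }
  }

  double kinetic() const {
    double ke = 0.0;
    for (int i = 0; i < n; ++i)
      ke += mass[i] * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    return 0.5 * ke / KCAL2AKMA;
  }
};

static System make_system(NumericMatrix coords, NumericMatrix vel,
                          NumericVector mass, IntegerVector type,
                          IntegerVector chain, NumericVector charge,
                          IntegerVector bond_i, IntegerVector bond_j,
                          NumericVector bond_r0, double k_bond,
                          NumericVector box,
                          NumericVector sig2, NumericVector lam,
                          NumericVector ahshift, double eps,
                          double rc_ah, double rc_dh, double kappa,
                          double coulfac, double skin) {
  System s;
  s.n = coords.nrow();
  s.nt = (int)std::lround(std::sqrt((double)sig2.size()));
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  s.vx.assign(s.n, 0.0); s.vy.assign(s.n, 0.0); s.vz.assign(s.n, 0.0);
  s.fx.assign(s.n, 0.0); s.fy.assign(s.n, 0.0); s.fz.assign(s.n, 0.0);
  for (int a = 0; a < 3; ++a) s.box[a] = box[a];
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = wrap0(coords(i, 0), s.box[0]);
    s.y[i] = wrap0(coords(i, 1), s.box[1]);
    s.z[i] = wrap0(coords(i, 2), s.box[2]);
    if (vel.nrow() == s.n) { s.vx[i] = vel(i, 0); s.vy[i] = vel(i, 1); s.vz[i] = vel(i, 2); }
  }
  s.mass.assign(mass.begin(), mass.end());
  s.invm.resize(s.n);
  for (int i = 0; i < s.n; ++i) s.invm[i] = 1.0 / s.mass[i];
  s.charge.assign(charge.begin(), charge.end());
  s.type.assign(type.begin(), type.end());
  s.chain.assign(chain.begin(), chain.end());
  s.bi.assign(bond_i.begin(), bond_i.end());
  s.bj.assign(bond_j.begin(), bond_j.end());
  s.br0.assign(bond_r0.begin(), bond_r0.end());
  s.k_bond = k_bond;
  s.sig2 = REAL(sig2); s.lam = REAL(lam); s.ahshift = REAL(ahshift);
  s.eps = eps; s.rc_ah = rc_ah; s.rc_dh = rc_dh;
  s.kappa = kappa; s.coulfac = coulfac;
  s.dh_shift_fac = std::exp(-kappa * rc_dh) / rc_dh;
  s.skin = skin;
  for (int i = 0; i < s.n; ++i)
    if (s.charge[i] != 0.0) s.charged_ids.push_back(i);
  return s;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix coords, NumericVector mass, IntegerVector type,
                IntegerVector chain, NumericVector charge,
                IntegerVector bond_i, IntegerVector bond_j,
                NumericVector bond_r0, double k_bond, NumericVector box,
                NumericVector sig2, NumericVector lam, NumericVector ahshift,
                double eps, double rc_ah, double rc_dh, double kappa,
                double coulfac, double skin) {
  NumericMatrix novel(0, 3);
  System s = make_system(coords, novel, mass, type, chain, charge, bond_i,
                         bond_j, bond_r0, k_bond, box, sig2, lam, ahshift,
                         eps, rc_ah, rc_dh, kappa, coulfac, skin);
  s.build_lists();
  double eb, ea, ed;
  s.forces(eb, ea, ed);
  NumericMatrix f(s.n, 3);
  for (int i = 0; i < s.n; ++i) { f(i, 0) = s.fx[i]; f(i, 1) = s.fy[i]; f(i, 2) = s.fz[i]; }
  return List::create(_["forces"] = f, _["e_bond"] = eb,
                      _["e_hydropathy"] = ea, _["e_elec"] = ed);
}

// Integrate n_steps of BAOAB Langevin dynamics; the box interpolates
// linearly from box0 to box1 (equal => constant volume) with affine
// coordinate rescaling. Frames and the energy decomposition are
// recorded every write_interval steps (step 0 is not a frame).
// [[Rcpp::export]]
List cpp_run(NumericMatrix coords, NumericMatrix vel, NumericVector mass,
             IntegerVector type, IntegerVector chain, NumericVector charge,
             IntegerVector bond_i, IntegerVector bond_j, NumericVector bond_r0,
             double k_bond, NumericVector box0, NumericVector box1,
             int n_steps, double dt, double gamma, double temperature,
             int write_interval, double seed,
             NumericVector sig2, NumericVector lam, NumericVector ahshift,
             double eps, double rc_ah, double rc_dh, double kappa,
             double coulfac, double skin) {
  System s = make_system(coords, vel, mass, type, chain, charge, bond_i,
                         bond_j, bond_r0, k_bond, box0, sig2, lam, ahshift,
                         eps, rc_ah, rc_dh, kappa, coulfac, skin);
  Rng rng((uint64_t)seed);
  const bool compressing =
    (box0[0] != box1[0] || box0[1] != box1[1] || box0[2] != box1[2]);
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1 * c1));
  std::vector<double> sigv(s.n);
  for (int i = 0; i < s.n; ++i)
    sigv[i] = std::sqrt(KB * temperature * KCAL2AKMA * s.invm[i]);

  const int nframes = (write_interval > 0) ? n_steps / write_interval : 0;
  NumericVector frames(Dimension(s.n, 3, std::max(nframes, 0)));
  NumericMatrix boxes(std::max(nframes, 0), 3);
  NumericMatrix elog(std::max(nframes, 0), 5); // step e_bond e_ah e_dh e_kin
  int iframe = 0;
  bool diverged = false;
  int diverged_step = -1;

  s.build_lists();
  double eb, ea, ed;
  s.forces(eb, ea, ed);

  for (int step = 1; step <= n_steps; ++step) {
    if (compressing) {
      double fprev = (double)(step - 1) / n_steps;
      double fnow = (double)step / n_steps;
      for (int a = 0; a < 3; ++a) {
        double Lp = box0[a] + fprev * (box1[a] - box0[a]);
        double Ln = box0[a] + fnow * (box1[a] - box0[a]);
        double sc = Ln / Lp;
        s.box[a] = Ln;
        if (sc != 1.0) {
          if (a == 0) for (int i = 0; i < s.n; ++i) s.x[i] *= sc;
          if (a == 1) for (int i = 0; i < s.n; ++i) s.y[i] *= sc;
          if (a == 2) for (int i = 0; i < s.n; ++i) s.z[i] *= sc;
        }
      }
    }
    const double hdt = 0.5 * dt;
    // B: half kick
    for (int i = 0; i < s.n; ++i) {
      const double a = hdt * KCAL2AKMA * s.invm[i];
      s.vx[i] += a * s.fx[i]; s.vy[i] += a * s.fy[i]; s.vz[i] += a * s.fz[i];
    }
    // A: half drift
    for (int i = 0; i < s.n; ++i) {
      s.x[i] += hdt * s.vx[i]; s.y[i] += hdt * s.vy[i]; s.z[i] += hdt * s.vz[i];
    }
    // O: Ornstein-Uhlenbeck
    if (gamma > 0.0) {
      for (int i = 0; i < s.n; ++i) {
        s.vx[i] = c1 * s.vx[i] + c2 * sigv[i] * rng.gauss();
        s.vy[i] = c1 * s.vy[i] + c2 * sigv[i] * rng.gauss();
        s.vz[i] = c1 * s.vz[i] + c2 * sigv[i] * rng.gauss();
      }
    }
    // A: half drift (coordinates stay unwrapped between rebuilds so
    // the cached pair image shifts remain valid; rebuilds rewrap)
    for (int i = 0; i < s.n; ++i) {
      s.x[i] += hdt * s.vx[i]; s.y[i] += hdt * s.vy[i];
      s.z[i] += hdt * s.vz[i];
    }
    if (compressing ? (step % 10 == 0 || s.needs_rebuild())
                    : s.needs_rebuild())
      s.build_lists();
    // B: half kick with fresh forces
    s.forces(eb, ea, ed);
    for (int i = 0; i < s.n; ++i) {
      const double a = hdt * KCAL2AKMA * s.invm[i];
      s.vx[i] += a * s.fx[i]; s.vy[i] += a * s.fy[i]; s.vz[i] += a * s.fz[i];
    }

    if (write_interval > 0 && step % write_interval == 0) {
      if (!std::isfinite(ea + ed + eb) || !std::isfinite(s.x[0])) {
        diverged = true; diverged_step = step; break;
      }
      for (int i = 0; i < s.n; ++i) {
        frames[(size_t)iframe * 3 * s.n + 0 * s.n + i] = wrap0(s.x[i], s.box[0]);
        frames[(size_t)iframe * 3 * s.n + 1 * s.n + i] = wrap0(s.y[i], s.box[1]);
        frames[(size_t)iframe * 3 * s.n + 2 * s.n + i] = wrap0(s.z[i], s.box[2]);
      }
      boxes(iframe, 0) = s.box[0]; boxes(iframe, 1) = s.box[1];
      boxes(iframe, 2) = s.box[2];
      elog(iframe, 0) = step; elog(iframe, 1) = eb; elog(iframe, 2) = ea;
      elog(iframe, 3) = ed; elog(iframe, 4) = s.kinetic();
      iframe++;
    }
    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix cout(s.n, 3), vout(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    cout(i, 0) = wrap0(s.x[i], s.box[0]);
    cout(i, 1) = wrap0(s.y[i], s.box[1]);
    cout(i, 2) = wrap0(s.z[i], s.box[2]);
    vout(i, 0) = s.vx[i]; vout(i, 1) = s.vy[i]; vout(i, 2) = s.vz[i];
  }
  double eb2, ea2, ed2; // final-state energies
  s.forces(eb2, ea2, ed2);
  return List::create(
    _["frames"] = frames, _["boxes"] = boxes, _["elog"] = elog,
    _["n_frames"] = iframe, _["coords"] = cout, _["vel"] = vout,
    _["box"] = NumericVector::create(s.box[0], s.box[1], s.box[2]),
    _["e_bond"] = eb2, _["e_hydropathy"] = ea2, _["e_elec"] = ed2,
    _["e_kinetic"] = s.kinetic(),
    _["n_rebuilds"] = (double)s.n_rebuilds,
    _["diverged"] = diverged, _["diverged_step"] = diverged_step);
}

// Inter-chain contacts: unordered pairs with minimum-image distance
// strictly below radius[i] + radius[j]; all same-chain pairs excluded.
// [[Rcpp::export]]
List cpp_find_contacts(NumericMatrix coords, NumericVector box,
                       NumericVector radius, IntegerVector chain) {
  const int n = coords.nrow();
  std::vector<double> xs(3 * n);
  double b[3] = {box[0], box[1], box[2]};
  for (int i = 0; i < n; ++i) {
    xs[3 * i] = wrap0(coords(i, 0), b[0]);
    xs[3 * i + 1] = wrap0(coords(i, 1), b[1]);
    xs[3 * i + 2] = wrap0(coords(i, 2), b[2]);
  }
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radius[i]);
  const double rlist = 2.0 * rmax;
  int dims[3];
  for (int a = 0; a < 3; ++a) {
    dims[a] = (int)std::floor(b[a] / rlist);
    if (dims[a] < 1) dims[a] = 1;
  }
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ncell = nx * ny * nz;
  std::vector<int> cellof(n), cnt(ncell, 0);
  for (int i = 0; i < n; ++i) {
    int cx = (int)(xs[3 * i] / b[0] * nx); if (cx >= nx) cx = nx - 1;
    int cy = (int)(xs[3 * i + 1] / b[1] * ny); if (cy >= ny) cy = ny - 1;
    int cz = (int)(xs[3 * i + 2] / b[2] * nz); if (cz >= nz) cz = nz - 1;
    int c = (cz * ny + cy) * nx + cx;
    cellof[i] = c; cnt[c]++;
  }
  std::vector<int> start(ncell + 1, 0);
  for (int c = 0; c < ncell; ++c) start[c + 1] = start[c] + cnt[c];
  std::vector<int> order(n);
  { std::vector<int> fill(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) order[fill[cellof[i]]++] = i; }
  std::vector<int> oi, oj;
  std::vector<double> od;
  const double hx = 0.5 * b[0], hy = 0.5 * b[1], hz = 0.5 * b[2];
  std::vector<int> nbr;
  for (int cz = 0; cz < nz; ++cz) for (int cy = 0; cy < ny; ++cy)
    for (int cx = 0; cx < nx; ++cx) {
      const int c = (cz * ny + cy) * nx + cx;
      if (start[c + 1] == start[c]) continue;
      System::fwd_cells(cx, cy, cz, dims, nbr);
      for (int cc : nbr) {
        for (int a = start[c]; a < start[c + 1]; ++a) {
          const int i = order[a];
          const int b0 = (cc == c) ? a + 1 : start[cc];
          for (int bb = b0; bb < start[cc + 1]; ++bb) {
            const int j = order[bb];
            if (chain[i] == chain[j]) continue;
            double dx = xs[3 * i] - xs[3 * j];
            if (dx > hx) dx -= b[0]; else if (dx < -hx) dx += b[0];
            double dy = xs[3 * i + 1] - xs[3 * j + 1];
            if (dy > hy) dy -= b[1]; else if (dy < -hy) dy += b[1];
            double dz = xs[3 * i + 2] - xs[3 * j + 2];
            if (dz > hz) dz -= b[2]; else if (dz < -hz) dz += b[2];
            const double r2 = dx * dx + dy * dy + dz * dz;
            const double rc = radius[i] + radius[j];
            if (r2 < rc * rc) {
              if (i < j) { oi.push_back(i); oj.push_back(j); }
              else { oi.push_back(j); oj.push_back(i); }
              od.push_back(std::sqrt(r2));
            }
          }
        }
      }
    }
  return List::create(_["i"] = IntegerVector(oi.begin(), oi.end()),
                      _["j"] = IntegerVector(oj.begin(), oj.end()),
                      _["dist"] = NumericVector(od.begin(), od.end()));
}
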