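// Compiled core of the coarse-grained fibril simulator: force kernels for
// breakable trilinear bonds, harmonic angles and soft-core Lennard-Jones
// pairs; cell-list neighbour search; steepest-descent + conjugate-gradient
// minimization; velocity-Verlet integration with a Langevin thermostat,
// rigid end clamps and bond-rupture bookkeeping.
//
// Units: Angstrom, fs, kcal/mol, amu. F2A converts (kcal/mol/A)/amu to
// acceleration in A/fs^2. Coordinates and forces are interleaved
// (x0,y0,z0,x1,...) for cache locality in the pair loop.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static const double F2A = 1.0 / 2390.0574;   // (kcal/mol/A)/amu -> A/fs^2
static const double MV2E = 2390.0574;        // amu (A/fs)^2 -> kcal/mol
static const double KBOLTZ = 0.0019872041;   // kcal/mol/K

// ---------------------------------------------------------------- RNG ----
struct XRng {
  uint64_t s[4];
  bool has_spare; double spare;
  explicit XRng(uint64_t seed) : has_spare(false), spare(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  inline uint64_t next() {
    uint64_t res = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return res;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  double gauss() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0; v = 2.0 * unif() - 1.0; s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * f; has_spare = true;
    return u * f;
  }
};

// ------------------------------------------------------------- system ----
struct Sim {
  int n;
  std::vector<double> p;             // interleaved positions, length 3n
  // bonds
  int nb;
  std::vector<int> bi, bj, bsp;
  std::vector<int> bstate;           // 0 intact, 1 softening, 2 severed
  int nspecies;
  std::vector<double> Lr0, Lr1, Lrb, Lk0, Lk1, La, Ltp;
  // angles
  int na;
  std::vector<int> ai, aj, ak;
  std::vector<double> aphi0;
  double kbend, afac;
  // pair law
  double eps, sig2, rc2, rsoft, rsoft2, fsoft, usoft, ushift, rc;
  // neighbour bookkeeping
  double skin;
  bool brute;
  std::vector<int> pl;               // pair list, interleaved (i,j)
  std::vector<double> pref;          // positions at last list build
  std::vector<std::vector<int> > excl;  // per-bead bonded partners
  // outputs of a force pass
  std::vector<double> f;             // interleaved forces, length 3n
  double e_bond, e_angle, e_inter;

  bool excluded(int i, int j) const {
    const std::vector<int>& e = excl[i];
    for (size_t q = 0; q < e.size(); q++) if (e[q] == j) return true;
    return false;
  }

  void init_excl() {
    excl.assign(n, std::vector<int>());
    for (int b = 0; b < nb; b++) {
      excl[bi[b]].push_back(bj[b]);
      excl[bj[b]].push_back(bi[b]);
    }
  }

  // bond tension (kcal/mol/A); positive pulls the pair together
  inline double tension(int sp, double r) const {
    if (r < Lr1[sp]) return Lk0[sp] * (r - Lr0[sp]);
    if (r < Lrb[sp]) return Lk0[sp] * (Lr1[sp] - Lr0[sp]) + Lk1[sp] * (r - Lr1[sp]);
    double edge = Lrb[sp] + La[sp];
    if (r < edge) return Ltp[sp] * (1.0 - (r - Lrb[sp]) / La[sp]);
    return 0.0;
  }

  inline double bond_u(int sp, double r) const {
    double t1 = Lk0[sp] * (Lr1[sp] - Lr0[sp]);
    if (r < Lr1[sp]) return 0.5 * Lk0[sp] * (r - Lr0[sp]) * (r - Lr0[sp]);
    double e1 = 0.5 * Lk0[sp] * (Lr1[sp] - Lr0[sp]) * (Lr1[sp] - Lr0[sp]);
    if (r < Lrb[sp]) {
      double d = r - Lr1[sp];
      return e1 + t1 * d + 0.5 * Lk1[sp] * d * d;
    }
    double db = Lrb[sp] - Lr1[sp];
    double erb = e1 + t1 * db + 0.5 * Lk1[sp] * db * db;
    double edge = Lrb[sp] + La[sp];
    if (r < edge) {
      double d = r - Lrb[sp];
      return erb + Ltp[sp] * d - 0.5 * Ltp[sp] / La[sp] * d * d;
    }
    return erb + 0.5 * Ltp[sp] * La[sp];
  }

  void build_pairs() {
    pl.clear();
    pref = p;
    double rl = rc + skin, rl2 = rl * rl;
    if (brute) {
      for (int i = 0; i < n; i++)
        for (int j = i + 1; j < n; j++)
          if (!excluded(i, j)) { pl.push_back(i); pl.push_back(j); }
      return;
    }
    double lo[3], hi[3];
    for (int d = 0; d < 3; d++) { lo[d] = p[d]; hi[d] = p[d]; }
    for (int i = 1; i < n; i++)
      for (int d = 0; d < 3; d++) {
        lo[d] = std::min(lo[d], p[3 * i + d]);
        hi[d] = std::max(hi[d], p[3 * i + d]);
      }
    int nc[3]; double cw[3];
    for (int d = 0; d < 3; d++) {
      nc[d] = std::max(1, (int)((hi[d] - lo[d]) / rl));
      cw[d] = (hi[d] - lo[d]) / nc[d] + 1e-9;
    }
    std::vector<int> head(nc[0] * nc[1] * nc[2], -1), nxt(n, -1), ci(3 * n);
    for (int i = 0; i < n; i++) {
      for (int d = 0; d < 3; d++) {
        int c = (int)((p[3 * i + d] - lo[d]) / cw[d]);
        ci[3 * i + d] = std::min(nc[d] - 1, std::max(0, c));
      }
      int c = (ci[3 * i] * nc[1] + ci[3 * i + 1]) * nc[2] + ci[3 * i + 2];
      nxt[i] = head[c]; head[c] = i;
    }
    for (int i = 0; i < n; i++) {
      double xi = p[3 * i], yi = p[3 * i + 1], zi = p[3 * i + 2];
      for (int dx = -1; dx <= 1; dx++) {
        int ix = ci[3 * i] + dx; if (ix < 0 || ix >= nc[0]) continue;
        for (int dy = -1; dy <= 1; dy++) {
          int iy = ci[3 * i + 1] + dy; if (iy < 0 || iy >= nc[1]) continue;
          for (int dz = -1; dz <= 1; dz++) {
            int iz = ci[3 * i + 2] + dz; if (iz < 0 || iz >= nc[2]) continue;
            int c = (ix * nc[1] + iy) * nc[2] + iz;
            for (int j = head[c]; j >= 0; j = nxt[j]) {
              if (j <= i) continue;
              double ddx = xi - p[3 * j], ddy = yi - p[3 * j + 1],
                     ddz = zi - p[3 * j + 2];
              double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (r2 < rl2 && !excluded(i, j)) { pl.push_back(i); pl.push_back(j); }
            }
          }
        }
      }
    }
  }

  bool need_rebuild() const {
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < n; i++) {
      double dx = p[3 * i] - pref[3 * i], dy = p[3 * i + 1] - pref[3 * i + 1],
             dz = p[3 * i + 2] - pref[3 * i + 2];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }

  // full force pass; if allow_break, updates bond states and appends the
  // indices of newly softening bonds (first r >= r_break crossing)
  void forces(bool eflag, bool allow_break, std::vector<int>* new_breaks,
              std::vector<double>* break_r) {
    f.assign(3 * n, 0.0);
    e_bond = e_angle = e_inter = 0.0;

    for (int b = 0; b < nb; b++) {
      if (bstate[b] >= 2) continue;
      int i = bi[b], j = bj[b], sp = bsp[b];
      double dx = p[3 * j] - p[3 * i], dy = p[3 * j + 1] - p[3 * i + 1],
             dz = p[3 * j + 2] - p[3 * i + 2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (!std::isfinite(r) || r < 1e-10) Rcpp::stop("degenerate bond length");
      if (allow_break) {
        if (bstate[b] == 0 && r >= Lrb[sp]) {
          bstate[b] = 1;
          if (new_breaks) { new_breaks->push_back(b); break_r->push_back(r); }
        }
        if (bstate[b] == 1 && r >= Lrb[sp] + La[sp]) { bstate[b] = 2; continue; }
      }
      double t = tension(sp, r) / r;
      f[3 * i] += t * dx; f[3 * i + 1] += t * dy; f[3 * i + 2] += t * dz;
      f[3 * j] -= t * dx; f[3 * j + 1] -= t * dy; f[3 * j + 2] -= t * dz;
      if (eflag) e_bond += bond_u(sp, r);
    }
    // severed bonds still carry their rupture plateau energy
    if (eflag) {
      for (int b = 0; b < nb; b++) {
        if (bstate[b] >= 2) {
          int sp = bsp[b];
          e_bond += bond_u(sp, Lrb[sp] + La[sp] + 1.0);
        }
      }
    }

    for (int q = 0; q < na; q++) {
      int i = ai[q], j = aj[q], k = ak[q];
      double axv = p[3 * i] - p[3 * j], ayv = p[3 * i + 1] - p[3 * j + 1],
             azv = p[3 * i + 2] - p[3 * j + 2];
      double bxv = p[3 * k] - p[3 * j], byv = p[3 * k + 1] - p[3 * j + 1],
             bzv = p[3 * k + 2] - p[3 * j + 2];
      double ra2 = axv * axv + ayv * ayv + azv * azv;
      double rb2 = bxv * bxv + byv * byv + bzv * bzv;
      double ra = std::sqrt(ra2), rb = std::sqrt(rb2);
      double c = (axv * bxv + ayv * byv + azv * bzv) / (ra * rb);
      c = std::max(-1.0, std::min(1.0, c));
      double phi = std::acos(c);
      double dphi = phi - aphi0[q];
      if (eflag) e_angle += 0.5 * afac * kbend * dphi * dphi;
      double s = std::sqrt(1.0 - c * c);
      if (s < 1e-8) continue;          // collinear: direction undefined, moment ~ 0
      double dEdphi = afac * kbend * dphi;
      double ci_ = dEdphi / (ra * s), ck_ = dEdphi / (rb * s);
      double ahx = axv / ra, ahy = ayv / ra, ahz = azv / ra;
      double bhx = bxv / rb, bhy = byv / rb, bhz = bzv / rb;
      double fix = ci_ * (bhx - c * ahx), fiy = ci_ * (bhy - c * ahy),
             fiz = ci_ * (bhz - c * ahz);
      double fkx = ck_ * (ahx - c * bhx), fky = ck_ * (ahy - c * bhy),
             fkz = ck_ * (ahz - c * bhz);
      f[3 * i] += fix; f[3 * i + 1] += fiy; f[3 * i + 2] += fiz;
      f[3 * k] += fkx; f[3 * k + 1] += fky; f[3 * k + 2] += fkz;
      f[3 * j] -= fix + fkx; f[3 * j + 1] -= fiy + fky; f[3 * j + 2] -= fiz + fkz;
    }

    const size_t npair = pl.size() / 2;
    const double* P = p.data();
    double* F = f.data();
    for (size_t q = 0; q < npair; q++) {
      int i = pl[2 * q], j = pl[2 * q + 1];
      double dx = P[3 * i] - P[3 * j], dy = P[3 * i + 1] - P[3 * j + 1],
             dz = P[3 * i + 2] - P[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      double fr;                        // F/r
      if (r2 < rsoft2) {
        double r = std::sqrt(r2);
        fr = fsoft / r;
        if (eflag) e_inter += usoft + ushift + fsoft * (rsoft - r);
      } else {
        double s2 = sig2 / r2, s6 = s2 * s2 * s2;
        fr = 24.0 * eps * (2.0 * s6 * s6 - s6) / r2;
        if (eflag) e_inter += 4.0 * eps * (s6 * s6 - s6) + ushift;
      }
      F[3 * i] += fr * dx; F[3 * i + 1] += fr * dy; F[3 * i + 2] += fr * dz;
      F[3 * j] -= fr * dx; F[3 * j + 1] -= fr * dy; F[3 * j + 2] -= fr * dz;
    }
  }

  double energy() {
    forces(true, false, nullptr, nullptr);
    return e_bond + e_angle + e_inter;
  }
};

static Sim make_sim(NumericMatrix pos,
                    IntegerVector bond_i, IntegerVector bond_j,
                    IntegerVector bond_species, IntegerVector bond_state,
                    NumericMatrix laws,
                    IntegerVector angle_i, IntegerVector angle_j,
                    IntegerVector angle_k, NumericVector angle_phi0,
                    double k_bend, double angle_factor,
                    double eps, double sigma, double lambda, double cutoff,
                    bool brute, double skin) {
  Sim s;
  s.n = pos.nrow();
  s.p.resize(3 * s.n);
  for (int i = 0; i < s.n; i++) {
    s.p[3 * i] = pos(i, 0); s.p[3 * i + 1] = pos(i, 1); s.p[3 * i + 2] = pos(i, 2);
  }
  s.nb = bond_i.size();
  s.bi.assign(bond_i.begin(), bond_i.end());
  s.bj.assign(bond_j.begin(), bond_j.end());
  s.bsp.assign(bond_species.begin(), bond_species.end());
  s.bstate.assign(bond_state.begin(), bond_state.end());
  for (int b = 0; b < s.nb; b++) {
    if (s.bi[b] < 0 || s.bi[b] >= s.n || s.bj[b] < 0 || s.bj[b] >= s.n)
      Rcpp::stop("bond refers to bead outside the system");
  }
  s.nspecies = laws.nrow();
  s.Lr0.resize(s.nspecies); s.Lr1.resize(s.nspecies); s.Lrb.resize(s.nspecies);
  s.Lk0.resize(s.nspecies); s.Lk1.resize(s.nspecies); s.La.resize(s.nspecies);
  s.Ltp.resize(s.nspecies);
  for (int k = 0; k < s.nspecies; k++) {
    s.Lr0[k] = laws(k, 0); s.Lr1[k] = laws(k, 1); s.Lrb[k] = laws(k, 2);
    s.Lk0[k] = laws(k, 3); s.Lk1[k] = laws(k, 4);
    s.La[k] = laws(k, 6); s.Ltp[k] = laws(k, 7);
  }
  s.na = angle_i.size();
  s.ai.assign(angle_i.begin(), angle_i.end());
  s.aj.assign(angle_j.begin(), angle_j.end());
  s.ak.assign(angle_k.begin(), angle_k.end());
  for (int q = 0; q < s.na; q++) {
    if (s.ai[q] < 0 || s.ai[q] >= s.n || s.aj[q] < 0 || s.aj[q] >= s.n ||
        s.ak[q] < 0 || s.ak[q] >= s.n)
      Rcpp::stop("angle refers to bead outside the system");
  }
  s.aphi0.assign(angle_phi0.begin(), angle_phi0.end());
  s.kbend = k_bend; s.afac = angle_factor;
  s.eps = eps; s.sig2 = sigma * sigma;
  s.rc = cutoff; s.rc2 = cutoff * cutoff;
  s.rsoft = lambda * sigma; s.rsoft2 = s.rsoft * s.rsoft;
  double sr = sigma / s.rsoft, sr6 = sr * sr * sr * sr * sr * sr;
  s.fsoft = 24.0 * eps * (2.0 * sr6 * sr6 - sr6) / s.rsoft;
  s.usoft = 4.0 * eps * (sr6 * sr6 - sr6);
  double sc = sigma / cutoff, sc6 = sc * sc * sc * sc * sc * sc;
  s.ushift = -4.0 * eps * (sc6 * sc6 - sc6);
  s.brute = brute;
  s.skin = skin;
  s.init_excl();
  s.build_pairs();
  return s;
}

// [[Rcpp::export]]
List cg_forces(NumericMatrix pos,
               IntegerVector bond_i, IntegerVector bond_j,
               IntegerVector bond_species, IntegerVector bond_state,
               NumericMatrix laws,
               IntegerVector angle_i, IntegerVector angle_j,
               IntegerVector angle_k, NumericVector angle_phi0,
               double k_bend, double angle_factor,
               double eps, double sigma, double lambda, double cutoff,
               bool brute, bool energies) {
  Sim s = make_sim(pos, bond_i, bond_j, bond_species, bond_state, laws,
                   angle_i, angle_j, angle_k, angle_phi0, k_bend,
                   angle_factor, eps, sigma, lambda, cutoff, brute, 2.0);
  s.forces(energies, false, nullptr, nullptr);
  NumericMatrix fo(s.n, 3);
  for (int i = 0; i < s.n; i++) {
    fo(i, 0) = s.f[3 * i]; fo(i, 1) = s.f[3 * i + 1]; fo(i, 2) = s.f[3 * i + 2];
  }
  if (energies) {
    return List::create(_["forces"] = fo, _["e_bond"] = s.e_bond,
                        _["e_angle"] = s.e_angle, _["e_inter"] = s.e_inter);
  }
  return List::create(_["forces"] = fo);
}

// All bead pairs closer than rmax (0-based indices), via an axial sweep.
// [[Rcpp::export]]
IntegerMatrix cg_close_pairs(NumericMatrix pos, double rmax) {
  int n = pos.nrow();
  std::vector<int> ri, rj;
  double r2max = rmax * rmax;
  std::vector<int> ord(n);
  for (int i = 0; i < n; i++) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return pos(a, 0) < pos(b, 0); });
  for (int a = 0; a < n; a++) {
    int i = ord[a];
    for (int b = a + 1; b < n; b++) {
      int j = ord[b];
      if (pos(j, 0) - pos(i, 0) > rmax) break;
      double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
             dz = pos(i, 2) - pos(j, 2);
      if (dx * dx + dy * dy + dz * dz <= r2max) {
        ri.push_back(std::min(i, j)); rj.push_back(std::max(i, j));
      }
    }
  }
  IntegerMatrix out(ri.size(), 2);
  for (size_t q = 0; q < ri.size(); q++) { out(q, 0) = ri[q]; out(q, 1) = rj[q]; }
  return out;
}

// ---------------------------------------------------------- minimizer ----
// steepest descent then Polak-Ribiere conjugate gradient; beads with
// fixed[i] != 0 (the clamps) do not move.
// [[Rcpp::export]]
List cg_minimize(NumericMatrix pos, IntegerVector fixed,
                 IntegerVector bond_i, IntegerVector bond_j,
                 IntegerVector bond_species, IntegerVector bond_state,
                 NumericMatrix laws,
                 IntegerVector angle_i, IntegerVector angle_j,
                 IntegerVector angle_k, NumericVector angle_phi0,
                 double k_bend, double angle_factor,
                 double eps, double sigma, double lambda, double cutoff,
                 double skin, double ftol, int max_iter_sd, int max_iter_cg) {
  Sim s = make_sim(pos, bond_i, bond_j, bond_species, bond_state, laws,
                   angle_i, angle_j, angle_k, angle_phi0, k_bend,
                   angle_factor, eps, sigma, lambda, cutoff, false, skin);
  int n = s.n, n3 = 3 * n;
  std::vector<char> fix(n3, 0);
  for (int i = 0; i < n; i++)
    if (fixed[i] != 0) fix[3 * i] = fix[3 * i + 1] = fix[3 * i + 2] = 1;

  auto fmax_free = [&]() {
    double m = 0.0;
    for (int q = 0; q < n3; q++) if (!fix[q]) m = std::max(m, std::abs(s.f[q]));
    return m;
  };
  auto maybe_rebuild = [&]() { if (!s.brute && s.need_rebuild()) s.build_pairs(); };

  double e = s.energy();
  double fm = fmax_free();
  int it_sd = 0, it_cg = 0;
  double alpha = 1e-3;
  std::vector<double> save(n3);

  while (it_sd < max_iter_sd && fm > ftol) {
    double cap = (fm > 0) ? std::min(alpha, 0.1 / fm) : alpha;
    save = s.p;
    for (int q = 0; q < n3; q++) if (!fix[q]) s.p[q] += cap * s.f[q];
    maybe_rebuild();
    double e2 = s.energy();
    if (e2 <= e) { e = e2; alpha *= 1.1; } else {
      s.p = save; alpha *= 0.5;
      maybe_rebuild();
      s.energy();
    }
    fm = fmax_free();
    it_sd++;
  }

  std::vector<double> d(n3, 0), g(n3, 0);
  for (int q = 0; q < n3; q++) if (!fix[q]) { g[q] = s.f[q]; d[q] = g[q]; }
  while (it_cg < max_iter_cg && fm > ftol) {
    double dmax = 0, gd = 0;
    for (int q = 0; q < n3; q++) {
      dmax = std::max(dmax, std::abs(d[q]));
      gd += g[q] * d[q];
    }
    if (gd <= 0 || dmax == 0) {
      gd = 0; dmax = 0;
      for (int q = 0; q < n3; q++) {
        d[q] = g[q]; gd += g[q] * d[q]; dmax = std::max(dmax, std::abs(d[q]));
      }
      if (gd <= 0 || dmax == 0) break;
    }
    double step = std::min(1e-2, 0.1 / dmax);
    save = s.p;
    double e_try = 0; bool ok = false;
    for (int ls = 0; ls < 25; ls++) {
      for (int q = 0; q < n3; q++) if (!fix[q]) s.p[q] = save[q] + step * d[q];
      maybe_rebuild();
      e_try = s.energy();
      if (e_try <= e - 1e-4 * step * gd) { ok = true; break; }
      step *= 0.5;
    }
    if (!ok) { s.p = save; maybe_rebuild(); s.energy(); break; }
    e = e_try;
    double gg_old = 0, gdot = 0;
    for (int q = 0; q < n3; q++) gg_old += g[q] * g[q];
    for (int q = 0; q < n3; q++) {
      double gn = fix[q] ? 0 : s.f[q];
      gdot += gn * (gn - g[q]);
      g[q] = gn;
    }
    double beta = (gg_old > 0) ? std::max(0.0, gdot / gg_old) : 0.0;
    for (int q = 0; q < n3; q++) d[q] = g[q] + beta * d[q];
    fm = fmax_free();
    it_cg++;
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; i++) {
    out(i, 0) = s.p[3 * i]; out(i, 1) = s.p[3 * i + 1]; out(i, 2) = s.p[3 * i + 2];
  }
  return List::create(_["pos"] = out, _["energy"] = e, _["fmax"] = fm,
                      _["iter_sd"] = it_sd, _["iter_cg"] = it_cg,
                      _["converged"] = fm <= ftol);
}

// ----------------------------------------------------------- dynamics ----
// clamp_mode: 0 all beads free, 1 clamps fixed, 2 clamps pulled apart
// along x at the relative speed pull_speed (each clamp moves at half).
// [[Rcpp::export]]
List cg_run(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
            IntegerVector clamp_group, IntegerVector molecule,
            IntegerVector bond_i, IntegerVector bond_j,
            IntegerVector bond_species, IntegerVector bond_state,
            IntegerVector bond_is_tc, NumericMatrix laws,
            IntegerVector angle_i, IntegerVector angle_j,
            IntegerVector angle_k, NumericVector angle_phi0,
            double k_bend, double angle_factor,
            double eps, double sigma, double lambda, double cutoff,
            double skin, double dt, int n_steps, double temperature,
            double tau, double pull_speed, int clamp_mode,
            int sample_every, double area, double L0,
            double stop_frac, double stop_min_strain, double max_strain,
            int n_smooth, int seed) {
  Sim s = make_sim(pos, bond_i, bond_j, bond_species, bond_state, laws,
                   angle_i, angle_j, angle_k, angle_phi0, k_bend,
                   angle_factor, eps, sigma, lambda, cutoff, false, skin);
  int n = s.n;
  const int nspecies = s.nspecies;
  std::vector<double> v(3 * n);
  for (int i = 0; i < n; i++) {
    v[3 * i] = vel(i, 0); v[3 * i + 1] = vel(i, 1); v[3 * i + 2] = vel(i, 2);
  }
  std::vector<char> istc(bond_is_tc.begin(), bond_is_tc.end());

  std::vector<int> cl1, cl2;
  for (int i = 0; i < n; i++) {
    if (clamp_group[i] == 1) cl1.push_back(i);
    else if (clamp_group[i] == 2) cl2.push_back(i);
  }
  bool clamps_active = clamp_mode != 0 && !cl1.empty() && !cl2.empty();
  std::vector<char> held(n, 0);
  if (clamps_active)
    for (int i = 0; i < n; i++) held[i] = clamp_group[i] != 0;
  double vc1 = 0, vc2 = 0;
  if (clamp_mode == 2) { vc1 = -0.5 * pull_speed; vc2 = 0.5 * pull_speed; }
  if (clamps_active) {
    for (size_t q = 0; q < cl1.size(); q++) {
      v[3 * cl1[q]] = vc1; v[3 * cl1[q] + 1] = 0; v[3 * cl1[q] + 2] = 0;
    }
    for (size_t q = 0; q < cl2.size(); q++) {
      v[3 * cl2[q]] = vc2; v[3 * cl2[q] + 1] = 0; v[3 * cl2[q] + 2] = 0;
    }
  }
  auto clamp_sep = [&]() {
    if (!clamps_active) return 0.0;
    double c1 = 0, c2 = 0;
    for (size_t q = 0; q < cl1.size(); q++) c1 += s.p[3 * cl1[q]];
    for (size_t q = 0; q < cl2.size(); q++) c2 += s.p[3 * cl2[q]];
    return c2 / cl2.size() - c1 / cl1.size();
  };
  if (clamps_active && L0 <= 0) L0 = clamp_sep();

  int nfree = 0;
  for (int i = 0; i < n; i++) if (!held[i]) nfree++;
  int ndof = 3 * std::max(1, nfree);

  // precomputed per-bead integration constants
  std::vector<double> hc(n), vth(n);
  for (int i = 0; i < n; i++) {
    hc[i] = 0.5 * dt * F2A / mass[i];
    vth[i] = std::sqrt(KBOLTZ * temperature * F2A / mass[i]);
  }

  XRng rng((uint64_t)seed * 2654435761ULL + 1ULL);
  double c1lang = (tau > 0) ? std::exp(-dt / tau) : 1.0;
  double c2lang = (tau > 0) ? std::sqrt(1.0 - c1lang * c1lang) : 0.0;
  bool do_lang = (tau > 0) && temperature >= 0;
  std::vector<int> mol(molecule.begin(), molecule.end());
  int nmol = 0;
  for (int i = 0; i < n; i++) nmol = std::max(nmol, mol[i] + 1);
  std::vector<double> mvx(nmol), mvy(nmol), mvz(nmol);
  std::vector<int> mcount(nmol);

  int nsmax = n_steps / std::max(1, sample_every) + 2;
  std::vector<double> S_step, S_time, S_strain, S_stress, S_temp,
      S_ebond, S_eangle, S_einter, S_epstc;
  std::vector<std::vector<double> > S_f(nspecies), S_nint(nspecies);
  S_step.reserve(nsmax);
  std::vector<int> E_step, E_bond, E_species;
  std::vector<double> E_r, E_strain;

  std::vector<int> new_breaks; std::vector<double> break_r;
  double cur_strain = 0.0;

  auto record_breaks = [&](int step) {
    for (size_t q = 0; q < new_breaks.size(); q++) {
      E_step.push_back(step);
      E_bond.push_back(new_breaks[q] + 1);
      E_species.push_back(s.bsp[new_breaks[q]] + 1);
      E_r.push_back(break_r[q]);
      E_strain.push_back(cur_strain);
    }
    new_breaks.clear(); break_r.clear();
  };

  std::vector<double> smooth_buf;
  double smooth_peak = 0.0;
  bool stopped = false;
  int last_step = 0;

  auto sample = [&](int step) {
    double sep = clamp_sep();
    double strain = (clamps_active && L0 > 0) ? (sep - L0) / L0 : 0.0;
    double f1 = 0, f2 = 0;
    for (size_t q = 0; q < cl1.size(); q++) f1 += s.f[3 * cl1[q]];
    for (size_t q = 0; q < cl2.size(); q++) f2 += s.f[3 * cl2[q]];
    double stress = clamps_active ? 0.5 * (std::abs(f1) + std::abs(f2)) / area : 0.0;
    double ke = 0;
    for (int i = 0; i < n; i++) {
      if (held[i]) continue;
      ke += mass[i] * (v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                       v[3 * i + 2] * v[3 * i + 2]);
    }
    double temp = ke * MV2E / (KBOLTZ * ndof);
    std::vector<double> fsum(nspecies, 0.0); std::vector<int> cnt(nspecies, 0);
    double tc_sum = 0; int tc_cnt = 0;
    for (int b = 0; b < s.nb; b++) {
      if (s.bstate[b] != 0) continue;
      int i = s.bi[b], j = s.bj[b], sp = s.bsp[b];
      double ddx = s.p[3 * j] - s.p[3 * i], ddy = s.p[3 * j + 1] - s.p[3 * i + 1],
             ddz = s.p[3 * j + 2] - s.p[3 * i + 2];
      double r = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      fsum[sp] += s.tension(sp, r); cnt[sp]++;
      if (istc[b]) { tc_sum += (r - s.Lr0[sp]) / s.Lr0[sp]; tc_cnt++; }
    }
    S_step.push_back(step); S_time.push_back(step * dt);
    S_strain.push_back(strain); S_stress.push_back(stress); S_temp.push_back(temp);
    S_ebond.push_back(s.e_bond); S_eangle.push_back(s.e_angle); S_einter.push_back(s.e_inter);
    S_epstc.push_back(tc_cnt > 0 ? tc_sum / tc_cnt : 0.0);
    for (int k = 0; k < nspecies; k++) {
      S_f[k].push_back(cnt[k] > 0 ? fsum[k] / cnt[k] : NA_REAL);
      S_nint[k].push_back(cnt[k]);
    }
    smooth_buf.push_back(stress);
    if ((int)smooth_buf.size() > n_smooth) smooth_buf.erase(smooth_buf.begin());
    double sm = 0;
    for (size_t q = 0; q < smooth_buf.size(); q++) sm += smooth_buf[q];
    sm /= smooth_buf.size();
    if ((int)smooth_buf.size() == n_smooth) smooth_peak = std::max(smooth_peak, sm);
    if (clamp_mode == 2 && strain > stop_min_strain && smooth_peak > 0 &&
        sm < stop_frac * smooth_peak) stopped = true;
    if (clamp_mode == 2 && strain >= max_strain) stopped = true;
  };

  s.forces(true, false, nullptr, nullptr);
  sample(0);

  for (int step = 1; step <= n_steps && !stopped; step++) {
    for (int i = 0; i < n; i++) {
      if (held[i]) {
        s.p[3 * i] += dt * v[3 * i];   // prescribed clamp motion
        continue;
      }
      double h = hc[i];
      v[3 * i] += h * s.f[3 * i];
      v[3 * i + 1] += h * s.f[3 * i + 1];
      v[3 * i + 2] += h * s.f[3 * i + 2];
      s.p[3 * i] += dt * v[3 * i];
      s.p[3 * i + 1] += dt * v[3 * i + 1];
      s.p[3 * i + 2] += dt * v[3 * i + 2];
    }
    if (s.need_rebuild()) s.build_pairs();
    if (clamp_mode == 2 && L0 > 0) cur_strain = (clamp_sep() - L0) / L0;
    bool do_sample = (step % sample_every == 0) || step == n_steps;
    s.forces(do_sample, true, &new_breaks, &break_r);
    record_breaks(step);
    for (int i = 0; i < n; i++) {
      if (held[i]) continue;
      double h = hc[i];
      v[3 * i] += h * s.f[3 * i];
      v[3 * i + 1] += h * s.f[3 * i + 1];
      v[3 * i + 2] += h * s.f[3 * i + 2];
    }
    if (do_lang) {
      // profile-unbiased Langevin: thermostat only the fluctuation of each
      // bead about its molecule's drift velocity, so that rigid molecular
      // sliding feels no spurious viscous drag from the heat bath
      std::fill(mvx.begin(), mvx.end(), 0.0);
      std::fill(mvy.begin(), mvy.end(), 0.0);
      std::fill(mvz.begin(), mvz.end(), 0.0);
      std::fill(mcount.begin(), mcount.end(), 0);
      for (int i = 0; i < n; i++) {
        if (held[i]) continue;
        int m = mol[i];
        mvx[m] += v[3 * i]; mvy[m] += v[3 * i + 1]; mvz[m] += v[3 * i + 2];
        mcount[m]++;
      }
      for (size_t m = 0; m < mvx.size(); m++) {
        if (mcount[m] > 0) { mvx[m] /= mcount[m]; mvy[m] /= mcount[m]; mvz[m] /= mcount[m]; }
      }
      for (int i = 0; i < n; i++) {
        if (held[i]) continue;
        int m = mol[i];
        double cv = c2lang * vth[i];
        v[3 * i] = mvx[m] + c1lang * (v[3 * i] - mvx[m]) + cv * rng.gauss();
        v[3 * i + 1] = mvy[m] + c1lang * (v[3 * i + 1] - mvy[m]) + cv * rng.gauss();
        v[3 * i + 2] = mvz[m] + c1lang * (v[3 * i + 2] - mvz[m]) + cv * rng.gauss();
      }
    }
    if (do_sample) sample(step);
    last_step = step;
  }

  NumericMatrix pout(n, 3), vout(n, 3);
  for (int i = 0; i < n; i++) {
    pout(i, 0) = s.p[3 * i]; pout(i, 1) = s.p[3 * i + 1]; pout(i, 2) = s.p[3 * i + 2];
    vout(i, 0) = v[3 * i]; vout(i, 1) = v[3 * i + 1]; vout(i, 2) = v[3 * i + 2];
  }
  List series = List::create(
      _["step"] = S_step, _["time_fs"] = S_time, _["strain"] = S_strain,
      _["stress"] = S_stress, _["temperature"] = S_temp,
      _["e_bond"] = S_ebond, _["e_angle"] = S_eangle, _["e_inter"] = S_einter,
      _["eps_tc"] = S_epstc);
  List fser(nspecies), nser(nspecies);
  for (int k = 0; k < nspecies; k++) { fser[k] = S_f[k]; nser[k] = S_nint[k]; }
  List events = List::create(
      _["step"] = E_step, _["bond"] = E_bond, _["species"] = E_species,
      _["r"] = E_r, _["strain"] = E_strain);
  return List::create(
      _["pos"] = pout, _["vel"] = vout,
      _["bond_state"] = IntegerVector(s.bstate.begin(), s.bstate.end()),
      _["series"] = series, _["mean_force"] = fser, _["n_intact"] = nser,
      _["events"] = events, _["L0"] = L0, _["last_step"] = last_step,
      _["stopped_early"] = stopped);
}
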