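// Compiled core: pair potentials, neighbour lists, Langevin integrator.
//
// Species codes (0-based internally, 1-based from R):
//   1 membrane, 2 membrane receptor, 3 filament binder bead,
//   4 filament core bead, 5 cargo.
//
// Interactions:
//   membrane/receptor x membrane/receptor : anisotropic one-particle-thick
//     membrane potential (soft 4-2 core below r_min, cos^(2*zeta) tail to
//     r_cut, orientation kernel phi = 1 + mu*(a - 1)).
//   binder x membrane        : short-range adhesion (WCA core + cos^2 tail)
//   core   x membrane        : WCA (adhesion instead when bind_all3)
//   filament x filament      : WCA when self-exclusion is on, skipping
//                              bonded pairs; nothing when off
//   cargo x receptor         : adhesion (depth eps_cargo)
//   cargo x plain membrane / filament / cargo : WCA
//
// Units: bead diameter sigma = 1, k_B T = 1, mass = 1.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_set>
#include <cstdint>

using namespace Rcpp;

static const int S_MEM = 0, S_REC = 1, S_BIND = 2, S_CORE = 3, S_CARGO = 4;
static const int NSPEC = 5;

// interaction kinds
static const int I_NONE = 0, I_MEMB = 1, I_WCA = 2, I_ADH = 3;

struct Params {
  double eps_mem, mu, rmin, rcut;
  int zeta;
  double eps_binder, eps_cargo, adh_w, eps_rep;
  bool bind_all3, self_excl;
  bool tension_on;
  double tension_c, tension_target;
  double dt, gamma_t, gamma_r, temperature, skin;
  double cargo_diam;           // cargo sphere diameter (sigma)
  double max_move;             // >0: clamp per-step displacements (settling)
  uint64_t seed;
  // derived tables
  int itype[NSPEC][NSPEC];
  double adh_eps[NSPEC][NSPEC];
  double sigc[NSPEC][NSPEC];   // contact distance (WCA vanish point)
  double cut2[NSPEC][NSPEC];
  double rlist;                // max cutoff + skin
  // tabulated attractive tail of the membrane kernel (engine fast path)
  std::vector<double> tab_uA, tab_duA;
  double tab_dr;
};

static double spec_diam(const Params &p, int s) {
  return s == S_CARGO ? p.cargo_diam : 1.0;
}

static void fill_tables(Params &p) {
  for (int a = 0; a < NSPEC; ++a)
    for (int b = 0; b < NSPEC; ++b) {
      p.itype[a][b] = I_NONE;
      p.adh_eps[a][b] = 0.0;
      p.sigc[a][b] = 0.5 * (spec_diam(p, a) + spec_diam(p, b));
      p.cut2[a][b] = 0.0;
    }
  auto set = [&](int a, int b, int t, double eps) {
    p.itype[a][b] = p.itype[b][a] = t;
    p.adh_eps[a][b] = p.adh_eps[b][a] = eps;
  };
  set(S_MEM, S_MEM, I_MEMB, 0);
  set(S_MEM, S_REC, I_MEMB, 0);
  set(S_REC, S_REC, I_MEMB, 0);
  set(S_BIND, S_MEM, I_ADH, p.eps_binder);
  set(S_BIND, S_REC, I_ADH, p.eps_binder);
  if (p.bind_all3) {
    set(S_CORE, S_MEM, I_ADH, p.eps_binder);
    set(S_CORE, S_REC, I_ADH, p.eps_binder);
  } else {
    set(S_CORE, S_MEM, I_WCA, 0);
    set(S_CORE, S_REC, I_WCA, 0);
  }
  int filex = p.self_excl ? I_WCA : I_NONE;
  set(S_BIND, S_BIND, filex, 0);
  set(S_BIND, S_CORE, filex, 0);
  set(S_CORE, S_CORE, filex, 0);
  set(S_CARGO, S_MEM, I_WCA, 0);
  set(S_CARGO, S_REC, I_ADH, p.eps_cargo);
  set(S_CARGO, S_BIND, I_WCA, 0);
  set(S_CARGO, S_CORE, I_WCA, 0);
  set(S_CARGO, S_CARGO, I_WCA, 0);

  for (int a = 0; a < NSPEC; ++a)
    for (int b = 0; b < NSPEC; ++b) {
      double rc = 0.0;
      switch (p.itype[a][b]) {
      case I_MEMB: rc = p.rcut; break;
      case I_WCA:  rc = p.sigc[a][b]; break;
      case I_ADH:  rc = p.sigc[a][b] + p.adh_w; break;
      default: rc = 0.0;
      }
      p.cut2[a][b] = rc * rc;
    }
  // tabulate the tail kernel u_A and its radial derivative
  const int ntab = 4096;
  p.tab_uA.resize(ntab + 1);
  p.tab_duA.resize(ntab + 1);
  p.tab_dr = (p.rcut - p.rmin) / ntab;
  for (int t = 0; t <= ntab; ++t) {
    double r = p.rmin + t * p.tab_dr;
    double psi = 0.5 * M_PI * (r - p.rmin) / (p.rcut - p.rmin);
    double c = std::cos(psi), s = std::sin(psi);
    double czm1 = std::pow(c, 2 * p.zeta - 1);
    p.tab_uA[t] = -p.eps_mem * czm1 * c;
    p.tab_duA[t] = p.eps_mem * p.zeta * M_PI / (p.rcut - p.rmin) * czm1 * s;
  }
}

// list cutoff from the species actually present
static void set_rlist(Params &p, const std::vector<int> &sp) {
  bool present[NSPEC] = {false, false, false, false, false};
  for (int s : sp) present[s] = true;
  double maxcut = 0.0;
  for (int a = 0; a < NSPEC; ++a)
    for (int b = a; b < NSPEC; ++b)
      if (present[a] && present[b] && p.cut2[a][b] > maxcut * maxcut)
        maxcut = std::sqrt(p.cut2[a][b]);
  p.rlist = maxcut + p.skin;
}

static Params parse_params(const List &pl) {
  Params p;
  p.eps_mem = as<double>(pl["eps_mem"]);
  p.mu = as<double>(pl["mu"]);
  p.zeta = as<int>(pl["zeta"]);
  p.rmin = as<double>(pl["rmin"]);
  p.rcut = as<double>(pl["rcut"]);
  p.eps_binder = as<double>(pl["eps_binder"]);
  p.eps_cargo = as<double>(pl["eps_cargo"]);
  p.adh_w = as<double>(pl["adh_w"]);
  p.eps_rep = as<double>(pl["eps_rep"]);
  p.bind_all3 = as<bool>(pl["bind_all3"]);
  p.self_excl = as<bool>(pl["self_excl"]);
  p.tension_on = as<bool>(pl["tension_on"]);
  p.tension_c = as<double>(pl["tension_c"]);
  p.tension_target = as<double>(pl["tension_target"]);
  p.dt = as<double>(pl["dt"]);
  p.gamma_t = as<double>(pl["gamma_t"]);
  p.gamma_r = as<double>(pl["gamma_r"]);
  p.temperature = as<double>(pl["temperature"]);
  p.skin = as<double>(pl["skin"]);
  p.cargo_diam = pl.containsElementNamed("cargo_diam") ?
      as<double>(pl["cargo_diam"]) : 4.0;
  p.max_move = pl.containsElementNamed("max_move") ?
      as<double>(pl["max_move"]) : 0.0;
  p.seed = (uint64_t)as<double>(pl["seed"]);
  fill_tables(p);
  return p;
}

// ---------------------------------------------------------------------------
// counter-based RNG (splitmix64 finaliser): one independent stream per
// (seed, step, particle, channel) so checkpoint resume is exact.

static inline uint64_t sm_mix(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double cb_unif(uint64_t seed, uint64_t step, uint64_t i,
                             uint64_t ch) {
  uint64_t k = sm_mix(seed ^ (step * 0xD1342543DE82EF95ULL));
  k = sm_mix(k ^ (i * 0x9E3779B97F4A7C15ULL));
  k = sm_mix(k ^ (ch * 0xC2B2AE3D27D4EB4FULL));
  return (double)((k >> 11) + 1ULL) * (1.0 / 9007199254740993.0); // (0,1)
}

// two gaussians from channels (2c, 2c+1)
static inline void cb_gauss2(uint64_t seed, uint64_t step, uint64_t i, int c,
                             double &g1, double &g2) {
  double u1 = cb_unif(seed, step, i, 2 * c);
  double u2 = cb_unif(seed, step, i, 2 * c + 1);
  double r = std::sqrt(-2.0 * std::log(u1));
  g1 = r * std::cos(2.0 * M_PI * u2);
  g2 = r * std::sin(2.0 * M_PI * u2);
}

// ---------------------------------------------------------------------------
// pair kernels. rv = x_j - x_i (minimum image). Forces returned act on j;
// force on i is the negative. g_i, g_j are -dU/dn (unprojected).

struct PairOut {
  double e;
  double f[3];   // force on j
  double gi[3], gj[3];
  bool has_torque;
};

static inline double dotp(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// membrane-membrane anisotropic potential
static void pair_membrane(const double *rv, const double *ni, const double *nj,
                          const Params &p, double r2, PairOut &out) {
  double r = std::sqrt(r2);
  double rh[3] = {rv[0] / r, rv[1] / r, rv[2] / r};
  double di = dotp(ni, rh), dj = dotp(nj, rh);
  double a = dotp(ni, nj) - di * dj;
  double phi = 1.0 + p.mu * (a - 1.0);
  double U, dUdr, Ca;
  if (r < p.rmin) {
    double q = p.rmin / r, q2 = q * q, q4 = q2 * q2;
    U = p.eps_mem * (q4 - 2.0 * q2) + p.eps_mem * (1.0 - phi);
    dUdr = p.eps_mem * (-4.0 * q4 + 4.0 * q2) / r;
    Ca = -p.eps_mem * p.mu;
  } else {
    double psi = 0.5 * M_PI * (r - p.rmin) / (p.rcut - p.rmin);
    double c = std::cos(psi), s = std::sin(psi);
    double cz; // c^(2*zeta)
    double czm1; // c^(2*zeta - 1)
    if (p.zeta == 4) {
      double c2 = c * c, c4 = c2 * c2;
      czm1 = c4 * c2 * c;
      cz = czm1 * c;
    } else {
      czm1 = std::pow(c, 2 * p.zeta - 1);
      cz = czm1 * c;
    }
    double uA = -p.eps_mem * cz;
    double duA = p.eps_mem * p.zeta * M_PI / (p.rcut - p.rmin) * czm1 * s;
    U = uA * phi;
    dUdr = duA * phi;
    Ca = uA * p.mu;
  }
  // da/dx_j = (1/r) [ g + 2 di dj rh ],  g = -(dj ni + di nj)
  double g[3];
  for (int k = 0; k < 3; ++k) g[k] = -(dj * ni[k] + di * nj[k]);
  double corr = 2.0 * di * dj;
  for (int k = 0; k < 3; ++k) {
    double dadx = (g[k] + corr * rh[k]) / r;
    out.f[k] = -(dUdr * rh[k] + Ca * dadx);
  }
  // -dU/dn_i = -Ca (nj - dj rh);  -dU/dn_j = -Ca (ni - di rh)
  for (int k = 0; k < 3; ++k) {
    out.gi[k] = -Ca * (nj[k] - dj * rh[k]);
    out.gj[k] = -Ca * (ni[k] - di * rh[k]);
  }
  out.e = U;
  out.has_torque = true;
}

// engine fast path: identical to pair_membrane but with the tail kernel
// linearly interpolated from the precomputed table
static void pair_membrane_tab(const double *rv, const double *ni,
                              const double *nj, const Params &p, double r2,
                              PairOut &out) {
  double r = std::sqrt(r2);
  double inv_r = 1.0 / r;
  double rh[3] = {rv[0] * inv_r, rv[1] * inv_r, rv[2] * inv_r};
  double di = dotp(ni, rh), dj = dotp(nj, rh);
  double a = dotp(ni, nj) - di * dj;
  double phi = 1.0 + p.mu * (a - 1.0);
  double U, dUdr, Ca;
  if (r < p.rmin) {
    double q = p.rmin * inv_r, q2 = q * q, q4 = q2 * q2;
    U = p.eps_mem * (q4 - 2.0 * q2) + p.eps_mem * (1.0 - phi);
    dUdr = p.eps_mem * (-4.0 * q4 + 4.0 * q2) * inv_r;
    Ca = -p.eps_mem * p.mu;
  } else {
    double u = (r - p.rmin) / p.tab_dr;
    int t = (int)u;
    double w = u - t;
    double uA = p.tab_uA[t] * (1 - w) + p.tab_uA[t + 1] * w;
    double duA = p.tab_duA[t] * (1 - w) + p.tab_duA[t + 1] * w;
    U = uA * phi;
    dUdr = duA * phi;
    Ca = uA * p.mu;
  }
  double corr = 2.0 * di * dj;
  for (int k = 0; k < 3; ++k) {
    double dadx = (-(dj * ni[k] + di * nj[k]) + corr * rh[k]) * inv_r;
    out.f[k] = -(dUdr * rh[k] + Ca * dadx);
  }
  for (int k = 0; k < 3; ++k) {
    out.gi[k] = -Ca * (nj[k] - dj * rh[k]);
    out.gj[k] = -Ca * (ni[k] - di * rh[k]);
  }
  out.e = U;
  out.has_torque = true;
}

// WCA with vanish point at sigc (LJ diameter sigc * 2^(-1/6))
static void pair_wca(const double *rv, double sigc, double eps, double r2,
                     PairOut &out) {
  double s = sigc * 0.8908987181403393; // 2^(-1/6)
  double s2 = s * s / r2;
  double s6 = s2 * s2 * s2, s12 = s6 * s6;
  out.e = 4.0 * eps * (s12 - s6) + eps;
  double dUdr_over_r = 4.0 * eps * (-12.0 * s12 + 6.0 * s6) / r2;
  for (int k = 0; k < 3; ++k) out.f[k] = -dUdr_over_r * rv[k];
  out.has_torque = false;
}

// adhesion: WCA core shifted to -eps, cos^2 tail of width w beyond contact
static void pair_adhesion(const double *rv, double sigc, double eps, double w,
                          double eps_rep, double r2, PairOut &out) {
  if (r2 < sigc * sigc) {
    pair_wca(rv, sigc, eps_rep, r2, out);
    out.e -= eps;
    return;
  }
  double r = std::sqrt(r2);
  double psi = 0.5 * M_PI * (r - sigc) / w;
  double c = std::cos(psi);
  out.e = -eps * c * c;
  double dUdr = eps * 0.5 * M_PI / w * std::sin(2.0 * psi);
  for (int k = 0; k < 3; ++k) out.f[k] = -dUdr * rv[k] / r;
  out.has_torque = false;
}

static void pair_bond(const double *rv, double r0, double k, PairOut &out) {
  double r = std::sqrt(dotp(rv, rv));
  double d = r - r0;
  out.e = 0.5 * k * d * d;
  double dUdr = k * d;
  for (int kk = 0; kk < 3; ++kk) out.f[kk] = -dUdr * rv[kk] / r;
  out.has_torque = false;
}

// ---------------------------------------------------------------------------
// system-level force evaluation

struct SysState {
  int N;
  std::vector<double> x, v, n;     // 3N each
  std::vector<int> sp;             // 0-based species
  std::vector<int> img;            // 2N wrap counters
  double Lx, Ly;
};

struct Forces {
  std::vector<double> f, g;        // 3N
  double e_mem, e_wca, e_adh, e_bond, e_teth;
  double w_lat;                    // lateral virial sum f_j . r_(xy)
};

struct BondTable {
  std::vector<int> bi, bj;
  std::vector<double> r0, k;
  std::unordered_set<uint64_t> excl;
};

struct TethTable {
  std::vector<int> i;
  std::vector<double> px, py, pz, k;
};

static inline uint64_t pair_key(int i, int j, int N) {
  if (i > j) std::swap(i, j);
  return (uint64_t)i * (uint64_t)N + (uint64_t)j;
}

static inline void min_image(double &dx, double &dy, double Lx, double Ly) {
  if (dx > 0.5 * Lx) dx -= Lx; else if (dx < -0.5 * Lx) dx += Lx;
  if (dy > 0.5 * Ly) dy -= Ly; else if (dy < -0.5 * Ly) dy += Ly;
}

// Verlet neighbour list built from an x,y cell grid (z open)
struct NeighList {
  std::vector<int> start, items;
  std::vector<double> x_ref;
  double scale_ref;
};

static void build_neigh(const SysState &S, const Params &p, const BondTable &B,
                        NeighList &nl) {
  int N = S.N;
  double rl = p.rlist, rl2 = rl * rl;
  int ncx = std::max(1, (int)std::floor(S.Lx / rl));
  int ncy = std::max(1, (int)std::floor(S.Ly / rl));
  nl.start.assign(N + 1, 0);
  nl.items.clear();
  std::vector<std::vector<int>> pairs(N);
  if (ncx < 3 || ncy < 3) {
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        double dx = S.x[3 * j] - S.x[3 * i];
        double dy = S.x[3 * j + 1] - S.x[3 * i + 1];
        double dz = S.x[3 * j + 2] - S.x[3 * i + 2];
        min_image(dx, dy, S.Lx, S.Ly);
        if (dx * dx + dy * dy + dz * dz < rl2 &&
            (S.sp[i] < S_BIND || S.sp[j] < S_BIND ||
             !B.excl.count(pair_key(i, j, N))))
          pairs[i].push_back(j);
      }
  } else {
    double cwx = S.Lx / ncx, cwy = S.Ly / ncy;
    std::vector<std::vector<int>> cells(ncx * ncy);
    std::vector<int> ci(N), cj(N);
    for (int i = 0; i < N; ++i) {
      int cx = (int)std::floor(S.x[3 * i] / cwx);
      int cy = (int)std::floor(S.x[3 * i + 1] / cwy);
      cx = ((cx % ncx) + ncx) % ncx;
      cy = ((cy % ncy) + ncy) % ncy;
      ci[i] = cx; cj[i] = cy;
      cells[cy * ncx + cx].push_back(i);
    }
    for (int i = 0; i < N; ++i) {
      for (int ox = -1; ox <= 1; ++ox)
        for (int oy = -1; oy <= 1; ++oy) {
          int cx = (ci[i] + ox + ncx) % ncx;
          int cy = (cj[i] + oy + ncy) % ncy;
          for (int j : cells[cy * ncx + cx]) {
            if (j <= i) continue;
            double dx = S.x[3 * j] - S.x[3 * i];
            double dy = S.x[3 * j + 1] - S.x[3 * i + 1];
            double dz = S.x[3 * j + 2] - S.x[3 * i + 2];
            min_image(dx, dy, S.Lx, S.Ly);
            if (dx * dx + dy * dy + dz * dz < rl2 &&
                (S.sp[i] < S_BIND || S.sp[j] < S_BIND ||
                 !B.excl.count(pair_key(i, j, N))))
              pairs[i].push_back(j);
          }
        }
    }
  }
  // sorted sublists give a deterministic force-summation order that does
  // not depend on when the list was rebuilt (checkpoint-exact resumes)
  for (int i = 0; i < N; ++i) std::sort(pairs[i].begin(), pairs[i].end());
  int tot = 0;
  for (int i = 0; i < N; ++i) { nl.start[i] = tot; tot += pairs[i].size(); }
  nl.start[N] = tot;
  nl.items.reserve(tot);
  for (int i = 0; i < N; ++i)
    for (int j : pairs[i]) nl.items.push_back(j);
  nl.x_ref = S.x;
  nl.scale_ref = 1.0;
}

static bool need_rebuild(const SysState &S, const Params &p,
                         const NeighList &nl) {
  if (std::fabs(nl.scale_ref - 1.0) > 1e-3) return true;
  double lim = 0.25 * p.skin * p.skin;
  for (int i = 0; i < S.N; ++i) {
    double dx = S.x[3 * i] - nl.x_ref[3 * i];
    double dy = S.x[3 * i + 1] - nl.x_ref[3 * i + 1];
    double dz = S.x[3 * i + 2] - nl.x_ref[3 * i + 2];
    min_image(dx, dy, S.Lx, S.Ly);
    if (dx * dx + dy * dy + dz * dz > lim) return true;
  }
  return false;
}

static void eval_pair(int i, int j, const SysState &S, const Params &p,
                      Forces &F) {
  double rv[3];
  rv[0] = S.x[3 * j] - S.x[3 * i];
  rv[1] = S.x[3 * j + 1] - S.x[3 * i + 1];
  rv[2] = S.x[3 * j + 2] - S.x[3 * i + 2];
  min_image(rv[0], rv[1], S.Lx, S.Ly);
  int a = S.sp[i], b = S.sp[j];
  double r2 = dotp(rv, rv);
  if (r2 >= p.cut2[a][b]) return;
  int t = p.itype[a][b];
  if (t == I_NONE) return;
  PairOut out;
  if (t == I_MEMB) {
    pair_membrane_tab(rv, &S.n[3 * i], &S.n[3 * j], p, r2, out);
    F.e_mem += out.e;
  } else if (t == I_WCA) {
    pair_wca(rv, p.sigc[a][b], p.eps_rep, r2, out);
    F.e_wca += out.e;
  } else {
    pair_adhesion(rv, p.sigc[a][b], p.adh_eps[a][b], p.adh_w, p.eps_rep, r2,
                  out);
    F.e_adh += out.e;
  }
  for (int k = 0; k < 3; ++k) {
    F.f[3 * j + k] += out.f[k];
    F.f[3 * i + k] -= out.f[k];
  }
  if (out.has_torque) {
    for (int k = 0; k < 3; ++k) {
      F.g[3 * i + k] += out.gi[k];
      F.g[3 * j + k] += out.gj[k];
    }
  }
  F.w_lat += out.f[0] * rv[0] + out.f[1] * rv[1];
}

static void compute_forces(const SysState &S, const Params &p,
                           const BondTable &B, const TethTable &T,
                           const NeighList *nl, Forces &F) {
  int N = S.N;
  F.f.assign(3 * N, 0.0);
  F.g.assign(3 * N, 0.0);
  F.e_mem = F.e_wca = F.e_adh = F.e_bond = F.e_teth = 0.0;
  F.w_lat = 0.0;
  if (nl) {
    for (int i = 0; i < N; ++i)
      for (int s = nl->start[i]; s < nl->start[i + 1]; ++s)
        eval_pair(i, nl->items[s], S, p, F);
  } else {
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j)
        if (S.sp[i] < S_BIND || S.sp[j] < S_BIND ||
            !B.excl.count(pair_key(i, j, N)))
          eval_pair(i, j, S, p, F);
  }
  // bonds
  for (size_t b = 0; b < B.bi.size(); ++b) {
    int i = B.bi[b], j = B.bj[b];
    double rv[3];
    rv[0] = S.x[3 * j] - S.x[3 * i];
    rv[1] = S.x[3 * j + 1] - S.x[3 * i + 1];
    rv[2] = S.x[3 * j + 2] - S.x[3 * i + 2];
    min_image(rv[0], rv[1], S.Lx, S.Ly);
    PairOut out;
    pair_bond(rv, B.r0[b], B.k[b], out);
    F.e_bond += out.e;
    for (int k = 0; k < 3; ++k) {
      F.f[3 * j + k] += out.f[k];
      F.f[3 * i + k] -= out.f[k];
    }
    F.w_lat += out.f[0] * rv[0] + out.f[1] * rv[1];
  }
  // tethers (external; excluded from lateral virial)
  for (size_t t = 0; t < T.i.size(); ++t) {
    int i = T.i[t];
    double dx = S.x[3 * i] - T.px[t];
    double dy = S.x[3 * i + 1] - T.py[t];
    double dz = S.x[3 * i + 2] - T.pz[t];
    F.e_teth += 0.5 * T.k[t] * (dx * dx + dy * dy + dz * dz);
    F.f[3 * i] -= T.k[t] * dx;
    F.f[3 * i + 1] -= T.k[t] * dy;
    F.f[3 * i + 2] -= T.k[t] * dz;
  }
}

// ---------------------------------------------------------------------------
// R interface helpers

static SysState unpack_state(const NumericMatrix &pos, const NumericMatrix &vel,
                             const NumericMatrix &ornt,
                             const IntegerVector &species,
                             const NumericVector &box,
                             const IntegerMatrix &images) {
  SysState S;
  S.N = pos.nrow();
  S.x.resize(3 * S.N);
  S.v.resize(3 * S.N);
  S.n.resize(3 * S.N);
  S.sp.resize(S.N);
  S.img.assign(2 * S.N, 0);
  for (int i = 0; i < S.N; ++i) {
    for (int k = 0; k < 3; ++k) {
      S.x[3 * i + k] = pos(i, k);
      S.v[3 * i + k] = vel(i, k);
      S.n[3 * i + k] = ornt(i, k);
    }
    S.sp[i] = species[i] - 1;
    if (S.sp[i] < 0 || S.sp[i] >= NSPEC) stop("bad species code");
    if (images.nrow() == S.N) {
      S.img[2 * i] = images(i, 0);
      S.img[2 * i + 1] = images(i, 1);
    }
  }
  S.Lx = box[0];
  S.Ly = box[1];
  return S;
}

static BondTable unpack_bonds(const NumericMatrix &bonds, int N) {
  BondTable B;
  int nb = bonds.nrow();
  for (int b = 0; b < nb; ++b) {
    int i = (int)bonds(b, 0) - 1, j = (int)bonds(b, 1) - 1;
    if (i < 0 || j < 0 || i >= N || j >= N || i == j) stop("bad bond indices");
    B.bi.push_back(i);
    B.bj.push_back(j);
    B.r0.push_back(bonds(b, 2));
    B.k.push_back(bonds(b, 3));
    B.excl.insert(pair_key(i, j, N));
  }
  return B;
}

static TethTable unpack_tethers(const NumericMatrix &teth, int N) {
  TethTable T;
  for (int t = 0; t < teth.nrow(); ++t) {
    int i = (int)teth(t, 0) - 1;
    if (i < 0 || i >= N) stop("bad tether index");
    T.i.push_back(i);
    T.px.push_back(teth(t, 1));
    T.py.push_back(teth(t, 2));
    T.pz.push_back(teth(t, 3));
    T.k.push_back(teth(t, 4));
  }
  return T;
}

// ---------------------------------------------------------------------------
// exported single-pair kernels (used by R wrappers and oracle tests)

// [[Rcpp::export]]
List cpp_pair_membrane(NumericVector rvec, NumericVector ni, NumericVector nj,
                       double eps, double mu, int zeta, double rmin,
                       double rcut) {
  Params p;
  p.eps_mem = eps; p.mu = mu; p.zeta = zeta; p.rmin = rmin; p.rcut = rcut;
  double rv[3] = {rvec[0], rvec[1], rvec[2]};
  double nni[3] = {ni[0], ni[1], ni[2]};
  double nnj[3] = {nj[0], nj[1], nj[2]};
  double r2 = dotp(rv, rv);
  if (r2 <= 0) stop("coincident particles");
  if (r2 >= rcut * rcut)
    return List::create(_["energy"] = 0.0,
                        _["force_j"] = NumericVector::create(0, 0, 0),
                        _["torque_i"] = NumericVector::create(0, 0, 0),
                        _["torque_j"] = NumericVector::create(0, 0, 0));
  PairOut out;
  pair_membrane(rv, nni, nnj, p, r2, out);
  return List::create(
      _["energy"] = out.e,
      _["force_j"] = NumericVector::create(out.f[0], out.f[1], out.f[2]),
      _["torque_i"] = NumericVector::create(out.gi[0], out.gi[1], out.gi[2]),
      _["torque_j"] = NumericVector::create(out.gj[0], out.gj[1], out.gj[2]));
}

// [[Rcpp::export]]
List cpp_pair_wca(NumericVector rvec, double sigma_c, double eps_rep) {
  double rv[3] = {rvec[0], rvec[1], rvec[2]};
  double r2 = dotp(rv, rv);
  if (r2 <= 0) stop("coincident particles");
  if (r2 >= sigma_c * sigma_c)
    return List::create(_["energy"] = 0.0,
                        _["force_j"] = NumericVector::create(0, 0, 0));
  PairOut out;
  pair_wca(rv, sigma_c, eps_rep, r2, out);
  return List::create(
      _["energy"] = out.e,
      _["force_j"] = NumericVector::create(out.f[0], out.f[1], out.f[2]));
}

// [[Rcpp::export]]
List cpp_pair_adhesion(NumericVector rvec, double sigma_c, double eps,
                       double w, double eps_rep) {
  double rv[3] = {rvec[0], rvec[1], rvec[2]};
  double r2 = dotp(rv, rv);
  if (r2 <= 0) stop("coincident particles");
  double rc = sigma_c + w;
  if (r2 >= rc * rc)
    return List::create(_["energy"] = 0.0,
                        _["force_j"] = NumericVector::create(0, 0, 0));
  PairOut out;
  pair_adhesion(rv, sigma_c, eps, w, eps_rep, r2, out);
  return List::create(
      _["energy"] = out.e,
      _["force_j"] = NumericVector::create(out.f[0], out.f[1], out.f[2]));
}

// [[Rcpp::export]]
List cpp_pair_bond(NumericVector rvec, double r0, double k) {
  double rv[3] = {rvec[0], rvec[1], rvec[2]};
  PairOut out;
  pair_bond(rv, r0, k, out);
  return List::create(
      _["energy"] = out.e,
      _["force_j"] = NumericVector::create(out.f[0], out.f[1], out.f[2]));
}

// ---------------------------------------------------------------------------
// full-system single evaluation

// [[Rcpp::export]]
List cpp_compute_forces(NumericMatrix pos, NumericMatrix vel,
                        NumericMatrix ornt, IntegerVector species,
                        NumericVector box, NumericMatrix bonds,
                        NumericMatrix tethers, List params,
                        bool all_pairs = false) {
  Params p = parse_params(params);
  IntegerMatrix noimg(0, 2);
  SysState S = unpack_state(pos, vel, ornt, species, box, noimg);
  set_rlist(p, S.sp);
  BondTable B = unpack_bonds(bonds, S.N);
  TethTable T = unpack_tethers(tethers, S.N);
  Forces F;
  if (all_pairs) {
    compute_forces(S, p, B, T, nullptr, F);
  } else {
    NeighList nl;
    build_neigh(S, p, B, nl);
    compute_forces(S, p, B, T, &nl, F);
  }
  NumericMatrix fo(S.N, 3), go(S.N, 3);
  for (int i = 0; i < S.N; ++i)
    for (int k = 0; k < 3; ++k) {
      fo(i, k) = F.f[3 * i + k];
      go(i, k) = F.g[3 * i + k];
    }
  double epot = F.e_mem + F.e_wca + F.e_adh + F.e_bond + F.e_teth;
  return List::create(
      _["forces"] = fo, _["torques"] = go, _["e_pot"] = epot,
      _["e_mem"] = F.e_mem, _["e_wca"] = F.e_wca, _["e_adh"] = F.e_adh,
      _["e_bond"] = F.e_bond, _["e_tether"] = F.e_teth,
      _["w_lat"] = F.w_lat);
}

// ---------------------------------------------------------------------------
// Langevin run loop (GJF velocity-Verlet; overdamped orientation update)

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, NumericMatrix ornt,
             IntegerVector species, NumericVector box, IntegerMatrix images,
             NumericMatrix bonds, NumericMatrix tethers, List params,
             int n_steps, double step0, int frame_stride, int obs_stride) {
  Params p = parse_params(params);
  SysState S = unpack_state(pos, vel, ornt, species, box, images);
  set_rlist(p, S.sp);
  BondTable B = unpack_bonds(bonds, S.N);
  TethTable T = unpack_tethers(tethers, S.N);
  int N = S.N;

  double dt = p.dt, kT = p.temperature;
  double gdt2 = 0.5 * p.gamma_t * dt;
  double a_c = (1.0 - gdt2) / (1.0 + gdt2);
  double b_c = 1.0 / (1.0 + gdt2);
  double sig_beta = std::sqrt(2.0 * p.gamma_t * kT * dt);
  double rot_mob = dt / p.gamma_r;
  double sig_rot = std::sqrt(2.0 * kT * dt / p.gamma_r);

  NeighList nl;
  build_neigh(S, p, B, nl);
  Forces F;
  compute_forces(S, p, B, T, &nl, F);
  long n_rebuilds = 0;
  long n_pairs_sample = nl.start[N];

  std::vector<double> beta(3 * N);
  int status = 0, bad_particle = -1;
  double bad_step = 0;

  List frames;
  int n_obs = (obs_stride > 0) ? n_steps / obs_stride : 0;
  NumericMatrix obs(n_obs, 12);
  int obs_row = 0;
  double cum_scale = 1.0;

  for (int s = 1; s <= n_steps; ++s) {
    double gstep = step0 + s;
    // barostat first (with the stored virial), then the orientation and
    // position updates: every quantity stored across the step boundary then
    // refers to the returned state, so checkpoint resumes are bit-exact
    // lateral barostat
    if (p.tension_on) {
      double kin_lat = 0.0;
      for (int i = 0; i < N; ++i) {
        kin_lat += S.v[3 * i] * S.v[3 * i] +
                   S.v[3 * i + 1] * S.v[3 * i + 1];
      }
      double area = S.Lx * S.Ly;
      double Pi = (kin_lat + F.w_lat) / (2.0 * area);
      double lam = 1.0 + p.tension_c * dt * (Pi - p.tension_target);
      if (lam > 1.0001) lam = 1.0001;
      if (lam < 0.9999) lam = 0.9999;
      S.Lx *= lam;
      S.Ly *= lam;
      for (int i = 0; i < N; ++i) {
        S.x[3 * i] *= lam;
        S.x[3 * i + 1] *= lam;
      }
      cum_scale *= lam;
      nl.scale_ref *= lam;
    }
    // orientation update first, from the torques of the last force
    // evaluation; the returned end-of-run state is then exactly the state a
    // fresh start would evaluate, making checkpoint resumes exact
    // overdamped orientation update (membrane species only)
    for (int i = 0; i < N; ++i) {
      if (S.sp[i] > S_REC) continue;
      double *n = &S.n[3 * i];
      double g[3] = {F.g[3 * i], F.g[3 * i + 1], F.g[3 * i + 2]};
      double gn = dotp(g, n);
      double xi[3] = {0, 0, 0};
      if (kT > 0) {
        double g1, g2, g3, g4;
        cb_gauss2(p.seed, (uint64_t)gstep, i, 2, g1, g2);
        cb_gauss2(p.seed, (uint64_t)gstep, i, 3, g3, g4);
        xi[0] = g1; xi[1] = g2; xi[2] = g3;
        double xn = dotp(xi, n);
        for (int k = 0; k < 3; ++k) xi[k] -= xn * n[k];
      }
      double nn[3];
      for (int k = 0; k < 3; ++k)
        nn[k] = n[k] + rot_mob * (g[k] - gn * n[k]) + sig_rot * xi[k];
      double nrm = std::sqrt(dotp(nn, nn));
      for (int k = 0; k < 3; ++k) n[k] = nn[k] / nrm;
    }
    // noise
    if (p.gamma_t > 0 && kT > 0) {
      for (int i = 0; i < N; ++i) {
        double g1, g2, g3, g4;
        cb_gauss2(p.seed, (uint64_t)gstep, i, 0, g1, g2);
        cb_gauss2(p.seed, (uint64_t)gstep, i, 1, g3, g4);
        beta[3 * i] = sig_beta * g1;
        beta[3 * i + 1] = sig_beta * g2;
        beta[3 * i + 2] = sig_beta * g3;
      }
    } else {
      std::fill(beta.begin(), beta.end(), 0.0);
    }
    // position update
    double max_disp2 = 0.0;
    for (int i = 0; i < N; ++i) {
      double dvec[3];
      double d2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        dvec[k] = b_c * dt * S.v[3 * i + k] +
                  0.5 * b_c * dt * dt * F.f[3 * i + k] +
                  0.5 * b_c * dt * beta[3 * i + k];
        d2 += dvec[k] * dvec[k];
      }
      if (p.max_move > 0 && d2 > p.max_move * p.max_move) {
        double sc = p.max_move / std::sqrt(d2);
        for (int k = 0; k < 3; ++k) dvec[k] *= sc;
        d2 = p.max_move * p.max_move;
        // damp the velocity of clamped particles so the excess does not
        // re-enter on the next step
        for (int k = 0; k < 3; ++k) S.v[3 * i + k] *= 0.5;
      }
      for (int k = 0; k < 3; ++k) S.x[3 * i + k] += dvec[k];
      max_disp2 = std::max(max_disp2, d2);
      // wrap x,y
      if (S.x[3 * i] < 0) { S.x[3 * i] += S.Lx; S.img[2 * i] -= 1; }
      else if (S.x[3 * i] >= S.Lx) { S.x[3 * i] -= S.Lx; S.img[2 * i] += 1; }
      if (S.x[3 * i + 1] < 0) { S.x[3 * i + 1] += S.Ly; S.img[2 * i + 1] -= 1; }
      else if (S.x[3 * i + 1] >= S.Ly) { S.x[3 * i + 1] -= S.Ly; S.img[2 * i + 1] += 1; }
    }
    if (p.max_move <= 0 && max_disp2 > 1.0) {
      status = 1;
      bad_step = gstep;
      double worst = 0;
      for (int i = 0; i < N; ++i) {
        double d2 = 0;
        for (int k = 0; k < 3; ++k) {
          double dv = S.v[3 * i + k];
          d2 += dv * dv;
        }
        if (d2 > worst) { worst = d2; bad_particle = i; }
      }
      break;
    }
    if (need_rebuild(S, p, nl)) { build_neigh(S, p, B, nl); ++n_rebuilds; }
    // new forces
    std::vector<double> f_old = F.f;
    compute_forces(S, p, B, T, &nl, F);
    // velocity update
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < 3; ++k)
        S.v[3 * i + k] = a_c * S.v[3 * i + k] +
                         0.5 * dt * (a_c * f_old[3 * i + k] + F.f[3 * i + k]) +
                         b_c * beta[3 * i + k];
    // observers and frames are captured at the exact state of this step's
    // force evaluation (positions after the move, orientations before their
    // update, box before rescaling), so recorded energies can be reproduced
    // from saved frames bit-for-bit
    if (obs_stride > 0 && s % obs_stride == 0 && obs_row < n_obs) {
      double ekin = 0.0, kin_lat = 0.0;
      for (int i = 0; i < N; ++i) {
        double k2 = 0;
        for (int k = 0; k < 3; ++k) k2 += S.v[3 * i + k] * S.v[3 * i + k];
        ekin += 0.5 * k2;
        kin_lat += S.v[3 * i] * S.v[3 * i] + S.v[3 * i + 1] * S.v[3 * i + 1];
      }
      double epot = F.e_mem + F.e_wca + F.e_adh + F.e_bond + F.e_teth;
      double area = S.Lx * S.Ly;
      obs(obs_row, 0) = gstep;
      obs(obs_row, 1) = epot;
      obs(obs_row, 2) = F.e_bond;
      obs(obs_row, 3) = F.e_mem;
      obs(obs_row, 4) = F.e_wca;
      obs(obs_row, 5) = F.e_adh;
      obs(obs_row, 6) = F.e_teth;
      obs(obs_row, 7) = ekin;
      obs(obs_row, 8) = (N > 0) ? 2.0 * ekin / (3.0 * N) : 0.0;
      obs(obs_row, 9) = S.Lx;
      obs(obs_row, 10) = (kin_lat + F.w_lat) / (2.0 * area);
      obs(obs_row, 11) = ekin + epot;
      obs_row++;
    }
    if (frame_stride > 0 && s % frame_stride == 0) {
      NumericMatrix fp(N, 3), fn(N, 3);
      IntegerMatrix fi(N, 2);
      for (int i = 0; i < N; ++i) {
        for (int k = 0; k < 3; ++k) {
          fp(i, k) = S.x[3 * i + k];
          fn(i, k) = S.n[3 * i + k];
        }
        fi(i, 0) = S.img[2 * i];
        fi(i, 1) = S.img[2 * i + 1];
      }
      frames.push_back(List::create(
          _["step"] = gstep, _["box"] = NumericVector::create(S.Lx, S.Ly),
          _["pos"] = fp, _["ornt"] = fn, _["images"] = fi));
    }
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix po(N, 3), vo(N, 3), no(N, 3);
  IntegerMatrix io(N, 2);
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 3; ++k) {
      po(i, k) = S.x[3 * i + k];
      vo(i, k) = S.v[3 * i + k];
      no(i, k) = S.n[3 * i + k];
    }
    io(i, 0) = S.img[2 * i];
    io(i, 1) = S.img[2 * i + 1];
  }
  if (obs_row < n_obs) obs = obs(Range(0, std::max(0, obs_row - 1)), _);
  return List::create(
      _["pos"] = po, _["vel"] = vo, _["ornt"] = no, _["images"] = io,
      _["box"] = NumericVector::create(S.Lx, S.Ly), _["obs"] = obs,
      _["frames"] = frames, _["status"] = status,
      _["bad_step"] = bad_step, _["bad_particle"] = bad_particle + 1,
      _["cum_scale"] = cum_scale, _["n_rebuilds"] = (double)n_rebuilds,
      _["n_pairs"] = (double)n_pairs_sample);
}
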