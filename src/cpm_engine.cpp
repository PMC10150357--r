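// Cellular Potts engine: periodic 3D spin lattice, incremental Hamiltonian
// deltas, Metropolis dynamics, and the division/death lifecycle.
//
// All coordinates are 0-based voxel indices; the R wrappers translate to
// 1-based array indices.  Center-of-mass sums are kept in unwrapped
// coordinates: every voxel enters the sum as the periodic image nearest the
// cell's current center of mass, so compact cells (extent well below L/2)
// carry an exact, incrementally maintained center of mass.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static inline double sq(double x) { return x * x; }

static inline uint64_t rotl64(const uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

// xoshiro256++ seeded through splitmix64; independent of R's RNG so that a
// run is reproducible from the integer seed in its manifest alone.
struct Rng {
  uint64_t s[4];
  void seed(uint64_t x) {
    for (int i = 0; i < 4; i++) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  uint64_t next() {
    const uint64_t r = rotl64(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl64(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0, 1)
  int below(int n) {
    int r = (int)(unif() * n);
    return r >= n ? n - 1 : r;
  }
  long long below64(long long n) {
    long long r = (long long)(unif() * (double)n);
    return r >= n ? n - 1 : r;
  }
};

struct Cell {
  int type;          // 0 healthy, 1 cancer
  bool alive;
  bool dying;
  int pi, pj;        // phenotype indices (adhesion, motility), -1 for healthy
  long long volume;
  long long surface; // unlike-neighbor face count
  double sx, sy, sz; // sums of unwrapped voxel coordinates
  long long birth;   // MCS
  double ex, ey, ez; // motility direction (unit vector)
  double tv, ts;     // target volume / target surface (0 when dying)
};

// event kinds
enum { EV_DIVISION = 1, EV_DEATH = 2, EV_MECH_DEATH = 3 };

struct Sim {
  int L;
  long long N;
  std::vector<int> spins;
  std::vector<Cell> cells;

  // Hamiltonian couplings
  double V0, lamV, S0, lamS, Tmc, lam_c;
  int t_mot;
  double J_healthy, healthy_mot;
  int n_off;
  int OX[26], OY[26], OZ[26];

  // lifecycle
  double div_age, death_age, div_vol_frac, max_div, max_death, mut_prob;
  int dep_mode;      // 0 none, 1 linear
  int mut_boundary;  // 0 abort, 1 reflect

  // nutrient
  int nut_mode;      // 0 static, 1 orbiting
  double A, Tper, Rn;
  double cx, cy, cz; // fixed box center

  long long time;
  Rng rng;
  long long attempts, accepts, noops;
  long long n_cancer; // alive cancer cells (dying included)
  bool extinct;

  std::vector<double> ev_t;
  std::vector<int> ev_kind, ev_cell, ev_pi, ev_pj, ev_mut;
  std::vector<double> ev_x, ev_y, ev_z, ev_r;

  std::vector<double> comp_t;
  std::vector<int> comp_i, comp_j, comp_n;

  inline long long sidx(int x, int y, int z) const {
    return (long long)x + (long long)L * ((long long)y + (long long)L * z);
  }
  inline void coords(long long s, int &x, int &y, int &z) const {
    x = (int)(s % L);
    y = (int)((s / L) % L);
    z = (int)(s / ((long long)L * L));
  }
  inline int wrap(int v) const {
    if (v < 0) return v + L;
    if (v >= L) return v - L;
    return v;
  }
  // periodic image of integer coordinate x nearest reference c
  inline double img(int x, double c) const {
    return x + L * std::floor((c - x) / (double)L + 0.5);
  }
  // Contact energy per unlike-cell face: the negative of the pair's bond
  // strength (adhesion lowers the energy of shared area; nonnegative
  // parameters mean no repulsion).  Cancer pairs use the arithmetic mean of
  // their adhesion parameters; any pair involving healthy tissue uses the
  // healthy reference strength.
  inline double Jpair(const Cell &a, const Cell &b) const {
    if (a.type == 1 && b.type == 1) return -5.0 * (a.pi + b.pi);
    return -J_healthy;
  }
  inline double mstr(const Cell &c) const {
    return c.type == 1 ? 10.0 * c.pj : healthy_mot;
  }
  inline double cdist(double x, double y, double z) const {
    return std::sqrt(sq(x - cx) + sq(y - cy) + sq(z - cz));
  }

  void set_neighborhood(int n) {
    n_off = 0;
    if (n == 6) {
      const int d[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; k++) { OX[k]=d[k][0]; OY[k]=d[k][1]; OZ[k]=d[k][2]; }
      n_off = 6;
    } else if (n == 26) {
      for (int dx = -1; dx <= 1; dx++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dz = -1; dz <= 1; dz++) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            OX[n_off]=dx; OY[n_off]=dy; OZ[n_off]=dz; n_off++;
          }
    } else {
      stop("neighborhood must be 6 or 26");
    }
  }

  void unit_vec(double &x, double &y, double &z) {
    for (;;) {
      double u = 2.0 * unifr() - 1.0, v = 2.0 * unifr() - 1.0;
      double s2 = u * u + v * v;
      if (s2 < 1.0 && s2 > 0.0) {
        double f = 2.0 * std::sqrt(1.0 - s2);
        x = u * f; y = v * f; z = 1.0 - 2.0 * s2;
        return;
      }
    }
  }
  inline double unifr() { return rng.unif(); }

  void sink(double t, double &ox, double &oy, double &oz) const {
    ox = cx; oy = cy; oz = cz;
    if (nut_mode == 1) {
      ox += A * std::cos(2.0 * M_PI * t / Tper);
      oy += A * std::sin(2.0 * M_PI * t / Tper);
    }
  }
  double nutrient(double x, double y, double z, double t) const {
    double ox, oy, oz;
    sink(t, ox, oy, oz);
    double d = std::sqrt(sq(x - ox) + sq(y - oy) + sq(z - oz)) / Rn;
    return d < 0.0 ? 0.0 : (d > 1.0 ? 1.0 : d);
  }

  void log_event(int kind, int id, int pi, int pj,
                 double x, double y, double z, int mut) {
    ev_t.push_back((double)time);
    ev_kind.push_back(kind);
    ev_cell.push_back(id);
    ev_pi.push_back(pi);
    ev_pj.push_back(pj);
    ev_x.push_back(x); ev_y.push_back(y); ev_z.push_back(z);
    ev_r.push_back(cdist(x, y, z));
    ev_mut.push_back(mut);
  }

  // Compute dH for copying candidate b into site s.  When `apply` (either
  // forced or by the Metropolis draw) the flip and all bookkeeping updates
  // are carried out.  Both paths share one image/delta computation so the
  // accepted dH is exactly the applied one.
  double do_flip(long long s, int b_id, bool force_apply, bool metropolis,
                 bool *accepted_out) {
    int a_id = spins[s];
    if (a_id == b_id) {
      if (accepted_out) *accepted_out = true;
      return 0.0;
    }
    Cell &A = cells[a_id - 1];
    Cell &B = cells[b_id - 1];
    int x, y, z;
    coords(s, x, y, z);
    bool annih = (A.volume == 1);
    double dH = 0.0;

    if (!annih)
      dH += lamV * (sq(A.volume - 1 - A.tv) - sq(A.volume - A.tv));
    else
      dH -= lamV * sq(1.0 - A.tv);
    dH += lamV * (sq(B.volume + 1 - B.tv) - sq(B.volume - B.tv));

    // surface and adhesion deltas over the neighborhood
    int nids[28];
    long long nds[28];
    int nn = 0;
    double dAdh = 0.0;
    for (int o = 0; o < n_off; o++) {
      int xn = wrap(x + OX[o]), yn = wrap(y + OY[o]), zn = wrap(z + OZ[o]);
      int t = spins[sidx(xn, yn, zn)];
      Cell &Tt = cells[t - 1];
      long long da = 0, db = 0, dt = 0;
      if (t != a_id) { da -= 1; dAdh -= Jpair(A, Tt); }
      if (t != b_id) { db += 1; dAdh += Jpair(B, Tt); }
      dt = (long long)(b_id != t) - (long long)(a_id != t);
      long long dd[3] = {da, db, dt};
      int ids[3] = {a_id, b_id, t};
      for (int q = 0; q < 3; q++) {
        if (dd[q] == 0) continue;
        int k = 0;
        for (; k < nn; k++) if (nids[k] == ids[q]) { nds[k] += dd[q]; break; }
        if (k == nn) { nids[nn] = ids[q]; nds[nn] = dd[q]; nn++; }
      }
    }
    dH += dAdh;
    for (int k = 0; k < nn; k++) {
      if (nds[k] == 0) continue;
      if (annih && nids[k] == a_id) continue; // whole term removed below
      Cell &C = cells[nids[k] - 1];
      dH += lamS * (sq(C.surface + nds[k] - C.ts) - sq(C.surface - C.ts));
    }
    if (annih) dH -= lamS * sq((double)A.surface - A.ts);

    // center-of-mass dependent terms (motility, central potential)
    double comAx = A.sx / A.volume, comAy = A.sy / A.volume, comAz = A.sz / A.volume;
    double iax = img(x, comAx), iay = img(y, comAy), iaz = img(z, comAz);
    double mA = mstr(A);
    if (annih) {
      if (mA != 0.0)
        dH -= -mA * (A.ex * comAx + A.ey * comAy + A.ez * comAz);
      if (A.type == 1 && lam_c != 0.0)
        dH -= lam_c * cdist(comAx, comAy, comAz);
    } else {
      double v = (double)A.volume;
      double nax = (A.sx - iax) / (v - 1), nay = (A.sy - iay) / (v - 1),
             naz = (A.sz - iaz) / (v - 1);
      if (mA != 0.0)
        dH += -mA * (A.ex * (nax - comAx) + A.ey * (nay - comAy) +
                     A.ez * (naz - comAz));
      if (A.type == 1 && lam_c != 0.0)
        dH += lam_c * (cdist(nax, nay, naz) - cdist(comAx, comAy, comAz));
    }
    double comBx = B.sx / B.volume, comBy = B.sy / B.volume, comBz = B.sz / B.volume;
    double ibx = img(x, comBx), iby = img(y, comBy), ibz = img(z, comBz);
    {
      double v = (double)B.volume;
      double nbx = (B.sx + ibx) / (v + 1), nby = (B.sy + iby) / (v + 1),
             nbz = (B.sz + ibz) / (v + 1);
      double mB = mstr(B);
      if (mB != 0.0)
        dH += -mB * (B.ex * (nbx - comBx) + B.ey * (nby - comBy) +
                     B.ez * (nbz - comBz));
      if (B.type == 1 && lam_c != 0.0)
        dH += lam_c * (cdist(nbx, nby, nbz) - cdist(comBx, comBy, comBz));
    }

    bool acc = true;
    if (metropolis && dH > 0.0)
      acc = (rng.unif() < std::exp(-dH / Tmc));
    if (force_apply) acc = true;
    if (accepted_out) *accepted_out = acc;
    if (!acc) return dH;

    spins[s] = b_id;
    for (int k = 0; k < nn; k++) cells[nids[k] - 1].surface += nds[k];
    A.volume -= 1;
    A.sx -= iax; A.sy -= iay; A.sz -= iaz;
    B.volume += 1;
    B.sx += ibx; B.sy += iby; B.sz += ibz;
    if (annih) {
      A.alive = false;
      A.volume = 0; A.surface = 0;
      A.sx = A.sy = A.sz = 0.0;
      if (A.type == 1) {
        n_cancer--;
        // a dying cell completing its shrinkage was already logged at
        // marking; only spontaneous annihilations count as mechanical death
        if (!A.dying)
          log_event(EV_MECH_DEATH, a_id, A.pi, A.pj, comAx, comAy, comAz, 0);
      }
    }
    return dH;
  }

  void sweep_once() {
    for (long long k = 0; k < N; k++) {
      long long s = rng.below64(N);
      int o = rng.below(n_off);
      int x, y, z;
      coords(s, x, y, z);
      int b = spins[sidx(wrap(x + OX[o]), wrap(y + OY[o]), wrap(z + OZ[o]))];
      attempts++;
      if (spins[s] == b) { noops++; continue; }
      bool acc;
      do_flip(s, b, false, true, &acc);
      if (acc) accepts++;
    }
  }

  void reassign_motility() {
    for (size_t i = 0; i < cells.size(); i++) {
      if (!cells[i].alive) continue;
      unit_vec(cells[i].ex, cells[i].ey, cells[i].ez);
    }
  }

  void mark_dying(int id) {
    Cell &C = cells[id - 1];
    if (!C.alive || C.dying) return;
    C.dying = true;
    C.tv = 0.0;
    C.ts = 0.0;
    log_event(EV_DEATH, id, C.pi, C.pj,
              C.sx / C.volume, C.sy / C.volume, C.sz / C.volume, 0);
  }

  bool divide_cell(int id) {
    {
      Cell &P0 = cells[id - 1];
      if (!P0.alive || P0.type != 1 || P0.dying || P0.volume < 2) return false;
    }
    double comx, comy, comz;
    int ppi, ppj;
    std::vector<long long> vox;
    std::vector<double> wx, wy, wz;
    {
      Cell &P0 = cells[id - 1];
      comx = P0.sx / P0.volume; comy = P0.sy / P0.volume; comz = P0.sz / P0.volume;
      ppi = P0.pi; ppj = P0.pj;
      vox.reserve((size_t)P0.volume);
      for (long long s = 0; s < N; s++) {
        if (spins[s] != id) continue;
        int x, y, z;
        coords(s, x, y, z);
        vox.push_back(s);
        wx.push_back(img(x, comx));
        wy.push_back(img(y, comy));
        wz.push_back(img(z, comz));
      }
    }
    std::vector<char> side(vox.size());
    int n1 = -1;
    for (int att = 0; att < 10; att++) {
      double nx, ny, nz;
      unit_vec(nx, ny, nz);
      int c1 = 0;
      for (size_t k = 0; k < vox.size(); k++) {
        double d = (wx[k] - comx) * nx + (wy[k] - comy) * ny + (wz[k] - comz) * nz;
        side[k] = d >= 0 ? 1 : 0;
        if (side[k]) c1++;
      }
      if (c1 > 0 && c1 < (int)vox.size()) { n1 = c1; break; }
    }
    if (n1 < 0) return false; // degenerate split, skip this event

    int small_side = (2 * n1 <= (int)vox.size()) ? 1 : 0;
    int nid = (int)cells.size() + 1;
    Cell D;
    D.type = 1; D.alive = true; D.dying = false;
    D.pi = ppi; D.pj = ppj;
    D.volume = 0; D.surface = 0;
    D.sx = D.sy = D.sz = 0.0;
    D.birth = time;
    unit_vec(D.ex, D.ey, D.ez);
    D.tv = V0; D.ts = S0;
    cells.push_back(D);
    n_cancer++;
    Cell &P = cells[id - 1];
    Cell &Dd = cells[nid - 1];
    P.volume = 0; P.sx = P.sy = P.sz = 0.0;
    for (size_t k = 0; k < vox.size(); k++) {
      if (side[k] == small_side) {
        spins[vox[k]] = nid;
        Dd.volume++; Dd.sx += wx[k]; Dd.sy += wy[k]; Dd.sz += wz[k];
      } else {
        P.volume++; P.sx += wx[k]; P.sy += wy[k]; P.sz += wz[k];
      }
    }
    // surfaces of the two daughters change (new internal interface); other
    // cells' face counts are unaffected by the relabeling
    long long sp = 0, sd = 0;
    for (size_t k = 0; k < vox.size(); k++) {
      int own = spins[vox[k]];
      int x, y, z;
      coords(vox[k], x, y, z);
      int cnt = 0;
      for (int o = 0; o < n_off; o++) {
        int t = spins[sidx(wrap(x + OX[o]), wrap(y + OY[o]), wrap(z + OZ[o]))];
        if (t != own) cnt++;
      }
      if (own == id) sp += cnt; else sd += cnt;
    }
    P.surface = sp;
    Dd.surface = sd;
    P.birth = time; // both daughters restart their age

    int mut = 0;
    if (rng.unif() < mut_prob) {
      int which = rng.below(2);
      int axis = rng.below(2);
      int sgn = rng.below(2) ? 1 : -1;
      Cell &M = which ? Dd : P;
      int v = (axis == 0) ? M.pi : M.pj;
      int nv = v + sgn;
      if (nv < 0 || nv > 11) {
        if (mut_boundary == 1) { nv = v - sgn; mut = 1; }
        else { nv = v; mut = 0; } // abort: step would leave the grid
      } else {
        mut = 1;
      }
      if (mut) { if (axis == 0) M.pi = nv; else M.pj = nv; }
    }
    log_event(EV_DIVISION, id, ppi, ppj, comx, comy, comz, mut);
    return true;
  }

  void lifecycle_once() {
    size_t maxid = cells.size();
    for (size_t i = 0; i < maxid; i++) {
      Cell &C = cells[i];
      if (!C.alive || C.type != 1 || C.dying) continue;
      double age = (double)(time - C.birth);
      double nav = nutrient(C.sx / C.volume, C.sy / C.volume, C.sz / C.volume,
                            (double)time);
      if (age > div_age && C.volume > div_vol_frac * V0) {
        double r = (dep_mode == 1) ? nav * max_div : max_div;
        if (rng.unif() < r) {
          divide_cell((int)i + 1);
          continue;
        }
      }
      // re-fetch: divide_cell may have grown the cell vector
      Cell &C2 = cells[i];
      if (age > death_age && !C2.dying) {
        double r = (dep_mode == 1) ? (1.0 - nav) * max_death : max_death;
        if (rng.unif() < r) mark_dying((int)i + 1);
      }
    }
  }

  void record_composition() {
    int counts[144];
    std::fill(counts, counts + 144, 0);
    for (size_t i = 0; i < cells.size(); i++) {
      Cell &C = cells[i];
      if (C.alive && C.type == 1 && !C.dying)
        counts[C.pi * 12 + C.pj]++;
    }
    for (int i = 0; i < 12; i++)
      for (int j = 0; j < 12; j++) {
        comp_t.push_back((double)time);
        comp_i.push_back(i);
        comp_j.push_back(j);
        comp_n.push_back(counts[i * 12 + j]);
      }
  }

  // returns 1 when the cancer population went extinct
  int run(long long n_mcs, int cadence, bool lifecycle_on) {
    if (comp_t.empty() && cadence > 0) record_composition();
    for (long long step = 0; step < n_mcs; step++) {
      if (t_mot > 0 && (time % t_mot) == 0) reassign_motility();
      sweep_once();
      if (lifecycle_on) lifecycle_once();
      time++;
      if (cadence > 0 && (time % cadence) == 0) record_composition();
      if (lifecycle_on && n_cancer == 0) {
        extinct = true;
        if (cadence > 0 && (time % cadence) != 0) record_composition();
        break;
      }
      if ((step & 63) == 0) Rcpp::checkUserInterrupt();
    }
    return extinct ? 1 : 0;
  }
};

static Sim *get(SEXP xp) {
  Rcpp::XPtr<Sim> p(xp);
  return p.get();
}

// [[Rcpp::export]]
SEXP cpp_sim_new(List params) {
  Sim *sim = new Sim();
  sim->L = as<int>(params["grid_side"]);
  sim->N = (long long)sim->L * sim->L * sim->L;
  sim->spins.assign((size_t)sim->N, 0);
  sim->V0 = as<double>(params["target_volume"]);
  sim->lamV = as<double>(params["volume_coupling"]);
  sim->S0 = as<double>(params["target_surface"]);
  sim->lamS = as<double>(params["surface_coupling"]);
  sim->Tmc = as<double>(params["temperature"]);
  sim->lam_c = std::fabs(as<double>(params["central_coupling"]));
  sim->t_mot = as<int>(params["motility_recalc_interval"]);
  sim->J_healthy = as<double>(params["adhesion_healthy"]);
  sim->healthy_mot = as<double>(params["healthy_motility"]);
  sim->set_neighborhood(as<int>(params["neighborhood"]));
  sim->div_age = as<double>(params["division_age_min"]);
  sim->death_age = as<double>(params["death_age_min"]);
  sim->div_vol_frac = as<double>(params["division_volume_fraction"]);
  sim->max_div = as<double>(params["max_division_rate"]);
  sim->max_death = as<double>(params["max_death_rate"]);
  sim->mut_prob = as<double>(params["mutation_probability"]);
  std::string mb = as<std::string>(params["mutation_boundary"]);
  sim->mut_boundary = (mb == "reflect") ? 1 : 0;
  std::string dm = as<std::string>(params["dependency_mode"]);
  sim->dep_mode = (dm == "linear") ? 1 : 0;
  std::string nm = as<std::string>(params["nutrient_mode"]);
  sim->nut_mode = (nm == "orbiting") ? 1 : 0;
  sim->A = as<double>(params["orbit_amplitude"]);
  sim->Tper = as<double>(params["orbit_period"]);
  if (sim->nut_mode == 1 && sim->Tper <= 0)
    stop("orbit period must be positive in orbiting mode");
  sim->Rn = as<double>(params["decay_radius"]);
  double c = (sim->L - 1) / 2.0;
  sim->cx = sim->cy = sim->cz = c;
  sim->time = 0;
  sim->rng.seed((uint64_t)as<double>(params["rng_seed"]));
  sim->attempts = sim->accepts = sim->noops = 0;
  sim->n_cancer = 0;
  sim->extinct = false;
  Rcpp::XPtr<Sim> ptr(sim, true);
  return ptr;
}

// [[Rcpp::export]]
void cpp_sim_load(SEXP xp, IntegerVector spins, IntegerVector type,
                  IntegerVector pi, IntegerVector pj, NumericVector birth) {
  Sim *s = get(xp);
  if ((long long)spins.size() != s->N) stop("spin array size mismatch");
  int M = type.size();
  for (long long k = 0; k < s->N; k++) {
    int id = spins[(R_xlen_t)k];
    if (id < 1 || id > M) stop("spin id out of range");
    s->spins[(size_t)k] = id;
  }
  s->cells.clear();
  s->cells.resize(M);
  s->n_cancer = 0;
  std::vector<double> ax(M, -1.0), ay(M), az(M);
  for (int i = 0; i < M; i++) {
    Cell &C = s->cells[i];
    C.type = type[i];
    C.alive = false;
    C.dying = false;
    C.pi = pi[i];
    C.pj = pj[i];
    C.volume = 0;
    C.surface = 0;
    C.sx = C.sy = C.sz = 0.0;
    C.birth = (long long)birth[i];
    C.tv = s->V0;
    C.ts = s->S0;
    s->unit_vec(C.ex, C.ey, C.ez);
  }
  // anchor pass: image nearest the cell's first voxel, then one refinement
  // pass relative to the resulting mean
  for (int pass = 0; pass < 2; pass++) {
    std::vector<double> nsx(M, 0.0), nsy(M, 0.0), nsz(M, 0.0);
    std::vector<long long> nv(M, 0);
    for (long long k = 0; k < s->N; k++) {
      int id = s->spins[(size_t)k] - 1;
      int x, y, z;
      s->coords(k, x, y, z);
      double rx, ry, rz;
      if (pass == 0) {
        if (ax[id] < 0) { ax[id] = x; ay[id] = y; az[id] = z; }
        rx = ax[id]; ry = ay[id]; rz = az[id];
      } else {
        Cell &C = s->cells[id];
        rx = C.sx / C.volume; ry = C.sy / C.volume; rz = C.sz / C.volume;
      }
      nsx[id] += s->img(x, rx);
      nsy[id] += s->img(y, ry);
      nsz[id] += s->img(z, rz);
      nv[id]++;
    }
    for (int i = 0; i < M; i++) {
      Cell &C = s->cells[i];
      C.volume = nv[i];
      C.sx = nsx[i]; C.sy = nsy[i]; C.sz = nsz[i];
      C.alive = nv[i] > 0;
    }
  }
  // surfaces
  for (long long k = 0; k < s->N; k++) {
    int own = s->spins[(size_t)k];
    int x, y, z;
    s->coords(k, x, y, z);
    long long cnt = 0;
    for (int o = 0; o < s->n_off; o++) {
      int t = s->spins[(size_t)s->sidx(s->wrap(x + s->OX[o]),
                                       s->wrap(y + s->OY[o]),
                                       s->wrap(z + s->OZ[o]))];
      if (t != own) cnt++;
    }
    s->cells[own - 1].surface += cnt;
  }
  for (int i = 0; i < M; i++)
    if (s->cells[i].alive && s->cells[i].type == 1) s->n_cancer++;
}

// [[Rcpp::export]]
List cpp_sim_info(SEXP xp) {
  Sim *s = get(xp);
  return List::create(
      _["grid_side"] = s->L, _["time"] = (double)s->time,
      _["attempts"] = (double)s->attempts, _["accepts"] = (double)s->accepts,
      _["noops"] = (double)s->noops, _["n_cancer"] = (double)s->n_cancer,
      _["n_cells"] = (int)s->cells.size(), _["extinct"] = s->extinct);
}

// [[Rcpp::export]]
List cpp_sim_state(SEXP xp) {
  Sim *s = get(xp);
  IntegerVector sp((R_xlen_t)s->N);
  for (long long k = 0; k < s->N; k++) sp[(R_xlen_t)k] = s->spins[(size_t)k];
  sp.attr("dim") = IntegerVector::create(s->L, s->L, s->L);
  int M = (int)s->cells.size();
  IntegerVector id(M), type(M), pi(M), pj(M);
  NumericVector vol(M), surf(M), cx(M), cy(M), cz(M), birth(M),
      ex(M), ey(M), ez(M), tv(M), ts(M);
  LogicalVector alive(M), dying(M);
  for (int i = 0; i < M; i++) {
    Cell &C = s->cells[i];
    id[i] = i + 1;
    type[i] = C.type;
    pi[i] = C.pi; pj[i] = C.pj;
    vol[i] = (double)C.volume;
    surf[i] = (double)C.surface;
    if (C.volume > 0) {
      cx[i] = C.sx / C.volume; cy[i] = C.sy / C.volume; cz[i] = C.sz / C.volume;
    } else {
      cx[i] = NA_REAL; cy[i] = NA_REAL; cz[i] = NA_REAL;
    }
    birth[i] = (double)C.birth;
    ex[i] = C.ex; ey[i] = C.ey; ez[i] = C.ez;
    tv[i] = C.tv; ts[i] = C.ts;
    alive[i] = C.alive;
    dying[i] = C.dying;
  }
  DataFrame cells = DataFrame::create(
      _["cell_id"] = id, _["type"] = type, _["adh_index"] = pi,
      _["mot_index"] = pj, _["volume"] = vol, _["surface"] = surf,
      _["com_x"] = cx, _["com_y"] = cy, _["com_z"] = cz,
      _["birth_time"] = birth, _["dir_x"] = ex, _["dir_y"] = ey,
      _["dir_z"] = ez, _["target_volume"] = tv, _["target_surface"] = ts,
      _["alive"] = alive, _["dying"] = dying);
  return List::create(_["spins"] = sp, _["cells"] = cells,
                      _["time"] = (double)s->time);
}

// [[Rcpp::export]]
List cpp_sim_sweep(SEXP xp, int n) {
  Sim *s = get(xp);
  long long a0 = s->attempts, c0 = s->accepts, n0 = s->noops;
  for (int i = 0; i < n; i++) {
    s->sweep_once();
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["attempts"] = (double)(s->attempts - a0),
                      _["accepts"] = (double)(s->accepts - c0),
                      _["noops"] = (double)(s->noops - n0));
}

// [[Rcpp::export]]
int cpp_sim_run(SEXP xp, double n_mcs, int cadence, bool lifecycle_on) {
  Sim *s = get(xp);
  return s->run((long long)n_mcs, cadence, lifecycle_on);
}

// [[Rcpp::export]]
void cpp_sim_lifecycle(SEXP xp) { get(xp)->lifecycle_once(); }

// [[Rcpp::export]]
void cpp_sim_reassign_motility(SEXP xp) { get(xp)->reassign_motility(); }

// [[Rcpp::export]]
void cpp_sim_advance_time(SEXP xp, double dt) {
  get(xp)->time += (long long)dt;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_directions(SEXP xp, int n) {
  Sim *s = get(xp);
  NumericMatrix m(n, 3);
  for (int i = 0; i < n; i++) {
    double x, y, z;
    s->unit_vec(x, y, z);
    m(i, 0) = x; m(i, 1) = y; m(i, 2) = z;
  }
  return m;
}

static int candidate_check(Sim *s, long long k, int candidate) {
  int x, y, z;
  s->coords(k, x, y, z);
  if (s->spins[(size_t)k] == candidate) return 1;
  for (int o = 0; o < s->n_off; o++) {
    int t = s->spins[(size_t)s->sidx(s->wrap(x + s->OX[o]),
                                     s->wrap(y + s->OY[o]),
                                     s->wrap(z + s->OZ[o]))];
    if (t == candidate) return 1;
  }
  return 0;
}

// site: 1-based (x, y, z)
static long long site_index(Sim *s, IntegerVector site) {
  if (site.size() != 3) stop("site must be (x, y, z)");
  int x = site[0] - 1, y = site[1] - 1, z = site[2] - 1;
  if (x < 0 || x >= s->L || y < 0 || y >= s->L || z < 0 || z >= s->L)
    stop("site outside lattice");
  return s->sidx(x, y, z);
}

// [[Rcpp::export]]
double cpp_sim_delta_h(SEXP xp, IntegerVector site, int candidate) {
  Sim *s = get(xp);
  long long k = site_index(s, site);
  if (!candidate_check(s, k, candidate))
    stop("candidate id is not present in the site's neighborhood");
  return s->do_flip(k, candidate, false, false, nullptr);
}

// [[Rcpp::export]]
double cpp_sim_apply_flip(SEXP xp, IntegerVector site, int candidate) {
  Sim *s = get(xp);
  long long k = site_index(s, site);
  if (!candidate_check(s, k, candidate))
    stop("candidate id is not present in the site's neighborhood");
  return s->do_flip(k, candidate, true, false, nullptr);
}

// [[Rcpp::export]]
List cpp_sim_divide(SEXP xp, int cell_id) {
  Sim *s = get(xp);
  if (cell_id < 1 || cell_id > (int)s->cells.size()) stop("no such cell");
  Cell &C = s->cells[cell_id - 1];
  if (C.type != 1) stop("only cancer cells divide");
  bool ok = s->divide_cell(cell_id);
  if (!ok) return List::create(_["divided"] = false);
  return List::create(_["divided"] = true, _["parent_id"] = cell_id,
                      _["daughter_id"] = (int)s->cells.size());
}

// [[Rcpp::export]]
void cpp_sim_kill(SEXP xp, int cell_id) {
  Sim *s = get(xp);
  if (cell_id < 1 || cell_id > (int)s->cells.size()) stop("no such cell");
  Cell &C = s->cells[cell_id - 1];
  if (C.type != 1) stop("only cancer cells die");
  s->mark_dying(cell_id);
}

// [[Rcpp::export]]
double cpp_sim_cell_nutrient(SEXP xp, int cell_id) {
  Sim *s = get(xp);
  Cell &C = s->cells[cell_id - 1];
  if (!C.alive) stop("cell is not alive");
  return s->nutrient(C.sx / C.volume, C.sy / C.volume, C.sz / C.volume,
                     (double)s->time);
}

// [[Rcpp::export]]
void cpp_sim_set_phenotype(SEXP xp, int cell_id, int pi, int pj) {
  Sim *s = get(xp);
  Cell &C = s->cells[cell_id - 1];
  if (C.type != 1) stop("healthy cells carry no phenotype");
  if (pi < 0 || pi > 11 || pj < 0 || pj > 11) stop("phenotype index outside grid");
  C.pi = pi; C.pj = pj;
}

// [[Rcpp::export]]
void cpp_sim_set_birth(SEXP xp, int cell_id, double t) {
  Sim *s = get(xp);
  s->cells[cell_id - 1].birth = (long long)t;
}

// [[Rcpp::export]]
void cpp_sim_set_direction(SEXP xp, int cell_id, NumericVector e) {
  Sim *s = get(xp);
  double nrm = std::sqrt(sq(e[0]) + sq(e[1]) + sq(e[2]));
  if (nrm <= 0) stop("zero direction");
  Cell &C = s->cells[cell_id - 1];
  C.ex = e[0] / nrm; C.ey = e[1] / nrm; C.ez = e[2] / nrm;
}

// [[Rcpp::export]]
DataFrame cpp_sim_events(SEXP xp) {
  Sim *s = get(xp);
  int n = (int)s->ev_t.size();
  NumericVector t(n), x(n), y(n), z(n), r(n);
  IntegerVector kind(n), cell(n), pi(n), pj(n), mut(n);
  for (int i = 0; i < n; i++) {
    t[i] = s->ev_t[i]; kind[i] = s->ev_kind[i]; cell[i] = s->ev_cell[i];
    pi[i] = s->ev_pi[i]; pj[i] = s->ev_pj[i];
    x[i] = s->ev_x[i]; y[i] = s->ev_y[i]; z[i] = s->ev_z[i]; r[i] = s->ev_r[i];
    mut[i] = s->ev_mut[i];
  }
  return DataFrame::create(
      _["time_mcs"] = t, _["kind"] = kind, _["cell_id"] = cell,
      _["adh_index"] = pi, _["mot_index"] = pj, _["x"] = x, _["y"] = y,
      _["z"] = z, _["radius"] = r, _["mutated"] = mut);
}

// [[Rcpp::export]]
DataFrame cpp_sim_composition(SEXP xp) {
  Sim *s = get(xp);
  int n = (int)s->comp_t.size();
  NumericVector t(n);
  IntegerVector i(n), j(n), cnt(n);
  for (int k = 0; k < n; k++) {
    t[k] = s->comp_t[k]; i[k] = s->comp_i[k]; j[k] = s->comp_j[k];
    cnt[k] = s->comp_n[k];
  }
  return DataFrame::create(_["time_mcs"] = t, _["adh_index"] = i,
                           _["mot_index"] = j, _["count"] = cnt);
}

// [[Rcpp::export]]
void cpp_sim_record_composition(SEXP xp) { get(xp)->record_composition(); }

// Recompute volume, surface, and center of mass from the spin array (images
// taken nearest each cell's cached center of mass) and report the largest
// discrepancies against the incremental caches.
// [[Rcpp::export]]
List cpp_sim_check(SEXP xp) {
  Sim *s = get(xp);
  int M = (int)s->cells.size();
  std::vector<long long> vol(M, 0), surf(M, 0);
  std::vector<double> nsx(M, 0.0), nsy(M, 0.0), nsz(M, 0.0);
  for (long long k = 0; k < s->N; k++) {
    int id = s->spins[(size_t)k] - 1;
    int x, y, z;
    s->coords(k, x, y, z);
    vol[id]++;
    Cell &C = s->cells[id];
    double rx = C.volume > 0 ? C.sx / C.volume : x;
    double ry = C.volume > 0 ? C.sy / C.volume : y;
    double rz = C.volume > 0 ? C.sz / C.volume : z;
    nsx[id] += s->img(x, rx);
    nsy[id] += s->img(y, ry);
    nsz[id] += s->img(z, rz);
    for (int o = 0; o < s->n_off; o++) {
      int t = s->spins[(size_t)s->sidx(s->wrap(x + s->OX[o]),
                                       s->wrap(y + s->OY[o]),
                                       s->wrap(z + s->OZ[o]))];
      if (t != id + 1) surf[id]++;
    }
  }
  long long max_dv = 0, max_ds = 0, total = 0;
  double max_dc = 0.0;
  for (int i = 0; i < M; i++) {
    Cell &C = s->cells[i];
    total += vol[i];
    long long dv = std::llabs(vol[i] - C.volume);
    long long ds = std::llabs(surf[i] - C.surface);
    if (dv > max_dv) max_dv = dv;
    if (ds > max_ds) max_ds = ds;
    if (vol[i] > 0 && C.volume > 0) {
      double dcx = nsx[i] / vol[i] - C.sx / C.volume;
      double dcy = nsy[i] / vol[i] - C.sy / C.volume;
      double dcz = nsz[i] / vol[i] - C.sz / C.volume;
      double d = std::sqrt(sq(dcx) + sq(dcy) + sq(dcz));
      if (d > max_dc) max_dc = d;
    }
  }
  return List::create(_["max_volume_diff"] = (double)max_dv,
                      _["max_surface_diff"] = (double)max_ds,
                      _["max_com_diff"] = max_dc,
                      _["sum_volume"] = (double)total);
}

// Connected components (within the flip neighborhood) per alive cell, for
// auditing fragmentation: no connectivity constraint is enforced in the
// dynamics.
// [[Rcpp::export]]
DataFrame cpp_sim_fragments(SEXP xp) {
  Sim *s = get(xp);
  std::vector<char> seen((size_t)s->N, 0);
  int M = (int)s->cells.size();
  std::vector<int> comps(M, 0);
  std::vector<long long> stack;
  for (long long k = 0; k < s->N; k++) {
    if (seen[(size_t)k]) continue;
    int id = s->spins[(size_t)k];
    comps[id - 1]++;
    stack.clear();
    stack.push_back(k);
    seen[(size_t)k] = 1;
    while (!stack.empty()) {
      long long c = stack.back();
      stack.pop_back();
      int x, y, z;
      s->coords(c, x, y, z);
      for (int o = 0; o < s->n_off; o++) {
        long long nb = s->sidx(s->wrap(x + s->OX[o]), s->wrap(y + s->OY[o]),
                               s->wrap(z + s->OZ[o]));
        if (!seen[(size_t)nb] && s->spins[(size_t)nb] == id) {
          seen[(size_t)nb] = 1;
          stack.push_back(nb);
        }
      }
    }
  }
  std::vector<int> ids, nc;
  for (int i = 0; i < M; i++)
    if (s->cells[i].alive) { ids.push_back(i + 1); nc.push_back(comps[i]); }
  return DataFrame::create(_["cell_id"] = wrap(ids),
                           _["components"] = wrap(nc));
}
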