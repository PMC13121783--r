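// Fixed-step Monte Carlo core of the spindle simulator.
//
// Geometry: 1D axis in nm, poles fixed at +/- S/2.  Microtubules are rigid
// discrete lattices (site size d) anchored to their pole by a kappa3
// spring; kinetochore microtubules (kMTs) additionally couple to a sister
// kinetochore through a kappa2 linker, so an attached kMT acts as a spring
// keff = kappa2*kappa3/(kappa2+kappa3) anchored at pole + o*length.  The
// sister kinetochores are joined by the kappa1 linker (rest length x0).
// Springs equilibrate instantaneously relative to the 1-ms event clock;
// every event probability in a tick uses the start-of-tick configuration.
//
// Sub-step order within a tick: force solve -> overlap bookkeeping ->
// motor events (Eg5, KIF2A, NuMA) -> plus-end polymerization -> minus-end
// depolymerization -> kMT detachment/reattachment -> classification.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const int OCC_EMPTY = 0, OCC_EG5 = 1, OCC_KIF2A = 2, OCC_NUMA = 3;

struct MT {
  int role;           // 0 kMT, 1 bMT
  int pole;           // 0 left, 1 right
  double o;           // orientation: +1 left-pole, -1 right-pole
  int pair_id;        // bMT pair index, -1 for kMT
  int n;              // lattice sites
  // occupancy stored as flat arrays with a head offset: site s (counted
  // from the minus end) lives at index head + s; minus-end removal is a
  // head increment, plus-end growth a push_back
  std::vector<signed char> occ_type;
  std::vector<int> occ_id;
  int head;
  int attached;       // 0 none, 1 left sister, 2 right sister
  bool growable;
  bool ever_attached;
  long removed;       // cumulative minus-end removals
  long arrivals;      // KIF2A arrivals at the minus-end site (diagnostic)
};

struct K13 { int mt, site; double clock; bool active; };
struct EG5 { int mt1, site1, mt2, site2; bool active; };
struct NUMA { int mt1, site1, mt2, site2; bool active; };

struct Pars {
  int N; double h, d, S, poleL, poleR;
  double kappa1, kappa2, kappa3, keff, x0;      // x0 in nm here
  // detachment law (converted to 1/s)
  double k1, k2, F1, F2, A, b_per_nm; bool aurora;
  double katt0, alpha;
  double vp0, B, Fp0;
  bool detach_enabled, eg5_on, k13_on, numa_on;
  double wall;
  // eg5
  double e_kon, e_koff0, e_kF0, e_kB0, e_theta, e_mu, kBT;
  // kif2a
  double c13, kdiff, k13_koff, kdep, tau_end;
  // numa
  double n_kon, n_mu, n_koff;
  // pinned fixture mode
  bool pin; double pin_F, pin_x, pin_yL, pin_yR;
};

inline double kdetach_per_s(double F, const Pars& P) {
  if (F < 0) F = 0;
  double eF2 = std::exp(F / P.F2), eF1 = std::exp(-F / P.F1);
  return (P.k1 * eF2 * (1.0 - eF1) + P.k2 * eF2 * eF1);
}

inline double site_pos(const MT& m, double minus_pos, int s, double d) {
  return minus_pos + m.o * (s + 0.5) * d;
}

struct Core {
  Pars P;
  std::vector<MT> mts;
  std::vector<K13> k13s;
  std::vector<EG5> eg5s;
  std::vector<NUMA> numas;
  double xL, xR;
  // per-kMT force of the current tick
  std::vector<double> F;
  // overlap per pair
  std::vector<double> ov_lo, ov_hi; std::vector<bool> ov_empty;
  int n_kmt, n_mt;

  // event/transition logs
  std::vector<double> ev_t; std::vector<int> ev_mt, ev_type, ev_tgt;
  std::vector<double> tr_t; std::vector<int> tr_lab;
  int last_label;

  double mt_len(const MT& m) const { return m.n * P.d; }
  double pole_pos(const MT& m) const { return m.pole == 0 ? P.poleL : P.poleR; }
  double relaxed_plus(const MT& m) const { return pole_pos(m) + m.o * mt_len(m); }
  // minus position used for motor geometry: bMTs sit at their pole; kMT
  // motor geometry only needs site indices, so the pole anchor is fine too.
  double minus_base(const MT& m) const { return pole_pos(m); }

  void solve() {
    if (P.pin) {
      for (int i = 0; i < n_kmt; ++i)
        F[i] = (mts[i].attached != 0) ? P.pin_F : 0.0;
      return;
    }
    int nL = 0, nR = 0; double SL = 0, SR = 0;
    for (int i = 0; i < n_kmt; ++i) {
      if (mts[i].attached == 1) { nL++; SL += relaxed_plus(mts[i]); }
      else if (mts[i].attached == 2) { nR++; SR += relaxed_plus(mts[i]); }
    }
    if (nL + nR > 0) {
      double a11 = P.keff * nL + P.kappa1, a12 = -P.kappa1;
      double a21 = -P.kappa1, a22 = P.keff * nR + P.kappa1;
      double b1 = P.keff * SL - P.kappa1 * P.x0;
      double b2 = P.keff * SR + P.kappa1 * P.x0;
      double det = a11 * a22 - a12 * a21;
      xL = (b1 * a22 - a12 * b2) / det;
      xR = (a11 * b2 - b1 * a21) / det;
    }
    for (int i = 0; i < n_kmt; ++i) {
      if (mts[i].attached == 0) { F[i] = 0.0; continue; }
      double xa = (mts[i].attached == 1) ? xL : xR;
      F[i] = P.keff * mts[i].o * (xa - relaxed_plus(mts[i]));
    }
  }

  void update_overlaps() {
    for (int p = 0; p < P.N; ++p) {
      const MT& l = mts[2 * P.N + 2 * p];
      const MT& r = mts[2 * P.N + 2 * p + 1];
      double lo = std::max(P.poleL, P.poleR - r.n * P.d);
      double hi = std::min(P.poleL + l.n * P.d, P.poleR);
      ov_lo[p] = lo; ov_hi[p] = hi; ov_empty[p] = !(hi > lo);
    }
  }

  bool in_overlap(const MT& m, int s) const {
    if (m.pair_id < 0) return false;
    int p = m.pair_id;
    if (ov_empty[p]) return false;
    double pos = site_pos(m, minus_base(m), s, P.d);
    return pos > ov_lo[p] && pos < ov_hi[p];
  }

  // count of lattice sites of mt inside its pair's overlap, and mapping
  int overlap_site_count(const MT& m) const {
    if (m.pair_id < 0 || ov_empty[m.pair_id] || m.n == 0) return 0;
    double base = minus_base(m);
    // s in overlap iff lo < base + o*(s+.5)d < hi
    double a = (ov_lo[m.pair_id] - base) / (m.o * P.d) - 0.5;
    double b = (ov_hi[m.pair_id] - base) / (m.o * P.d) - 0.5;
    if (a > b) std::swap(a, b);
    int s0 = std::max(0, (int)std::ceil(a + 1e-12));
    int s1 = std::min(m.n - 1, (int)std::floor(b - 1e-12));
    return std::max(0, s1 - s0 + 1);
  }
  int overlap_site_at(const MT& m, int k) const { // k-th overlap site
    double base = minus_base(m);
    double a = (ov_lo[m.pair_id] - base) / (m.o * P.d) - 0.5;
    double b = (ov_hi[m.pair_id] - base) / (m.o * P.d) - 0.5;
    if (a > b) std::swap(a, b);
    int s0 = std::max(0, (int)std::ceil(a + 1e-12));
    return s0 + k;
  }

  void clear_site(int mt, int s) {
    MT& m = mts[mt];
    m.occ_type[m.head + s] = OCC_EMPTY; m.occ_id[m.head + s] = 0;
  }
  void set_site(int mt, int s, int type, int id) {
    MT& m = mts[mt];
    m.occ_type[m.head + s] = (signed char)type; m.occ_id[m.head + s] = id;
  }
  int occ_at(const MT& m, int s) const { return m.occ_type[m.head + s]; }
  bool free_site(const MT& m, int s) const {
    return s >= 0 && s < m.n && m.occ_type[m.head + s] == OCC_EMPTY;
  }

  void detach_k13(int id) {
    K13& k = k13s[id];
    if (!k.active) return;
    clear_site(k.mt, k.site);
    k.active = false;
  }
  void unbind_eg5_pair(EG5& e, int which) {
    if (which == 1 && e.site1 >= 0) { clear_site(e.mt1, e.site1); e.site1 = -1; }
    if (which == 2 && e.site2 >= 0) { clear_site(e.mt2, e.site2); e.site2 = -1; }
    if (e.site1 < 0 && e.site2 < 0) e.active = false;
  }
  void unbind_numa_dom(NUMA& nu, int which) {
    if (which == 1 && nu.site1 >= 0) { clear_site(nu.mt1, nu.site1); nu.site1 = -1; }
    if (which == 2 && nu.site2 >= 0) { clear_site(nu.mt2, nu.site2); nu.site2 = -1; }
    if (nu.site1 < 0 && nu.site2 < 0) nu.active = false;
  }

  // zone-restriction housekeeping after overlap boundaries move
  void enforce_zones() {
    for (size_t i = 0; i < k13s.size(); ++i) {
      K13& k = k13s[i];
      if (k.active && mts[k.mt].pair_id >= 0 && in_overlap(mts[k.mt], k.site))
        detach_k13((int)i);
    }
    for (size_t i = 0; i < eg5s.size(); ++i) {
      EG5& e = eg5s[i];
      if (!e.active) continue;
      if (e.site1 >= 0 && !in_overlap(mts[e.mt1], e.site1)) unbind_eg5_pair(e, 1);
      if (e.active && e.site2 >= 0 && !in_overlap(mts[e.mt2], e.site2))
        unbind_eg5_pair(e, 2);
    }
  }

  void eg5_events() {
    double pF = P.e_kF0 * P.h, pB = P.e_kB0 * P.h, poff = P.e_koff0 * P.h,
           pmu = P.e_mu * P.h;
    for (size_t i = 0; i < eg5s.size(); ++i) {
      EG5& e = eg5s[i];
      if (!e.active) continue;
      for (int pair = 1; pair <= 2; ++pair) {
        int* mtp = (pair == 1) ? &e.mt1 : &e.mt2;
        int* sp  = (pair == 1) ? &e.site1 : &e.site2;
        if (*sp < 0) {
          // detached pair: rebind onto the antiparallel partner lattice
          int omt = (pair == 1) ? e.mt2 : e.mt1;
          int osite = (pair == 1) ? e.site2 : e.site1;
          if (osite >= 0 && unif_rand() < pmu) {
            const MT& om = mts[omt];
            int tgt_mt = 2 * 2 * 0; // resolved below
            // partner = other MT of the same bMT pair
            int base = 2 * P.N + 2 * om.pair_id;
            tgt_mt = (omt == base) ? base + 1 : base;
            const MT& tm = mts[tgt_mt];
            double pos = site_pos(om, minus_base(om), osite, P.d);
            int s2 = (int)std::lround((pos - minus_base(tm)) / (tm.o * P.d) - 0.5);
            if (s2 >= 0 && s2 < tm.n && free_site(tm, s2) && in_overlap(tm, s2)) {
              *mtp = tgt_mt; *sp = s2; set_site(tgt_mt, s2, OCC_EG5, (int)i);
            }
          }
          continue;
        }
        MT& m = mts[*mtp];
        if (unif_rand() < poff) { unbind_eg5_pair(e, pair); continue; }
        // forward step: toward the plus end (site index increases)
        if (unif_rand() < pF) {
          int t = *sp + 1;
          if (t < m.n && occ_at(m, t) == OCC_EMPTY && in_overlap(m, t)) {
            clear_site(*mtp, *sp); *sp = t; set_site(*mtp, t, OCC_EG5, (int)i);
          }
        }
        if (unif_rand() < pB) {
          int t = *sp - 1;
          if (t >= 0 && occ_at(m, t) == OCC_EMPTY && in_overlap(m, t)) {
            clear_site(*mtp, *sp); *sp = t; set_site(*mtp, t, OCC_EG5, (int)i);
          }
        }
        if (!e.active) break;
      }
    }
    // binding from solution: one pair of heads onto a free overlap site
    for (int p = 0; p < P.N; ++p) {
      if (ov_empty[p]) continue;
      int ml = 2 * P.N + 2 * p, mr = ml + 1;
      int cl = overlap_site_count(mts[ml]), cr = overlap_site_count(mts[mr]);
      int ntot = cl + cr;
      if (ntot == 0) continue;
      if (unif_rand() < P.e_kon * ntot * P.h) {
        int k = (int)(unif_rand() * ntot); if (k >= ntot) k = ntot - 1;
        int mt = (k < cl) ? ml : mr;
        int s = (k < cl) ? overlap_site_at(mts[ml], k)
                         : overlap_site_at(mts[mr], k - cl);
        if (free_site(mts[mt], s)) {
          int id = -1;
          for (size_t i = 0; i < eg5s.size(); ++i)
            if (!eg5s[i].active) { id = (int)i; break; }
          if (id < 0) { eg5s.push_back(EG5()); id = (int)eg5s.size() - 1; }
          EG5& e = eg5s[id];
          e.mt1 = mt; e.site1 = s; e.mt2 = mt; e.site2 = -1; e.active = true;
          set_site(mt, s, OCC_EG5, id);
        }
      }
    }
  }

  void k13_events() {
    double pdf = P.kdiff * P.h, poff = P.k13_koff * P.h;
    for (size_t i = 0; i < k13s.size(); ++i) {
      K13& k = k13s[i];
      if (!k.active) continue;
      MT& m = mts[k.mt];
      if (k.site == 0) {
        // resident at the minus end: depolymerase engaged (pole-localised
        // machinery holds it), no diffusion; leaves by the residence-time
        // limit tau_end or by being bumped during depolymerization
        k.clock += P.h;
        if (k.clock >= P.tau_end) detach_k13((int)i);
        continue;
      } else k.clock = 0.0;
      // unbiased lattice diffusion with site exclusion, overlap forbidden,
      // plus unbinding: one deviate per motor per tick, the three events
      // mapped to disjoint probability intervals (each at its exact rate)
      double u = unif_rand();
      if (u < pdf) {
        int t = k.site + 1;
        if (t < m.n && occ_at(m, t) == OCC_EMPTY && !in_overlap(m, t)) {
          clear_site(k.mt, k.site); k.site = t; set_site(k.mt, t, OCC_KIF2A, (int)i);
        }
      } else if (u < 2.0 * pdf) {
        int t = k.site - 1;
        if (t >= 0 && occ_at(m, t) == OCC_EMPTY && !in_overlap(m, t)) {
          clear_site(k.mt, k.site); k.site = t; set_site(k.mt, t, OCC_KIF2A, (int)i);
          if (t == 0) m.arrivals++;
        }
      } else if (u > 1.0 - poff) detach_k13((int)i);
    }
    // binding from solution: per-site rate c13 aggregated per lattice
    for (int j = 0; j < n_mt; ++j) {
      MT& m = mts[j];
      if (m.n == 0) continue;
      if (unif_rand() < P.c13 * m.n * P.h) {
        int s = (int)(unif_rand() * m.n); if (s >= m.n) s = m.n - 1;
        if (occ_at(m, s) == OCC_EMPTY && !in_overlap(m, s)) {
          int id = -1;
          for (size_t i = 0; i < k13s.size(); ++i)
            if (!k13s[i].active) { id = (int)i; break; }
          if (id < 0) { k13s.push_back(K13()); id = (int)k13s.size() - 1; }
          K13& k = k13s[id];
          k.mt = j; k.site = s; k.clock = 0.0; k.active = true;
          set_site(j, s, OCC_KIF2A, id);
          if (s == 0) m.arrivals++;
        }
      }
    }
  }

  void numa_events() {
    double poff = P.n_koff * P.h, pmu = P.n_mu * P.h;
    for (size_t i = 0; i < numas.size(); ++i) {
      NUMA& nu = numas[i];
      if (!nu.active) continue;
      if (nu.site1 >= 0 && unif_rand() < poff) unbind_numa_dom(nu, 1);
      if (nu.active && nu.site2 >= 0 && unif_rand() < poff) unbind_numa_dom(nu, 2);
      if (!nu.active) continue;
      // free second domain binds the parallel (same-pole) bridging MT
      if (nu.site2 < 0 && nu.site1 >= 0 && unif_rand() < pmu) {
        const MT& m1 = mts[nu.mt1];
        // partner: next same-pole bMT (cyclic over pairs)
        int p2 = (m1.pair_id + 1) % P.N;
        int tgt = 2 * P.N + 2 * p2 + (m1.pole == 0 ? 0 : 1);
        if (tgt != nu.mt1) {
          const MT& tm = mts[tgt];
          double pos = site_pos(m1, minus_base(m1), nu.site1, P.d);
          int s2 = (int)std::lround((pos - minus_base(tm)) / (tm.o * P.d) - 0.5);
          if (s2 >= 0 && s2 < tm.n && free_site(tm, s2) && !in_overlap(tm, s2)) {
            nu.mt2 = tgt; nu.site2 = s2; set_site(tgt, s2, OCC_NUMA, (int)i);
          }
        }
      }
    }
    // first-domain binding from solution (non-overlap bMT sites)
    for (int p = 0; p < P.N; ++p) {
      for (int side = 0; side < 2; ++side) {
        int j = 2 * P.N + 2 * p + side;
        MT& m = mts[j];
        if (m.n == 0) continue;
        if (unif_rand() < P.n_kon * m.n * P.h) {
          int s = (int)(unif_rand() * m.n); if (s >= m.n) s = m.n - 1;
          if (occ_at(m, s) == OCC_EMPTY && !in_overlap(m, s)) {
            int id = -1;
            for (size_t i = 0; i < numas.size(); ++i)
              if (!numas[i].active) { id = (int)i; break; }
            if (id < 0) { numas.push_back(NUMA()); id = (int)numas.size() - 1; }
            NUMA& nu = numas[id];
            nu.mt1 = j; nu.site1 = s; nu.mt2 = j; nu.site2 = -1; nu.active = true;
            set_site(j, s, OCC_NUMA, id);
          }
        }
      }
    }
  }

  void polymerize() {
    for (int j = 0; j < n_mt; ++j) {
      MT& m = mts[j];
      double rate;
      if (m.role == 0) {
        if (!m.growable) continue;
        if (m.attached != 0) {
          // signed force: pulling accelerates growth, pushing slows it,
          // stalling at F = -F_p0 (speed floored at zero)
          rate = P.vp0 / P.B * (1.0 + F[j] / P.Fp0);
          if (rate < 0) rate = 0;
        } else rate = P.vp0;
      } else rate = P.vp0;
      // plus ends pause at a small margin from the opposite pole
      double opp = (m.pole == 0) ? P.poleR : P.poleL;
      double plus = relaxed_plus(m);
      if (std::fabs(opp - plus) <= P.wall) continue;
      if (rate <= 0) continue;
      if (unif_rand() < rate / P.d * P.h) {
        m.n += 1;
        m.occ_type.push_back(OCC_EMPTY); m.occ_id.push_back(0);
        // invariant: occ arrays always span exactly head + n entries
      }
    }
  }

  void depolymerize() {
    double pdep = P.kdep * P.h;
    for (int j = 0; j < n_mt; ++j) {
      MT& m = mts[j];
      if (m.n == 0 || m.occ_type[m.head] != OCC_KIF2A) continue;
      if (unif_rand() >= pdep) continue;
      int resident = m.occ_id[m.head];
      bool second_occupied = (m.n > 1 && m.occ_type[m.head + 1] != OCC_EMPTY);
      m.occ_type[m.head] = OCC_EMPTY; m.occ_id[m.head] = 0;
      m.head += 1;
      m.n -= 1; m.removed += 1;
      // shift site indices of every motor on this lattice
      for (size_t i = 0; i < k13s.size(); ++i)
        if (k13s[i].active && k13s[i].mt == j && k13s[i].site > 0) k13s[i].site--;
      for (size_t i = 0; i < eg5s.size(); ++i) {
        if (!eg5s[i].active) continue;
        if (eg5s[i].site1 >= 0 && eg5s[i].mt1 == j) eg5s[i].site1--;
        if (eg5s[i].site2 >= 0 && eg5s[i].mt2 == j) eg5s[i].site2--;
      }
      for (size_t i = 0; i < numas.size(); ++i) {
        if (!numas[i].active) continue;
        if (numas[i].site1 >= 0 && numas[i].mt1 == j) numas[i].site1--;
        if (numas[i].site2 >= 0 && numas[i].mt2 == j) numas[i].site2--;
      }
      if (second_occupied || m.n == 0) {
        // bumped off by the trailing occupant (or the lattice is gone)
        k13s[resident].active = false;
      } else {
        // backward step onto the new first tubulin, still resident
        set_site(j, 0, OCC_KIF2A, resident);
        k13s[resident].site = 0;
      }
    }
  }

  void attach_detach(double tnow) {
    if (!P.detach_enabled) return;
    double x_nm = P.pin ? P.pin_x : (xR - xL);
    // Aurora modulation saturates at the zero-tension level: stretch below
    // the rest separation is clamped, keeping X_detach within [1, 1+A]
    double dx = x_nm - P.x0; if (dx < 0) dx = 0;
    double Xd = 1.0;
    if (P.aurora) Xd = 1.0 + P.A * std::exp(-P.b_per_nm * dx);
    for (int i = 0; i < n_kmt; ++i) {
      MT& m = mts[i];
      if (m.attached != 0) {
        double rate = kdetach_per_s(F[i], P) * Xd;
        double p = rate * P.h; if (p > 1.0) p = 1.0;
        if (unif_rand() < p) {
          int from = m.attached;
          m.attached = 0;
          ev_t.push_back(tnow); ev_mt.push_back(i + 1);
          ev_type.push_back(0); ev_tgt.push_back(from);
        }
      } else {
        double yL, yR;
        if (P.pin) { yL = P.pin_yL; yR = P.pin_yR; }
        else {
          double plus = relaxed_plus(m);
          yL = std::fabs(xL - plus); yR = std::fabs(xR - plus);
        }
        double pL = P.katt0 * std::exp(-P.alpha * P.kappa2 * yL) * P.h;
        double pR = P.katt0 * std::exp(-P.alpha * P.kappa2 * yR) * P.h;
        if (pL > 1.0) pL = 1.0;
        if (pR > 1.0) pR = 1.0;
        bool fL = unif_rand() < pL, fR = unif_rand() < pR;
        int tgt = 0;
        if (fL && fR) {
          if (yL < yR) tgt = 1; else if (yR < yL) tgt = 2;
          else tgt = (unif_rand() < 0.5) ? 1 : 2;
        } else if (fL) tgt = 1; else if (fR) tgt = 2;
        if (tgt != 0) {
          m.attached = tgt; m.ever_attached = true;
          ev_t.push_back(tnow); ev_mt.push_back(i + 1);
          ev_type.push_back(1); ev_tgt.push_back(tgt);
        }
      }
    }
  }

  int classify() const {
    int considered = 0, incorrect = 0;
    bool det = false, sL = false, sR = false, pL = false, pR = false;
    for (int i = 0; i < n_kmt; ++i) {
      const MT& m = mts[i];
      if (!m.ever_attached) continue;
      considered++;
      if (m.attached == 0) { det = true; continue; }
      if (m.attached == 1) sL = true; else sR = true;
      if (m.pole == 0) pL = true; else pR = true;
      bool bad = (m.pole == 0 && m.attached == 2) ||
                 (m.pole == 1 && m.attached == 1);
      if (bad) incorrect++;
    }
    if (considered == 0) return 12;      // nothing engaged yet
    if (det) return -1;                  // transient detachment
    bool one_pole = !(pL && pR);
    if ((sL != sR) && one_pole) return 11;   // monotelic
    if (sL && sR && one_pole) return 10;     // syntelic
    if (incorrect == 0) return 0;            // bi-oriented
    return incorrect;                        // merotelic type-k
  }
};

Pars read_pars(List rp) {
  Pars P;
  P.N = as<int>(rp["N"]); P.h = as<double>(rp["h"]);
  P.d = as<double>(rp["d_nm"]);
  P.S = as<double>(rp["spindle_length_um"]) * 1000.0;
  P.poleL = -P.S / 2; P.poleR = P.S / 2;
  P.kappa1 = as<double>(rp["kappa1"]); P.kappa2 = as<double>(rp["kappa2"]);
  P.kappa3 = as<double>(rp["kappa3"]);
  P.keff = P.kappa2 * P.kappa3 / (P.kappa2 + P.kappa3);
  P.x0 = as<double>(rp["x0_um"]) * 1000.0;
  List dl = rp["detach"];
  P.k1 = as<double>(dl["k1"]) / 60.0; P.k2 = as<double>(dl["k2"]) / 60.0;
  P.F1 = as<double>(dl["F1"]); P.F2 = as<double>(dl["F2"]);
  P.A = as<double>(dl["A"]); P.b_per_nm = as<double>(dl["b"]) / 1000.0;
  P.aurora = as<bool>(dl["aurora_active"]);
  List al = rp["attach"];
  P.katt0 = as<double>(al["k_attach0"]); P.alpha = as<double>(al["alpha"]);
  List pl = rp["poly"];
  P.vp0 = as<double>(pl["v_p0"]); P.B = as<double>(pl["B"]);
  P.Fp0 = as<double>(pl["F_p0"]);
  P.detach_enabled = as<bool>(rp["detach_enabled"]);
  P.eg5_on = as<bool>(rp["eg5_enabled"]);
  P.k13_on = as<bool>(rp["kif2a_enabled"]);
  P.numa_on = as<bool>(rp["numa_enabled"]);
  P.wall = as<double>(rp["bmt_wall_nm"]);
  List e5 = rp["eg5"];
  P.e_kon = as<double>(e5["kon_per_uM_s"]) * as<double>(e5["conc_uM"]);
  P.e_koff0 = as<double>(e5["koff0"]); P.e_kF0 = as<double>(e5["kF0"]);
  P.e_kB0 = as<double>(e5["kB0"]); P.e_theta = as<double>(e5["theta"]);
  P.e_mu = as<double>(e5["mu"]); P.kBT = as<double>(e5["kBT_pNnm"]);
  List k13 = rp["kif2a"];
  P.c13 = as<double>(k13["kon_per_uM_s"]) * as<double>(k13["conc_uM"]);
  P.kdiff = as<double>(k13["kdiff"]); P.k13_koff = as<double>(k13["koff"]);
  P.kdep = as<double>(k13["kdep"]); P.tau_end = as<double>(k13["tau_end_s"]);
  List nm = rp["numa"];
  P.n_kon = as<double>(nm["kon_per_uM_s"]) * as<double>(nm["conc_uM"]);
  P.n_mu = as<double>(nm["mu"]); P.n_koff = as<double>(nm["koff"]);
  P.pin = as<bool>(rp["pin"]);
  P.pin_F = as<double>(rp["pin_F"]); P.pin_x = as<double>(rp["pin_x_nm"]);
  P.pin_yL = as<double>(rp["pin_yL"]); P.pin_yR = as<double>(rp["pin_yR"]);
  return P;
}

} // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(List rp, List init, double duration_s, double sample_every_s) {
  Core C;
  C.P = read_pars(rp);
  const Pars& P = C.P;
  IntegerVector role = init["role"], pole = init["pole"], n0 = init["n_sites"],
                att0 = init["attached"];
  LogicalVector grow = init["growable"], ever = init["ever_attached"];
  int n_mt = role.size();
  C.n_mt = n_mt; C.n_kmt = 2 * P.N;
  C.mts.resize(n_mt);
  int bmt_seen = 0;
  for (int j = 0; j < n_mt; ++j) {
    MT& m = C.mts[j];
    m.role = role[j]; m.pole = pole[j];
    m.o = (m.pole == 0) ? 1.0 : -1.0;
    m.pair_id = (m.role == 1) ? (bmt_seen++ / 2) : -1;
    m.n = n0[j];
    m.head = 0;
    m.occ_type.assign(m.n, (signed char)OCC_EMPTY);
    m.occ_id.assign(m.n, 0);
    m.occ_type.reserve(m.n + 60000); m.occ_id.reserve(m.n + 60000);
    m.attached = att0[j];
    m.growable = grow[j]; m.ever_attached = ever[j];
    m.removed = 0; m.arrivals = 0;
  }
  C.xL = as<double>(init["xL"]); C.xR = as<double>(init["xR"]);
  C.F.assign(C.n_kmt, 0.0);
  C.ov_lo.assign(P.N, 0.0); C.ov_hi.assign(P.N, 0.0);
  C.ov_empty.assign(P.N, true);

  // The initial condition is a working, fluxing spindle: each lattice
  // starts with a depolymerase resident at its minus end plus a small
  // standing population in transit, so minus-end removal is active from
  // the first tick (an empty motor field would let every microtubule
  // overgrow during the population build-up and collapse the
  // interkinetochore tension).
  C.update_overlaps();
  if (P.k13_on) {
    for (int j = 0; j < C.n_mt; ++j) {
      MT& m = C.mts[j];
      if (m.n == 0) continue;
      K13 k0; k0.mt = j; k0.site = 0; k0.clock = 0.0; k0.active = true;
      C.k13s.push_back(k0);
      C.set_site(j, 0, OCC_KIF2A, (int)C.k13s.size() - 1);
      for (int w = 0; w < 2; ++w) {
        int s = 1 + (int)(unif_rand() * (m.n - 1));
        if (s < m.n && m.occ_type[s] == OCC_EMPTY && !C.in_overlap(m, s)) {
          K13 kw; kw.mt = j; kw.site = s; kw.clock = 0.0; kw.active = true;
          C.k13s.push_back(kw);
          C.set_site(j, s, OCC_KIF2A, (int)C.k13s.size() - 1);
        }
      }
    }
  }

  long n_ticks = (long)std::llround(duration_s / P.h);
  long sample_ticks = std::max(1L, (long)std::llround(sample_every_s / P.h));
  int n_samp = (int)(n_ticks / sample_ticks) + 1;
  int n_kmt = C.n_kmt;
  int ncol = 3 + n_kmt + n_mt + n_kmt + 1 + n_mt;
  NumericMatrix traj(n_samp, ncol);

  C.solve(); C.update_overlaps();
  C.last_label = C.classify();
  C.tr_t.push_back(0.0); C.tr_lab.push_back(C.last_label);

  int row = 0;
  auto record = [&](double t) {
    int c = 0;
    traj(row, c++) = t; traj(row, c++) = C.xL; traj(row, c++) = C.xR;
    for (int i = 0; i < n_kmt; ++i) traj(row, c++) = C.F[i];
    for (int j = 0; j < n_mt; ++j) traj(row, c++) = C.mts[j].n * P.d;
    for (int i = 0; i < n_kmt; ++i) traj(row, c++) = C.mts[i].attached;
    traj(row, c++) = C.last_label;
    for (int j = 0; j < n_mt; ++j) traj(row, c++) = (double)C.mts[j].removed;
    row++;
  };
  record(0.0);

  for (long tick = 0; tick < n_ticks; ++tick) {
    double tnow = (tick + 1) * P.h;
    C.solve();
    C.update_overlaps();
    C.enforce_zones();
    if (P.eg5_on) C.eg5_events();
    if (P.k13_on) C.k13_events();
    if (P.numa_on) C.numa_events();
    C.polymerize();
    if (P.k13_on) C.depolymerize();
    C.attach_detach(tnow);
    int lab = C.classify();
    if (lab != C.last_label) {
      C.tr_t.push_back(tnow); C.tr_lab.push_back(lab);
      C.last_label = lab;
    }
    if ((tick + 1) % sample_ticks == 0 && row < n_samp) record(tnow);
    if (tick % 200000 == 0) Rcpp::checkUserInterrupt();
  }

  // final state + diagnostics
  IntegerVector fin_n(n_mt), fin_att(n_kmt);
  NumericVector removed(n_mt), arrivals(n_mt);
  for (int j = 0; j < n_mt; ++j) {
    fin_n[j] = C.mts[j].n;
    removed[j] = (double)C.mts[j].removed;
    arrivals[j] = (double)C.mts[j].arrivals;
  }
  for (int i = 0; i < n_kmt; ++i) fin_att[i] = C.mts[i].attached;
  int n_k13 = 0, n_e5 = 0, n_nu = 0;
  for (size_t i = 0; i < C.k13s.size(); ++i) if (C.k13s[i].active) n_k13++;
  for (size_t i = 0; i < C.eg5s.size(); ++i) if (C.eg5s[i].active) n_e5++;
  for (size_t i = 0; i < C.numas.size(); ++i) if (C.numas[i].active) n_nu++;

  return List::create(
    _["traj"] = traj,
    _["trans_t"] = wrap(C.tr_t), _["trans_label"] = wrap(C.tr_lab),
    _["ev_t"] = wrap(C.ev_t), _["ev_mt"] = wrap(C.ev_mt),
    _["ev_type"] = wrap(C.ev_type), _["ev_target"] = wrap(C.ev_tgt),
    _["final_n_sites"] = fin_n, _["final_attached"] = fin_att,
    _["final_xL"] = C.xL, _["final_xR"] = C.xR,
    _["removed"] = removed, _["arrivals"] = arrivals,
    _["motors_bound"] = IntegerVector::create(
      _["kif2a"] = n_k13, _["eg5"] = n_e5, _["numa"] = n_nu));
}
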