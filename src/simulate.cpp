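// Event-driven kinetic Monte Carlo core for facilitated diffusion on a
// 1D DNA lattice with volume exclusion.
//
// Bound molecules are kept in a position-ordered doubly linked list (they
// cannot pass each other), their next event times in a binary min-heap.
// Association from the free pool is a single exponential channel whose
// propensity is k_assoc * n_free * (free start positions / total start
// positions); the number of free start positions per species is maintained
// incrementally from the gap structure of the lattice. Because slide events
// only ever reschedule the molecule at the heap root, the heap needs no
// decrease-key: events are replace-root (slide), pop (unbind) or push
// (bind). Waiting times are exponential with mean tau0*exp(E) for cognate
// species (E looked up per footprint position and strand) and tau0 for
// non-cognate crowders; the association channel is rescaled exactly (next
// reaction method) when its propensity changes, and redrawn after every
// binding or unbinding.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// xoshiro256++ (Blackman & Vigna), seeded through splitmix64
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      s[i] = splitmix64(x);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double u01() {  // [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  inline double expdraw(double mean) { return -mean * std::log(1.0 - u01()); }
  inline int bit() { return (int)(next() & 1ULL); }
};

struct SpeciesPar {
  int copies, w;
  double k_assoc, p_unbind, tau0;
  bool cognate;
  const double *dwell_fwd, *dwell_rev;  // footprint-position indexed
  long long Atot;                       // M - w + 1
};

static inline long long contrib(long long g, int w) {
  return g >= w ? g - w + 1 : 0;
}

// [[Rcpp::export]]
List fd_simulate_cpp(int M, List species, double duration,
                     int target_fpos,  // 0-based footprint-start or -1
                     double seed_hi, double seed_lo, bool record_occupancy,
                     int max_visit_records, bool check_invariants) {
  const int ns = species.size();
  std::vector<SpeciesPar> sp(ns);
  std::vector<NumericVector> keep_dwell(2 * ns);  // protect from gc
  int ntot = 0;
  for (int s = 0; s < ns; ++s) {
    List li = species[s];
    sp[s].copies = as<int>(li["copies"]);
    sp[s].w = as<int>(li["footprint"]);
    sp[s].k_assoc = as<double>(li["k_assoc"]);
    sp[s].p_unbind = as<double>(li["p_unbind"]);
    sp[s].tau0 = as<double>(li["tau0"]);
    sp[s].cognate = as<bool>(li["cognate"]);
    sp[s].Atot = (long long)M - sp[s].w + 1;
    if (sp[s].Atot < 1) stop("footprint larger than sequence");
    if (sp[s].cognate) {
      keep_dwell[2 * s] = as<NumericVector>(li["dwell_fwd"]);
      keep_dwell[2 * s + 1] = as<NumericVector>(li["dwell_rev"]);
      if ((long long)keep_dwell[2 * s].size() != sp[s].Atot ||
          (long long)keep_dwell[2 * s + 1].size() != sp[s].Atot)
        stop("dwell arrays must have length M - footprint + 1");
      sp[s].dwell_fwd = REAL(keep_dwell[2 * s]);
      sp[s].dwell_rev = REAL(keep_dwell[2 * s + 1]);
    } else {
      sp[s].dwell_fwd = sp[s].dwell_rev = nullptr;
    }
    ntot += sp[s].copies;
  }

  uint64_t sd = ((uint64_t)(int64_t)seed_hi << 32) ^ (uint64_t)(int64_t)seed_lo;
  Rng rng(sd);

  // molecule state (structure of arrays)
  std::vector<int> msp(ntot), mpos(ntot), mstrand(ntot), mprev(ntot),
      mnext(ntot), mbindpos(ntot);
  std::vector<double> mlast(ntot), mbindt(ntot);
  std::vector<long long> msteps(ntot);
  std::vector<char> mbound(ntot, 0);
  std::vector<std::vector<int>> free_stack(ns);
  {
    int id = 0;
    for (int s = 0; s < ns; ++s)
      for (int c = 0; c < sp[s].copies; ++c) {
        msp[id] = s;
        free_stack[s].push_back(id);
        ++id;
      }
  }

  std::vector<int> nfree(ns), nbound(ns, 0);
  for (int s = 0; s < ns; ++s) nfree[s] = sp[s].copies;
  std::vector<long long> Afree(ns);
  for (int s = 0; s < ns; ++s) Afree[s] = sp[s].Atot;  // empty lattice

  int head = -1;  // leftmost bound molecule

  // heap over bound molecules; +inf sentinels past nh let the 4-ary sift
  // scan a full block of children without bounds checks
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> htime((size_t)ntot + 4, INF);
  std::vector<int> hmol((size_t)ntot + 4, -1);
  int nh = 0;
  // 4-ary min-heap: shallower than binary, fewer mispredicted branches
  auto sift_up = [&](int i) {
    double t = htime[i];
    int m = hmol[i];
    while (i > 0) {
      int p = (i - 1) >> 2;
      if (htime[p] <= t) break;
      htime[i] = htime[p];
      hmol[i] = hmol[p];
      i = p;
    }
    htime[i] = t;
    hmol[i] = m;
  };
  auto sift_down = [&](int i) {
    double t = htime[i];
    int m = hmol[i];
    for (;;) {
      int c0 = 4 * i + 1;
      if (c0 >= nh) break;
      int c = c0;
      double tc = htime[c0];
      if (htime[c0 + 1] < tc) { tc = htime[c0 + 1]; c = c0 + 1; }
      if (htime[c0 + 2] < tc) { tc = htime[c0 + 2]; c = c0 + 2; }
      if (htime[c0 + 3] < tc) { tc = htime[c0 + 3]; c = c0 + 3; }
      if (tc >= t) break;
      htime[i] = htime[c];
      hmol[i] = hmol[c];
      i = c;
    }
    htime[i] = t;
    hmol[i] = m;
  };

  // gap-structure update over all species
  auto gap_delta = [&](long long g_old, long long g_new) -> bool {
    bool changed = false;
    for (int s = 0; s < ns; ++s) {
      long long d = contrib(g_new, sp[s].w) - contrib(g_old, sp[s].w);
      if (d != 0) {
        Afree[s] += d;
        changed = true;
      }
    }
    return changed;
  };

  auto compute_R = [&]() -> double {
    double R = 0.0;
    for (int s = 0; s < ns; ++s)
      if (nfree[s] > 0 && sp[s].k_assoc > 0 && Afree[s] > 0)
        R += sp[s].k_assoc * (double)nfree[s] * (double)Afree[s] /
             (double)sp[s].Atot;
    return R;
  };

  double t_assoc = INF, R_cur = compute_R();
  double t = 0.0, t_global = 0.0;
  if (R_cur > 0) t_assoc = rng.expdraw(1.0 / R_cur);

  auto redraw_assoc = [&](double now) {
    R_cur = compute_R();
    t_assoc = (R_cur > 0) ? now + rng.expdraw(1.0 / R_cur) : INF;
  };
  auto rescale_assoc = [&](double now) {
    double Rnew = compute_R();
    if (Rnew == R_cur) return;
    if (Rnew <= 0) {
      t_assoc = INF;
    } else if (R_cur <= 0 || !(t_assoc < INF)) {
      t_assoc = now + rng.expdraw(1.0 / Rnew);
    } else {
      t_assoc = now + (R_cur / Rnew) * (t_assoc - now);
    }
    R_cur = Rnew;
  };

  // observables
  std::vector<double> bound_time(ns, 0.0), sum_dwell(ns, 0.0);
  std::vector<double> sum_steps(ns, 0.0), n_visits(ns, 0.0);
  std::vector<std::vector<double>> occ(ns);
  if (record_occupancy)
    for (int s = 0; s < ns; ++s) occ[s].assign((size_t)sp[s].Atot, 0.0);
  NumericMatrix visits(max_visit_records > 0 ? max_visit_records : 0, 5);
  int n_visit_rec = 0;
  double fpt = -1.0, target_time = 0.0, t_occ_start = 0.0;
  bool target_occupied = false;
  double n_events = 0.0;
  long long violations = 0;

  auto target_enter = [&](double now) {
    if (!target_occupied) {
      target_occupied = true;
      t_occ_start = now;
      if (fpt < 0) fpt = now;
    }
  };
  auto target_leave = [&](double now) {
    if (target_occupied) {
      target_occupied = false;
      target_time += now - t_occ_start;
    }
  };

  auto dwell_mean = [&](int s, int pos, int strand) -> double {
    if (!sp[s].cognate) return sp[s].tau0;
    return strand ? sp[s].dwell_rev[pos] : sp[s].dwell_fwd[pos];
  };

  auto advance_global = [&](double now) {
    double dtg = now - t_global;
    for (int s = 0; s < ns; ++s) bound_time[s] += nbound[s] * dtg;
    t_global = now;
  };

  while (true) {
    double t_ev = nh > 0 ? htime[0] : INF;
    bool is_assoc = t_assoc < t_ev;
    double tn = is_assoc ? t_assoc : t_ev;
    if (!(tn <= duration)) break;
    advance_global(tn);
    t = tn;
    n_events += 1.0;

    if (is_assoc) {
      // ---- association event ----
      double r = rng.u01() * R_cur;
      int s = -1;
      for (int k = 0; k < ns; ++k) {
        if (nfree[k] > 0 && sp[k].k_assoc > 0 && Afree[k] > 0) {
          r -= sp[k].k_assoc * (double)nfree[k] * (double)Afree[k] /
               (double)sp[k].Atot;
          s = k;
          if (r <= 0) break;
        }
      }
      if (s < 0) {  // numerical edge: propensity stale
        redraw_assoc(t);
        continue;
      }
      const int w = sp[s].w;
      long long idx = (long long)(rng.u01() * (double)Afree[s]);
      if (idx >= Afree[s]) idx = Afree[s] - 1;
      // walk gaps to find the idx-th free start position for footprint w
      int prev_ins = -1, next_ins = head;
      long long base = 0, g, landing = -1;
      int cur = head;
      g = (cur >= 0 ? (long long)mpos[cur] : (long long)M) - base;
      long long c = contrib(g, w);
      if (idx < c) {
        landing = base + idx;
      } else {
        idx -= c;
        while (cur >= 0) {
          prev_ins = cur;
          base = (long long)mpos[cur] + sp[msp[cur]].w;
          int nxt = mnext[cur];
          g = (nxt >= 0 ? (long long)mpos[nxt] : (long long)M) - base;
          c = contrib(g, w);
          if (idx < c) {
            landing = base + idx;
            next_ins = nxt;
            break;
          }
          idx -= c;
          cur = nxt;
        }
      }
      if (landing < 0) {  // should not happen; counters drifted
        ++violations;
        redraw_assoc(t);
        continue;
      }
      // split the gap [base0, base0+g0) at the landing footprint
      long long base0 =
          prev_ins >= 0 ? (long long)mpos[prev_ins] + sp[msp[prev_ins]].w : 0;
      long long end0 = next_ins >= 0 ? (long long)mpos[next_ins] : (long long)M;
      long long g0 = end0 - base0;
      long long g1 = landing - base0, g2 = g0 - w - g1;
      for (int k = 0; k < ns; ++k)
        Afree[k] += contrib(g1, sp[k].w) + contrib(g2, sp[k].w) -
                    contrib(g0, sp[k].w);
      int m = free_stack[s].back();
      free_stack[s].pop_back();
      mpos[m] = (int)landing;
      mstrand[m] = rng.bit();
      mlast[m] = t;
      mbindt[m] = t;
      msteps[m] = 0;
      mbindpos[m] = (int)landing;
      mprev[m] = prev_ins;
      mnext[m] = next_ins;
      if (prev_ins >= 0)
        mnext[prev_ins] = m;
      else
        head = m;
      if (next_ins >= 0) mprev[next_ins] = m;
      mbound[m] = 1;
      --nfree[s];
      ++nbound[s];
      htime[nh] = t + rng.expdraw(dwell_mean(s, (int)landing, mstrand[m]));
      hmol[nh] = m;
      ++nh;
      sift_up(nh - 1);
      if (sp[s].cognate && (int)landing == target_fpos) target_enter(t);
      redraw_assoc(t);
    } else {
      // ---- bound-molecule event (slide attempt or unbind) ----
      int m = hmol[0];
      int s = msp[m];
      const int w = sp[s].w;
      double dt = t - mlast[m];
      if (record_occupancy) occ[s][(size_t)mpos[m]] += dt;
      msteps[m] += 1;
      double u = rng.u01();
      if (u < sp[s].p_unbind) {
        // unbind: close visit, merge gaps, pop heap
        n_visits[s] += 1.0;
        sum_steps[s] += (double)msteps[m];
        sum_dwell[s] += t - mbindt[m];
        if (n_visit_rec < max_visit_records) {
          visits(n_visit_rec, 0) = s + 1;
          visits(n_visit_rec, 1) = mbindpos[m] + 1;
          visits(n_visit_rec, 2) = mpos[m] + 1;
          visits(n_visit_rec, 3) = (double)msteps[m];
          visits(n_visit_rec, 4) = t - mbindt[m];
          ++n_visit_rec;
        }
        if (sp[s].cognate && mpos[m] == target_fpos) target_leave(t);
        int p = mprev[m], n = mnext[m];
        long long gl = (long long)mpos[m] -
                       (p >= 0 ? (long long)mpos[p] + sp[msp[p]].w : 0);
        long long gr = (n >= 0 ? (long long)mpos[n] : (long long)M) -
                       ((long long)mpos[m] + w);
        long long merged = gl + w + gr;
        for (int k = 0; k < ns; ++k)
          Afree[k] += contrib(merged, sp[k].w) - contrib(gl, sp[k].w) -
                      contrib(gr, sp[k].w);
        if (p >= 0)
          mnext[p] = n;
        else
          head = n;
        if (n >= 0) mprev[n] = p;
        mbound[m] = 0;
        free_stack[s].push_back(m);
        ++nfree[s];
        --nbound[s];
        --nh;
        if (nh > 0) {
          htime[0] = htime[nh];
          hmol[0] = hmol[nh];
          htime[nh] = INF;
          sift_down(0);
        } else {
          htime[0] = INF;
        }
        redraw_assoc(t);
      } else {
        // slide attempt; blocked moves are rejected (time still advanced)
        bool goleft = u < sp[s].p_unbind + 0.5 * (1.0 - sp[s].p_unbind);
        int oldpos = mpos[m];
        bool moved = false, gaps_changed = false;
        if (goleft) {
          int p = mprev[m];
          long long gl = (long long)oldpos -
                         (p >= 0 ? (long long)mpos[p] + sp[msp[p]].w : 0);
          if (gl >= 1) {
            int n = mnext[m];
            long long gr = (n >= 0 ? (long long)mpos[n] : (long long)M) -
                           ((long long)oldpos + w);
            mpos[m] = oldpos - 1;
            moved = true;
            gaps_changed = gap_delta(gl, gl - 1);
            gaps_changed = gap_delta(gr, gr + 1) || gaps_changed;
          }
        } else {
          int n = mnext[m];
          long long gr = (n >= 0 ? (long long)mpos[n] : (long long)M) -
                         ((long long)oldpos + w);
          if (gr >= 1) {
            int p = mprev[m];
            long long gl = (long long)oldpos -
                           (p >= 0 ? (long long)mpos[p] + sp[msp[p]].w : 0);
            mpos[m] = oldpos + 1;
            moved = true;
            gaps_changed = gap_delta(gr, gr - 1);
            gaps_changed = gap_delta(gl, gl + 1) || gaps_changed;
          }
        }
        if (moved && sp[s].cognate) {
          if (oldpos == target_fpos) target_leave(t);
          if (mpos[m] == target_fpos) target_enter(t);
        }
        if (gaps_changed) rescale_assoc(t);
        mlast[m] = t;
        htime[0] = t + rng.expdraw(dwell_mean(s, mpos[m], mstrand[m]));
        sift_down(0);
      }
    }

    if (check_invariants) {
      for (int s2 = 0; s2 < ns; ++s2)
        if (nfree[s2] + nbound[s2] != sp[s2].copies) ++violations;
      // local exclusion around the list head chain (full scan is O(n);
      // only done under the debug flag)
      for (int m2 = head; m2 >= 0; m2 = mnext[m2]) {
        int n2 = mnext[m2];
        if (n2 >= 0 && mpos[m2] + sp[msp[m2]].w > mpos[n2]) ++violations;
      }
    }
  }

  // close accounting at the horizon
  advance_global(duration);
  for (int m = 0; m < ntot; ++m)
    if (mbound[m] && record_occupancy)
      occ[msp[m]][(size_t)mpos[m]] += duration - mlast[m];
  if (target_occupied) target_time += duration - t_occ_start;

  List occ_out(ns);
  if (record_occupancy)
    for (int s = 0; s < ns; ++s) occ_out[s] = NumericVector(occ[s].begin(), occ[s].end());

  NumericMatrix stats(ns, 6);
  for (int s = 0; s < ns; ++s) {
    stats(s, 0) = sp[s].copies;
    stats(s, 1) = n_visits[s];
    stats(s, 2) = sum_steps[s];
    stats(s, 3) = sum_dwell[s];
    stats(s, 4) = bound_time[s];
    stats(s, 5) = nbound[s];  // visits still open at the horizon
  }
  colnames(stats) =
      CharacterVector::create("copies", "n_visits", "sum_steps", "sum_dwell",
                              "bound_time", "open_visits");

  NumericMatrix vout(n_visit_rec, 5);
  for (int i = 0; i < n_visit_rec; ++i)
    for (int j = 0; j < 5; ++j) vout(i, j) = visits(i, j);
  colnames(vout) = CharacterVector::create("species", "bind_pos",
                                           "unbind_pos", "steps", "dwell");

  return List::create(
      _["species_stats"] = stats, _["fpt"] = fpt < 0 ? NA_REAL : fpt,
      _["target_time"] = target_time, _["n_events"] = n_events,
      _["occupancy"] = occ_out, _["visits"] = vout,
      _["n_visit_records"] = n_visit_rec, _["violations"] = (double)violations);
}
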