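// Forward-time Wright-Fisher engine for a two-copy segmental duplication
// under mutation, interlocus gene conversion (IGC) and crossover.
//
// Mirrors the plain-R engine (R/engine.R) exactly in model semantics; only
// the execution strategy differs (era-pruned generations, stamped registry
// arrays instead of recomputed registries). All randomness flows through R's
// RNG so runs are reproducible from set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Chrom {
  bool present = false;
  bool dup = false;
  std::vector<int> b0, b1, b2;  // original, single-copy, duplicated
};

struct Counters {
  long long mutations = 0, mut_skipped = 0, crossovers = 0;
  long long igc_events = 0, igc_truncated = 0, igc_identity_skipped = 0;
  long long fixed_erased = 0;
  long long trajectory_attempts = 0;
};

inline int runif_int(int n) {  // uniform on 0..n-1
  int v;
  do { v = (int)(unif_rand() * n); } while (v >= n);
  return v;
}

// --- conditioned fixation trajectory --------------------------------------

std::vector<int> sample_traj(int N, long T2max, double max_attempts,
                             long long *attempts_used) {
  const int twoN = 2 * N;
  const double dtwoN = (double)twoN;
  for (double a = 1; a <= max_attempts; ++a) {
    std::vector<int> path;
    path.push_back(1);
    int x = 1;
    bool fixed = false;
    for (long t = 1;; ++t) {
      x = (int)R::rbinom(dtwoN, (double)x / dtwoN);
      path.push_back(x);
      if (x == twoN) { fixed = true; break; }
      if (x == 0) break;
      if (T2max > 0 && t >= T2max) break;
    }
    if (fixed) {
      if (attempts_used) *attempts_used = (long long)a;
      return path;
    }
  }
  stop("no fixation trajectory accepted within attempt budget");
}

// --- per-meiosis mechanics ------------------------------------------------

// daughter block: partner's positions at chromosome coords <= junction,
// parent's at coords > junction; both inputs sorted, output sorted.
void recomb_block(const std::vector<int> &partner, const std::vector<int> &parent,
                  long off, long junction, std::vector<int> &out) {
  out.clear();
  for (int p : partner) {
    if (off + p <= junction) out.push_back(p);
    else break;
  }
  for (int p : parent)
    if (off + p > junction) out.push_back(p);
}

struct HotspotRegions {
  // precomputed interval unions for junction sampling
  std::vector<long> s3, e3, s2, e2;  // 3-block region; clipped to [0, 2L)
  long len3 = 0, len2 = 0;
};

long sample_from(const std::vector<long> &s, const std::vector<long> &e, long total) {
  long u = (long)(unif_rand() * total);
  if (u >= total) u = total - 1;
  for (size_t i = 0; i < s.size(); ++i) {
    long len = e[i] - s[i];
    if (u < len) return s[i] + u;
    u -= len;
  }
  return e.back() - 1;  // unreachable
}

long choose_junction(bool dupP, bool dupQ, int model, long L,
                     const HotspotRegions &hs) {
  if (dupP != dupQ) return (long)runif_int((int)(2 * L));  // shared length
  if (dupP) {
    switch (model) {
      case 0: return L + runif_int((int)L);            // SCC: [L, 2L)
      case 1: return (long)runif_int((int)(3 * L));    // WRC: [0, 3L)
      default: return sample_from(hs.s3, hs.e3, hs.len3);
    }
  }
  switch (model) {  // both two-block: model region clipped to [0, 2L)
    case 0: return L + runif_int((int)L);
    case 1: return (long)runif_int((int)(2 * L));
    default:
      if (hs.len2 == 0) return (long)runif_int((int)(2 * L));
      return sample_from(hs.s2, hs.e2, hs.len2);
  }
}

// --- stamped per-position occupancy registry ------------------------------

struct Registry {
  std::vector<int> cnt, stamp;
  int cur = 0;
  void init(int L) { cnt.assign(L, 0); stamp.assign(L, -1); }
  void new_generation() { ++cur; }
  inline int count(int pos) const { return stamp[pos] == cur ? cnt[pos] : 0; }
  inline void add(int pos) {
    if (stamp[pos] != cur) { stamp[pos] = cur; cnt[pos] = 0; }
    ++cnt[pos];
  }
  inline void remove(int pos) {
    if (stamp[pos] == cur && cnt[pos] > 0) --cnt[pos];
  }
};

// IGC copy-paste of the donor tract [lo, hi] onto the receptor,
// maintaining the joint occupancy registry.
void apply_tract(std::vector<int> &recv, const std::vector<int> &donor,
                 int lo, int hi, Registry &reg) {
  auto dlo = std::lower_bound(donor.begin(), donor.end(), lo);
  auto dhi = std::upper_bound(donor.begin(), donor.end(), hi);
  auto rlo = std::lower_bound(recv.begin(), recv.end(), lo);
  auto rhi = std::upper_bound(recv.begin(), recv.end(), hi);
  if ((dhi - dlo) == (rhi - rlo) && std::equal(dlo, dhi, rlo)) return;  // no-op
  for (auto it = rlo; it != rhi; ++it) reg.remove(*it);
  for (auto it = dlo; it != dhi; ++it) reg.add(*it);
  std::vector<int> out;
  out.reserve(recv.size() + (dhi - dlo));
  out.insert(out.end(), recv.begin(), rlo);
  out.insert(out.end(), dlo, dhi);
  out.insert(out.end(), rhi, recv.end());
  recv.swap(out);
}

// --- era genealogy --------------------------------------------------------

struct Genealogy {
  int k, twoN;
  std::vector<int> parent;       // k x twoN (row-major by generation)
  std::vector<char> partner;     // k x twoN
  std::vector<char> fertile;     // (k+1) x twoN, row 0 = base generation
  std::vector<char> carrier;     // (k+1) x twoN
  int event_gen = 0, event_slot = -1;
};

void build_genealogy(Genealogy &G, int twoN, int k, double r,
                     const std::vector<char> &base_carrier,
                     const std::vector<int> &want, int event_gen, bool prune) {
  G.k = k; G.twoN = twoN;
  G.parent.assign((size_t)k * twoN, 0);
  G.partner.assign((size_t)k * twoN, 0);
  G.fertile.assign((size_t)(k + 1) * twoN, 0);
  G.carrier.assign((size_t)(k + 1) * twoN, 0);
  G.event_gen = event_gen; G.event_slot = -1;

  std::copy(base_carrier.begin(), base_carrier.end(), G.carrier.begin());
  std::vector<int> prev_car, prev_non, slots(twoN);
  for (int g = 1; g <= k; ++g) {
    char *car_prev = &G.carrier[(size_t)(g - 1) * twoN];
    char *car_cur = &G.carrier[(size_t)g * twoN];
    int *par = &G.parent[(size_t)(g - 1) * twoN];
    int s = want[g - 1];
    if (s == 0 || g == event_gen) {
      for (int x = 0; x < twoN; ++x) par[x] = runif_int(twoN);
      if (g == event_gen) {
        if (s != 1) stop("duplication event generation must have carrier count 1");
        G.event_slot = runif_int(twoN);
        car_cur[G.event_slot] = 1;
      }
    } else {
      prev_car.clear(); prev_non.clear();
      for (int x = 0; x < twoN; ++x)
        (car_prev[x] ? prev_car : prev_non).push_back(x);
      if (prev_car.empty()) stop("carrier schedule demands carriers with none upstream");
      if (s < twoN && prev_non.empty())
        stop("carrier schedule demands non-carriers with none upstream");
      // uniform random subset of size s via partial Fisher-Yates
      for (int x = 0; x < twoN; ++x) slots[x] = x;
      for (int i = 0; i < s; ++i) {
        int j = i + runif_int(twoN - i);
        std::swap(slots[i], slots[j]);
        car_cur[slots[i]] = 1;
      }
      for (int x = 0; x < twoN; ++x) {
        if (car_cur[x])
          par[x] = prev_car[runif_int((int)prev_car.size())];
        else
          par[x] = prev_non[runif_int((int)prev_non.size())];
      }
    }
  }

  char *last = &G.fertile[(size_t)k * twoN];
  std::fill(last, last + twoN, 1);
  if (prune) {
    for (int g = k; g >= 1; --g) {
      char *fer = &G.fertile[(size_t)g * twoN];
      char *fer_prev = &G.fertile[(size_t)(g - 1) * twoN];
      int *par = &G.parent[(size_t)(g - 1) * twoN];
      char *pu = &G.partner[(size_t)(g - 1) * twoN];
      for (int x = 0; x < twoN; ++x) {
        if (!fer[x]) continue;
        int p = par[x];
        fer_prev[p] = 1;
        if (r > 0 && unif_rand() < r) {
          pu[x] = 1;
          fer_prev[p ^ 1] = 1;
        }
      }
    }
  } else {
    std::fill(G.fertile.begin(), G.fertile.end(), 1);
    if (r > 0)
      for (size_t i = 0; i < G.partner.size(); ++i)
        G.partner[i] = unif_rand() < r;
  }
}

// --- engine ---------------------------------------------------------------

struct Engine {
  int N, twoN;
  long L;
  double muL, r, g2L, q;
  int model;
  HotspotRegions hs;
  double identity_threshold;  // < 0 => off
  bool prune;
  Registry reg_sc, reg_od;
  Counters cnt;
  std::vector<Chrom> cur, nxt;

  void mutate_block(std::vector<int> &blk, Registry &reg) {
    if (unif_rand() >= muL) return;
    int pos = -1;
    for (int tries = 0; tries < 64; ++tries) {
      int c = runif_int((int)L);
      if (reg.count(c) == 0) { pos = c; break; }
    }
    if (pos < 0) {  // dense fallback: exact uniform over eligible positions
      std::vector<int> eligible;
      for (int c = 0; c < (int)L; ++c)
        if (reg.count(c) == 0) eligible.push_back(c);
      if (eligible.empty()) { ++cnt.mut_skipped; return; }
      pos = eligible[runif_int((int)eligible.size())];
    }
    blk.insert(std::upper_bound(blk.begin(), blk.end(), pos), pos);
    reg.add(pos);
    ++cnt.mutations;
  }

  void igc_chromosome(Chrom &d) {
    int ne = (int)R::rpois(g2L);
    for (int e = 0; e < ne; ++e) {
      int jglobal = runif_int((int)(2 * L));
      int jpos = jglobal % (int)L;
      int l = (q >= 1.0) ? 1 : 1 + (int)R::rgeom(q);
      int half = l / 2;
      int lo = jpos - half, hi = jpos + half;
      if (lo < 0 || hi > (int)L - 1) ++cnt.igc_truncated;
      lo = std::max(lo, 0); hi = std::min(hi, (int)L - 1);
      bool orig_to_dup = unif_rand() < 0.5;
      if (identity_threshold >= 0) {
        long diff = (long)d.b0.size() + (long)d.b2.size();
        {
          size_t i = 0, j = 0;
          while (i < d.b0.size() && j < d.b2.size()) {
            if (d.b0[i] == d.b2[j]) { diff -= 2; ++i; ++j; }
            else if (d.b0[i] < d.b2[j]) ++i;
            else ++j;
          }
        }
        if (1.0 - (double)diff / (double)L < identity_threshold) {
          ++cnt.igc_identity_skipped;
          continue;
        }
      }
      if (orig_to_dup) apply_tract(d.b2, d.b0, lo, hi, reg_od);
      else apply_tract(d.b0, d.b2, lo, hi, reg_od);
      ++cnt.igc_events;
    }
  }

  void advance_era(const Genealogy &G) {
    const int k = G.k;
    for (int g = 1; g <= k; ++g) {
      const char *fer = &G.fertile[(size_t)g * twoN];
      const int *par = &G.parent[(size_t)(g - 1) * twoN];
      const char *pu = &G.partner[(size_t)(g - 1) * twoN];
      const char *car = &G.carrier[(size_t)g * twoN];
      for (int x = 0; x < twoN; ++x) {
        Chrom &d = nxt[x];
        if (!fer[x]) { d.present = false; d.dup = false; d.b0.clear(); d.b1.clear(); d.b2.clear(); continue; }
        const Chrom &P = cur[par[x]];
        d.present = true;
        d.dup = P.dup;
        if (pu[x]) {
          const Chrom &Q = cur[par[x] ^ 1];
          long junction = choose_junction(P.dup, Q.dup, model, L, hs);
          recomb_block(Q.b0, P.b0, 0, junction, d.b0);
          recomb_block(Q.b1, P.b1, L, junction, d.b1);
          if (P.dup) {
            static const std::vector<int> empty;
            recomb_block(Q.dup ? Q.b2 : empty, P.b2, 2 * L, junction, d.b2);
          } else d.b2.clear();
          ++cnt.crossovers;
        } else {
          d.b0 = P.b0; d.b1 = P.b1;
          if (P.dup) d.b2 = P.b2; else d.b2.clear();
        }
        if (g == G.event_gen && x == G.event_slot) {
          d.dup = true;
          d.b2 = d.b0;
        }
        if (car[x] != (char)d.dup) stop("internal: carrier mask / block count mismatch");
      }
      // occupancy registries for this generation's materialized chromosomes
      reg_sc.new_generation(); reg_od.new_generation();
      for (int x = 0; x < twoN; ++x) {
        const Chrom &d = nxt[x];
        if (!d.present) continue;
        for (int p : d.b1) reg_sc.add(p);
        for (int p : d.b0) reg_od.add(p);
        if (d.dup) for (int p : d.b2) reg_od.add(p);
      }
      for (int x = 0; x < twoN; ++x) {
        Chrom &d = nxt[x];
        if (!d.present) continue;
        mutate_block(d.b0, reg_od);
        mutate_block(d.b1, reg_sc);
        if (d.dup) mutate_block(d.b2, reg_od);
      }
      if (g2L > 0) {
        for (int x = 0; x < twoN; ++x) {
          Chrom &d = nxt[x];
          if (d.present && d.dup) igc_chromosome(d);
        }
      }
      cur.swap(nxt);
    }
  }

  List record(int n_sample) {
    std::vector<int> ind(N);
    for (int i = 0; i < N; ++i) ind[i] = i;
    for (int i = 0; i < n_sample; ++i)
      std::swap(ind[i], ind[i + runif_int(N - i)]);
    List orig(2 * n_sample), sc(2 * n_sample), dup(2 * n_sample);
    int n_car = 0;
    for (int i = 0; i < n_sample; ++i) {
      for (int h = 0; h < 2; ++h) {
        const Chrom &c = cur[2 * ind[i] + h];
        orig[2 * i + h] = IntegerVector(c.b0.begin(), c.b0.end());
        sc[2 * i + h] = IntegerVector(c.b1.begin(), c.b1.end());
        if (c.dup) {
          dup[2 * i + h] = IntegerVector(c.b2.begin(), c.b2.end());
          ++n_car;
        } else dup[2 * i + h] = R_NilValue;
      }
    }
    return List::create(_["original"] = orig, _["singlecopy"] = sc,
                        _["duplicated"] = dup, _["n_carriers"] = n_car);
  }

  void prune_fixed_all() {
    std::vector<int> c0(L, 0), c1(L, 0), c2(L, 0);
    int ndup = 0;
    for (const Chrom &c : cur) {
      for (int p : c.b0) ++c0[p];
      for (int p : c.b1) ++c1[p];
      if (c.dup) { ++ndup; for (int p : c.b2) ++c2[p]; }
    }
    std::vector<char> fix_sc(L, 0), fix_od(L, 0);
    bool any_sc = false, any_od = false;
    for (int p = 0; p < (int)L; ++p) {
      if (c1[p] == twoN) { fix_sc[p] = 1; any_sc = true; }
      if (ndup == 0) {
        if (c0[p] == twoN) { fix_od[p] = 1; any_od = true; }
      } else if (ndup == twoN) {
        if (c0[p] == twoN && c2[p] == twoN) { fix_od[p] = 1; any_od = true; }
      }
    }
    if (!any_sc && !any_od) return;
    auto strip = [&](std::vector<int> &blk, const std::vector<char> &fix) {
      size_t w = 0;
      for (size_t i = 0; i < blk.size(); ++i) {
        if (!fix[blk[i]]) blk[w++] = blk[i];
        else ++cnt.fixed_erased;
      }
      blk.resize(w);
    };
    for (Chrom &c : cur) {
      if (any_od) strip(c.b0, fix_od);
      if (any_sc) strip(c.b1, fix_sc);
      if (any_od && c.dup) strip(c.b2, fix_od);
    }
  }
};

void build_hotspots(HotspotRegions &hs, const NumericMatrix &hotspots, long L) {
  for (int i = 0; i < hotspots.nrow(); ++i) {
    long s = (long)hotspots(i, 0), e = (long)hotspots(i, 1);
    hs.s3.push_back(s); hs.e3.push_back(e); hs.len3 += e - s;
    long s2 = s, e2 = std::min(e, 2 * L);
    if (s2 < e2) { hs.s2.push_back(s2); hs.e2.push_back(e2); hs.len2 += e2 - s2; }
  }
}

}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_sample_trajectory(int N, int T2max, double max_attempts) {
  if (N < 2) stop("N must be >= 2");
  long long attempts = 0;
  std::vector<int> path = sample_traj(N, T2max, max_attempts, &attempts);
  IntegerVector out(path.begin(), path.end());
  out.attr("attempts") = (double)attempts;
  return out;
}

// [[Rcpp::export]]
List cpp_run_simulation(int N, int L, double muL, double r, double g2L, double q,
                        int model, NumericMatrix hotspots, int k, int T1,
                        int T2max, int TT, int n_sample, double identity_threshold,
                        bool prune) {
  if (r > 1) stop("per-meiosis crossover probability exceeds 1");
  Engine E;
  E.N = N; E.twoN = 2 * N; E.L = L;
  E.muL = muL; E.r = r; E.g2L = g2L; E.q = q;
  E.model = model;
  E.identity_threshold = identity_threshold;
  E.prune = prune;
  build_hotspots(E.hs, hotspots, L);
  if (model == 2 && E.hs.len3 == 0) stop("HSC model requires hotspots");
  E.reg_sc.init(L); E.reg_od.init(L);
  E.cur.assign(E.twoN, Chrom());
  E.nxt.assign(E.twoN, Chrom());
  for (Chrom &c : E.cur) c.present = true;

  std::vector<int> traj;
  int T2 = -1;
  if (T1 < TT) {
    traj = sample_traj(N, T2max, 1e9, &E.cnt.trajectory_attempts);
    T2 = (int)traj.size() - 1;
    if (T1 + 1 + T2 > TT)
      stop("phase lengths inconsistent: T1 + 1 + T2 exceeds TT");
  }

  List recordings;
  std::vector<List> recs;
  Genealogy G;
  std::vector<char> base_carrier(E.twoN, 0);
  std::vector<int> want;
  long t = 0;
  while (t < TT) {
    int k_era = (int)std::min((long)k, (long)TT - t);
    want.assign(k_era, 0);
    int event_gen = 0;
    for (int g = 1; g <= k_era; ++g) {
      long tp = (t + g) - ((long)T1 + 1);
      if (tp < 0) want[g - 1] = 0;
      else if (T2 >= 0 && tp <= T2) want[g - 1] = traj[tp];
      else want[g - 1] = E.twoN;
      if (tp == 0) event_gen = g;
    }
    for (int x = 0; x < E.twoN; ++x) base_carrier[x] = E.cur[x].dup;
    build_genealogy(G, E.twoN, k_era, r, base_carrier, want, event_gen, prune);
    G.event_gen = event_gen;
    E.advance_era(G);
    t += k_era;
    List rec = E.record(n_sample);
    rec["t"] = (double)t;
    recs.push_back(rec);
    E.prune_fixed_all();
    Rcpp::checkUserInterrupt();
  }

  List out_recs(recs.size());
  for (size_t i = 0; i < recs.size(); ++i) out_recs[i] = recs[i];
  return List::create(
    _["trajectory"] = (T2 >= 0) ? IntegerVector(traj.begin(), traj.end())
                                : IntegerVector(0),
    _["T2"] = T2,
    _["recordings"] = out_recs,
    _["counters"] = NumericVector::create(
      _["mutations"] = (double)E.cnt.mutations,
      _["mut_skipped"] = (double)E.cnt.mut_skipped,
      _["crossovers"] = (double)E.cnt.crossovers,
      _["igc_events"] = (double)E.cnt.igc_events,
      _["igc_truncated"] = (double)E.cnt.igc_truncated,
      _["igc_identity_skipped"] = (double)E.cnt.igc_identity_skipped,
      _["fixed_erased"] = (double)E.cnt.fixed_erased,
      _["trajectory_attempts"] = (double)E.cnt.trajectory_attempts));
}

// Test hooks: single-operation views of the engine's internal mechanics so
// the R reference implementations can be asserted against them exactly.

// [[Rcpp::export]]
IntegerVector cpp_recombine_block(IntegerVector partner, IntegerVector parent,
                                  double off, double junction) {
  std::vector<int> q(partner.begin(), partner.end());
  std::vector<int> p(parent.begin(), parent.end());
  std::vector<int> out;
  recomb_block(q, p, (long)off, (long)junction, out);
  return IntegerVector(out.begin(), out.end());
}

// [[Rcpp::export]]
IntegerVector cpp_apply_igc_tract(IntegerVector receptor, IntegerVector donor,
                                  int lo, int hi) {
  std::vector<int> recv(receptor.begin(), receptor.end());
  std::vector<int> don(donor.begin(), donor.end());
  Registry dummy;
  dummy.init(1 + std::max(hi, (int)std::max(
      recv.empty() ? 0 : recv.back(), don.empty() ? 0 : don.back())));
  apply_tract(recv, don, lo, hi, dummy);
  return IntegerVector(recv.begin(), recv.end());
}
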