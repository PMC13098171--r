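#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Rounding convention throughout the engine: round half to even, matching
// base R's round(). nearbyint() uses the default FE_TONEAREST mode.
static inline long rhe(double x) {
  return (long) std::nearbyint(x);
}

// Multinomial draw via R's RNG. prob need not be normalised; it is copied
// and normalised here because R::rmultinom requires sum(prob) == 1.
static void draw_multinom(int n, const std::vector<double> &prob,
                          std::vector<int> &out) {
  const int k = (int) prob.size();
  std::vector<double> p(prob);
  double s = 0.0;
  for (int i = 0; i < k; ++i) s += p[i];
  for (int i = 0; i < k; ++i) p[i] /= s;
  rmultinom(n, p.data(), k, out.data());
}

// Sparse interaction matrix in triplet form: entry (ai[t], aj[t]) = ax[t],
// A[i][j] = effect of population j on the growth probability of i.
struct SparseA {
  std::vector<int> i, j;
  std::vector<double> x;
  bool active = false;
};

struct EngineState {
  int P = 0;                       // populations
  int G = 0;                       // groups
  std::vector<long> ab;            // abundances
  std::vector<int> grp;            // 0-based group of each population
  std::vector<long> cap;           // per-group capacity; 0 once extinct
  std::vector<double> frac;        // per-group niche fraction
  std::vector<std::vector<int>> members;

  long total() const {
    long t = 0;
    for (int i = 0; i < P; ++i) t += ab[i];
    return t;
  }
  void group_totals(std::vector<long> &ng) const {
    std::fill(ng.begin(), ng.end(), 0L);
    for (int i = 0; i < P; ++i) ng[grp[i]] += ab[i];
  }
  int n_alive() const {
    int a = 0;
    for (int i = 0; i < P; ++i) if (ab[i] > 0) ++a;
    return a;
  }
};

// Dilution: multinomial sample with replacement down to round(D * N).
// Returns false when the target size is 0 (collapse). Newly emptied groups
// lose their carrying capacity permanently.
static bool dilute_state(EngineState &st, double D) {
  long N = st.total();
  long target = rhe(D * (double) N);
  if (target < 1) {
    std::fill(st.ab.begin(), st.ab.end(), 0L);
    for (int g = 0; g < st.G; ++g) st.cap[g] = 0;
    return false;
  }
  std::vector<double> prob(st.P);
  for (int i = 0; i < st.P; ++i) prob[i] = (double) st.ab[i];
  std::vector<int> draw(st.P);
  draw_multinom((int) target, prob, draw);
  for (int i = 0; i < st.P; ++i) st.ab[i] = draw[i];
  std::vector<long> ng(st.G);
  st.group_totals(ng);
  for (int g = 0; g < st.G; ++g)
    if (st.cap[g] > 0 && ng[g] == 0) st.cap[g] = 0;
  return true;
}

// One growth phase: iterate until every surviving group sits exactly at its
// carrying capacity. Each iteration k uses the state at k-1 (a snapshot) to
// compute probabilities; the global increment is I_k = max(1,
// round(rate * N_total)), split per group as max(1, round(I_k * frac_g)).
// Interaction-modified probabilities: p'_i = p_(i|G) + sum_j A_ij p_j with
// p_j the GLOBAL relative abundance, clipped at 0; the multinomial draw
// normalises within the scope. Overshoot beyond a capacity is trimmed by
// removing individuals uniformly from the allocation just made.
// remove `excess` individuals uniformly without replacement from the
// members of group g (used when dilution's with-replacement sampling leaves
// a group above its capacity, and for overshoot trimming)
static void remove_uniform(EngineState &st, int g, long excess) {
  const std::vector<int> &mem = st.members[g];
  long remaining = 0;
  for (int m : mem) remaining += st.ab[m];
  for (long e = 0; e < excess; ++e) {
    double u = unif_rand() * (double) remaining;
    double acc = 0.0;
    for (int m : mem) {
      acc += (double) st.ab[m];
      if (u < acc) {
        --st.ab[m];
        break;
      }
    }
    --remaining;
  }
}

static void grow_state(EngineState &st, double rate, const SparseA &A) {
  std::vector<long> ng(st.G), ng_snap(st.G);
  // a group can leave dilution above its capacity (sampling is with
  // replacement): truncate it to exactly its capacity before growing
  st.group_totals(ng);
  for (int g = 0; g < st.G; ++g)
    if (st.cap[g] > 0 && ng[g] > st.cap[g]) remove_uniform(st, g, ng[g] - st.cap[g]);
  std::vector<double> pglob(st.P), addi;
  if (A.active) addi.resize(st.P);
  std::vector<long> snap(st.P);

  for (;;) {
    st.group_totals(ng);
    bool any_unfinished = false;
    for (int g = 0; g < st.G; ++g)
      if (st.cap[g] > 0 && ng[g] < st.cap[g]) { any_unfinished = true; break; }
    if (!any_unfinished) break;

    long Ntot = st.total();
    long Ik = rhe(rate * (double) Ntot);
    if (Ik < 1) Ik = 1;

    // snapshot of the pre-iteration state
    for (int i = 0; i < st.P; ++i) snap[i] = st.ab[i];
    ng_snap = ng;
    if (A.active) {
      for (int i = 0; i < st.P; ++i)
        pglob[i] = (double) snap[i] / (double) Ntot;
      std::fill(addi.begin(), addi.end(), 0.0);
      for (size_t t = 0; t < A.x.size(); ++t)
        addi[A.i[t]] += A.x[t] * pglob[A.j[t]];
    }

    bool any_growth = false;
    for (int g = 0; g < st.G; ++g) {
      if (st.cap[g] == 0 || ng_snap[g] >= st.cap[g]) continue;
      long inc = rhe((double) Ik * st.frac[g]);
      if (inc < 1) inc = 1;

      const std::vector<int> &mem = st.members[g];
      const int kg = (int) mem.size();
      std::vector<double> p(kg);
      double psum = 0.0;
      for (int m = 0; m < kg; ++m) {
        double pi = (double) snap[mem[m]] / (double) ng_snap[g];
        if (A.active) pi += addi[mem[m]];
        if (pi < 0.0) pi = 0.0;
        p[m] = pi;
        psum += pi;
      }
      if (psum <= 0.0) continue;  // scope stalls this iteration

      std::vector<int> draw(kg);
      draw_multinom((int) inc, p, draw);
      for (int m = 0; m < kg; ++m) st.ab[mem[m]] += draw[m];
      any_growth = true;

      long newng = ng[g] + inc;
      if (newng > st.cap[g]) {
        long excess = newng - st.cap[g];
        long remaining = inc;
        for (long e = 0; e < excess; ++e) {
          double u = unif_rand() * (double) remaining;
          double acc = 0.0;
          for (int m = 0; m < kg; ++m) {
            acc += (double) draw[m];
            if (u < acc) {
              --draw[m];
              --st.ab[mem[m]];
              break;
            }
          }
          --remaining;
        }
      }
    }
    if (!any_growth) break;  // every unfinished scope stalled: no progress possible
  }
}

static EngineState make_state(const IntegerVector &abundance,
                              const IntegerVector &group,
                              const IntegerVector &capacity,
                              const NumericVector &frac) {
  EngineState st;
  st.P = abundance.size();
  st.G = capacity.size();
  st.ab.resize(st.P);
  st.grp.resize(st.P);
  st.cap.resize(st.G);
  st.frac.resize(st.G);
  st.members.resize(st.G);
  for (int i = 0; i < st.P; ++i) {
    st.ab[i] = abundance[i];
    st.grp[i] = group[i];
    st.members[group[i]].push_back(i);
  }
  for (int g = 0; g < st.G; ++g) {
    st.cap[g] = capacity[g];
    st.frac[g] = frac[g];
  }
  return st;
}

static SparseA make_sparse(const IntegerVector &ai, const IntegerVector &aj,
                           const NumericVector &ax) {
  SparseA A;
  A.active = ax.size() > 0;
  for (int t = 0; t < ax.size(); ++t) {
    A.i.push_back(ai[t]);
    A.j.push_back(aj[t]);
    A.x.push_back(ax[t]);
  }
  return A;
}

// [[Rcpp::export]]
IntegerVector cpp_growth_phase(IntegerVector abundance, IntegerVector group,
                               IntegerVector capacity, NumericVector frac,
                               IntegerVector ai, IntegerVector aj,
                               NumericVector ax, double growth_rate) {
  EngineState st = make_state(abundance, group, capacity, frac);
  SparseA A = make_sparse(ai, aj, ax);
  grow_state(st, growth_rate, A);
  IntegerVector out(st.P);
  for (int i = 0; i < st.P; ++i) out[i] = (int) st.ab[i];
  return out;
}

// Full trajectory: alternate dilution and growth for n_cycles. Capacities
// are fixed before the first cycle. When fill_after_absorption is set and a
// single population remains (and the next dilution cannot collapse it), the
// remaining cycles are identical to the current state and are filled in
// without further RNG use.
// [[Rcpp::export]]
List cpp_run_trajectory(IntegerVector abundance, IntegerVector group,
                        IntegerVector capacity, NumericVector frac,
                        IntegerVector ai, IntegerVector aj, NumericVector ax,
                        double D, double growth_rate, int n_cycles,
                        bool record_all, bool fill_after_absorption) {
  EngineState st = make_state(abundance, group, capacity, frac);
  SparseA A = make_sparse(ai, aj, ax);

  IntegerMatrix states;
  if (record_all) states = IntegerMatrix(n_cycles, st.P);

  int collapse_cycle = 0;   // 0 = never
  int absorbed_cycle = 0;   // 0 = never
  int n_recorded = 0;
  std::string status = "completed";

  for (int c = 1; c <= n_cycles; ++c) {
    if (!dilute_state(st, D)) {
      status = "collapsed";
      collapse_cycle = c;
      if (record_all)
        for (int i = 0; i < st.P; ++i) states(c - 1, i) = 0;
      n_recorded = c;
      break;
    }
    grow_state(st, growth_rate, A);
    if (record_all)
      for (int i = 0; i < st.P; ++i) states(c - 1, i) = (int) st.ab[i];
    n_recorded = c;

    if (st.n_alive() == 1) {
      if (absorbed_cycle == 0) absorbed_cycle = c;
      if (fill_after_absorption && rhe(D * (double) st.total()) >= 1) {
        // stationary from here on: single population regrows to capacity
        if (record_all)
          for (int cc = c + 1; cc <= n_cycles; ++cc)
            for (int i = 0; i < st.P; ++i) states(cc - 1, i) = (int) st.ab[i];
        n_recorded = n_cycles;
        break;
      }
    }
  }

  IntegerVector fin(st.P);
  for (int i = 0; i < st.P; ++i) fin[i] = (int) st.ab[i];
  IntegerVector final_cap(st.G);
  for (int g = 0; g < st.G; ++g) final_cap[g] = (int) st.cap[g];

  List out = List::create(
      _["final"] = fin, _["status"] = status,
      _["collapse_cycle"] = collapse_cycle,
      _["absorbed_cycle"] = absorbed_cycle, _["n_recorded"] = n_recorded,
      _["final_capacity"] = final_cap);
  if (record_all) out["states"] = states;
  return out;
}

// Collision-free seed splitting: splitmix64 finaliser of the master seed,
// then an affine step with an odd multiplier, reduced mod 2^31. The affine
// map is a bijection on Z/2^31, so distinct child indices (up to 2^31 of
// them) can never collide for a fixed master seed.
// [[Rcpp::export]]
IntegerVector cpp_child_seeds(double master, NumericVector idx) {
  uint64_t z = (uint64_t)(int64_t) master;
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  z ^= z >> 31;
  const uint64_t base = z & 0x7FFFFFFFULL;
  const uint64_t step = 2654435761ULL;  // odd => injective mod 2^31
  IntegerVector out(idx.size());
  for (int i = 0; i < idx.size(); ++i) {
    uint64_t k = (uint64_t)(int64_t) idx[i];
    out[i] = (int) ((base + k * step) & 0x7FFFFFFFULL);
  }
  return out;
}
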