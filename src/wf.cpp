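// Forward-in-time diploid Wright-Fisher engine.
//
// One C++ advance routine backs both the single-step R surface
// (advance_generation) and the full in-C++ scenario loop (run_scenario),
// so the two entry points cannot drift apart.
//
// Conventions:
//  * positions are 0-based bp, stored as int (sequence length <= 2^31-1);
//  * haplotypes are sorted unique position vectors of derived alleles;
//  * generation index g runs forward 1..G; the state passed in/out labels
//    the generation it represents;
//  * all randomness comes from R's RNG stream (RNGScope via Rcpp
//    attributes), so set.seed() on the R side gives full determinism.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>

using namespace Rcpp;

namespace {

struct Hap {
  std::vector<int> mut;   // sorted unique derived-allele positions
  bool inv = false;       // inversion orientation flag
};

struct Ind {
  Hap h[2];
};

typedef std::vector<Ind> Deme;

enum EvKind { EV_RESIZE = 0, EV_SPLIT = 1, EV_ADMIX = 2, EV_INV = 3 };

struct Event {
  int gen;                 // forward generation index at which it applies
  int kind;
  std::vector<int> par;    // kind-specific integer payload
};

struct Params {
  double L;                // sequence length, bp
  double mu;               // mutation rate per bp per generation
  double map_rate;         // Morgan per bp
  int mig_model;           // 0 none, 1 island/reciprocal, 2 source-sink
  double m;                // backward migration probability
  int mig_period;          // apply migration only when g %% period == 0
  bool inv_active;
  double inv_start, inv_end;  // closed interval, bp
  double inv_sel;          // selection coefficient of the inversion (0.2)
  int prune_every;
  std::vector<Event> events;
};

Params parse_params(const List& plan) {
  Params P;
  P.L = as<double>(plan["sequence_length_bp"]);
  P.mu = as<double>(plan["mutation_rate"]);
  P.map_rate = as<double>(plan["map_rate"]);
  P.mig_model = as<int>(plan["migration_model"]);
  P.m = as<double>(plan["migration_rate"]);
  P.mig_period = as<int>(plan["migration_period"]);
  P.inv_active = as<bool>(plan["inversion_active"]);
  P.inv_start = as<double>(plan["inversion_start"]);
  P.inv_end = as<double>(plan["inversion_end"]);
  P.inv_sel = as<double>(plan["inversion_sel"]);
  P.prune_every = as<int>(plan["prune_every"]);
  List evs = plan["events"];
  for (int i = 0; i < evs.size(); ++i) {
    List e = evs[i];
    Event ev;
    ev.gen = as<int>(e["gen"]);
    ev.kind = as<int>(e["kind"]);
    IntegerVector p = e["params"];
    ev.par.assign(p.begin(), p.end());
    P.events.push_back(ev);
  }
  return P;
}

inline int runif_int(int n) {
  // uniform on 0..n-1
  int k;
  do { k = (int)(unif_rand() * n); } while (k >= n);
  return k;
}

// Meiosis: recombine the two parental haplotypes and add new mutations.
// Crossover positions falling inside the inversion interval are discarded
// (not relocated) when the parent is heterozygous for the inversion.
Hap make_gamete_core(const Ind& par, const Params& P,
                     std::vector<double>* kept_cx = nullptr) {
  const Hap* src[2] = { &par.h[0], &par.h[1] };
  bool het = P.inv_active && (src[0]->inv != src[1]->inv);

  int ncx = (int)R::rpois(P.L * P.map_rate);
  std::vector<double> cx;
  cx.reserve(ncx);
  for (int i = 0; i < ncx; ++i) {
    double x = unif_rand() * P.L;
    if (het && x >= P.inv_start && x <= P.inv_end) continue;  // suppressed
    cx.push_back(x);
  }
  std::sort(cx.begin(), cx.end());
  if (kept_cx) *kept_cx = cx;

  int cur = (unif_rand() < 0.5) ? 0 : 1;
  Hap g;
  g.mut.reserve(src[0]->mut.size() + 8);

  double mid = 0.5 * (P.inv_start + P.inv_end);
  size_t idx[2] = { 0, 0 };
  double from = 0.0;
  for (size_t k = 0; k <= cx.size(); ++k) {
    double to = (k < cx.size()) ? cx[k] : P.L;
    // move both read pointers up to the segment start
    for (int s = 0; s < 2; ++s) {
      const std::vector<int>& v = src[s]->mut;
      while (idx[s] < v.size() && (double)v[idx[s]] < from) ++idx[s];
    }
    const std::vector<int>& v = src[cur]->mut;
    while (idx[cur] < v.size() && (double)v[idx[cur]] < to) {
      g.mut.push_back(v[idx[cur]]);
      ++idx[cur];
    }
    if (P.inv_active && from <= mid && mid < to) g.inv = src[cur]->inv;
    cur = 1 - cur;
    from = to;
  }

  // new mutations; duplicate positions within the gamete are resampled
  int nm = (int)R::rpois(P.L * P.mu);
  for (int i = 0; i < nm; ++i) {
    for (int tries = 0; tries < 1000; ++tries) {
      int pos = (int)(unif_rand() * P.L);
      if (pos >= (int)P.L) continue;
      std::vector<int>::iterator it =
        std::lower_bound(g.mut.begin(), g.mut.end(), pos);
      if (it != g.mut.end() && *it == pos) continue;  // collision: resample
      g.mut.insert(it, pos);
      break;
    }
  }
  return g;
}

// Backward-migration rule: returns the parental deme for an offspring born
// into deme d (island model: uniform among the other demes with prob m;
// source-sink: deme 0 is the source and never receives migrants).
int choose_parent_deme_core(int d, int n_demes, const Params& P,
                            bool mig_active) {
  if (!mig_active || n_demes < 2) return d;
  if (P.mig_model == 2) {               // source-sink
    if (d == 0) return 0;
    return (unif_rand() < P.m) ? 0 : d;
  }
  if (unif_rand() < P.m) {              // island / reciprocal
    int k = runif_int(n_demes - 1);
    return (k >= d) ? k + 1 : k;
  }
  return d;
}

// Two distinct parents from a deme, probability proportional to fitness.
void choose_parents(const Deme& deme, const std::vector<double>& cum,
                    int& i, int& j) {
  int n = (int)deme.size();
  if (cum.empty()) {
    i = runif_int(n);
    do { j = runif_int(n); } while (j == i);
  } else {
    double tot = cum.back();
    i = (int)(std::lower_bound(cum.begin(), cum.end(), unif_rand() * tot) -
              cum.begin());
    do {
      j = (int)(std::lower_bound(cum.begin(), cum.end(), unif_rand() * tot) -
                cum.begin());
    } while (j == i);
  }
}

void prune_fixed(std::vector<Deme>& pop) {
  long total = 0;
  std::unordered_map<int, long> cnt;
  for (size_t d = 0; d < pop.size(); ++d)
    for (size_t k = 0; k < pop[d].size(); ++k)
      for (int s = 0; s < 2; ++s) {
        ++total;
        const std::vector<int>& v = pop[d][k].h[s].mut;
        for (size_t q = 0; q < v.size(); ++q) ++cnt[v[q]];
      }
  std::vector<int> fixed;
  for (std::unordered_map<int, long>::iterator it = cnt.begin();
       it != cnt.end(); ++it)
    if (it->second == total) fixed.push_back(it->first);
  if (fixed.empty()) return;
  std::sort(fixed.begin(), fixed.end());
  for (size_t d = 0; d < pop.size(); ++d)
    for (size_t k = 0; k < pop[d].size(); ++k)
      for (int s = 0; s < 2; ++s) {
        std::vector<int>& v = pop[d][k].h[s].mut;
        std::vector<int> keep;
        keep.reserve(v.size());
        std::set_difference(v.begin(), v.end(), fixed.begin(), fixed.end(),
                            std::back_inserter(keep));
        v.swap(keep);
      }
}

// Produce generation g from the current population, applying any events
// scheduled at g.
void advance_one(std::vector<Deme>& pop, const Params& P, int g) {
  int splitFrom = -1;
  std::vector<int> splitSizes;
  bool admix = false;
  int admixSize = 0;
  std::vector<int> admixSrc;
  std::vector<int> sizes(pop.size());
  for (size_t d = 0; d < pop.size(); ++d) sizes[d] = (int)pop[d].size();

  for (size_t e = 0; e < P.events.size(); ++e) {
    const Event& ev = P.events[e];
    if (ev.gen != g) continue;
    if (ev.kind == EV_RESIZE) {
      sizes[ev.par[0]] = ev.par[1];
    } else if (ev.kind == EV_SPLIT) {
      splitFrom = ev.par[0];
      splitSizes.assign(ev.par.begin() + 1, ev.par.end());
    } else if (ev.kind == EV_ADMIX) {
      admix = true;
      admixSize = ev.par[0];
      admixSrc.assign(ev.par.begin() + 1, ev.par.end());
    } else if (ev.kind == EV_INV) {
      // seed one inversion-bearing haplotype in deme 0
      int n0 = (int)pop[0].size();
      int k = runif_int(2 * n0);
      pop[0][k / 2].h[k % 2].inv = true;
    }
  }

  // inversion frequency and fitness weights, per parental deme
  std::vector<std::vector<double> > cum(pop.size());
  if (P.inv_active) {
    for (size_t d = 0; d < pop.size(); ++d) {
      int n = (int)pop[d].size();
      int ninv = 0;
      for (int k = 0; k < n; ++k)
        ninv += (pop[d][k].h[0].inv ? 1 : 0) + (pop[d][k].h[1].inv ? 1 : 0);
      if (ninv == 0) continue;  // uniform fast path
      double q = (double)ninv / (2.0 * n);
      // fitness effect of each inversion copy (multiplicative across the
      // two haplotypes): advantageous below q = 0.5, deleterious above
      double w = 1.0 - (q - 0.5) * P.inv_sel;
      cum[d].resize(n);
      double acc = 0.0;
      for (int k = 0; k < n; ++k) {
        int copies = (pop[d][k].h[0].inv ? 1 : 0) +
                     (pop[d][k].h[1].inv ? 1 : 0);
        acc += copies == 0 ? 1.0 : (copies == 1 ? w : w * w);
        cum[d][k] = acc;
      }
    }
  }

  bool mig_active = P.mig_model > 0 && P.m > 0.0 &&
                    (P.mig_period <= 1 || (g % P.mig_period) == 0);

  // layout of the offspring generation
  std::vector<int> newSizes;
  std::vector<int> fixedSrc;  // -1: migration rule on same index; -2: admix
  if (admix) {
    newSizes.push_back(admixSize);
    fixedSrc.push_back(-2);
  } else if (splitFrom >= 0) {
    for (size_t d = 0; d < pop.size(); ++d) {
      if ((int)d == splitFrom) {
        for (size_t s = 0; s < splitSizes.size(); ++s) {
          newSizes.push_back(splitSizes[s]);
          fixedSrc.push_back(splitFrom);
        }
      } else {
        newSizes.push_back(sizes[d]);
        fixedSrc.push_back((int)d);
      }
    }
  } else {
    for (size_t d = 0; d < pop.size(); ++d) {
      newSizes.push_back(sizes[d]);
      fixedSrc.push_back(-1);
    }
  }

  int n_old = (int)pop.size();
  std::vector<Deme> np(newSizes.size());
  for (size_t d = 0; d < np.size(); ++d) {
    if (newSizes[d] < 1)
      stop("event scheduling would empty a deme at generation %d", g);
    np[d].resize(newSizes[d]);
    for (int k = 0; k < newSizes[d]; ++k) {
      int pd;
      if (fixedSrc[d] == -2) {
        pd = admixSrc[runif_int((int)admixSrc.size())];
      } else if (fixedSrc[d] >= 0) {
        pd = fixedSrc[d];
      } else {
        pd = choose_parent_deme_core((int)d, n_old, P, mig_active);
      }
      if (pop[pd].size() < 2)
        stop("parental deme %d too small at generation %d", pd, g);
      int i, j;
      choose_parents(pop[pd], cum[pd], i, j);
      np[d][k].h[0] = make_gamete_core(pop[pd][i], P);
      np[d][k].h[1] = make_gamete_core(pop[pd][j], P);
    }
  }
  pop.swap(np);

  if (P.prune_every > 0 && (g % P.prune_every) == 0) prune_fixed(pop);
}

List pop_to_r(const std::vector<Deme>& pop, int gen) {
  List demes(pop.size());
  for (size_t d = 0; d < pop.size(); ++d) {
    int n = (int)pop[d].size();
    List haps(2 * n);
    LogicalVector inv(2 * n);
    for (int k = 0; k < n; ++k)
      for (int s = 0; s < 2; ++s) {
        const Hap& h = pop[d][k].h[s];
        haps[2 * k + s] = IntegerVector(h.mut.begin(), h.mut.end());
        inv[2 * k + s] = h.inv;
      }
    demes[d] = List::create(_["haplotypes"] = haps, _["inversion"] = inv);
  }
  NumericVector q(pop.size());
  for (size_t d = 0; d < pop.size(); ++d) {
    int n = (int)pop[d].size(), ninv = 0;
    for (int k = 0; k < n; ++k)
      ninv += (pop[d][k].h[0].inv ? 1 : 0) + (pop[d][k].h[1].inv ? 1 : 0);
    q[d] = (double)ninv / (2.0 * n);
  }
  return List::create(_["generation"] = gen, _["demes"] = demes,
                      _["inversion_frequency"] = q);
}

std::vector<Deme> pop_from_r(const List& state) {
  List demes = state["demes"];
  std::vector<Deme> pop(demes.size());
  for (int d = 0; d < demes.size(); ++d) {
    List dm = demes[d];
    List haps = dm["haplotypes"];
    LogicalVector inv = dm["inversion"];
    int n2 = haps.size();
    if (n2 % 2 != 0) stop("deme %d has an odd number of haplotypes", d + 1);
    pop[d].resize(n2 / 2);
    for (int k = 0; k < n2; ++k) {
      IntegerVector v = haps[k];
      Hap& h = pop[d][k / 2].h[k % 2];
      h.mut.assign(v.begin(), v.end());
      h.inv = inv[k];
    }
  }
  return pop;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_chromosome(List plan) {
  Params P = parse_params(plan);
  IntegerVector init = plan["init_deme_sizes"];
  int G = as<int>(plan["total_generations"]);
  std::vector<Deme> pop(init.size());
  for (int d = 0; d < init.size(); ++d) pop[d].resize(init[d]);
  for (int g = 1; g <= G; ++g) {
    advance_one(pop, P, g);
    if (g % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return pop_to_r(pop, G);
}

// [[Rcpp::export]]
List cpp_advance(List state, List plan, int n_steps) {
  Params P = parse_params(plan);
  std::vector<Deme> pop = pop_from_r(state);
  int g0 = as<int>(state["generation"]);
  for (int g = g0 + 1; g <= g0 + n_steps; ++g) advance_one(pop, P, g);
  return pop_to_r(pop, g0 + n_steps);
}

// [[Rcpp::export]]
List cpp_make_gamete(IntegerVector mutA, bool invA,
                     IntegerVector mutB, bool invB,
                     double sequence_length_bp, double map_rate, double mu,
                     bool inversion_active,
                     double inversion_start, double inversion_end) {
  Params P;
  P.L = sequence_length_bp;
  P.mu = mu;
  P.map_rate = map_rate;
  P.mig_model = 0; P.m = 0; P.mig_period = 1;
  P.inv_active = inversion_active;
  P.inv_start = inversion_start;
  P.inv_end = inversion_end;
  P.inv_sel = 0.0;
  P.prune_every = 0;
  Ind par;
  par.h[0].mut.assign(mutA.begin(), mutA.end());
  par.h[0].inv = invA;
  par.h[1].mut.assign(mutB.begin(), mutB.end());
  par.h[1].inv = invB;
  std::vector<double> cx;
  Hap g = make_gamete_core(par, P, &cx);
  return List::create(
    _["mutations"] = IntegerVector(g.mut.begin(), g.mut.end()),
    _["carries_inversion"] = g.inv,
    _["crossovers"] = NumericVector(cx.begin(), cx.end()));
}

// [[Rcpp::export]]
int cpp_choose_parent_deme(int deme0, int n_demes, int migration_model,
                           double m, bool mig_active) {
  Params P;
  P.mig_model = migration_model;
  P.m = m;
  P.mig_period = 1;
  return choose_parent_deme_core(deme0, n_demes, P, mig_active);
}
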