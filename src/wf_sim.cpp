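// Forward Wright-Fisher simulator with a population split.
//
// Haplotypes are sparse sorted vectors of derived-allele positions on a
// continuous sequence [0, L): with real-valued mutation and crossover
// positions every new mutation is its own site (infinite-sites behaviour;
// a draw colliding with a position already on the receiving gamete is
// redrawn). Demography: burn-in at constant size, random split into two
// demes of half size, linear growth of one individual per generation per
// deme, then stationary drift. No migration, no selection.
//
// Sites lost from a deme simply stop appearing in its haplotypes; sites
// fixed within a deme are stripped from its haplotypes every generation and
// recorded in a per-deme fixed registry, re-materialised as frequency 1 in
// the output. Sites fixed in both demes contribute nothing to any F_ST
// component (num = den = 0) and are dropped.
//
// All randomness comes from R's RNG so set.seed() governs the simulation.

#include <Rcpp.h>
#include <algorithm>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

typedef std::vector<double> Hap;

// one recombinant gamete from a diploid parent (two haplotypes)
static Hap make_gamete(const Hap &h1, const Hap &h2, double L, double rho) {
  int n_cross = R::rpois(L * rho);
  const Hap *active = (unif_rand() < 0.5) ? &h1 : &h2;
  const Hap *other = (active == &h1) ? &h2 : &h1;
  Hap out;
  if (n_cross == 0) {
    out = *active;
  } else {
    std::vector<double> cuts(n_cross);
    for (int i = 0; i < n_cross; ++i) cuts[i] = unif_rand() * L;
    std::sort(cuts.begin(), cuts.end());
    out.reserve(active->size());
    double seg_start = 0.0;
    for (int i = 0; i <= n_cross; ++i) {
      double seg_end = (i == n_cross) ? L : cuts[i];
      Hap::const_iterator lo =
          std::lower_bound(active->begin(), active->end(), seg_start);
      Hap::const_iterator hi =
          std::lower_bound(active->begin(), active->end(), seg_end);
      out.insert(out.end(), lo, hi);
      std::swap(active, other);
      seg_start = seg_end;
    }
  }
  return out;
}

static void add_mutations(Hap &g, double L, double mu) {
  int n_mut = R::rpois(L * mu);
  for (int i = 0; i < n_mut; ++i) {
    double pos = unif_rand() * L;
    Hap::iterator it = std::lower_bound(g.begin(), g.end(), pos);
    while (it != g.end() && *it == pos) {  // infinite sites: redraw collision
      pos = unif_rand() * L;
      it = std::lower_bound(g.begin(), g.end(), pos);
    }
    g.insert(it, pos);
  }
}

// positions present on every haplotype of the deme (running sorted intersection)
static Hap fixed_sites(const std::vector<Hap> &pop) {
  Hap cur = pop.empty() ? Hap() : pop[0];
  for (size_t i = 1; i < pop.size() && !cur.empty(); ++i) {
    Hap next;
    std::set_intersection(cur.begin(), cur.end(), pop[i].begin(),
                          pop[i].end(), std::back_inserter(next));
    cur.swap(next);
  }
  return cur;
}

static void strip_sites(std::vector<Hap> &pop, const Hap &sites) {
  if (sites.empty()) return;
  for (size_t i = 0; i < pop.size(); ++i) {
    Hap kept;
    kept.reserve(pop[i].size());
    std::set_difference(pop[i].begin(), pop[i].end(), sites.begin(),
                        sites.end(), std::back_inserter(kept));
    pop[i].swap(kept);
  }
}

// one WF generation: offspring haplotype pairs from uniformly drawn parents
// (selfing allowed); diploid = two gametes from two parents, haploid = one
// recombinant of two parent haplotypes.
static void next_generation(std::vector<Hap> &pop, int n_offspring_ind,
                            double L, double mu, double rho, bool haploid) {
  std::vector<Hap> next;
  if (haploid) {
    int n_par = pop.size();
    next.reserve(n_offspring_ind);
    for (int j = 0; j < n_offspring_ind; ++j) {
      int p1 = (int)(unif_rand() * n_par);
      int p2 = (int)(unif_rand() * n_par);
      Hap g = make_gamete(pop[p1], pop[p2], L, rho);
      add_mutations(g, L, mu);
      next.push_back(g);
    }
  } else {
    int n_par = pop.size() / 2;
    next.reserve(2 * n_offspring_ind);
    for (int j = 0; j < n_offspring_ind; ++j) {
      int mom = (int)(unif_rand() * n_par);
      int dad = (int)(unif_rand() * n_par);
      Hap g1 = make_gamete(pop[2 * mom], pop[2 * mom + 1], L, rho);
      add_mutations(g1, L, mu);
      Hap g2 = make_gamete(pop[2 * dad], pop[2 * dad + 1], L, rho);
      add_mutations(g2, L, mu);
      next.push_back(g1);
      next.push_back(g2);
    }
  }
  pop.swap(next);
}

// census frequency table of a deme, including its fixed registry at freq 1
static void count_freqs(const std::vector<Hap> &pop, const Hap &fixed,
                        std::unordered_map<double, double> &freq) {
  double n = (double)pop.size();
  std::unordered_map<double, int> counts;
  for (size_t i = 0; i < pop.size(); ++i)
    for (size_t k = 0; k < pop[i].size(); ++k) counts[pop[i][k]] += 1;
  for (std::unordered_map<double, int>::const_iterator it = counts.begin();
       it != counts.end(); ++it)
    freq[it->first] = it->second / n;
  for (size_t k = 0; k < fixed.size(); ++k) freq[fixed[k]] = 1.0;
}

static DataFrame freq_table(const std::vector<Hap> &d1, const Hap &fix1,
                            const std::vector<Hap> &d2, const Hap &fix2) {
  std::unordered_map<double, double> f1, f2;
  count_freqs(d1, fix1, f1);
  count_freqs(d2, fix2, f2);
  std::vector<double> pos;
  pos.reserve(f1.size() + f2.size());
  for (std::unordered_map<double, double>::const_iterator it = f1.begin();
       it != f1.end(); ++it)
    pos.push_back(it->first);
  for (std::unordered_map<double, double>::const_iterator it = f2.begin();
       it != f2.end(); ++it)
    if (f1.find(it->first) == f1.end()) pos.push_back(it->first);
  std::sort(pos.begin(), pos.end());
  int n = pos.size();
  NumericVector position(n), p1(n), p2(n);
  int m = 0;
  for (int i = 0; i < n; ++i) {
    std::unordered_map<double, double>::const_iterator a = f1.find(pos[i]);
    std::unordered_map<double, double>::const_iterator b = f2.find(pos[i]);
    double q1 = (a == f1.end()) ? 0.0 : a->second;
    double q2 = (b == f2.end()) ? 0.0 : b->second;
    if (q1 >= 1.0 && q2 >= 1.0) continue;  // fixed in both: no contribution
    position[m] = pos[i];
    p1[m] = q1;
    p2[m] = q2;
    ++m;
  }
  position = Rcpp::head(position, m);
  p1 = Rcpp::head(p1, m);
  p2 = Rcpp::head(p2, m);
  return DataFrame::create(Named("position") = position, Named("p1") = p1,
                           Named("p2") = p2);
}

// [[Rcpp::export(name = ".wf_sim_core")]]
List wf_sim_core(int N, double L, double mu, double rho, int burnin_gens,
                 int growth_gens, int stationary_gens, bool haploid,
                 IntegerVector snapshot_gens, NumericVector init_freqs) {
  if (N < 2 || N % 2 != 0) stop("N must be even and >= 2");
  int n_haps = haploid ? N : 2 * N;

  std::vector<Hap> pop(n_haps);  // monomorphic start
  Hap fixed_burnin;              // positions fixed before the split

  // optional seeded standing variation (diagnostics: drift-fate checks)
  for (int s = 0; s < init_freqs.size(); ++s) {
    int n_car = (int)std::floor(init_freqs[s] * n_haps + 0.5);
    IntegerVector perm = Rcpp::sample(n_haps, n_car, false);
    double pos = unif_rand() * L;
    for (int j = 0; j < n_car; ++j) {
      Hap &h = pop[perm[j] - 1];
      h.insert(std::lower_bound(h.begin(), h.end(), pos), pos);
    }
  }

  for (int g = 0; g < burnin_gens; ++g) {
    next_generation(pop, N, L, mu, rho, haploid);
    Hap fx = fixed_sites(pop);
    if (!fx.empty()) {
      strip_sites(pop, fx);
      fixed_burnin.insert(fixed_burnin.end(), fx.begin(), fx.end());
    }
    if (g % 64 == 0) Rcpp::checkUserInterrupt();
  }

  // random split into two demes of N/2 individuals each
  std::vector<Hap> deme1, deme2;
  {
    IntegerVector perm = Rcpp::sample(N, N, false);
    for (int i = 0; i < N; ++i) {
      std::vector<Hap> &dst = (i < N / 2) ? deme1 : deme2;
      int id = perm[i] - 1;
      if (haploid) {
        dst.push_back(pop[id]);
      } else {
        dst.push_back(pop[2 * id]);
        dst.push_back(pop[2 * id + 1]);
      }
    }
  }
  pop.clear();

  Hap fixed1, fixed2;  // per-deme fixed registries (post-split)
  List snapshots;
  CharacterVector snap_names;
  int total_post = growth_gens + stationary_gens;
  int half_N = N / 2;

  for (int g = 0; g < total_post; ++g) {
    // deme size schedule: N/2 + min(g+1, growth_gens) individuals
    int size_next = half_N + std::min(g + 1, growth_gens);
    next_generation(deme1, size_next, L, mu, rho, haploid);
    next_generation(deme2, size_next, L, mu, rho, haploid);
    int expect = haploid ? size_next : 2 * size_next;
    if ((int)deme1.size() != expect || (int)deme2.size() != expect)
      stop("deme size schedule violated");  // conservation assertion
    Hap fx1 = fixed_sites(deme1);
    if (!fx1.empty()) {
      strip_sites(deme1, fx1);
      fixed1.insert(fixed1.end(), fx1.begin(), fx1.end());
      std::sort(fixed1.begin(), fixed1.end());
    }
    Hap fx2 = fixed_sites(deme2);
    if (!fx2.empty()) {
      strip_sites(deme2, fx2);
      fixed2.insert(fixed2.end(), fx2.begin(), fx2.end());
      std::sort(fixed2.begin(), fixed2.end());
    }
    for (int s = 0; s < snapshot_gens.size(); ++s) {
      if (snapshot_gens[s] == g + 1) {
        snapshots.push_back(freq_table(deme1, fixed1, deme2, fixed2));
        snap_names.push_back(std::to_string(g + 1));
      }
    }
    if (g % 64 == 0) Rcpp::checkUserInterrupt();
  }
  snapshots.attr("names") = snap_names;

  DataFrame freqs = freq_table(deme1, fixed1, deme2, fixed2);
  return List::create(
      Named("freqs") = freqs, Named("snapshots") = snapshots,
      Named("n_haps_per_deme") = haploid ? N : 2 * N,
      Named("fixed_burnin") = NumericVector(fixed_burnin.begin(),
                                            fixed_burnin.end()));
}
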