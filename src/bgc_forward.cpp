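// Forward-time Wright-Fisher simulator of GC-biased gene conversion modeled
// as genic selection on haplotypes.  Without within-locus recombination the
// population is clonal, so it is represented as a set of haplotype classes
// (distinct mutation histories) with counts; per-generation work is a
// fitness-weighted multinomial over classes plus rare mutation events.
// All randomness goes through R's RNG so set.seed() controls everything.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct HapClass {
  std::vector<int> diffs;  // sites where state differs from the reference
  double w;                // multiplicative fitness
  int count;
};

// strong-allele state of a class at a site: ref XOR carries-diff
inline int state_at(const std::vector<int>& ref, const HapClass& h, int site) {
  bool d = std::binary_search(h.diffs.begin(), h.diffs.end(), site);
  return ref[site] ^ (d ? 1 : 0);
}

// fitness-weighted multinomial resampling of class counts to 2N offspring
void resample(std::vector<HapClass>& pop, int two_n) {
  // big classes first: the sequential conditional-binomial draw can stop
  // as soon as the remaining offspring count hits zero
  std::sort(pop.begin(), pop.end(),
            [](const HapClass& a, const HapClass& b) { return a.count > b.count; });
  const size_t K = pop.size();
  double tot = 0.0;
  for (const auto& h : pop) tot += h.count * h.w;
  int left = two_n;
  for (size_t i = 0; i < K; ++i) {
    if (i + 1 == K) {
      pop[i].count = left;
      break;
    }
    if (left == 0) {
      pop[i].count = 0;
      continue;
    }
    double wi = pop[i].count * pop[i].w;
    double p = (tot > 0) ? wi / tot : 0.0;
    if (p > 1.0) p = 1.0;
    int c = (int)R::rbinom((double)left, p);
    tot -= wi;
    pop[i].count = c;
    left -= c;
  }
  pop.erase(std::remove_if(pop.begin(), pop.end(),
                           [](const HapClass& h) { return h.count == 0; }),
            pop.end());
}

// mutate: flip one uniform site on one uniform haplotype copy
void mutate_one(std::vector<HapClass>& pop, const std::vector<int>& ref,
                int two_n, int L, double sd) {
  double u = R::runif(0.0, 1.0) * two_n;
  size_t ci = 0;
  double acc = 0.0;
  for (; ci < pop.size(); ++ci) {
    acc += pop[ci].count;
    if (u < acc) break;
  }
  if (ci >= pop.size()) ci = pop.size() - 1;
  int site = (int)(R::runif(0.0, 1.0) * L);
  if (site >= L) site = L - 1;
  HapClass child = pop[ci];
  child.count = 1;
  pop[ci].count -= 1;
  int before = state_at(ref, child, site);
  auto it = std::lower_bound(child.diffs.begin(), child.diffs.end(), site);
  if (it != child.diffs.end() && *it == site) child.diffs.erase(it);
  else child.diffs.insert(it, site);
  double eff = std::fabs(R::rnorm(0.0, sd));
  // weak -> strong gains fitness, strong -> weak loses it
  child.w *= (before == 0) ? (1.0 + eff) : std::max(1e-12, 1.0 - eff);
  if (pop[ci].count == 0) pop.erase(pop.begin() + ci);
  pop.push_back(child);
}

void evolve(std::vector<HapClass>& pop, const std::vector<int>& ref,
            int two_n, int L, double mu_hap, double sd, long gens) {
  for (long g = 0; g < gens; ++g) {
    resample(pop, two_n);
    int n_mut = (int)R::rbinom((double)two_n, mu_hap);
    for (int m = 0; m < n_mut; ++m) mutate_one(pop, ref, two_n, L, sd);
    // keep fitnesses in a safe numeric range
    if ((g & 1023) == 0) {
      double wmax = 0.0;
      for (const auto& h : pop) wmax = std::max(wmax, h.w);
      if (wmax > 1e100 || (wmax > 0 && wmax < 1e-100)) {
        for (auto& h : pop) h.w /= wmax;
      }
    }
  }
}

// strong-allele count per site over the whole population (sites in `sites`)
std::vector<int> strong_counts(const std::vector<HapClass>& pop,
                               const std::vector<int>& ref,
                               const std::vector<int>& sites) {
  std::vector<int> out(sites.size(), 0);
  for (const auto& h : pop) {
    for (size_t s = 0; s < sites.size(); ++s) {
      if (state_at(ref, h, sites[s])) out[s] += h.count;
    }
  }
  return out;
}

// sample m haplotype copies without replacement; returns per-class take
std::vector<int> sample_classes(const std::vector<HapClass>& pop, int two_n,
                                int m) {
  std::vector<int> take(pop.size(), 0);
  int left_pop = two_n, left_m = m;
  for (size_t i = 0; i < pop.size() && left_m > 0; ++i) {
    // multivariate hypergeometric via sequential binomial-like draws
    int c = (int)R::rhyper((double)pop[i].count,
                           (double)(left_pop - pop[i].count), (double)left_m);
    take[i] = c;
    left_m -= c;
    left_pop -= pop[i].count;
  }
  return take;
}

std::vector<int> union_sites(const std::vector<HapClass>& pop,
                             const std::vector<int>& take) {
  std::vector<int> sites;
  for (size_t i = 0; i < pop.size(); ++i) {
    if (take[i] > 0) {
      sites.insert(sites.end(), pop[i].diffs.begin(), pop[i].diffs.end());
    }
  }
  std::sort(sites.begin(), sites.end());
  sites.erase(std::unique(sites.begin(), sites.end()), sites.end());
  return sites;
}

}  // namespace

// [[Rcpp::export(name = ".bgc_forward_cpp")]]
List bgc_forward_cpp(int N, double theta_locus, double scaled_bgc, int L,
                     double burnin_units, double split_units, int n_human,
                     int n_chimp, double fitness_sd) {
  if (N < 2 || L < 1) stop("invalid population size or locus length");
  if ((double)L * (double)N > 2e9) stop("L x N exceeds the memory guard");
  const int two_n = 2 * N;
  const double mu_hap = theta_locus / (4.0 * N);  // per haplotype per gen
  double sd = fitness_sd;
  if (sd <= 0.0) {
    // mean |effect| of sqrt(2/pi)*sd scaled by 4N equals scaled_bgc
    sd = scaled_bgc / (4.0 * N) * std::sqrt(M_PI / 2.0);
  }
  const long burnin_gens = (long)std::llround(burnin_units * N);
  const long split_gens = (long)std::llround(split_units * 4.0 * N);

  // reference sequence: initial strong-allele states, GC content 1/2
  std::vector<int> ref(L);
  for (int i = 0; i < L; ++i) ref[i] = (R::unif_rand() < 0.5) ? 1 : 0;

  std::vector<HapClass> pop{HapClass{{}, 1.0, two_n}};
  evolve(pop, ref, two_n, L, mu_hap, sd, burnin_gens);

  // record the population-majority state at the split as the ancestral state
  std::vector<int> seg_sites;
  for (const auto& h : pop) {
    seg_sites.insert(seg_sites.end(), h.diffs.begin(), h.diffs.end());
  }
  std::sort(seg_sites.begin(), seg_sites.end());
  seg_sites.erase(std::unique(seg_sites.begin(), seg_sites.end()),
                  seg_sites.end());
  std::vector<int> split_state = ref;  // differs only at segregating sites
  {
    std::vector<int> cnt = strong_counts(pop, ref, seg_sites);
    for (size_t s = 0; s < seg_sites.size(); ++s) {
      int strong = cnt[s];
      int weak = two_n - strong;
      split_state[seg_sites[s]] =
          (strong > weak) ? 1 : (strong < weak ? 0 : (R::unif_rand() < 0.5));
    }
  }

  std::vector<HapClass> human = pop, chimp = pop;  // vicariance event
  evolve(human, ref, two_n, L, mu_hap, sd, split_gens);
  evolve(chimp, ref, two_n, L, mu_hap, sd, split_gens);

  std::vector<int> take_h = sample_classes(human, two_n, n_human);
  std::vector<int> take_c = sample_classes(chimp, two_n, n_chimp);
  std::vector<int> sites = union_sites(human, take_h);
  {
    std::vector<int> cs = union_sites(chimp, take_c);
    sites.insert(sites.end(), cs.begin(), cs.end());
    std::sort(sites.begin(), sites.end());
    sites.erase(std::unique(sites.begin(), sites.end()), sites.end());
  }

  const size_t M = sites.size();
  IntegerVector site_id(M), human_strong(M), chimp_strong(M), anc_state(M);
  std::vector<int> hcnt(M, 0), ccnt(M, 0);
  for (size_t i = 0; i < human.size(); ++i) {
    if (take_h[i] == 0) continue;
    for (size_t s = 0; s < M; ++s) {
      if (state_at(ref, human[i], sites[s])) hcnt[s] += take_h[i];
    }
  }
  for (size_t i = 0; i < chimp.size(); ++i) {
    if (take_c[i] == 0) continue;
    for (size_t s = 0; s < M; ++s) {
      if (state_at(ref, chimp[i], sites[s])) ccnt[s] += take_c[i];
    }
  }
  double gc = 0.0;
  {
    std::vector<int> all(L);
    for (int i = 0; i < L; ++i) all[i] = i;
    std::vector<int> cnt = strong_counts(human, ref, all);
    long tot = 0;
    for (int i = 0; i < L; ++i) tot += cnt[i];
    gc = (double)tot / ((double)two_n * L);
  }
  for (size_t s = 0; s < M; ++s) {
    site_id[s] = sites[s];
    human_strong[s] = hcnt[s];
    chimp_strong[s] = ccnt[s];
    anc_state[s] = split_state[sites[s]];
  }
  return List::create(_["site"] = site_id, _["human_strong"] = human_strong,
                      _["chimp_strong"] = chimp_strong,
                      _["split_state"] = anc_state,
                      _["n_human"] = n_human, _["n_chimp"] = n_chimp,
                      _["gc_content"] = gc);
}

// Single-site Wright-Fisher fixation trials under genic selection s,
// starting from one mutant copy.  Returns the number of fixations.
// [[Rcpp::export(name = ".wf_fixation_cpp")]]
int wf_fixation_cpp(int N, double s, int n_trials) {
  if (N < 1 || n_trials < 1) stop("invalid arguments");
  const int two_n = 2 * N;
  int fixed = 0;
  for (int t = 0; t < n_trials; ++t) {
    int k = 1;
    while (k > 0 && k < two_n) {
      double p = k * (1.0 + s) / (k * (1.0 + s) + (two_n - k));
      k = (int)R::rbinom((double)two_n, p);
    }
    if (k == two_n) ++fixed;
  }
  return fixed;
}
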