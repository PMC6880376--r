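// Forward Wright-Fisher simulator with infinite-sites mutation, uniform
// crossover recombination, star-like population splits and an optional
// additive hard sweep. Uses R's RNG so results are reproducible via
// set.seed() on the R side.
#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<int> Hap;            // sorted positions carrying derived allele
typedef std::vector<Hap> Pop;            // 2N haplotypes; diploid i owns rows 2i, 2i+1

static bool has_pos(const Hap &h, int pos) {
  return std::binary_search(h.begin(), h.end(), pos);
}

// Produce one gamete from diploid parent (a, b): recombine, then mutate.
static Hap make_gamete(const Hap &a, const Hap &b, double rec_total,
                       double mu_total, int seq_len,
                       std::unordered_set<int> &used) {
  const Hap *cur = (unif_rand() < 0.5) ? &a : &b;
  const Hap *oth = (cur == &a) ? &b : &a;
  Hap g;
  int k = (int) R::rpois(rec_total);
  if (k == 0) {
    g = *cur;
  } else {
    std::vector<int> bp(k);
    for (int i = 0; i < k; ++i) bp[i] = 1 + (int) (unif_rand() * (seq_len - 1));
    std::sort(bp.begin(), bp.end());
    bp.push_back(seq_len);
    g.reserve(cur->size() + oth->size());
    int lo = 1;
    for (size_t s = 0; s < bp.size(); ++s) {
      int hi = bp[s];
      if (hi >= lo) {
        Hap::const_iterator it0 =
            std::lower_bound(cur->begin(), cur->end(), lo);
        Hap::const_iterator it1 =
            std::upper_bound(cur->begin(), cur->end(), hi);
        g.insert(g.end(), it0, it1);
      }
      std::swap(cur, oth);
      lo = hi + 1;
    }
  }
  int m = (int) R::rpois(mu_total);
  for (int i = 0; i < m; ++i) {
    int pos = 0, tries = 0;
    do {
      pos = 1 + (int) (unif_rand() * seq_len);
      if (pos > seq_len) pos = seq_len;
      if (++tries > 1000) { pos = 0; break; }  // position space saturated
    } while (used.count(pos));
    if (pos == 0) continue;
    used.insert(pos);
    Hap::iterator it = std::lower_bound(g.begin(), g.end(), pos);
    g.insert(it, pos);
  }
  return g;
}

// One neutral (or selected) WF generation. Selection is additive on the
// count of the beneficial allele at sweep_pos: fitness 1, 1+s, 1+2s.
static Pop next_generation(const Pop &pop, int n_offspring, double rec_total,
                           double mu_total, int seq_len,
                           std::unordered_set<int> &used, bool selected,
                           int sweep_pos, double s) {
  int n_par = (int) pop.size() / 2;
  std::vector<double> w;
  double wmax = 1.0;
  if (selected) {
    w.resize(n_par);
    for (int i = 0; i < n_par; ++i) {
      int g = (has_pos(pop[2 * i], sweep_pos) ? 1 : 0) +
              (has_pos(pop[2 * i + 1], sweep_pos) ? 1 : 0);
      w[i] = 1.0 + s * g;
    }
    wmax = 1.0 + 2.0 * s;
  }
  Pop nxt;
  nxt.reserve(2 * n_offspring);
  for (int i = 0; i < n_offspring; ++i) {
    for (int par = 0; par < 2; ++par) {
      int p;
      if (selected) {
        do {
          p = (int) (unif_rand() * n_par);
          if (p >= n_par) p = n_par - 1;
        } while (unif_rand() * wmax > w[p]);
      } else {
        p = (int) (unif_rand() * n_par);
        if (p >= n_par) p = n_par - 1;
      }
      nxt.push_back(make_gamete(pop[2 * p], pop[2 * p + 1], rec_total,
                                mu_total, seq_len, used));
    }
  }
  return nxt;
}

static double allele_freq(const Pop &pop, int pos) {
  int c = 0;
  for (size_t i = 0; i < pop.size(); ++i)
    if (has_pos(pop[i], pos)) ++c;
  return (double) c / (double) pop.size();
}

static void add_pop_positions(std::unordered_set<int> &s, const Pop &pop) {
  for (size_t h = 0; h < pop.size(); ++h)
    s.insert(pop[h].begin(), pop[h].end());
}

// The infinite-sites reservation set must only contain positions that are
// still segregating somewhere (plus reserved ones); extinct mutations free
// their positions. Rebuilding whenever the set grows past a quarter of the
// position space keeps collision redraws cheap without rebuilding (an
// O(population) pass) every generation.
static void rebuild_used(std::unordered_set<int> &used,
                         const std::unordered_set<int> &base,
                         const Pop &current) {
  used = base;
  add_pop_positions(used, current);
}

static inline bool needs_rebuild(const std::unordered_set<int> &used,
                                 int seq_len) {
  return (int) used.size() > seq_len / 4;
}

// [[Rcpp::export]]
List wf_simulate_cpp(int n_anc, IntegerVector pop_sizes,
                     IntegerVector split_gens, IntegerVector n_sample,
                     int seq_len, double mu, double rec, int burnin,
                     int sweep_pop, int sweep_pos, double sweep_s,
                     int sweep_gen, double sweep_min_freq,
                     int sweep_max_attempts) {
  RNGScope scope;
  int npop = pop_sizes.size();
  double mu_total = mu * seq_len;
  double rec_total = rec * seq_len;
  std::unordered_set<int> reserved;
  if (sweep_pop >= 0) reserved.insert(sweep_pos);  // never hit by neutral mutation
  std::unordered_set<int> used = reserved;

  // Ancestral burn-in from a monomorphic start.
  Pop anc(2 * n_anc);
  for (int g = 0; g < burnin; ++g) {
    anc = next_generation(anc, n_anc, rec_total, mu_total, seq_len, used,
                          false, 0, 0.0);
    if (needs_rebuild(used, seq_len)) rebuild_used(used, reserved, anc);
  }

  // Found each daughter population from the same ancestral snapshot and let
  // it drift (and sweep, for the focal one) independently.
  std::vector<Pop> pops(npop);
  int attempts_used = 0;
  double final_freq = NA_REAL;
  // Positions that must stay reserved while evolving population p: the
  // sweep site, the ancestral snapshot (future founders) and the final
  // states of populations already evolved.
  std::unordered_set<int> base = reserved;
  add_pop_positions(base, anc);
  for (int p = 0; p < npop; ++p) {
    Pop founders;
    if (pop_sizes[p] == n_anc) {
      founders = anc;  // exact copy: split_gens = 0 means identical daughters
    } else {
      founders.reserve(2 * pop_sizes[p]);
      for (int i = 0; i < pop_sizes[p]; ++i) {
        int j = (int) (unif_rand() * n_anc);
        if (j >= n_anc) j = n_anc - 1;
        founders.push_back(anc[2 * j]);
        founders.push_back(anc[2 * j + 1]);
      }
    }
    bool is_focal = (p == sweep_pop);
    rebuild_used(used, base, founders);
    if (!is_focal) {
      Pop cur = founders;
      for (int g = 0; g < split_gens[p]; ++g) {
        cur = next_generation(cur, pop_sizes[p], rec_total, mu_total, seq_len,
                              used, false, 0, 0.0);
        if (needs_rebuild(used, seq_len)) rebuild_used(used, base, cur);
      }
      pops[p] = cur;
    } else {
      // Sweep with re-introduction on loss, up to sweep_max_attempts.
      // A lost allele never recurs (sweep_pos is reserved), so selection is
      // inert after loss and each attempt can safely run to completion.
      int max_att = std::max(1, sweep_max_attempts);
      for (int att = 1; att <= max_att; ++att) {
        attempts_used = att;
        Pop cur = founders;
        rebuild_used(used, base, cur);
        bool introduced = false;
        for (int g = 0; g < split_gens[p]; ++g) {
          if (!introduced && g == sweep_gen) {
            int h = (int) (unif_rand() * cur.size());
            if (h >= (int) cur.size()) h = (int) cur.size() - 1;
            Hap::iterator it =
                std::lower_bound(cur[h].begin(), cur[h].end(), sweep_pos);
            cur[h].insert(it, sweep_pos);
            introduced = true;
          }
          cur = next_generation(cur, pop_sizes[p], rec_total, mu_total,
                                seq_len, used, introduced, sweep_pos, sweep_s);
          if (needs_rebuild(used, seq_len)) rebuild_used(used, base, cur);
        }
        double f = introduced ? allele_freq(cur, sweep_pos) : 0.0;
        if ((f > 0.0 && f >= sweep_min_freq) || att == max_att) {
          pops[p] = cur;
          final_freq = f;
          break;
        }
      }
    }
    add_pop_positions(base, pops[p]);
  }

  // Sample n_sample diploids per population (without replacement).
  std::vector<Pop> samples(npop);
  for (int p = 0; p < npop; ++p) {
    int N = pop_sizes[p], k = n_sample[p];
    std::vector<int> idx(N);
    for (int i = 0; i < N; ++i) idx[i] = i;
    for (int i = 0; i < k; ++i) {
      int j = i + (int) (unif_rand() * (N - i));
      if (j >= N) j = N - 1;
      std::swap(idx[i], idx[j]);
    }
    samples[p].reserve(2 * k);
    for (int i = 0; i < k; ++i) {
      samples[p].push_back(pops[p][2 * idx[i]]);
      samples[p].push_back(pops[p][2 * idx[i] + 1]);
    }
  }

  // Union of positions, kept only if segregating in the combined sample.
  std::unordered_set<int> seen;
  std::vector<int> all_pos;
  int tot_haps = 0;
  for (int p = 0; p < npop; ++p) {
    tot_haps += (int) samples[p].size();
    for (size_t h = 0; h < samples[p].size(); ++h)
      for (size_t i = 0; i < samples[p][h].size(); ++i)
        if (seen.insert(samples[p][h][i]).second)
          all_pos.push_back(samples[p][h][i]);
  }
  std::sort(all_pos.begin(), all_pos.end());
  std::vector<int> keep;
  for (size_t i = 0; i < all_pos.size(); ++i) {
    int c = 0;
    for (int p = 0; p < npop; ++p)
      for (size_t h = 0; h < samples[p].size(); ++h)
        if (has_pos(samples[p][h], all_pos[i])) ++c;
    if (c > 0 && c < tot_haps) keep.push_back(all_pos[i]);
  }

  int S = (int) keep.size();
  List hap_out(npop);
  for (int p = 0; p < npop; ++p) {
    int nh = (int) samples[p].size();
    IntegerMatrix M(S, nh);
    for (int h = 0; h < nh; ++h)
      for (int i = 0; i < S; ++i)
        M(i, h) = has_pos(samples[p][h], keep[i]) ? 1 : 0;
    hap_out[p] = M;
  }
  double pop_freq = NA_REAL;
  if (sweep_pop >= 0) pop_freq = final_freq;
  return List::create(_["positions"] = wrap(keep), _["haplotypes"] = hap_out,
                      _["sweep_final_freq"] = pop_freq,
                      _["sweep_attempts"] = attempts_used);
}
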