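// Wright-Fisher generation loop for diploid and autotetraploid
// populations with fully recessive multiplicative fitness.
//
// Semantics mirror the reference R implementations in R/meiosis.R and
// R/population.R (the test suite cross-checks the two routes):
//   - haplotype = vector of mutation ids (1-based), sorted by (pos, id);
//   - homozygosity is by mutation identity, never by position;
//   - crossovers: Poisson(rho*L) hits on the L-1 inter-base boundaries,
//     boundaries hit an even number of times cancel;
//   - tetraploid meiosis: one of the 3 bivalent matchings uniformly,
//     each bivalent contributes one recombinant chromosome (fair
//     chromatid coin), so gametes carry 2 chromosomes;
//   - new mutations: Poisson(mu*L) per gamete chromosome, uniform
//     positions in [0, L);
//   - fixed mutations are removed each generation and counted as
//     substitutions, so fitness reflects segregating load only.
//
// All randomness flows through R's RNG, so runs are reproducible from
// set.seed() on the R side.

#include <Rcpp.h>
#include <algorithm>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

typedef std::vector<int> Hap;  // mutation ids, 1-based, sorted by (pos, id)

struct Registry {
  std::vector<double> pos;
  std::vector<double> sel;
  std::vector<int> origin;
  int add(double p, double s, int gen) {
    pos.push_back(p);
    sel.push_back(s);
    origin.push_back(gen);
    return static_cast<int>(pos.size());  // 1-based id
  }
  bool less(int a, int b) const {
    double pa = pos[a - 1], pb = pos[b - 1];
    if (pa != pb) return pa < pb;
    return a < b;
  }
};

static void intersect_sorted(const Registry& reg, const Hap& a, const Hap& b,
                             Hap& out) {
  out.clear();
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) {
      out.push_back(a[i]);
      ++i;
      ++j;
    } else if (reg.less(a[i], b[j])) {
      ++i;
    } else {
      ++j;
    }
  }
}

// fitness of the individual whose copies are haps[first .. first+ploidy)
static double individual_fitness(const Registry& reg,
                                 const std::vector<Hap>& haps, int first,
                                 int ploidy, Hap& buf1, Hap& buf2) {
  buf1 = haps[first];
  for (int j = 1; j < ploidy && !buf1.empty(); ++j) {
    intersect_sorted(reg, buf1, haps[first + j], buf2);
    buf1.swap(buf2);
  }
  double w = 1.0;
  for (int id : buf1) w *= (1.0 + reg.sel[id - 1]);
  return w;
}

// Poisson(rho*L) boundary hits in [1, L-1]; boundaries hit an even number
// of times cancel; result strictly increasing
static void draw_breakpoints(double rho, double L, std::vector<int>& bp) {
  bp.clear();
  int n = static_cast<int>(R::rpois(rho * L));
  if (n <= 0 || L <= 1) return;
  for (int i = 0; i < n; ++i)
    bp.push_back(1 + static_cast<int>(unif_rand() * (L - 1.0)));
  std::sort(bp.begin(), bp.end());
  std::vector<int> odd;
  size_t i = 0;
  while (i < bp.size()) {
    size_t j = i;
    while (j < bp.size() && bp[j] == bp[i]) ++j;
    if ((j - i) % 2 == 1) odd.push_back(bp[i]);
    i = j;
  }
  bp.swap(odd);
}

// copy from A/B alternating at breakpoints; start 0 = A; position p lies
// left of breakpoint b iff p < b
static void recombine_haps(const Registry& reg, const Hap& A, const Hap& B,
                           const std::vector<int>& bp, int start, Hap& out) {
  out.clear();
  if (bp.empty()) {
    out = (start == 0) ? A : B;
    return;
  }
  size_t iA = 0, iB = 0;
  int src = start;
  for (size_t seg = 0; seg <= bp.size(); ++seg) {
    double segend = (seg < bp.size()) ? static_cast<double>(bp[seg])
                                      : R_PosInf;
    const Hap& S = (src == 0) ? A : B;
    const Hap& O = (src == 0) ? B : A;
    size_t& iS = (src == 0) ? iA : iB;
    size_t& iO = (src == 0) ? iB : iA;
    while (iS < S.size() && reg.pos[S[iS] - 1] < segend) {
      out.push_back(S[iS]);
      ++iS;
    }
    while (iO < O.size() && reg.pos[O[iO] - 1] < segend) ++iO;
    src = 1 - src;
  }
}

static void mutate_hap(Registry& reg, Hap& h, double mu, double L, double snew,
                       int gen) {
  int k = static_cast<int>(R::rpois(mu * L));
  for (int i = 0; i < k; ++i) {
    double p = std::floor(unif_rand() * L);
    if (p >= L) p = L - 1;
    int id = reg.add(p, snew, gen);
    Hap::iterator it = h.begin();
    while (it != h.end() && reg.less(*it, id)) ++it;
    h.insert(it, id);
  }
}

// the three perfect matchings of copies {0,1,2,3} into two bivalents
static const int MATCHINGS[3][4] = {{0, 1, 2, 3}, {0, 2, 1, 3}, {0, 3, 1, 2}};

// append the 1 (diploid) or 2 (tetraploid) gamete chromosomes of the
// parent at haps[first ..] into 'dest'
static void make_gamete_cpp(Registry& reg, const std::vector<Hap>& haps,
                            int first, int ploidy, double mu, double rho,
                            double L, double snew, int gen,
                            std::vector<Hap>& dest, std::vector<int>& bpbuf) {
  if (ploidy == 2) {
    draw_breakpoints(rho, L, bpbuf);
    int start = (unif_rand() < 0.5) ? 0 : 1;
    dest.push_back(Hap());
    recombine_haps(reg, haps[first], haps[first + 1], bpbuf, start,
                   dest.back());
    mutate_hap(reg, dest.back(), mu, L, snew, gen);
  } else {
    int m = static_cast<int>(unif_rand() * 3.0);
    if (m > 2) m = 2;
    for (int b = 0; b < 2; ++b) {
      int c1 = first + MATCHINGS[m][2 * b];
      int c2 = first + MATCHINGS[m][2 * b + 1];
      draw_breakpoints(rho, L, bpbuf);
      int start = (unif_rand() < 0.5) ? 0 : 1;
      dest.push_back(Hap());
      recombine_haps(reg, haps[c1], haps[c2], bpbuf, start, dest.back());
      mutate_hap(reg, dest.back(), mu, L, snew, gen);
    }
  }
}

static int sample_parent(const std::vector<double>& cumw) {
  double u = unif_rand() * cumw.back();
  return static_cast<int>(std::lower_bound(cumw.begin(), cumw.end(), u) -
                          cumw.begin());
}

static Registry registry_from_r(NumericVector pos, NumericVector s,
                                IntegerVector origin) {
  Registry reg;
  reg.pos.assign(pos.begin(), pos.end());
  reg.sel.assign(s.begin(), s.end());
  reg.origin.assign(origin.begin(), origin.end());
  return reg;
}

static std::vector<Hap> haps_from_r(List haps_in) {
  std::vector<Hap> haps(haps_in.size());
  for (int i = 0; i < haps_in.size(); ++i) {
    IntegerVector h = haps_in[i];
    haps[i].assign(h.begin(), h.end());
  }
  return haps;
}

static List haps_to_r(const std::vector<Hap>& haps) {
  List out(haps.size());
  for (size_t i = 0; i < haps.size(); ++i)
    out[i] = IntegerVector(haps[i].begin(), haps[i].end());
  return out;
}

// R-convention median of a vector of counts (modified in place)
static double median_of(std::vector<double>& v) {
  if (v.empty()) return 0.0;
  std::sort(v.begin(), v.end());
  size_t n = v.size();
  if (n % 2 == 1) return v[n / 2];
  return 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// [[Rcpp::export]]
List engine_run(List haps_in, NumericVector pos_in, NumericVector s_in,
                IntegerVector origin_in, int N, int ploidy, double L,
                double mu, double rho, double s_new, int generations,
                bool selfing, IntegerVector snapshot_gens,
                int start_generation, int substitutions0) {
  Registry reg = registry_from_r(pos_in, s_in, origin_in);
  std::vector<Hap> pop = haps_from_r(haps_in);
  if (static_cast<int>(pop.size()) != N * ploidy)
    stop("population has wrong number of haplotypes");

  std::unordered_set<int> snap_set(snapshot_gens.begin(),
                                   snapshot_gens.end());
  List snapshots;
  CharacterVector snap_names;

  NumericMatrix traj(generations, 7);
  Hap buf1, buf2;
  std::vector<int> bpbuf;
  int substitutions = substitutions0;

  // fitness of the current (parent) generation
  std::vector<double> w(N);
  for (int i = 0; i < N; ++i)
    w[i] = individual_fitness(reg, pop, i * ploidy, ploidy, buf1, buf2);

  std::vector<Hap> child;
  child.reserve(N * ploidy);

  for (int g = 1; g <= generations; ++g) {
    checkUserInterrupt();
    int gen_abs = start_generation + g;

    std::vector<double> cumw(N);
    double acc = 0.0;
    for (int i = 0; i < N; ++i) {
      acc += w[i];
      cumw[i] = acc;
    }
    if (!(acc > 0.0)) stop("degenerate population: total fitness is zero");

    child.clear();
    double parent_fit_sum = 0.0;
    for (int i = 0; i < N; ++i) {
      int p1 = sample_parent(cumw);
      int p2 = sample_parent(cumw);
      if (!selfing && N > 1) {
        while (p2 == p1) p2 = sample_parent(cumw);
      }
      parent_fit_sum += w[p1] + w[p2];
      make_gamete_cpp(reg, pop, p1 * ploidy, ploidy, mu, rho, L, s_new,
                      gen_abs, child, bpbuf);
      make_gamete_cpp(reg, pop, p2 * ploidy, ploidy, mu, rho, L, s_new,
                      gen_abs, child, bpbuf);
    }

    // carrier counts; remove fixed mutations (substitutions)
    std::unordered_map<int, int> counts;
    for (const Hap& h : child)
      for (int id : h) ++counts[id];
    int total = N * ploidy;
    std::unordered_set<int> fixed;
    for (std::unordered_map<int, int>::iterator it = counts.begin();
         it != counts.end(); ++it)
      if (it->second == total) fixed.insert(it->first);
    if (!fixed.empty()) {
      for (Hap& h : child)
        h.erase(std::remove_if(h.begin(), h.end(),
                               [&](int id) { return fixed.count(id) > 0; }),
                h.end());
      substitutions += static_cast<int>(fixed.size());
    }

    std::vector<double> freqs;
    freqs.reserve(counts.size());
    for (std::unordered_map<int, int>::iterator it = counts.begin();
         it != counts.end(); ++it)
      if (fixed.count(it->first) == 0)
        freqs.push_back(static_cast<double>(it->second) / total);
    int n_seg = static_cast<int>(freqs.size());
    double med_freq = median_of(freqs);

    pop.swap(child);
    for (int i = 0; i < N; ++i)
      w[i] = individual_fitness(reg, pop, i * ploidy, ploidy, buf1, buf2);

    double mean_w = 0.0;
    for (int i = 0; i < N; ++i) mean_w += w[i];
    mean_w /= N;
    double ss = 0.0;
    for (int i = 0; i < N; ++i) ss += (w[i] - mean_w) * (w[i] - mean_w);
    double sd_w = (N > 1) ? std::sqrt(ss / (N - 1)) : 0.0;

    traj(g - 1, 0) = gen_abs;
    traj(g - 1, 1) = mean_w;
    traj(g - 1, 2) = sd_w;
    traj(g - 1, 3) = parent_fit_sum / (2.0 * N);
    traj(g - 1, 4) = med_freq;
    traj(g - 1, 5) = n_seg;
    traj(g - 1, 6) = substitutions;

    if (snap_set.count(gen_abs)) {
      snapshots.push_back(NumericVector(w.begin(), w.end()));
      snap_names.push_back(std::to_string(gen_abs));
    }
  }

  snapshots.attr("names") = snap_names;
  return List::create(
      _["haplotypes"] = haps_to_r(pop),
      _["pos"] = NumericVector(reg.pos.begin(), reg.pos.end()),
      _["s"] = NumericVector(reg.sel.begin(), reg.sel.end()),
      _["origin"] = IntegerVector(reg.origin.begin(), reg.origin.end()),
      _["substitutions"] = substitutions, _["trajectory"] = traj,
      _["snapshots"] = snapshots);
}

// Fitness values of a virtual offspring cohort sampled by the standard
// reproduction rules, without replacing the population.  New mutations
// arising in these gametes stay local to the cohort.
// [[Rcpp::export]]
NumericVector engine_offspring(List haps_in, NumericVector pos_in,
                               NumericVector s_in, IntegerVector origin_in,
                               int N, int ploidy, double L, double mu,
                               double rho, double s_new, int n_offspring,
                               bool selfing, int generation) {
  Registry reg = registry_from_r(pos_in, s_in, origin_in);
  std::vector<Hap> pop = haps_from_r(haps_in);
  if (static_cast<int>(pop.size()) != N * ploidy)
    stop("population has wrong number of haplotypes");

  Hap buf1, buf2;
  std::vector<int> bpbuf;
  std::vector<double> cumw(N);
  double acc = 0.0;
  for (int i = 0; i < N; ++i) {
    acc += individual_fitness(reg, pop, i * ploidy, ploidy, buf1, buf2);
    cumw[i] = acc;
  }
  if (!(acc > 0.0)) stop("degenerate population: total fitness is zero");

  NumericVector out(n_offspring);
  std::vector<Hap> child;
  for (int i = 0; i < n_offspring; ++i) {
    checkUserInterrupt();
    int p1 = sample_parent(cumw);
    int p2 = sample_parent(cumw);
    if (!selfing && N > 1) {
      while (p2 == p1) p2 = sample_parent(cumw);
    }
    child.clear();
    make_gamete_cpp(reg, pop, p1 * ploidy, ploidy, mu, rho, L, s_new,
                    generation, child, bpbuf);
    make_gamete_cpp(reg, pop, p2 * ploidy, ploidy, mu, rho, L, s_new,
                    generation, child, bpbuf);
    out[i] = individual_fitness(reg, child, 0, ploidy, buf1, buf2);
  }
  return out;
}
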