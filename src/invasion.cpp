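// Individual-based P-element invasion engine.
//
// Diploid genomes are stored as two position-sorted insertion lists per
// individual. Positions are integer base pairs encoded as doubles on a
// concatenated coordinate axis (chromosome c spans [c*L, (c+1)*L)).
// All randomness goes through R's RNG so set.seed() in R makes every
// simulation reproducible.

#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct Layout {
  int n_chrom;
  double chrom_len, recomb, cluster_len, genome_len;
  // piRNA cluster occupies the high-coordinate end of each chromosome
  bool in_cluster(double pos) const {
    if (cluster_len <= 0) return false;
    double off = pos - chrom_len * std::floor(pos / chrom_len);
    return off >= chrom_len - cluster_len;
  }
};

static Layout as_layout(const List& l) {
  Layout L;
  L.n_chrom = as<int>(l["n_chromosomes"]);
  L.chrom_len = as<double>(l["chrom_length"]);
  L.recomb = as<double>(l["recomb_rate"]);
  L.cluster_len = as<double>(l["cluster_len"]);
  L.genome_len = L.n_chrom * L.chrom_len;
  return L;
}

struct Ins { double pos; double s; };
static inline bool ins_lt(const Ins& a, const Ins& b) { return a.pos < b.pos; }
typedef std::vector<Ins> Hap;

struct Ind {
  Hap h[2];
  double w;       // cached relative fitness (set at birth; constant afterwards)
  bool silenced;  // true iff any insertion lies in a piRNA cluster
};

// magnitude of s drawn from Beta(alpha, beta); alpha <= 0 encodes a fully
// neutral DFE (point mass at 0)
static inline double draw_s(double alpha, double beta) {
  if (alpha <= 0) return 0.0;
  return -R::rbeta(alpha, beta);
}

static inline bool pos_lt(const Ins& a, double v) { return a.pos < v; }

// haplotypes are position-sorted, so per-chromosome cluster occupancy is a
// binary search for an insertion in [chrom_end - cluster_len, chrom_end)
static bool any_cluster(const Ind& ind, const Layout& L) {
  if (L.cluster_len <= 0) return false;
  for (int k = 0; k < 2; ++k) {
    const Hap& h = ind.h[k];
    for (int c = 0; c < L.n_chrom; ++c) {
      double hi = (c + 1) * L.chrom_len;
      auto it = std::lower_bound(h.begin(), h.end(), hi - L.cluster_len,
                                 pos_lt);
      if (it != h.end() && it->pos < hi) return true;
    }
  }
  return false;
}

// multiplicative fitness: (1 + h*s) per heterozygous locus, (1 + s) per
// homozygous locus (counted once); cluster loci have s = 0 so contribute 1
static double calc_fitness(const Ind& ind, double h, double floor_w,
                           long* n_floored) {
  double w = 1.0;
  const Hap& a = ind.h[0];
  const Hap& b = ind.h[1];
  size_t i = 0, j = 0;
  while (i < a.size() || j < b.size()) {
    if (j >= b.size() || (i < a.size() && a[i].pos < b[j].pos)) {
      w *= 1.0 + h * a[i].s; ++i;
    } else if (i >= a.size() || b[j].pos < a[i].pos) {
      w *= 1.0 + h * b[j].s; ++j;
    } else {                       // same position on both haplotypes
      w *= 1.0 + a[i].s; ++i; ++j;
    }
  }
  if (w < floor_w) { w = floor_w; if (n_floored) ++(*n_floored); }
  return w;
}

static void finalize(Ind& ind, const Layout& L, double h, double floor_w,
                     long* n_floored) {
  for (int k = 0; k < 2; ++k)
    if (!std::is_sorted(ind.h[k].begin(), ind.h[k].end(), ins_lt))
      std::sort(ind.h[k].begin(), ind.h[k].end(), ins_lt);
  ind.silenced = any_cluster(ind, L);
  ind.w = calc_fitness(ind, h, floor_w, n_floored);
}

// one recombinant gamete; crossovers are a Poisson process along each
// chromosome, chromosomes assort independently
static Hap gamete(const Ind& p, const Layout& L) {
  Hap g;
  g.reserve((p.h[0].size() + p.h[1].size()) / 2 + 4);
  for (int c = 0; c < L.n_chrom; ++c) {
    double lo = c * L.chrom_len, hi = lo + L.chrom_len;
    int k = (L.recomb > 0) ? (int) R::rpois(L.chrom_len * L.recomb) : 0;
    std::vector<double> br((size_t) k);
    for (int t = 0; t < k; ++t) br[t] = lo + R::unif_rand() * L.chrom_len;
    std::sort(br.begin(), br.end());
    int start = (R::unif_rand() < 0.5) ? 0 : 1;
    size_t g0 = g.size();
    for (int hp = 0; hp < 2; ++hp) {
      const Hap& H = p.h[hp];
      auto it = std::lower_bound(H.begin(), H.end(), lo, pos_lt);
      size_t mark = g.size();
      if (k == 0) {                       // whole chromosome from one parent
        if (start == hp)
          for (; it != H.end() && it->pos < hi; ++it) g.push_back(*it);
      } else {
        for (; it != H.end() && it->pos < hi; ++it) {
          int seg = (int)(std::upper_bound(br.begin(), br.end(), it->pos) -
                          br.begin());
          if ((start + seg) % 2 == hp) g.push_back(*it);
        }
      }
      if (hp == 1 && mark > g0 && mark < g.size())
        std::inplace_merge(g.begin() + g0, g.begin() + mark, g.end(), ins_lt);
    }
  }
  return g;  // globally sorted: chromosomes in order, merged within
}

// trap-model transposition step for one (zygote) genome. Decisions for all
// copies are drawn against the pre-transposition state; a cluster insertion
// present in that state makes the individual fully inactive.
static void transpose_ind(Ind& ind, double u, double v, double alpha,
                          double beta, const Layout& L) {
  if (ind.silenced || u <= 0) return;
  std::unordered_set<long long> occ;
  for (int k = 0; k < 2; ++k)
    for (const Ins& x : ind.h[k]) occ.insert((long long) x.pos);
  size_t n0[2] = { ind.h[0].size(), ind.h[1].size() };
  std::vector<char> excised[2];
  std::vector<Ins> added[2];
  for (int k = 0; k < 2; ++k) excised[k].assign(n0[k], 0);
  for (int k = 0; k < 2; ++k) {
    for (size_t i = 0; i < n0[k]; ++i) {
      if (R::unif_rand() >= u) continue;
      long long p;
      do {
        p = (long long) std::floor(R::unif_rand() * L.genome_len);
      } while (occ.count(p));
      occ.insert(p);
      Ins nw;
      nw.pos = (double) p;
      nw.s = L.in_cluster(nw.pos) ? 0.0 : draw_s(alpha, beta);
      added[(R::unif_rand() < 0.5) ? 0 : 1].push_back(nw);
      if (v > 0 && R::unif_rand() < v) excised[k][i] = 1;
    }
  }
  for (int k = 0; k < 2; ++k) {
    Hap nh;
    nh.reserve(n0[k] + added[k].size());
    for (size_t i = 0; i < n0[k]; ++i)
      if (!excised[k][i]) nh.push_back(ind.h[k][i]);
    size_t mark = nh.size();
    std::sort(added[k].begin(), added[k].end(), ins_lt);
    for (const Ins& x : added[k]) nh.push_back(x);
    std::inplace_merge(nh.begin(), nh.begin() + mark, nh.end(), ins_lt);
    ind.h[k].swap(nh);
  }
}

// founder lines: carrier lines receive Poisson(lambda) distinct insertion
// loci shared by all flies of the line (isogenic); heterozygous loci sit on
// one random haplotype, homozygous loci on both
static void init_pop(std::vector<Ind>& pop, int n_lines, int flies_per_line,
                     double p_carrier, double lambda, bool homozygous,
                     double alpha, double beta, const Layout& L, double h,
                     double floor_w, long* n_floored) {
  pop.clear();
  pop.reserve((size_t) n_lines * flies_per_line);
  for (int ln = 0; ln < n_lines; ++ln) {
    Ind proto;
    if (p_carrier > 0 && lambda > 0 && R::unif_rand() < p_carrier) {
      int n = (int) R::rpois(lambda);
      std::unordered_set<long long> occ;
      for (int i = 0; i < n; ++i) {
        long long p;
        do {
          p = (long long) std::floor(R::unif_rand() * L.genome_len);
        } while (occ.count(p));
        occ.insert(p);
        Ins x;
        x.pos = (double) p;
        x.s = L.in_cluster(x.pos) ? 0.0 : draw_s(alpha, beta);
        if (homozygous) { proto.h[0].push_back(x); proto.h[1].push_back(x); }
        else proto.h[(R::unif_rand() < 0.5) ? 0 : 1].push_back(x);
      }
    }
    finalize(proto, L, h, floor_w, n_floored);
    for (int f = 0; f < flies_per_line; ++f) pop.push_back(proto);
  }
}

static inline int sample_cum(const std::vector<double>& cum, double tot) {
  double r = R::unif_rand() * tot;
  return (int)(std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
}

// one non-overlapping generation: fitness-proportional sampling of two
// distinct parents per offspring, recombinant gametes, then transposition
// in the zygote
static void step_pop(std::vector<Ind>& pop, int census, double u, double v,
                     double alpha, double beta, double h, double floor_w,
                     const Layout& L, long* n_floored) {
  int N = (int) pop.size();
  if (N == 0) stop("empty population");
  std::vector<double> cum((size_t) N);
  double tot = 0;
  for (int i = 0; i < N; ++i) { tot += pop[i].w; cum[i] = tot; }
  if (!(tot > 0)) stop("population collapse: total fitness is zero");
  std::vector<Ind> next;
  next.reserve((size_t) census);
  for (int o = 0; o < census; ++o) {
    int p1 = sample_cum(cum, tot);
    int p2 = p1;
    while (p2 == p1 && N > 1) p2 = sample_cum(cum, tot);
    Ind child;
    child.h[0] = gamete(pop[p1], L);
    child.h[1] = gamete(pop[p2], L);
    child.silenced = any_cluster(child, L);  // pre-transposition state
    transpose_ind(child, u, v, alpha, beta, L);
    finalize(child, L, h, floor_w, n_floored);
    next.push_back(std::move(child));
  }
  pop.swap(next);
}

static double mean_cn(const std::vector<Ind>& pop) {
  double tot = 0;
  for (const Ind& ind : pop) tot += ind.h[0].size() + ind.h[1].size();
  return tot / (2.0 * pop.size());
}

// ---- R <-> internal conversion -------------------------------------------

static NumericMatrix hap_to_mat(const Hap& h) {
  NumericMatrix m((int) h.size(), 2);
  for (size_t i = 0; i < h.size(); ++i) { m(i, 0) = h[i].pos; m(i, 1) = h[i].s; }
  colnames(m) = CharacterVector::create("pos", "s");
  return m;
}

static Hap mat_to_hap(SEXP x) {
  Hap h;
  if (Rf_isNull(x)) return h;
  NumericMatrix m(x);
  h.reserve((size_t) m.nrow());
  for (int i = 0; i < m.nrow(); ++i) {
    Ins ins; ins.pos = m(i, 0); ins.s = m(i, 1);
    h.push_back(ins);
  }
  std::sort(h.begin(), h.end(), ins_lt);
  return h;
}

static List ind_to_list(const Ind& ind) {
  return List::create(_["h1"] = hap_to_mat(ind.h[0]),
                      _["h2"] = hap_to_mat(ind.h[1]));
}

static Ind list_to_ind(const List& l, const Layout& L, double h,
                       double floor_w) {
  Ind ind;
  ind.h[0] = mat_to_hap(l["h1"]);
  ind.h[1] = mat_to_hap(l["h2"]);
  ind.silenced = any_cluster(ind, L);
  ind.w = calc_fitness(ind, h, floor_w, nullptr);
  return ind;
}

static List pop_to_list(const std::vector<Ind>& pop) {
  List out((int) pop.size());
  for (size_t i = 0; i < pop.size(); ++i) out[i] = ind_to_list(pop[i]);
  return out;
}

static std::vector<Ind> list_to_pop(const List& l, const Layout& L, double h,
                                    double floor_w) {
  std::vector<Ind> pop;
  pop.reserve((size_t) l.size());
  for (int i = 0; i < l.size(); ++i)
    pop.push_back(list_to_ind(l[i], L, h, floor_w));
  return pop;
}

static void warn_floor(long n_floored) {
  if (n_floored > 0)
    Rcpp::warning("fitness floor applied to %ld individual(s)", n_floored);
}

// ---- exported entry points -----------------------------------------------

// [[Rcpp::export]]
List cpp_init_founders(int n_lines, int flies_per_line, double p_carrier,
                       double lambda, bool homozygous, double alpha,
                       double beta, List layout, double h, double floor_w) {
  Layout L = as_layout(layout);
  std::vector<Ind> pop;
  long fl = 0;
  init_pop(pop, n_lines, flies_per_line, p_carrier, lambda, homozygous,
           alpha, beta, L, h, floor_w, &fl);
  warn_floor(fl);
  return pop_to_list(pop);
}

// [[Rcpp::export]]
NumericVector cpp_fitness(List pop, double h, double floor_w, List layout) {
  Layout L = as_layout(layout);
  NumericVector out(pop.size());
  for (int i = 0; i < pop.size(); ++i) {
    Ind ind = list_to_ind(pop[i], L, h, floor_w);
    out[i] = ind.w;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_transpose_individual(List ind, double u, double v, double alpha,
                              double beta, List layout) {
  Layout L = as_layout(layout);
  Ind x = list_to_ind(ind, L, 0.5, 1e-9);
  transpose_ind(x, u, v, alpha, beta, L);
  return ind_to_list(x);
}

// [[Rcpp::export]]
NumericMatrix cpp_make_gamete(List ind, List layout) {
  Layout L = as_layout(layout);
  Ind x = list_to_ind(ind, L, 0.5, 1e-9);
  return hap_to_mat(gamete(x, L));
}

// [[Rcpp::export]]
List cpp_step_generation(List pop, int census, double u, double v,
                         double alpha, double beta, double h, double floor_w,
                         List layout) {
  Layout L = as_layout(layout);
  std::vector<Ind> p = list_to_pop(pop, L, h, floor_w);
  long fl = 0;
  step_pop(p, census, u, v, alpha, beta, h, floor_w, L, &fl);
  warn_floor(fl);
  return pop_to_list(p);
}

// [[Rcpp::export]]
List cpp_run_invasion(int n_lines, int flies_per_line, double p_carrier,
                      double lambda, bool homozygous, double u, double v,
                      double alpha, double beta, double h, double floor_w,
                      List layout, int census, IntegerVector record,
                      int generations, bool return_pop) {
  Layout L = as_layout(layout);
  std::vector<Ind> pop;
  long fl = 0;
  init_pop(pop, n_lines, flies_per_line, p_carrier, lambda, homozygous,
           alpha, beta, L, h, floor_w, &fl);
  std::unordered_set<int> rec(record.begin(), record.end());
  std::vector<int> gens;
  std::vector<double> cns;
  if (rec.count(0)) { gens.push_back(0); cns.push_back(mean_cn(pop)); }
  for (int t = 1; t <= generations; ++t) {
    step_pop(pop, census, u, v, alpha, beta, h, floor_w, L, &fl);
    if (rec.count(t)) { gens.push_back(t); cns.push_back(mean_cn(pop)); }
  }
  warn_floor(fl);
  List out = List::create(_["generation"] = wrap(gens),
                          _["copy_number"] = wrap(cns));
  if (return_pop) out["population"] = pop_to_list(pop);
  return out;
}

// [[Rcpp::export]]
double cpp_mean_cn(List pop) {
  double tot = 0;
  for (int i = 0; i < pop.size(); ++i) {
    List ind = pop[i];
    NumericMatrix h1 = ind["h1"], h2 = ind["h2"];
    tot += h1.nrow() + h2.nrow();
  }
  return tot / (2.0 * pop.size());
}

// [[Rcpp::export]]
LogicalVector cpp_silenced(List pop, List layout) {
  Layout L = as_layout(layout);
  LogicalVector out(pop.size());
  for (int i = 0; i < pop.size(); ++i) {
    Ind ind = list_to_ind(pop[i], L, 0.5, 1e-9);
    out[i] = ind.silenced;
  }
  return out;
}
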