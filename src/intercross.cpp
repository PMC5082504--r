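#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// A haplotype along one chromosome arm is a founder mosaic stored as
// right segment endpoints on the genetic map (cM, strictly increasing,
// last endpoint == arm length) plus the founder id of each segment.
struct Hap {
  std::vector<double> brk;
  std::vector<int> fdr;
};

static inline Hap founder_hap(int f, double L) {
  Hap h;
  h.brk.assign(1, L);
  h.fdr.assign(1, f);
  return h;
}

// Append the piece of `h` lying in (from, to] to `out`, merging segments
// that carry the same founder.
static void copy_region(const Hap &h, double from, double to, Hap &out) {
  if (to <= from) return;
  size_t i = std::upper_bound(h.brk.begin(), h.brk.end(), from) - h.brk.begin();
  for (; i < h.brk.size(); ++i) {
    double end = std::min(h.brk[i], to);
    if (!out.fdr.empty() && out.fdr.back() == h.fdr[i]) {
      out.brk.back() = end;  // extend matching segment
    } else {
      out.brk.push_back(end);
      out.fdr.push_back(h.fdr[i]);
    }
    if (h.brk[i] >= to) break;
  }
}

// One meiosis: crossover count ~ Poisson(arm length in Morgans), positions
// uniform on the genetic map, no interference; the gamete starts on a
// random chromatid and switches at every crossover.
static Hap meiosis(const Hap &hm, const Hap &hp, double L) {
  int k = (int) R::rpois(L / 100.0);
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  if (k == 0) return cur == 0 ? hm : hp;
  std::vector<double> xo(k);
  for (int i = 0; i < k; ++i) xo[i] = unif_rand() * L;
  std::sort(xo.begin(), xo.end());
  Hap out;
  double from = 0.0;
  for (int i = 0; i < k; ++i) {
    copy_region(cur == 0 ? hm : hp, from, xo[i], out);
    from = xo[i];
    cur = 1 - cur;
  }
  copy_region(cur == 0 ? hm : hp, from, L, out);
  return out;
}

// Genetic length over which two haplotypes carry different founders.
static double het_length(const Hap &a, const Hap &b) {
  double tot = 0.0, from = 0.0;
  size_t ia = 0, ib = 0;
  while (ia < a.brk.size() && ib < b.brk.size()) {
    double to = std::min(a.brk[ia], b.brk[ib]);
    if (a.fdr[ia] != b.fdr[ib]) tot += to - from;
    from = to;
    if (a.brk[ia] <= to) ++ia;
    if (b.brk[ib] <= to) ++ib;
  }
  return tot;
}

typedef std::vector<std::vector<Hap> > PopArm;  // [individual][2 haplotypes]

// Simulate a multiparent advanced-intercross panel and inbreed RILs.
//
// pedigree: list of n_ind x 2 integer matrices (1-based parent indices into
//   the previous generation), one per intercross generation.
// init_founders: founder line (1-based) of each generation-0 individual;
//   generation 0 individuals are homozygous founder-line flies.
// ril_pairs: n_ril x 2 founding pair (1-based indices into final generation).
// Returns, per RIL, a list over arms of list(brk, fdr) for the single
// haplotype retained after full-sib inbreeding to heterozygosity below
// het_target (fraction of total genetic length).
// [[Rcpp::export]]
List sim_panel_cpp(List pedigree, NumericVector arm_len_cM,
                   IntegerVector init_founders, IntegerMatrix ril_pairs,
                   double het_target, int max_inbreed) {
  const int n_arm = arm_len_cM.size();
  const int n0 = init_founders.size();
  const double total_L = sum(arm_len_cM);

  // generation 0: homozygous founder individuals
  std::vector<PopArm> pop(n_arm);
  for (int a = 0; a < n_arm; ++a) {
    pop[a].resize(n0);
    for (int i = 0; i < n0; ++i) {
      Hap h = founder_hap(init_founders[i], arm_len_cM[a]);
      pop[a][i].assign(2, h);
    }
  }

  // intercross generations
  for (int g = 0; g < pedigree.size(); ++g) {
    IntegerMatrix ped = pedigree[g];
    int n = ped.nrow();
    for (int a = 0; a < n_arm; ++a) {
      PopArm next(n);
      double L = arm_len_cM[a];
      for (int i = 0; i < n; ++i) {
        const std::vector<Hap> &p1 = pop[a][ped(i, 0) - 1];
        const std::vector<Hap> &p2 = pop[a][ped(i, 1) - 1];
        next[i].reserve(2);
        next[i].push_back(meiosis(p1[0], p1[1], L));
        next[i].push_back(meiosis(p2[0], p2[1], L));
      }
      pop[a].swap(next);
    }
  }

  // full-sib inbreeding per RIL, then retain one haplotype
  const int n_ril = ril_pairs.nrow();
  List out(n_ril);
  for (int r = 0; r < n_ril; ++r) {
    std::vector<std::vector<Hap> > pair_(2);  // two current individuals, arms x 2 haps flattened
    // pair_[k] holds 2*n_arm haplotypes: [arm*2 + hap]
    for (int k = 0; k < 2; ++k) {
      pair_[k].resize(2 * n_arm);
      int idx = ril_pairs(r, k) - 1;
      for (int a = 0; a < n_arm; ++a) {
        pair_[k][2 * a] = pop[a][idx][0];
        pair_[k][2 * a + 1] = pop[a][idx][1];
      }
    }
    for (int it = 0; it < max_inbreed; ++it) {
      std::vector<std::vector<Hap> > kids(2);
      double het = 0.0;
      for (int k = 0; k < 2; ++k) {
        kids[k].resize(2 * n_arm);
        for (int a = 0; a < n_arm; ++a) {
          double L = arm_len_cM[a];
          kids[k][2 * a]     = meiosis(pair_[0][2 * a], pair_[0][2 * a + 1], L);
          kids[k][2 * a + 1] = meiosis(pair_[1][2 * a], pair_[1][2 * a + 1], L);
          het += het_length(kids[k][2 * a], kids[k][2 * a + 1]);
        }
      }
      het /= 2.0 * total_L;
      pair_.swap(kids);
      if (het < het_target) break;
    }
    List arms(n_arm);
    for (int a = 0; a < n_arm; ++a) {
      const Hap &h = pair_[0][2 * a];
      arms[a] = List::create(_["brk"] = NumericVector(h.brk.begin(), h.brk.end()),
                             _["fdr"] = IntegerVector(h.fdr.begin(), h.fdr.end()));
    }
    out[r] = arms;
  }
  return out;
}
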