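// Forward Wright-Fisher core: discrete generations, diploid multinomial
// resampling with per-meiosis Poisson crossovers placed on the genetic map,
// symmetric per-site mutation on pre-allocated SNP slots, and codominant
// viability selection at a single sweep site (fitness 1, 1+s/2, 1+s for
// 0/1/2 derived copies).
//
// Haplotypes are stored SNP-major: a RawMatrix of L rows (SNPs) by H columns
// (haplotypes); columns 2k, 2k+1 form diploid individual k. All randomness
// comes from R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <vector>
using namespace Rcpp;

static int weighted_pick(const std::vector<double>& cumw) {
  const double u = unif_rand() * cumw.back();
  return (int)(std::upper_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
}

// One gamete from diploid parent p into `child` (length L).
static void make_gamete(const Rbyte* h0, const Rbyte* h1, Rbyte* child, int L,
                        const std::vector<double>& cm_cum, double total_cm,
                        double mu, int sweep_site) {
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  const Rbyte* src[2] = { h0, h1 };
  const int n_x = (total_cm > 0) ? (int)R::rpois(total_cm / 100.0) : 0;
  if (n_x == 0) {
    std::memcpy(child, src[cur], L);
  } else {
    std::vector<int> brk(n_x);
    for (int i = 0; i < n_x; ++i) {
      const double u = unif_rand() * total_cm;
      brk[i] = (int)(std::upper_bound(cm_cum.begin(), cm_cum.end(), u) -
                     cm_cum.begin());
    }
    std::sort(brk.begin(), brk.end());
    int from = 0;
    for (int i = 0; i < n_x; ++i) {
      if (brk[i] > from) std::memcpy(child + from, src[cur] + from, brk[i] - from);
      from = brk[i];
      cur = 1 - cur;
    }
    if (from < L) std::memcpy(child + from, src[cur] + from, L - from);
  }
  const int n_mut = (mu > 0) ? (int)R::rpois(mu * L) : 0;
  for (int i = 0; i < n_mut; ++i) {
    const int site = std::min(L - 1, (int)(unif_rand() * L));
    if (site == sweep_site) continue;  // the selected allele has a single origin
    child[site] ^= 1;
  }
}

// [[Rcpp::export]]
RawMatrix cpp_wf_evolve(RawMatrix pop, int generations, double mu,
                        NumericVector cm, int sweep_site, double s) {
  const int L = pop.nrow(), H = pop.ncol();
  const int N = H / 2;
  const double total_cm = (L > 1) ? (cm[L - 1] - cm[0]) : 0.0;
  std::vector<double> cm_cum(L);
  for (int j = 0; j < L; ++j) cm_cum[j] = cm[j] - cm[0];

  std::vector<Rbyte> cur((size_t)L * H), nxt((size_t)L * H);
  std::memcpy(cur.data(), RAW(pop), (size_t)L * H);
  std::vector<double> cumw(N);

  for (int g = 0; g < generations; ++g) {
    double acc = 0.0;
    if (sweep_site >= 0 && s > 0) {
      for (int k = 0; k < N; ++k) {
        const int gt = cur[(size_t)(2 * k) * L + sweep_site] +
                       cur[(size_t)(2 * k + 1) * L + sweep_site];
        acc += 1.0 + s * gt / 2.0;
        cumw[k] = acc;
      }
    } else {
      for (int k = 0; k < N; ++k) cumw[k] = (double)(k + 1);
    }
    for (int k = 0; k < N; ++k) {
      const int mother = weighted_pick(cumw);
      const int father = weighted_pick(cumw);
      make_gamete(&cur[(size_t)(2 * mother) * L], &cur[(size_t)(2 * mother + 1) * L],
                  &nxt[(size_t)(2 * k) * L], L, cm_cum, total_cm, mu, sweep_site);
      make_gamete(&cur[(size_t)(2 * father) * L], &cur[(size_t)(2 * father + 1) * L],
                  &nxt[(size_t)(2 * k + 1) * L], L, cm_cum, total_cm, mu, sweep_site);
    }
    cur.swap(nxt);
  }
  RawMatrix out(L, H);
  std::memcpy(RAW(out), cur.data(), (size_t)L * H);
  return out;
}

// Derived-allele count per SNP over a set of haplotype columns.
// [[Rcpp::export]]
IntegerVector cpp_raw_counts(RawMatrix pop) {
  const int L = pop.nrow(), H = pop.ncol();
  IntegerVector out(L);
  const Rbyte* p = RAW(pop);
  for (int h = 0; h < H; ++h)
    for (int j = 0; j < L; ++j) out[j] += p[(size_t)h * L + j];
  return out;
}
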