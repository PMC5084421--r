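// Haplotype-length statistics: EHH curves and their integrals (iHS, XP-EHH),
// segregating-site-length homozygosity (nSL) and windowed haplotype
// homozygosity (H12). Haplotype matrices arrive as haplotypes x SNPs integer
// matrices (column-major, so one SNP's alleles are contiguous).

#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Incremental identity-by-state partition of a set of haplotype rows.
// step() refines the partition by one SNP column and returns the number of
// still-identical pairs; group ids stay in [0, k_init), so renumbering is
// O(active) with a reusable scratch table. Rows whose group has shrunk to a
// singleton can never rejoin a pair, so they are dropped from the active
// set — the dominant cost saver when a few near-identical haplotypes keep
// homozygosity alive over long walks.
struct Refiner {
  std::vector<int> rows, grp, keys, remap, cnt;

  void init(const std::vector<int>& r) {
    rows = r;
    grp.assign(rows.size(), 0);
    keys.assign(rows.size(), 0);
    remap.assign(2 * rows.size(), -1);
    cnt.assign(rows.size(), 0);
  }

  double step(const int* col) {
    const int k = (int)rows.size();
    int next = 0;
    for (int i = 0; i < k; ++i) {
      keys[i] = 2 * grp[i] + col[rows[i]];
      if (remap[keys[i]] < 0) remap[keys[i]] = next++;
      grp[i] = remap[keys[i]];
    }
    for (int i = 0; i < k; ++i) remap[keys[i]] = -1;  // reset touched entries
    for (int g = 0; g < next; ++g) cnt[g] = 0;
    for (int i = 0; i < k; ++i) ++cnt[grp[i]];
    double pairs = 0.0;
    for (int g = 0; g < next; ++g) pairs += 0.5 * (double)cnt[g] * (cnt[g] - 1);
    int w = 0;
    for (int i = 0; i < k; ++i) {
      if (cnt[grp[i]] >= 2) {
        rows[w] = rows[i];
        grp[w] = grp[i];
        ++w;
      }
    }
    rows.resize(w);
    grp.resize(w);
    return pairs;
  }
};

struct EhhWalk {
  std::vector<int> idx;     // SNP indices visited (outward from core)
  std::vector<double> ehh;  // homozygosity fraction at each step
  bool edge;                // reached the chromosome end with EHH >= trunc
};

// Walk outward from `core` in direction `dir` over SNPs [lo, hi], computing
// EHH among `rows`; stops below `trunc` (that step is kept), at a physical
// gap > max_gap_bp, beyond max_extend_bp from the core (steps not kept), or
// at the chromosome end.
static EhhWalk ehh_walk(const IntegerMatrix& haps, const std::vector<int>& rows,
                        int core, int dir, int lo, int hi,
                        const NumericVector& bp, double trunc,
                        double max_gap_bp, double max_extend_bp, Refiner& ref) {
  EhhWalk w;
  w.edge = false;
  const int k = (int)rows.size();
  if (k < 2) return w;
  const double tot_pairs = 0.5 * (double)k * (k - 1);
  ref.init(rows);
  int j = core;
  double prev_bp = bp[core];
  while (true) {
    j += dir;
    if (j < lo || j > hi) { w.edge = true; break; }
    if (std::abs(bp[j] - bp[core]) > max_extend_bp) break;
    if (std::abs(bp[j] - prev_bp) > max_gap_bp) break;
    prev_bp = bp[j];
    const double e = ref.step(&haps(0, j)) / tot_pairs;
    w.idx.push_back(j);
    w.ehh.push_back(e);
    if (e < trunc || e == 0.0) break;
  }
  return w;
}

// Trapezoidal integral of an EHH walk over genetic distance from the core.
static double ihh_integral(const EhhWalk& w, int core, const NumericVector& cm) {
  double area = 0.0, prev_e = 1.0, prev_cm = cm[core];
  for (size_t i = 0; i < w.idx.size(); ++i) {
    area += 0.5 * (prev_e + w.ehh[i]) * std::abs(cm[w.idx[i]] - prev_cm);
    prev_e = w.ehh[i];
    prev_cm = cm[w.idx[i]];
  }
  return area;
}

static void chrom_bounds(const IntegerVector& chrom_id, int core, int* lo, int* hi) {
  const int L = chrom_id.size(), c = chrom_id[core];
  int a = core, b = core;
  while (a > 0 && chrom_id[a - 1] == c) --a;
  while (b < L - 1 && chrom_id[b + 1] == c) ++b;
  *lo = a; *hi = b;
}

// [[Rcpp::export]]
List cpp_ehh_curve(IntegerMatrix haps, IntegerVector rows0, int core0,
                   NumericVector bp, IntegerVector chrom_id, double trunc,
                   double max_gap_bp, double max_extend_bp) {
  std::vector<int> rows(rows0.begin(), rows0.end());
  int lo, hi;
  chrom_bounds(chrom_id, core0, &lo, &hi);
  Refiner ref;
  EhhWalk L_ = ehh_walk(haps, rows, core0, -1, lo, hi, bp, trunc, max_gap_bp,
                        max_extend_bp, ref);
  EhhWalk R_ = ehh_walk(haps, rows, core0, +1, lo, hi, bp, trunc, max_gap_bp,
                        max_extend_bp, ref);
  return List::create(
    Named("left_idx") = wrap(L_.idx), Named("left_ehh") = wrap(L_.ehh),
    Named("right_idx") = wrap(R_.idx), Named("right_ehh") = wrap(R_.ehh),
    Named("edge_left") = L_.edge, Named("edge_right") = R_.edge);
}

// iHH for the ancestral (0) and derived (1) classes at each core SNP.
// [[Rcpp::export]]
List cpp_ihs_ihh(IntegerMatrix haps, IntegerVector cores0, NumericVector bp,
                 NumericVector cm, IntegerVector chrom_id, double trunc,
                 double max_gap_bp, double max_extend_bp) {
  const int n = haps.nrow(), nc = cores0.size();
  NumericVector ihh_anc(nc, NA_REAL), ihh_der(nc, NA_REAL);
  LogicalVector edge(nc);
  Refiner ref;
  for (int c = 0; c < nc; ++c) {
    const int core = cores0[c];
    std::vector<int> anc, der;
    for (int i = 0; i < n; ++i)
      (haps(i, core) == 1 ? der : anc).push_back(i);
    if (anc.size() < 2 || der.size() < 2) continue;
    int lo, hi;
    chrom_bounds(chrom_id, core, &lo, &hi);
    bool any_edge = false;
    double v[2];
    const std::vector<int>* cls[2] = { &anc, &der };
    for (int a = 0; a < 2; ++a) {
      EhhWalk wl = ehh_walk(haps, *cls[a], core, -1, lo, hi, bp, trunc,
                            max_gap_bp, max_extend_bp, ref);
      EhhWalk wr = ehh_walk(haps, *cls[a], core, +1, lo, hi, bp, trunc,
                            max_gap_bp, max_extend_bp, ref);
      any_edge = any_edge || wl.edge || wr.edge;
      v[a] = ihh_integral(wl, core, cm) + ihh_integral(wr, core, cm);
    }
    ihh_anc[c] = v[0];
    ihh_der[c] = v[1];
    edge[c] = any_edge;
  }
  return List::create(Named("ihh_anc") = ihh_anc, Named("ihh_der") = ihh_der,
                      Named("edge") = edge);
}

// Mean identical-run length (in SNPs, both directions, capped) for one
// allele class at a core: SL = 1 + sum of per-step homozygosity fractions,
// which equals the mean over carrier pairs of the number of consecutive
// SNPs (core included) over which the pair is identical.
static double sl_class(const IntegerMatrix& haps, const std::vector<int>& rows,
                       int core, int lo, int hi, int max_ext, Refiner& ref) {
  const int k = (int)rows.size();
  const double tot_pairs = 0.5 * (double)k * (k - 1);
  double sl = 1.0;
  for (int dir = -1; dir <= 1; dir += 2) {
    ref.init(rows);
    int j = core, steps = 0;
    while (steps < max_ext) {
      j += dir;
      if (j < lo || j > hi) break;
      const double e = ref.step(&haps(0, j)) / tot_pairs;
      if (e == 0.0) break;
      sl += e;
      ++steps;
    }
  }
  return sl;
}

// [[Rcpp::export]]
List cpp_nsl_sl(IntegerMatrix haps, IntegerVector cores0, IntegerVector chrom_id,
                int max_ext) {
  const int n = haps.nrow(), nc = cores0.size();
  NumericVector sl_anc(nc, NA_REAL), sl_der(nc, NA_REAL);
  Refiner ref;
  for (int c = 0; c < nc; ++c) {
    const int core = cores0[c];
    std::vector<int> anc, der;
    for (int i = 0; i < n; ++i)
      (haps(i, core) == 1 ? der : anc).push_back(i);
    if (anc.size() < 2 || der.size() < 2) continue;
    int lo, hi;
    chrom_bounds(chrom_id, core, &lo, &hi);
    sl_anc[c] = sl_class(haps, anc, core, lo, hi, max_ext, ref);
    sl_der[c] = sl_class(haps, der, core, lo, hi, max_ext, ref);
  }
  return List::create(Named("sl_anc") = sl_anc, Named("sl_der") = sl_der);
}

// XP-EHH: population-wide (not allele-split) EHH for two populations,
// truncated where the pooled two-population EHH falls below `trunc`.
// [[Rcpp::export]]
List cpp_xpehh_ihh(IntegerMatrix haps, IntegerVector rowsA0, IntegerVector rowsB0,
                   IntegerVector cores0, NumericVector bp, NumericVector cm,
                   IntegerVector chrom_id, double trunc, double max_gap_bp,
                   double max_extend_bp) {
  std::vector<int> rowsA(rowsA0.begin(), rowsA0.end());
  std::vector<int> rowsB(rowsB0.begin(), rowsB0.end());
  std::vector<int> pooled(rowsA);
  pooled.insert(pooled.end(), rowsB.begin(), rowsB.end());
  const int nc = cores0.size();
  const double pairsA = 0.5 * (double)rowsA.size() * (rowsA.size() - 1);
  const double pairsB = 0.5 * (double)rowsB.size() * (rowsB.size() - 1);
  const double pairsP = 0.5 * (double)pooled.size() * (pooled.size() - 1);
  NumericVector ihhA(nc, NA_REAL), ihhB(nc, NA_REAL);
  Refiner refA, refB, refP;
  for (int c = 0; c < nc; ++c) {
    const int core = cores0[c];
    int lo, hi;
    chrom_bounds(chrom_id, core, &lo, &hi);
    double vA = 0.0, vB = 0.0;
    for (int dir = -1; dir <= 1; dir += 2) {
      refA.init(rowsA);
      refB.init(rowsB);
      refP.init(pooled);
      double eA = 1.0, eB = 1.0;
      double prev_cm = cm[core], prev_bp = bp[core];
      int j = core;
      while (true) {
        j += dir;
        if (j < lo || j > hi) break;
        if (std::abs(bp[j] - bp[core]) > max_extend_bp) break;
        if (std::abs(bp[j] - prev_bp) > max_gap_bp) break;
        prev_bp = bp[j];
        const int* col = &haps(0, j);
        const double nA = refA.step(col) / pairsA;
        const double nB = refB.step(col) / pairsB;
        const double nP = refP.step(col) / pairsP;
        const double d = std::abs(cm[j] - prev_cm);
        vA += 0.5 * (eA + nA) * d;
        vB += 0.5 * (eB + nB) * d;
        eA = nA; eB = nB;
        prev_cm = cm[j];
        if (nP < trunc) break;
      }
    }
    ihhA[c] = vA;
    ihhB[c] = vB;
  }
  return List::create(Named("ihh_a") = ihhA, Named("ihh_b") = ihhB);
}

// H12 over sliding windows: exact haplotype matching, top-two haplotype
// classes pooled. Returns one value per window center (0-based indices in
// `centers0`), all SNPs of one chromosome.
// [[Rcpp::export]]
NumericVector cpp_h12(IntegerMatrix haps, IntegerVector centers0, int window) {
  const int n = haps.nrow(), L = haps.ncol();
  const int half = window / 2;
  // row-major copy for memcmp
  std::vector<unsigned char> buf((size_t)n * L);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < n; ++i)
      buf[(size_t)i * L + j] = (unsigned char)haps(i, j);
  NumericVector out(centers0.size());
  std::vector<int> ord(n);
  for (int w = 0; w < centers0.size(); ++w) {
    const int start = centers0[w] - half;
    const unsigned char* base = buf.data() + start;
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return std::memcmp(base + (size_t)a * L, base + (size_t)b * L, window) < 0;
    });
    std::vector<double> freq;
    int run = 1;
    for (int i = 1; i < n; ++i) {
      if (std::memcmp(base + (size_t)ord[i] * L, base + (size_t)ord[i - 1] * L,
                      window) == 0) {
        ++run;
      } else {
        freq.push_back((double)run / n);
        run = 1;
      }
    }
    freq.push_back((double)run / n);
    std::sort(freq.begin(), freq.end(), std::greater<double>());
    double h12;
    if (freq.size() == 1) {
      h12 = 1.0;
    } else {
      double top2 = freq[0] + freq[1];
      h12 = top2 * top2;
      for (size_t k = 2; k < freq.size(); ++k) h12 += freq[k] * freq[k];
    }
    out[w] = h12;
  }
  return out;
}
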