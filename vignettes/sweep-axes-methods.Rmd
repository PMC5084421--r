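---
title: "Methods: selection-signature scans and their canonical-axis summary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection-signature scans and their canonical-axis summary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
statistics it computes, the factor-analytic summary, the outlier-region
rules, the Wright–Fisher generator used as the test substrate, and the
numerical and design choices made where a choice was genuinely open.

## The problem

A selective sweep — the rapid rise of a beneficial allele — drags linked
variation with it (hitchhiking) and leaves three distinguishable footprints:
a distorted site frequency spectrum (excess rare and high-frequency-derived
variants), unusually long stretches of haplotype homozygosity around the
selected site, and elevated allele-frequency differentiation between
populations that experienced the sweep and those that did not. The scan
statistics targeting these footprints disagree per SNP, because they are
sensitive to selection events of different ages and completeness. The
package computes a battery of such statistics on phased multi-population
haplotypes and summarizes them into three interpretable canonical axes.

## Input substrate and conventions

All statistics consume a `haplotype_set`: a binary matrix (haplotypes ×
SNPs) with 0 = ancestral and 1 = derived allele, population labels
(even counts per population — phased diploids), and a SNP map with physical
(bp, 1-based) and genetic (cM) positions plus the ancestral allele.
Coordinates are 1-based inclusive internally; BED I/O converts at the
boundary. SNPs whose ancestral state is unknown are kept for the
polarization-free statistics (FST, H12, VarLD, window membership) but are
never iHS/nSL cores and never enter derived-allele frequency classes
(Fay & Wu's θ~H~, the derived SFS). Inputs are assumed post-QC; the readers
enforce only structural invariants (binarity, phasing, sortedness) and
reject rather than coerce.

## The per-SNP statistics

**SFS family** (per population, sliding windows of `window = 100` SNPs,
step 1, so every eligible SNP centers exactly one window; the window value
is assigned to the central SNP, element `window/2` 0-based, leaving the
first and last 50 SNPs of a chromosome missing):

* θ~π~ = Σ 2i(n−i)/(n(n−1)), θ~W~ = S/a₁, θ~H~ = Σ 2i²/(n(n−1)) over sites
  with known derived count i;
* Tajima's D uses the full 1989 standardization
  D = (θ~π~ − θ~W~)/√(e₁S + e₂S(S−1)); S = 0 yields missing, and the
  degenerate n = 2 case (numerator identically zero, zero variance
  constants) is defined as 0;
* Fay & Wu's H = θ~π~ − θ~H~ is left unstandardized;
* Fu & Li's statistic is the within-sample D\* (singletons counted as
  alleles present on exactly one haplotype, either allele — no outgroup),
  with the published normalizing constants in their corrected form;
  defined for n ≥ 3.

All three are oriented `low_is_evidence`: strongly negative values are the
sweep signal. Per-window (not per-site) θ scaling is used throughout;
only genome-wide ranks are consumed downstream, and the scaling is
constant at fixed window size.

**Haplotype-length family.** EHH at offset k from a core is the fraction of
carrier pairs identical over the whole span core..k; it is 1 at the core
and non-increasing. Extension stops below a truncation of 0.05, at a
physical gap > 200 kb, or at the chromosome end (edge-truncated curves are
kept and flagged; dropping them is an option — keeping maximizes SNP
coverage for the factor analysis). iHH is the trapezoidal integral of EHH
over cM, both directions, integrated down to the truncation point. These
parameters (truncation 0.05, gap 200 kb, maximum extension 1 Mb from the
core, core MAF bound 0.05, 50 standardization bins) are the documented
defaults of the standard scan software for these tests, exposed as
arguments. The extension cap matters at desk scale: when the sample is a
sizeable fraction of the population, a few near-identical haplotype pairs
can hold EHH just above the truncation for many megabases. When no genetic map is
available a constant 1 cM/Mb is applied with a warning.

* iHS: ln(iHH~ancestral~/iHH~derived~) at cores with known ancestral state,
  derived frequency in [0.05, 0.95] and both allele classes ≥ 2 carriers;
  standardized to mean 0/sd 1 within 50 equal-width derived-frequency bins
  genome-wide per population (bins with < 20 cores merge into their left,
  else right, neighbour); the emitted value is |standardized iHS|.
* nSL replaces genetic distance by segregating-site counts: a pair's length
  is the number of consecutive SNPs (core included, both directions, each
  direction capped at 200 SNPs) over which the pair is identical; the class
  statistic SL is the mean over carrier pairs, computed as
  1 + Σ per-step homozygosity fractions. ln(SL~anc~/SL~der~) is standardized
  and absolute-valued exactly as iHS.
* H12 over 100-SNP windows compares haplotypes as exact strings;
  with descending haplotype frequencies p₁ ≥ p₂ ≥ …,
  H12 = (p₁+p₂)² + Σ~j>2~ p~j~². Exact matching over the full window is
  assumed (no mismatch tolerance).
* XP-EHH: per population pair and core, each population's EHH is computed
  over all of its haplotypes (not split by allele), truncating where the
  pooled two-population EHH falls below 0.05;
  XPEHH = ln(IHH~A~/IHH~B~) is z-scored genome-wide per pair, and each
  population's track is the mean of its standardized pairwise tracks with
  itself in the numerator (so the average is interpretable per population).
  Signed pairwise values are averaged; absolute value is applied only at
  the transform stage (`abs_is_evidence`).

**Differentiation family.** Per-SNP pairwise FST is Wright's
(H~T~ − H~S~)/H~T~ from haplotype-frequency heterozygosities
(H = 2p(1−p)); inputs are phased haplotypes, so no genotypic
observed-heterozygosity definition is used. The sign-inverted ratio
(H~O~ − H~E~)/H~E~, which is −1 at a fixed difference, is available behind
`form = "ho_he"` for comparison experiments; the default orientation makes
larger mean more differentiated, which is how the index is used as a
selection signal. Pairwise per-SNP values are averaged over 100-SNP
windows (missing SNPs skipped), assigned to the central SNP, and each
population's track is the mean over its pairs. VarLD compares local LD
structure: per pair and window, the signed Pearson correlation matrices of
the SNP columns in each population (zero-variance SNPs contribute zero
correlations and a unit diagonal, preserving the trace), scored as
Σ|λ~A,i~ − λ~B,i~| over rank-matched descending eigenvalues, z-scored
genome-wide per pair, and averaged per population. Externally computed
tests (e.g. SelEstim selection coefficients, XP-CLR composite-likelihood
scores) join the battery as score-track TSVs.

## Summarization into canonical axes

Each track declares an orientation; values are mapped to an evidence scale
v (identity, negation, or absolute value) and transformed by
sign(v)·ln(1+|v|) — monotone in evidence and defined for the negative
values the SFS tests produce. A plain ln is available for strictly
positive tracks (under it the model is exactly scale-invariant, since the
z-scoring absorbs multiplicative constants). Rows are (SNP, population)
pairs stacked over populations; columns are tests; each column is z-scored
over the complete rows. Complete-case rows (no imputation) feed the
Pearson correlation matrix and the factor analysis: the missingness is
structural (window edges, core-eligibility rules), not informative, and
complete-case is the simplest defensible rule.

One factor model is fitted on rows pooled across populations, and scores
are then computed per population: pooling yields axes that are comparable
across populations, which the between-population axis-score correlations
require. Extraction is principal-component: unrotated loading column j is
√λ~j~·v~j~ from the top-3 eigenpairs of the correlation matrix (an error
is raised below −1e−8 on the smallest eigenvalue). Rotation is the
classical iterative pairwise varimax with Kaiser normalization, sweeping
all column pairs until the criterion changes by < 1e−10 *and* the largest
rotation angle in a sweep falls below 1e−9 rad (at most 1000 sweeps); the
angle condition is needed for the rotation to agree with independent
implementations to < 1e−6 in the loadings, since the criterion is
quadratically flat near its optimum. Axes are ordered by explained
variance and sign-fixed so each axis' largest-|loading| entry is positive.
Score weights are R⁻¹Λ, so axis scores (z-rows × weights) have exactly
unit variance over the rows the correlation was computed from — a property
specific to principal-component extraction. Communalities are invariant
under the orthogonal rotation (checked to 1e−9). Axis labels
("sfs", "haplotype_length", "differentiation") are a post-hoc report
annotation assigned by which family's tests load highest — never an
algorithmic step.

## Candidate regions and genes

The genome-wide empirical distribution of each axis-population track is its
own null; thresholds are computed per population per axis. The strict rule
tiles each chromosome into fixed 1-Mb bins anchored at position 1 (the
simplest construction consistent with non-overlapping "1-Mb regions") and
calls a bin holding ≥ 25 SNPs above the top-0.1% threshold, merging
adjacent called bins. The relaxed rule (top 5%) merges consecutive
outliers ≤ 1 Mb apart, allowing single-SNP regions — its construction is a
package design choice, as only the threshold is standard. A gene is
reported for a region on ≥ 1 bp intersection; the deduplicated gene union
is the hand-off to enrichment tools (enrichment itself is out of scope).
Note that while tightening q always shrinks the total called span, it can
*split* one region into two (a middle outlier dropping out), so region
counts are not monotone in q.

## The synthetic-data generator

The generator is a discrete-generation diploid Wright–Fisher model on
pre-allocated SNP slots: an ancestral population of N~e~ diploids is burned
in from a monomorphic state for 4N~e~ generations, splits into star-topology
descendants, and each drifts independently. Per meiosis, a Poisson number
of crossovers (mean = map length/100 cM) is placed uniformly on the genetic
map; mutation flips alleles at a per-slot per-gamete rate; a sweep applies
codominant viability selection (fitness 1, 1+s/2, 1+s per derived copy)
with multinomial resampling of parents. A configured sweep is a
*single-origin new mutation*: standing variation at the slot is cleared,
one derived copy is injected, and mutation at the slot is suspended while
selection acts — without this, the per-slot mutation flux (2N~e~μ ≈ 0.04
per generation) re-seeds the allele on unrelated haplotypes and every
sweep becomes soft. The rescue option redraws the selected phase (up to
100 attempts) until the realized final frequency lands in a configured
band, i.e. conditions on the sweep being observable.

**Desk-scale diffusion rescaling.** The presets run at N~e~ = 200 — roughly
50× below a realistic livestock ancestral population — so the
per-generation selection and recombination rates are scaled *up* by the
same factor (presets use 40 cM/Mb and s up to 1), preserving the
population-scaled compound parameters (2N~e~s, 2N~e~r) that the statistics
respond to. Without the recombination rescaling a 25-generation sweep
leaves a ±4 Mb hitchhiking footprint that no 1-Mb region rule can
localize; with it the footprint is a few hundred kb, as for a strong sweep
at realistic sizes. The per-slot mutation rate default is 1e−4
(θ~slot~ = 0.08): high enough that ~45% of slots segregate in a pooled
sample of 96, low enough that the symmetric two-allele model stays near
its infinite-sites-like regime — at θ~slot~ = 0.2 the recurrent-mutation
equilibrium enriches intermediate frequencies and biases the genome-mean
Tajima's D to ≈ +0.4, while at 1e−4 the neutral-preset genome mean is
≈ +0.1.

Preset problem sizes were chosen once, from pilot measurements of the
generator itself, to make each preset fit its purpose: `preset_neutral()`
(2 populations, 20,000 slots / 20 Mb, 200 post-split generations, 48
haplotypes sampled per population) for calibration checks;
`preset_sweep()` (150,000 slots / 75 Mb, one s = 1 sweep started at
generation 180 of 200 and conditioned to a final frequency of 0.6–0.85 —
the mid-to-late sweep phase haplotype-length tests are designed for) large
enough that per-population complete-case SNP counts (~28,000) make a
top-0.1% outlier set of ~28 SNPs, so the strict 25-SNP rule is
attainable; `preset_seven_pops()` mirrors a seven-breed study layout at
small scale. The simulator emulates the *statistical structure* the tests
assume — neutral drift background, a clean hard sweep, star-shaped
population splits — and deliberately not: real demography (bottlenecks,
migration, admixture), chip ascertainment bias, variable recombination
and mutation rates, trio structure (haplotypes are emitted directly as
parental chromosomes), or soft/standing-variation sweeps. Passing tests on
this substrate therefore validate the statistical machinery, not
robustness to those real-data features.

## Numerical choices and degenerate inputs

* Window geometry: valid centers are 0-based indices w/2 … L−w/2−1; a
  chromosome shorter than the window yields all-missing tracks with a
  warning.
* Tajima's D at n = 2 is 0 (0/0 limit of a numerator that is identically
  zero); S = 0 windows are missing, not errors.
* Standardization bins with < 20 cores merge leftward (else rightward);
  bins with zero variance yield missing scores.
* VarLD eigenvalues: when the haplotype count n is below the window size,
  the spectrum is computed from the n×n Gram matrix of the scaled columns
  (identical nonzero eigenvalues, zeros padded, one unit eigenvalue per
  zero-variance SNP) — an exact reformulation verified against dense
  eigendecompositions, roughly 8× faster at n = 48, w = 100.
* Empirical thresholds use the type-7 (linear interpolation) quantile and
  require ≥ 1/q non-missing values.
* The pipeline derives all stage randomness from one top-level seed;
  rerunning an identical config reproduces byte-identical artifacts
  (md5-checksummed manifest).
* Ties: H12 pools the top two haplotype classes regardless of ties below
  them; region peaks take the first maximal SNP in genome order.

## Known limitations

* Complete-case rows discard SNPs that fail any single test's eligibility
  rules (mostly iHS/nSL core bounds), roughly half the panel at desk
  scale; an imputation or pairwise-correlation variant is not provided.
* Fay & Wu's H uses the window θ~π~ over all segregating sites while θ~H~
  is restricted to polarizable sites; with fully annotated ancestral
  states (as in the simulator) the two definitions coincide, but with many
  unpolarizable SNPs H would be inflated.
* The factor model is fitted by principal-component extraction, not
  maximum-likelihood common-factor analysis; with three strong test
  families the practical difference is in the uniquenesses, not the axis
  structure.
* One sweep per population per run; multi-locus selection, dominance
  other than codominance, and time-varying s are not modelled.
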