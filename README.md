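# sweepaxes

Selection-signature scans on phased haplotypes, summarized into canonical
axes.

Genome scans for selection come in three families that interrogate different
footprints of a selective sweep: site-frequency-spectrum (SFS) statistics
(Tajima's D, Fay & Wu's H, Fu & Li's D\*), haplotype-length statistics (iHS,
nSL, H12, XP-EHH) and population-differentiation statistics (windowed
pairwise F<sub>ST</sub>, VarLD, plus externally computed tests such as
SelEstim or XP-CLR). Their per-SNP results disagree substantially because
each family is sensitive to selection at a different evolutionary depth.
`sweepaxes` is for population geneticists who run several of these tests on
phased, multi-population SNP data (e.g. livestock breeds genotyped on a
dense chip) and want a principled joint summary rather than eleven
discordant Manhattan plots.

The package:

1. computes nine per-SNP score tracks on a phased haplotype matrix
   (0 = ancestral, 1 = derived), one track per test per population, with
   sliding windows of 100 SNPs where the test is windowed;
2. log-transforms each track on an orientation-aware evidence scale
   (`sign(v)·ln(1+|v|)`), stacks (SNP × population) rows over tests,
   and fits a **three-factor principal-axis model with varimax rotation**
   to the cross-test correlation matrix. Per-SNP axis scores are
   `z · R⁻¹Λ` (unit variance by construction); each test's communality
   `h² = Σⱼ λ²ⱼ` is the fraction of its variance the three axes explain;
3. calls candidate regions from the empirical genome-wide null: a strict
   rule (1-Mb bins holding ≥ 25 SNPs in the top 0.1% of an axis) and a
   relaxed rule (top-5% outliers merged within 1 Mb), then overlaps regions
   with gene annotation (BED/GFF3);
4. ships a forward Wright–Fisher simulator (diploid multinomial resampling,
   Poisson crossovers on a genetic map, per-slot mutation, codominant
   selection at a sweep site) that generates the phased multi-population
   test substrate with known truth.

## Worked example

Simulate two small diverged populations, scan, summarize and call regions
in one call:

```r
library(sweepaxes)

cfg <- run_config(
  sim = sim_config(n_pops = 2, N_e = 60, n_snps = 3000, chrom_length_bp = 3e6,
                   recomb_cm_per_mb = 40, burnin_gens = 240,
                   post_split_gens = 60, sample_haps = 20, seed = 12),
  q_strict = 0.01, out_dir = "demo_run", seed = 12
)
res <- run_pipeline(cfg)
res$model
#> <sweep_axes_fa> 9 tests, 3 axes, 64% of variance explained
#>            w1    w2    w3    r1    r2    r3 %var
#> TajimaD  0.30  0.00 -0.06  0.73  0.05 -0.05   53
#> FayWuH   0.36 -0.04 -0.01  0.86 -0.01  0.02   74
#> FuLiD    0.37 -0.06 -0.06  0.90 -0.05 -0.04   81
#> iHS     -0.02  0.49 -0.06  0.05  0.98 -0.03   97
#> nSL     -0.02  0.49 -0.06  0.03  0.98 -0.03   97
#> H12      0.21  0.09  0.26  0.55  0.24  0.36   49
#> XPEHH   -0.01  0.05 -0.18 -0.04  0.07 -0.23    6
#> FST      0.11 -0.01 -0.54  0.21 -0.05 -0.68   50
#> VarLD    0.02  0.00  0.62  0.11  0.06  0.79   64
axis_families(res$model)
#>              axis1              axis2              axis3
#>              "sfs" "haplotype_length"  "differentiation"
```

Each row shows the score weight per axis (`w`) with the test–axis
correlation (`r`), and `%var` — the communality × 100, i.e. how much of
that test's variance the three axes capture. Even at this toy scale the
axes recover the three test families: the SFS tests load together, iHS/nSL
form the haplotype-length axis, and F<sub>ST</sub>/VarLD the
differentiation axis. `res$axis_scores` holds the per-SNP axis tracks,
`res$regions_strict` / `res$regions_relaxed` the outlier regions, and
everything is also written under `out_dir` with an md5 manifest.

The same reporting arithmetic applies to published tables. For a
published eleven-test scan of seven Spanish beef cattle breeds
(`cattle_axis_table()`), recomputing communalities from the printed
test–axis correlations reproduces the printed `% variance` column:

```r
library(dplyr)
cattle_axis_table() |>
  filter(test %in% c("Tajima", "Fay-Wu", "H12")) |>
  mutate(recomputed = communality_pct(r1, r2, r3))
#>   test      r1    r2    r3 pct_variance recomputed
#> 1 Tajima  0.07  0.85  0.06           73       73.1
#> 2 Fay-Wu  0.09  0.77  0.07           61       60.6
#> 3 H12     0.67  0.32  0.06           55       55.5
```

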