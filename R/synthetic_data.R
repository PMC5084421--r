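# Forward Wright-Fisher simulator of phased multi-population haplotypes with
# known ancestral states, population splits and optional selective sweeps.
# This is the test substrate for the whole pipeline: neutral drift
# background, hitchhiking around swept loci.

#' Simulation configuration
#'
#' Discrete-generation diploid Wright-Fisher populations on a fixed grid of
#' pre-allocated SNP slots: an ancestral population of `N_e` diploids is
#' burned in for `burnin_gens` generations from a monomorphic (all-ancestral)
#' state, splits into `n_pops` copies at the end of burn-in, and each
#' descendant drifts independently for `post_split_gens` generations.
#' Mutation flips alleles at a per-site per-gamete rate `mutation_rate`
#' (allele 1 is "derived": it differs from the founding ancestral state);
#' recombination places a Poisson number of crossovers per meiosis uniformly
#' on the genetic map. A sweep applies codominant viability selection
#' (fitness 1, 1+s/2, 1+s per derived copy) at one SNP of one population
#' from `start_gen` generations after the split; the derived allele is
#' injected into one haplotype if absent.
#'
#' @param n_pops Number of descendant populations.
#' @param N_e Diploid population size (ancestral and descendants).
#' @param n_snps Number of pre-allocated SNP slots.
#' @param chrom_length_bp Chromosome length in bp (single chromosome; slots
#'   evenly spaced).
#' @param mutation_rate Per-site per-gamete mutation probability.
#' @param recomb_cm_per_mb Constant recombination rate, cM/Mb.
#' @param burnin_gens Ancestral burn-in generations (default `4 * N_e`).
#' @param post_split_gens Generations of independent drift after the split.
#' @param sample_haps Haplotypes sampled per population at the end (an even
#'   number; whole diploids are drawn, at most `2 * N_e`).
#' @param sweeps A tibble/data frame with columns `population` (label
#'   `"pop1"`..), `snp_index`, `s`, `start_gen` (relative to the split) and
#'   optionally `rescue` (default `TRUE`: redraw a sweep segment whose final
#'   derived frequency falls outside `[min_freq, max_freq]` — by default,
#'   only a lost sweep — up to 100 attempts). At most one sweep per
#'   population.
#' @param drop_monomorphic Drop SNP slots monomorphic across all samples
#'   (sweep sites are always kept).
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pops = 2L, N_e = 200L, n_snps = 20000L,
                       chrom_length_bp = 2e7, mutation_rate = 1e-4,
                       recomb_cm_per_mb = 1, burnin_gens = 4L * N_e,
                       post_split_gens = 200L, sample_haps = 48L,
                       sweeps = NULL, drop_monomorphic = TRUE, seed) {
  if (missing(seed) || is.null(seed)) abort("a seed is mandatory")
  if (sample_haps %% 2L != 0L) abort("sample_haps must be even (whole diploids)")
  if (sample_haps > 2L * N_e) abort("sample_haps cannot exceed 2 * N_e")
  if (!is.null(sweeps)) {
    sweeps <- as_tibble(sweeps)
    if (!all(c("population", "snp_index", "s", "start_gen") %in% names(sweeps))) {
      abort("sweeps needs columns population, snp_index, s, start_gen")
    }
    if (!("rescue" %in% names(sweeps))) sweeps$rescue <- TRUE
    if (!("min_freq" %in% names(sweeps))) sweeps$min_freq <- 0
    if (!("max_freq" %in% names(sweeps))) sweeps$max_freq <- 1
    if (any(sweeps$s <= 0 | sweeps$s > 1)) abort("selection coefficients must be in (0, 1]")
    if (anyDuplicated(sweeps$population)) abort("at most one sweep per population")
    if (any(sweeps$start_gen < 0 | sweeps$start_gen >= post_split_gens)) {
      abort("sweep start_gen must lie in [0, post_split_gens)")
    }
  }
  structure(list(
    n_pops = as.integer(n_pops), N_e = as.integer(N_e),
    n_snps = as.integer(n_snps), chrom_length_bp = chrom_length_bp,
    mutation_rate = mutation_rate, recomb_cm_per_mb = recomb_cm_per_mb,
    burnin_gens = as.integer(burnin_gens),
    post_split_gens = as.integer(post_split_gens),
    sample_haps = as.integer(sample_haps), sweeps = sweeps,
    drop_monomorphic = isTRUE(drop_monomorphic), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Desk-scale simulation presets
#'
#' All presets use desk-scale diffusion rescaling: the population size is
#' reduced ~50-fold relative to a realistic livestock ancestral population
#' and the per-generation recombination rate and selection coefficients are
#' scaled up by the same factor (40 cM/Mb, strong `s`), preserving the
#' population-scaled parameters that the statistics respond to.
#'
#' `preset_neutral()`: two populations, `N_e = 200`, 20,000 SNP slots over
#' 20 Mb, `4 N_e` burn-in, 200 post-split generations, 48 sampled
#' haplotypes per population, no sweeps. `preset_sweep()`: a larger, denser
#' genome (150,000 slots over 75 Mb, so that genome-wide top-0.1% outlier
#' sets are large enough for the strict 25-SNP region rule) plus one strong
#' hard sweep in `pop1`: `s = 1` at the desk-scale `N_e = 200` (diffusion
#' scaling: `2 N_e s = 400`, a strong sweep at realistic population sizes),
#' a single-origin mutation at the slot at 37.5 Mb, started 180 generations
#' after the split and conditioned (via rescue redraws) to be segregating at
#' derived frequency 0.6-0.95 when sampled, the mid-to-late sweep phase
#' where haplotype-length statistics are most informative.
#' `preset_seven_pops()`: seven populations of 48 sampled haplotypes
#' mirroring a multi-breed study layout, at a smaller genome scale.
#'
#' @param seed Seed stored in the config.
#' @return A [sim_config()].
#' @export
preset_neutral <- function(seed = 1L) {
  sim_config(n_pops = 2L, N_e = 200L, n_snps = 20000L, chrom_length_bp = 2e7,
             recomb_cm_per_mb = 40, seed = seed)
}

#' @rdname preset_neutral
#' @export
preset_sweep <- function(seed = 1L) {
  sim_config(n_pops = 2L, N_e = 200L, n_snps = 150000L, chrom_length_bp = 7.5e7,
             recomb_cm_per_mb = 40,
             sweeps = tibble(population = "pop1", snp_index = 75000L,
                             s = 1, start_gen = 180L, rescue = TRUE,
                             min_freq = 0.6, max_freq = 0.85),
             seed = seed)
}

#' @rdname preset_neutral
#' @export
preset_seven_pops <- function(seed = 1L) {
  sim_config(n_pops = 7L, N_e = 100L, n_snps = 5000L, chrom_length_bp = 5e6,
             recomb_cm_per_mb = 40, burnin_gens = 400L, post_split_gens = 100L,
             sample_haps = 48L, seed = seed)
}

#' Run a Wright-Fisher simulation
#'
#' @param config A [sim_config()].
#' @return A list with `haps` (a [haplotype_set()] of the sampled
#'   haplotypes), `map` (its [snp_map()]; every slot has a known ancestral
#'   allele) and `truth` (a list with `sweeps`, including the realized final
#'   derived frequency per sweep, and `split_times` per population pair).
#'   Identical configs (same seed) give identical output.
#' @export
simulate_populations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_snps
  H <- 2L * config$N_e
  spacing <- config$chrom_length_bp / L
  pos_bp <- round(spacing * seq_len(L))
  pos_cm <- pos_bp / 1e6 * config$recomb_cm_per_mb
  map <- snp_map(chrom = "1", pos_bp = pos_bp, pos_cm = pos_cm,
                 snp_id = paste0("snp", seq_len(L)), ancestral = "A")

  anc <- matrix(as.raw(0L), nrow = L, ncol = H)
  anc <- cpp_wf_evolve(anc, config$burnin_gens, config$mutation_rate,
                       pos_cm, -1L, 0)

  pops <- paste0("pop", seq_len(config$n_pops))
  sweep_freq <- list()
  pop_mats <- list()
  for (p in pops) {
    sw <- if (!is.null(config$sweeps)) {
      config$sweeps[config$sweeps$population == p, , drop = FALSE]
    } else {
      NULL
    }
    if (!is.null(sw) && nrow(sw) == 1L) {
      res <- evolve_with_sweep(anc, config, pos_cm, sw)
      pop_mats[[p]] <- res$mat
      sweep_freq[[p]] <- res$final_freq
    } else {
      pop_mats[[p]] <- cpp_wf_evolve(anc, config$post_split_gens,
                                     config$mutation_rate, pos_cm, -1L, 0)
    }
  }

  sampled <- purrr::map(pops, function(p) {
    ind <- sample.int(config$N_e, config$sample_haps %/% 2L)
    cols <- as.vector(rbind(2L * ind - 1L, 2L * ind))
    m <- pop_mats[[p]][, cols, drop = FALSE]
    matrix(as.integer(m), nrow = L)  # L x sample_haps
  })
  alleles <- t(do.call(cbind, sampled))
  pop_labels <- rep(pops, each = config$sample_haps)

  sweep_truth <- if (!is.null(config$sweeps)) {
    dplyr::mutate(config$sweeps,
                  snp_id = map$snp_id[.data$snp_index],
                  pos_bp = map$pos_bp[.data$snp_index],
                  final_freq = purrr::map_dbl(.data$population, function(p) {
                    f <- sweep_freq[[p]]
                    if (is.null(f)) 0 else f
                  }))
  } else {
    tibble(population = character(), snp_index = integer(), s = numeric(),
           start_gen = integer(), rescue = logical(), snp_id = character(),
           pos_bp = numeric(), final_freq = numeric())
  }
  split_times <- if (config$n_pops >= 2L) {
    prs <- utils::combn(pops, 2L)
    tibble(pop_a = prs[1, ], pop_b = prs[2, ],
           divergence_gens = 2L * config$post_split_gens)
  } else {
    tibble(pop_a = character(), pop_b = character(), divergence_gens = integer())
  }

  keep <- rep(TRUE, L)
  if (config$drop_monomorphic) {
    cnt <- colSums(alleles)
    keep <- cnt > 0L & cnt < nrow(alleles)
    if (nrow(sweep_truth)) keep[sweep_truth$snp_index] <- TRUE
  }
  map <- validate_snp_map(map[keep, , drop = FALSE])
  haps <- haplotype_set(alleles[, keep, drop = FALSE], pop = pop_labels, map = map)
  list(haps = haps, map = map,
       truth = list(sweeps = sweep_truth, split_times = split_times))
}

# Post-split evolution of one population carrying a sweep; if the derived
# allele is lost at the end of the selected phase and rescue is on, the
# selected phase is redrawn (up to 100 attempts).
evolve_with_sweep <- function(anc, config, pos_cm, sw) {
  site <- as.integer(sw$snp_index)
  pre <- as.integer(sw$start_gen)
  mat <- if (pre > 0L) {
    cpp_wf_evolve(anc, pre, config$mutation_rate, pos_cm, -1L, 0)
  } else {
    anc
  }
  sel_gens <- config$post_split_gens - pre
  attempts <- if (isTRUE(sw$rescue)) 100L else 1L
  lo <- if ("min_freq" %in% names(sw)) sw$min_freq else 0
  hi <- if ("max_freq" %in% names(sw)) sw$max_freq else 1
  for (a in seq_len(attempts)) {
    start <- mat
    row <- site
    # the sweep allele is a new mutation: clear standing variation at the
    # site, then place one derived copy on a random haplotype
    start[row, ] <- as.raw(0L)
    h <- sample.int(ncol(start), 1L)
    start[row, h] <- as.raw(1L)
    out <- cpp_wf_evolve(start, sel_gens, config$mutation_rate, pos_cm,
                         site - 1L, sw$s)
    freq <- cpp_raw_counts(out[row, , drop = FALSE])[1] / ncol(out)
    if (!isTRUE(sw$rescue) || (freq >= max(lo, 1e-12) && freq <= hi)) {
      return(list(mat = out, final_freq = freq))
    }
  }
  abort(sprintf("sweep at SNP %d outside the target frequency band in all %d attempts",
                site, attempts))
}
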