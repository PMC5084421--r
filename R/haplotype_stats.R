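# Haplotype-length statistics: EHH/iHH, iHS, nSL, windowed H12 and
# cross-population XP-EHH.

chrom_int <- function(map) as.integer(factor(map$chrom, levels = unique(map$chrom)))

# Genetic positions used for EHH integration; falls back to a constant
# 1 cM/Mb when the map has no genetic positions.
effective_cm <- function(map) {
  if (anyNA(map$pos_cm)) {
    warn("SNP map has no (complete) genetic positions: using 1 cM/Mb")
    return(map$pos_bp / 1e6)
  }
  map$pos_cm
}

#' Extended haplotype homozygosity curve at one core SNP
#'
#' EHH at offset k is the fraction of carrier-haplotype pairs that are
#' identical over the whole span from the core to offset k; it is 1 at the
#' core and non-increasing outward. Extension stops when EHH falls below
#' `truncation` (that point is kept), at a physical gap larger than
#' `max_gap_bp` between adjacent SNPs, or at the chromosome end (the curve is
#' then flagged edge-truncated).
#'
#' @param haps A [haplotype_set()].
#' @param population Population whose haplotypes are used.
#' @param core Core SNP id (or index into the map).
#' @param allele `"derived"`, `"ancestral"` (carriers of that allele at the
#'   core) or `"all"` (every haplotype of the population, as in XP-EHH).
#' @param truncation EHH value below which extension stops.
#' @param max_gap_bp Maximum tolerated physical gap between adjacent SNPs.
#' @param max_extend_bp Maximum extension from the core in bp (the scan
#'   software's documented default of 1 Mb); at desk scale a few identical
#'   haplotype pairs can otherwise hold EHH above the truncation for
#'   megabases.
#' @return A tibble with columns `offset` (signed SNP offset from the core),
#'   `snp_id`, `ehh` and `distance_cm`, with attributes `edge_left`,
#'   `edge_right` and `n_carriers`. `NULL` if fewer than 2 carriers.
#' @export
ehh <- function(haps, population, core, allele = c("derived", "ancestral", "all"),
                truncation = 0.05, max_gap_bp = 2e5, max_extend_bp = 1e6) {
  allele <- match.arg(allele)
  map <- haps$map
  core_idx <- if (is.character(core)) match(core, map$snp_id) else as.integer(core)
  if (is.na(core_idx)) abort("unknown core SNP")
  X <- pop_alleles(haps, population)
  rows <- switch(allele,
    derived = which(X[, core_idx] == 1L),
    ancestral = which(X[, core_idx] == 0L),
    all = seq_len(nrow(X))
  )
  if (length(rows) < 2L) return(NULL)
  cm <- effective_cm(map)
  res <- cpp_ehh_curve(X, rows - 1L, core_idx - 1L, map$pos_bp, chrom_int(map),
                       truncation, max_gap_bp, max_extend_bp)
  left_idx <- rev(res$left_idx) + 1L
  right_idx <- res$right_idx + 1L
  idx <- c(left_idx, core_idx, right_idx)
  curve <- tibble(
    offset = idx - core_idx,
    snp_id = map$snp_id[idx],
    ehh = c(rev(res$left_ehh), 1, res$right_ehh),
    distance_cm = abs(cm[idx] - cm[core_idx])
  )
  attr(curve, "edge_left") <- res$edge_left
  attr(curve, "edge_right") <- res$edge_right
  attr(curve, "n_carriers") <- length(rows)
  curve
}

#' Integrated EHH of a curve
#'
#' The trapezoidal integral of EHH over genetic distance, both directions
#' summed, integrated down to the truncation point of the curve.
#'
#' @param curve A curve from [ehh()].
#' @return The integral, in cM.
#' @export
ihh <- function(curve) {
  if (is.null(curve)) return(NA_real_)
  side_area <- function(side) {
    side <- side[order(abs(side$offset)), ]
    e <- c(1, side$ehh)
    d <- c(0, side$distance_cm)
    sum(0.5 * (e[-1] + e[-length(e)]) * diff(d))
  }
  side_area(curve[curve$offset < 0, ]) + side_area(curve[curve$offset > 0, ])
}

# Standardize values to mean 0 / sd 1 within derived-allele-frequency bins
# (equal width); bins with fewer than `min_bin` values are merged with their
# left (else right) neighbour.
standardize_by_freq <- function(values, freq, n_bins = 50L, min_bin = 20L) {
  ok <- !is.na(values)
  bin <- findInterval(freq, seq(0, 1, length.out = n_bins + 1),
                      rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin[ok], nbins = n_bins)
  relabel <- seq_len(n_bins)
  occupied <- which(counts > 0)
  small <- occupied[counts[occupied] < min_bin]
  if (length(small) && length(occupied) > 1L) {
    inform(sprintf("merging %d frequency bin(s) with < %d cores into neighbours",
                   length(small), min_bin))
    for (b in small) {
      neigh <- occupied[occupied != b]
      target <- if (any(neigh < b)) max(neigh[neigh < b]) else min(neigh[neigh > b])
      relabel[relabel == b] <- target
      counts[target] <- counts[target] + counts[b]
      counts[b] <- 0L
      occupied <- which(counts > 0)
    }
  }
  bin <- relabel[bin]
  out <- rep(NA_real_, length(values))
  for (b in unique(bin[ok])) {
    sel <- ok & bin == b
    m <- mean(values[sel])
    s <- stats::sd(values[sel])
    if (is.na(s) || s == 0) next
    out[sel] <- (values[sel] - m) / s
  }
  out
}

ihs_core_snps <- function(X, map, maf) {
  freq <- colMeans(X)
  which(!is.na(map$ancestral) & freq >= maf & freq <= 1 - maf &
          colSums(X) >= 2L & colSums(1L - X) >= 2L)
}

#' |iHS| score tracks
#'
#' For each core SNP (known ancestral state, derived frequency within
#' `[maf, 1 - maf]`, at least two carriers of each allele), the
#' unstandardized statistic is `ln(iHH_ancestral / iHH_derived)`, with iHH
#' the trapezoidal integral of the allele-class EHH decay over genetic
#' distance. Values are standardized to mean 0 / sd 1 within equal-width
#' derived-allele-frequency bins across the genome (per population), and the
#' absolute value is reported (`orientation = high_is_evidence`).
#'
#' @inheritParams ehh
#' @param populations Populations to scan (default all).
#' @param maf Core derived-allele frequency bound.
#' @param freq_bins Number of equal-width standardization bins.
#' @param min_bin_cores Bins with fewer cores are merged with a neighbour.
#' @param drop_edge Drop cores whose EHH curve was truncated by a chromosome
#'   end instead of keeping them (default keeps them).
#' @return A tidy track tibble (test `iHS`).
#' @export
ihs_tracks <- function(haps, populations = NULL, truncation = 0.05,
                       max_gap_bp = 2e5, max_extend_bp = 1e6, maf = 0.05,
                       freq_bins = 50L, min_bin_cores = 20L,
                       drop_edge = FALSE) {
  map <- haps$map
  cm <- effective_cm(map)
  cid <- chrom_int(map)
  if (is.null(populations)) populations <- populations(haps)
  purrr::map_dfr(populations, function(p) {
    X <- pop_alleles(haps, p)
    cores <- ihs_core_snps(X, map, maf)
    vals <- rep(NA_real_, nrow(map))
    if (length(cores)) {
      res <- cpp_ihs_ihh(X, cores - 1L, map$pos_bp, cm, cid, truncation,
                         max_gap_bp, max_extend_bp)
      un <- log(res$ihh_anc / res$ihh_der)
      un[!is.finite(un)] <- NA_real_
      if (drop_edge) un[res$edge] <- NA_real_
      std <- standardize_by_freq(un, colMeans(X)[cores], freq_bins, min_bin_cores)
      vals[cores] <- abs(std)
    }
    score_track(map, "iHS", p, vals, "high_is_evidence")
  })
}

#' |nSL| score tracks
#'
#' Same construction as [ihs_tracks()] but the haplotype-length measure `SL`
#' is the mean, over carrier pairs, of the number of consecutive SNPs (core
#' included, both directions, each direction capped at `max_extension` SNPs)
#' over which the pair is identical; no genetic map is needed. The statistic
#' is `ln(SL_ancestral / SL_derived)`, standardized within
#' derived-allele-frequency bins and reported as an absolute value.
#'
#' @inheritParams ihs_tracks
#' @param max_extension Per-direction cap, in segregating sites.
#' @return A tidy track tibble (test `nSL`).
#' @export
nsl_tracks <- function(haps, populations = NULL, max_extension = 200L,
                       maf = 0.05, freq_bins = 50L, min_bin_cores = 20L) {
  map <- haps$map
  cid <- chrom_int(map)
  if (is.null(populations)) populations <- populations(haps)
  purrr::map_dfr(populations, function(p) {
    X <- pop_alleles(haps, p)
    cores <- ihs_core_snps(X, map, maf)
    vals <- rep(NA_real_, nrow(map))
    if (length(cores)) {
      res <- cpp_nsl_sl(X, cores - 1L, cid, max_extension)
      un <- log(res$sl_anc / res$sl_der)
      un[!is.finite(un)] <- NA_real_
      std <- standardize_by_freq(un, colMeans(X)[cores], freq_bins, min_bin_cores)
      vals[cores] <- abs(std)
    }
    score_track(map, "nSL", p, vals, "high_is_evidence")
  })
}

#' H12 score tracks
#'
#' Garud's H12 over sliding windows of `window` SNPs: haplotypes are compared
#' as exact strings over the window, and with `p_j` the descending haplotype
#' frequencies, `H12 = (p1 + p2)^2 + sum_{j>2} p_j^2`. Each window's value is
#' assigned to its central SNP (`orientation = high_is_evidence`).
#'
#' @inheritParams sfs_tracks
#' @return A tidy track tibble (test `H12`).
#' @export
h12_tracks <- function(haps, populations = NULL, window = 100L, step = 1L) {
  map <- haps$map
  if (is.null(populations)) populations <- populations(haps)
  purrr::map_dfr(populations, function(p) {
    X <- pop_alleles(haps, p)
    vals <- rep(NA_real_, nrow(map))
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch)
      centers <- window_centers(length(idx), window, step)
      if (!length(centers)) next
      vals[idx[centers + 1L]] <- cpp_h12(X[, idx, drop = FALSE], centers, window)
    }
    score_track(map, "H12", p, vals, "high_is_evidence")
  })
}

#' XP-EHH score tracks
#'
#' For each population pair (A, B) and core SNP, the EHH of each population
#' is computed over all of its haplotypes (not split by allele) and
#' integrated over genetic distance, truncating where the pooled
#' two-population EHH falls below `truncation`; the pairwise statistic is
#' `ln(IHH_A / IHH_B)`, standardized genome-wide to mean 0 / sd 1. Each
#' population's track is the mean of its standardized pairwise tracks with
#' itself in the numerator (`orientation = abs_is_evidence`). Populations
#' with fewer than 4 haplotypes are excluded.
#'
#' @inheritParams ihs_tracks
#' @return A tidy track tibble (test `XPEHH`), one track per population.
#' @export
xpehh_tracks <- function(haps, populations = NULL, truncation = 0.05,
                         max_gap_bp = 2e5, max_extend_bp = 1e6) {
  map <- haps$map
  cm <- effective_cm(map)
  cid <- chrom_int(map)
  if (is.null(populations)) populations <- populations(haps)
  sizes <- table(haps$pop)[populations]
  small <- populations[sizes < 4L]
  if (length(small)) {
    inform(paste0("excluding population(s) with < 4 haplotypes from XP-EHH: ",
                  paste(small, collapse = ", ")))
    populations <- setdiff(populations, small)
  }
  if (length(populations) < 2L) abort("XP-EHH needs >= 2 populations")
  cores <- seq_len(nrow(map))
  pairs <- utils::combn(populations, 2L, simplify = FALSE)
  # standardized ln(IHH_A/IHH_B) per unordered pair, A = first alphabetically
  pair_z <- purrr::map(pairs, function(pr) {
    rows_a <- which(haps$pop == pr[1])
    rows_b <- which(haps$pop == pr[2])
    res <- cpp_xpehh_ihh(haps$alleles, rows_a - 1L, rows_b - 1L, cores - 1L,
                         map$pos_bp, cm, cid, truncation, max_gap_bp,
                         max_extend_bp)
    un <- log(res$ihh_a / res$ihh_b)
    un[!is.finite(un)] <- NA_real_
    as.numeric(scale(un))
  })
  names(pair_z) <- vapply(pairs, paste, "", collapse = "\r")
  purrr::map_dfr(populations, function(p) {
    contrib <- purrr::map(pairs, function(pr) {
      z <- pair_z[[paste(pr, collapse = "\r")]]
      if (pr[1] == p) z else if (pr[2] == p) -z else NULL
    })
    contrib <- contrib[!vapply(contrib, is.null, TRUE)]
    m <- do.call(cbind, contrib)
    vals <- rowMeans(m, na.rm = TRUE)
    vals[is.nan(vals)] <- NA_real_
    score_track(map, "XPEHH", p, vals, "abs_is_evidence")
  })
}
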