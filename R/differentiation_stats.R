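# Population-differentiation statistics: per-SNP pairwise FST with
# sliding-window averaging, and VarLD (eigenvalue comparison of windowed LD
# correlation matrices), both reduced to one track per population.

#' Per-SNP pairwise FST
#'
#' Wright's fixation index from haplotype-frequency heterozygosities:
#' `FST = (H_T - H_S) / H_T`, where `H_S` is the mean within-population
#' expected heterozygosity `2 p (1 - p)` and `H_T = 2 pbar (1 - pbar)` from
#' the pooled derived-allele frequency. SNPs monomorphic in the pooled
#' sample yield `NA`. Equal allele frequencies give 0 and a fixed difference
#' (equal sample sizes) gives 1. `form = "ho_he"` instead returns
#' `(H_S - H_T) / H_T`, the sign-inverted ratio of observed-to-expected
#' heterozygosity excess sometimes quoted for this index.
#'
#' @param count_a,count_b Derived-allele counts in populations A and B.
#' @param n_a,n_b Haplotype totals (must be positive).
#' @param form `"wright"` (default) or `"ho_he"`.
#' @return Numeric vector of FST values.
#' @export
fst_snp <- function(count_a, n_a, count_b, n_b, form = c("wright", "ho_he")) {
  form <- match.arg(form)
  if (any(n_a <= 0) || any(n_b <= 0)) abort("zero haplotypes in a population")
  p_a <- count_a / n_a
  p_b <- count_b / n_b
  h_s <- (2 * p_a * (1 - p_a) + 2 * p_b * (1 - p_b)) / 2
  p_t <- (count_a + count_b) / (n_a + n_b)
  h_t <- 2 * p_t * (1 - p_t)
  out <- ifelse(h_t > 0, (h_t - h_s) / h_t, NA_real_)
  if (form == "ho_he") out <- -out
  out
}

# sliding mean of x over windows, skipping NAs; all-NA windows give NA
window_mean_na <- function(x, window, centers) {
  ok <- !is.na(x)
  x[!ok] <- 0
  s <- window_sum(x, window, centers)
  k <- window_sum(as.numeric(ok), window, centers)
  ifelse(k > 0, s / k, NA_real_)
}

#' Windowed, population-averaged FST tracks
#'
#' Per-SNP pairwise FST is averaged over sliding windows of `window` SNPs
#' (missing SNPs skipped in the mean), assigned to the central SNP, and each
#' population's track is the mean of its windowed pairwise tracks with every
#' other population (`orientation = high_is_evidence`).
#'
#' @inheritParams sfs_tracks
#' @param form Passed to [fst_snp()].
#' @return A tidy track tibble (test `FST`), one track per population.
#' @export
fst_tracks <- function(haps, populations = NULL, window = 100L, step = 1L,
                       form = "wright") {
  map <- haps$map
  if (is.null(populations)) populations <- populations(haps)
  if (length(populations) < 2L) abort("FST needs >= 2 populations")
  counts <- purrr::map(populations, function(p) colSums(pop_alleles(haps, p)))
  sizes <- purrr::map_int(populations, function(p) sum(haps$pop == p))
  names(counts) <- names(sizes) <- populations
  pairs <- utils::combn(populations, 2L, simplify = FALSE)
  pair_windowed <- purrr::map(pairs, function(pr) {
    snp_fst <- fst_snp(counts[[pr[1]]], sizes[[pr[1]]],
                       counts[[pr[2]]], sizes[[pr[2]]], form = form)
    vals <- rep(NA_real_, nrow(map))
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch)
      centers <- window_centers(length(idx), window, step)
      if (!length(centers)) next
      vals[idx[centers + 1L]] <- window_mean_na(snp_fst[idx], window, centers)
    }
    vals
  })
  names(pair_windowed) <- vapply(pairs, paste, "", collapse = "\r")
  purrr::map_dfr(populations, function(p) {
    m <- do.call(cbind, pair_windowed[vapply(pairs, function(pr) p %in% pr, TRUE)])
    vals <- rowMeans(m, na.rm = TRUE)
    vals[is.nan(vals)] <- NA_real_
    score_track(map, "FST", p, vals, "high_is_evidence")
  })
}

#' VarLD score tracks
#'
#' For each population pair and sliding window of `window` SNPs, the signed
#' Pearson correlation matrices of the SNP allele columns are computed in
#' each population (SNPs with zero variance in a window contribute zero
#' correlation to all partners and a unit diagonal); the raw VarLD score is
#' the summed absolute difference between the rank-matched descending
#' eigenvalues of the two matrices. Raw scores are standardized genome-wide
#' (mean 0, sd 1) per pair, assigned to the central SNP, and averaged per
#' population over its pairs (`orientation = high_is_evidence`).
#'
#' @inheritParams sfs_tracks
#' @return A tidy track tibble (test `VarLD`), one track per population.
#' @export
varld_tracks <- function(haps, populations = NULL, window = 100L, step = 1L) {
  if (window < 2L) abort("VarLD window must span >= 2 SNPs")
  map <- haps$map
  if (is.null(populations)) populations <- populations(haps)
  if (length(populations) < 2L) abort("VarLD needs >= 2 populations")
  mono <- purrr::map_int(populations, function(p) {
    X <- pop_alleles(haps, p)
    sum(colSums(X) %in% c(0L, nrow(X)))
  })
  if (any(mono > 0)) {
    inform(sprintf("VarLD: %s SNP(s) with zero variance in some population get zero correlations",
                   paste(mono, collapse = "/")))
  }
  pairs <- utils::combn(populations, 2L, simplify = FALSE)
  pair_z <- purrr::map(pairs, function(pr) {
    XA <- pop_alleles(haps, pr[1])
    XB <- pop_alleles(haps, pr[2])
    vals <- rep(NA_real_, nrow(map))
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch)
      centers <- window_centers(length(idx), window, step)
      if (!length(centers)) next
      vals[idx[centers + 1L]] <- cpp_varld_raw(XA[, idx, drop = FALSE],
                                               XB[, idx, drop = FALSE],
                                               centers, window)
    }
    as.numeric(scale(vals))
  })
  names(pair_z) <- vapply(pairs, paste, "", collapse = "\r")
  purrr::map_dfr(populations, function(p) {
    m <- do.call(cbind, pair_z[vapply(pairs, function(pr) p %in% pr, TRUE)])
    vals <- rowMeans(m, na.rm = TRUE)
    vals[is.nan(vals)] <- NA_real_
    score_track(map, "VarLD", p, vals, "high_is_evidence")
  })
}

#' Raw VarLD score for a single window
#'
#' Exposed mainly for testing: the summed absolute difference between the
#' rank-matched eigenvalues of the two within-window correlation matrices.
#'
#' @param alleles_a,alleles_b 0/1 matrices (haplotypes x SNPs) over the same
#'   window of SNPs.
#' @return The raw (unstandardized) VarLD score.
#' @export
varld_window_raw <- function(alleles_a, alleles_b) {
  w <- ncol(alleles_a)
  if (w < 2L) abort("VarLD window must span >= 2 SNPs")
  if (ncol(alleles_b) != w) abort("windows must cover the same SNPs")
  a <- as.matrix(alleles_a); storage.mode(a) <- "integer"
  b <- as.matrix(alleles_b); storage.mode(b) <- "integer"
  center <- if (w %% 2L == 0L) w %/% 2L else w %/% 2L
  cpp_varld_raw(a, b, center, w)[1]
}
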