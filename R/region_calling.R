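# Empirical-outlier candidate-region detection on axis score tracks, and
# gene overlap. The genome-wide empirical distribution of each track is its
# own null: outliers are the top q fraction.

#' Empirical outlier threshold
#'
#' The `(1 - q)` empirical quantile (linear interpolation, type 7) of the
#' non-missing genome-wide scores.
#'
#' @param values Numeric vector of genome-wide scores (`NA` allowed).
#' @param q Upper-tail fraction (e.g. 0.001 for the top 0.1%).
#' @return The threshold value.
#' @export
empirical_threshold <- function(values, q) {
  v <- values[!is.na(values)]
  if (length(v) < 1 / q) {
    abort(sprintf("need >= %d non-missing values for q = %g, got %d",
                  ceiling(1 / q), q, length(v)))
  }
  unname(stats::quantile(v, probs = 1 - q, type = 7))
}

region_groups <- function(scores) {
  dplyr::group_split(dplyr::group_by(scores, .data$test, .data$population))
}

#' Strict candidate regions: 1-Mb bins with many top-0.1% SNPs
#'
#' Per track (axis x population), the genome-wide top `q` SNPs are outliers;
#' the genome is tiled into fixed, non-overlapping `bin_bp` bins anchored at
#' position 1 of each chromosome, and a bin is called when it holds at least
#' `min_snps` outliers. Adjacent called bins are merged into one region
#' (outlier counts summed, peak recomputed).
#'
#' @param scores A tidy track tibble (e.g. axis scores).
#' @param q Upper-tail fraction defining outliers.
#' @param min_snps Minimum outlier SNPs for a bin to be called.
#' @param bin_bp Bin width in bp.
#' @return A tibble of regions: `test`, `population`, `chrom`, `start_bp`,
#'   `end_bp`, `n_top_snps`, `peak_snp`, `peak_value`, `rule`.
#' @export
call_strict_regions <- function(scores, q = 0.001, min_snps = 25L, bin_bp = 1e6) {
  purrr::map_dfr(region_groups(scores), function(tr) {
    thr <- empirical_threshold(tr$value, q)
    out <- tr[!is.na(tr$value) & tr$value > thr, , drop = FALSE]
    if (!nrow(out)) return(empty_regions())
    out$bin <- floor((out$pos_bp - 1) / bin_bp)
    called <- out %>%
      dplyr::count(.data$chrom, .data$bin, name = "n_top") %>%
      dplyr::filter(.data$n_top >= min_snps) %>%
      dplyr::arrange(.data$chrom, .data$bin)
    if (!nrow(called)) return(empty_regions())
    called <- called %>%
      dplyr::group_by(.data$chrom) %>%
      dplyr::mutate(block = cumsum(c(1, diff(.data$bin) != 1))) %>%
      dplyr::ungroup()
    merged <- called %>%
      dplyr::group_by(.data$chrom, .data$block) %>%
      dplyr::summarise(start_bp = min(.data$bin) * bin_bp + 1,
                       end_bp = (max(.data$bin) + 1) * bin_bp,
                       .groups = "drop")
    purrr::map_dfr(seq_len(nrow(merged)), function(i) {
      rg <- merged[i, ]
      inside <- out[out$chrom == rg$chrom & out$pos_bp >= rg$start_bp &
                      out$pos_bp <= rg$end_bp, , drop = FALSE]
      peak <- inside[which.max(inside$value), ]
      tibble(test = tr$test[1], population = tr$population[1],
             chrom = rg$chrom, start_bp = rg$start_bp, end_bp = rg$end_bp,
             n_top_snps = nrow(inside), peak_snp = peak$snp_id,
             peak_value = peak$value, rule = "strict_0.1pct")
    })
  })
}

empty_regions <- function() {
  tibble(test = character(), population = character(), chrom = character(),
         start_bp = numeric(), end_bp = numeric(), n_top_snps = integer(),
         peak_snp = character(), peak_value = numeric(), rule = character())
}

#' Relaxed candidate regions: merged top-5% outlier runs
#'
#' SNPs above the genome-wide `1 - q` quantile are merged into one region
#' whenever consecutive outliers are at most `merge_gap_bp` apart;
#' single-SNP regions are allowed. Region bounds are the outlier positions.
#'
#' @inheritParams call_strict_regions
#' @param merge_gap_bp Maximum gap between consecutive outliers in a region.
#' @return A region tibble as in [call_strict_regions()], `rule =
#'   "relaxed_5pct"`.
#' @export
call_relaxed_regions <- function(scores, q = 0.05, merge_gap_bp = 1e6) {
  purrr::map_dfr(region_groups(scores), function(tr) {
    thr <- empirical_threshold(tr$value, q)
    out <- tr[!is.na(tr$value) & tr$value > thr, , drop = FALSE]
    if (!nrow(out)) return(empty_regions())
    out <- dplyr::arrange(out, .data$chrom, .data$pos_bp)
    out <- out %>%
      dplyr::group_by(.data$chrom) %>%
      dplyr::mutate(block = cumsum(c(1, diff(.data$pos_bp) > merge_gap_bp))) %>%
      dplyr::ungroup()
    out %>%
      dplyr::group_by(.data$chrom, .data$block) %>%
      dplyr::summarise(
        test = dplyr::first(.data$test), population = dplyr::first(.data$population),
        start_bp = min(.data$pos_bp), end_bp = max(.data$pos_bp),
        n_top_snps = dplyr::n(),
        peak_snp = .data$snp_id[which.max(.data$value)],
        peak_value = max(.data$value), .groups = "drop"
      ) %>%
      dplyr::mutate(rule = "relaxed_5pct") %>%
      dplyr::select(dplyr::all_of(names(empty_regions())))
  })
}

#' Overlap candidate regions with gene annotation
#'
#' A gene is reported for a region when their intervals (1-based inclusive)
#' intersect by at least 1 bp. Returns the region-to-gene mapping and the
#' deduplicated gene universe (the hand-off to enrichment tools).
#'
#' @param regions A region tibble.
#' @param genes A [read_gene_annotation()] tibble.
#' @return A list with `region_genes` (regions joined to overlapping genes)
#'   and `gene_universe` (sorted unique gene ids).
#' @export
overlap_genes <- function(regions, genes) {
  unmatched <- setdiff(unique(regions$chrom), unique(genes$chrom))
  if (length(unmatched)) {
    abort(paste0("region chromosome(s) absent from the annotation: ",
                 paste(unmatched, collapse = ", ")))
  }
  region_genes <- regions %>%
    dplyr::mutate(.region = dplyr::row_number()) %>%
    dplyr::inner_join(genes, by = "chrom", relationship = "many-to-many") %>%
    dplyr::filter(.data$start_bp.y <= .data$end_bp.x,
                  .data$end_bp.y >= .data$start_bp.x) %>%
    dplyr::rename(start_bp = "start_bp.x", end_bp = "end_bp.x",
                  gene_start_bp = "start_bp.y", gene_end_bp = "end_bp.y")
  list(region_genes = region_genes,
       gene_universe = sort(unique(region_genes$gene_id)))
}

#' Write regions as BED (plus a TSV with counts and peaks)
#'
#' BED output is 0-based half-open (converted at the boundary from the
#' internal 1-based inclusive intervals) and byte-deterministic for
#' identical inputs.
#'
#' @param regions A region tibble.
#' @param path Output BED path. A `.tsv` sidecar with `n_top_snps` and
#'   `peak_snp` columns is written next to it.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  bed <- paste(regions$chrom, fmt(regions$start_bp - 1), fmt(regions$end_bp),
               paste(regions$test, regions$population, sep = "."), sep = "\t")
  writeLines(bed, path)
  tsv <- sub("\\.bed$", "", path)
  readr::write_tsv(regions, paste0(tsv, ".tsv"))
  invisible(path)
}
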