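# Shared domain containers and readers/writers for the external formats the
# scan pipeline touches: phased VCF, plain haplotype tables, genetic maps,
# BED/GFF3 gene annotation and per-SNP score tracks.

ORIENTATIONS <- c("high_is_evidence", "low_is_evidence", "abs_is_evidence")

#' Build a SNP map
#'
#' A SNP map is a tibble with one row per SNP holding chromosome, physical
#' position (bp, 1-based), genetic position (cM), SNP identifier and the
#' ancestral allele (`NA` when the ancestral state is unknown). All haplotype
#' matrices and score tracks in the package are aligned to a SNP map.
#'
#' @param chrom Character vector of chromosome labels.
#' @param pos_bp Numeric vector of physical positions (1-based bp), strictly
#'   increasing within each chromosome.
#' @param pos_cm Numeric vector of genetic positions (cM), non-decreasing
#'   within each chromosome. `NA` allowed (fill via [read_genetic_map()]).
#' @param snp_id Character vector of unique SNP identifiers.
#' @param ancestral Character vector of ancestral alleles; `NA` marks SNPs
#'   whose ancestral state is unknown (such SNPs are never used as iHS/nSL
#'   cores and never enter derived-allele frequency classes).
#' @return A tibble of class `snp_map`.
#' @export
snp_map <- function(chrom, pos_bp, pos_cm = NA_real_, snp_id = NULL,
                    ancestral = NA_character_) {
  n <- length(pos_bp)
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(n))
  map <- tibble(
    chrom = as.character(rep_len(chrom, n)),
    pos_bp = as.numeric(pos_bp),
    pos_cm = as.numeric(rep_len(pos_cm, n)),
    snp_id = as.character(snp_id),
    ancestral = as.character(rep_len(ancestral, n))
  )
  validate_snp_map(map)
}

#' @rdname snp_map
#' @param map A candidate SNP map to validate.
#' @export
validate_snp_map <- function(map) {
  req <- c("chrom", "pos_bp", "pos_cm", "snp_id", "ancestral")
  missing_cols <- setdiff(req, names(map))
  if (length(missing_cols)) {
    abort(paste0("SNP map lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(map$snp_id)) abort("SNP ids must be unique")
  for (ch in unique(map$chrom)) {
    bp <- map$pos_bp[map$chrom == ch]
    if (is.unsorted(bp, strictly = TRUE)) {
      abort(paste0("pos_bp not strictly increasing on chromosome ", ch))
    }
    cm <- map$pos_cm[map$chrom == ch]
    cm <- cm[!is.na(cm)]
    if (length(cm) && is.unsorted(cm)) {
      abort(paste0("pos_cm not non-decreasing on chromosome ", ch))
    }
  }
  class(map) <- unique(c("snp_map", class(map)))
  map
}

#' Build a phased haplotype set
#'
#' The substrate of every statistic in the package: a binary matrix with one
#' row per haplotype and one column per SNP, coded 0 = ancestral and
#' 1 = derived (for SNPs with unknown ancestral state the coding is an
#' arbitrary but fixed reference orientation). Populations must contribute an
#' even number of haplotypes (phased diploids).
#'
#' @param alleles Integer matrix of 0/1 alleles, haplotypes x SNPs.
#' @param pop Character vector of population labels, one per haplotype row.
#' @param map The [snp_map()] the columns follow.
#' @param hap_id Optional haplotype identifiers.
#' @return An object of class `hap_set`: a list with elements `alleles`,
#'   `pop`, `hap_id` and `map`.
#' @export
haplotype_set <- function(alleles, pop, map, hap_id = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (!all(alleles %in% c(0L, 1L))) {
    abort("haplotype alleles must be strictly 0/1")
  }
  map <- validate_snp_map(map)
  if (ncol(alleles) != nrow(map)) {
    abort(sprintf("haplotype matrix has %d columns but SNP map has %d SNPs",
                  ncol(alleles), nrow(map)))
  }
  pop <- as.character(pop)
  if (length(pop) != nrow(alleles)) {
    abort("one population label is required per haplotype row")
  }
  odd <- names(which(table(pop) %% 2L != 0L))
  if (length(odd)) {
    abort(paste0("populations with an odd haplotype count (unphased diploids?): ",
                 paste(odd, collapse = ", ")))
  }
  if (is.null(hap_id)) hap_id <- paste0(pop, "_h", stats::ave(seq_along(pop), pop, FUN = seq_along))
  colnames(alleles) <- map$snp_id
  structure(list(alleles = alleles, pop = pop, hap_id = as.character(hap_id),
                 map = map),
            class = "hap_set")
}

#' @export
print.hap_set <- function(x, ...) {
  cat(sprintf("<hap_set> %d haplotypes x %d SNPs, %d population(s): %s\n",
              nrow(x$alleles), ncol(x$alleles), length(unique(x$pop)),
              paste(sort(unique(x$pop)), collapse = ", ")))
  invisible(x)
}

#' Populations of a haplotype set
#' @param haps A [haplotype_set()].
#' @return Sorted character vector of population labels.
#' @export
populations <- function(haps) sort(unique(haps$pop))

# subset the rows of one population (keeps the map)
pop_alleles <- function(haps, population) {
  keep <- haps$pop == population
  if (!any(keep)) abort(paste0("unknown population: ", population))
  haps$alleles[keep, , drop = FALSE]
}

#' Build a tidy score track
#'
#' A score track is one selection test evaluated in one population: a tibble
#' with one row per SNP of the map and columns `test`, `population`, `chrom`,
#' `pos_bp`, `snp_id`, `value` and `orientation`. `orientation` states which
#' direction of `value` is evidence of selection and drives the transform
#' applied before the factor analysis.
#'
#' @param map A [snp_map()].
#' @param test Test name.
#' @param population Population label.
#' @param values Numeric vector aligned to the map; `NA` permitted.
#' @param orientation One of `"high_is_evidence"`, `"low_is_evidence"`,
#'   `"abs_is_evidence"`.
#' @return A tibble (one row per SNP).
#' @export
score_track <- function(map, test, population, values, orientation) {
  orientation <- match.arg(orientation, ORIENTATIONS)
  if (length(values) != nrow(map)) {
    abort(sprintf("track '%s' has %d values for %d SNPs", test,
                  length(values), nrow(map)))
  }
  tibble(
    test = test, population = population,
    chrom = map$chrom, pos_bp = map$pos_bp, snp_id = map$snp_id,
    value = as.numeric(values), orientation = orientation
  )
}

# ---- phased VCF ------------------------------------------------------------

#' Read phased haplotypes from a VCF
#'
#' Biallelic SNPs with fully phased genotypes (`|` separator) are converted to
#' a binary haplotype matrix polarized by the ancestral allele. The ancestral
#' allele is taken from the INFO `AA` tag, or from `ancestral` (a named
#' character vector `snp_id -> allele`, or the path of a two-column TSV
#' `snp_id<TAB>ancestral`). SNPs whose ancestral allele equals ALT are
#' flipped so that 0 always means ancestral; SNPs without ancestral
#' annotation are kept REF-coded with `ancestral = NA`; SNPs whose annotated
#' ancestral allele matches neither REF nor ALT are dropped (count reported).
#'
#' @param path VCF file (plain text or gzipped).
#' @param ancestral Optional ancestral-allele source overriding the AA tag.
#' @param pop_of_sample Optional named character vector mapping sample name to
#'   population label; defaults to one population `"pop1"` for all samples.
#' @return A list with elements `haps` ([haplotype_set()]) and `map`
#'   ([snp_map()]).
#' @export
read_phased_vcf <- function(path, ancestral = NULL, pop_of_sample = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the 'vcfR' package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
  if (any(multi)) {
    abort(sprintf("multiallelic or ALT-less records are not supported (%d found, first at %s:%s)",
                  sum(multi), fix$CHROM[which(multi)[1]], fix$POS[which(multi)[1]]))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  unphased <- array(grepl("/", gt, fixed = TRUE), dim = dim(gt))
  if (any(unphased)) {
    bad <- which(unphased, arr.ind = TRUE)[1, ]
    abort(sprintf("unphased genotype at record %s:%s sample %s",
                  fix$CHROM[bad[1]], fix$POS[bad[1]], colnames(gt)[bad[2]]))
  }
  left <- substr(gt, 1L, 1L)
  right <- substr(gt, 3L, 3L)
  n_snp <- nrow(gt)
  samples <- colnames(gt)
  # haplotypes x SNPs, ALT-coded
  alleles <- matrix(0L, nrow = 2L * length(samples), ncol = n_snp)
  alleles[seq(1L, nrow(alleles), by = 2L), ] <- t(matrix(as.integer(left), nrow = n_snp))
  alleles[seq(2L, nrow(alleles), by = 2L), ] <- t(matrix(as.integer(right), nrow = n_snp))

  snp_id <- fix$ID
  if (is.null(snp_id)) snp_id <- rep(NA_character_, n_snp)
  fallback <- is.na(snp_id) | snp_id == "."
  snp_id[fallback] <- paste0(fix$CHROM[fallback], "_", fix$POS[fallback])

  aa <- resolve_ancestral(vcf, fix, snp_id, ancestral)
  anc <- rep(NA_character_, n_snp)
  flip <- rep(FALSE, n_snp)
  drop <- rep(FALSE, n_snp)
  known <- !is.na(aa)
  anc[known & aa == fix$REF] <- aa[known & aa == fix$REF]
  is_alt <- known & aa == fix$ALT
  anc[is_alt] <- aa[is_alt]
  flip[is_alt] <- TRUE
  neither <- known & aa != fix$REF & aa != fix$ALT
  drop[neither] <- TRUE
  if (any(drop)) {
    inform(sprintf("dropped %d SNP(s) whose ancestral allele matches neither REF nor ALT",
                   sum(drop)))
  }
  if (any(flip)) alleles[, flip] <- 1L - alleles[, flip]

  keep <- !drop
  map <- snp_map(chrom = fix$CHROM[keep], pos_bp = as.numeric(fix$POS[keep]),
                 pos_cm = NA_real_, snp_id = snp_id[keep], ancestral = anc[keep])
  pops <- if (is.null(pop_of_sample)) {
    rep("pop1", length(samples))
  } else {
    unname(pop_of_sample[samples])
  }
  haps <- haplotype_set(alleles[, keep, drop = FALSE],
                        pop = rep(pops, each = 2L), map = map,
                        hap_id = paste0(rep(samples, each = 2L), c("_1", "_2")))
  list(haps = haps, map = map)
}

resolve_ancestral <- function(vcf, fix, snp_id, ancestral) {
  if (is.null(ancestral)) {
    info <- fix$INFO
    aa <- rep(NA_character_, length(info))
    hit <- regmatches(info, regexpr("(?:^|;)AA=[^;]+", info))
    has <- grepl("(?:^|;)AA=", info)
    aa[has] <- sub("^;?AA=", "", regmatches(info, regexpr("(?:^|;)AA=[^;]+", info)))
    return(toupper(aa))
  }
  if (is.character(ancestral) && length(ancestral) == 1L && file.exists(ancestral)) {
    tab <- utils::read.table(ancestral, header = FALSE, stringsAsFactors = FALSE)
    ancestral <- stats::setNames(tab[[2]], tab[[1]])
  }
  toupper(unname(ancestral[snp_id]))
}

#' Write a haplotype set as a minimal phased VCF
#'
#' REF is the 0-coded allele (the ancestral allele where known, `A`
#' otherwise) and ALT the 1-coded allele; the ancestral allele is recorded in
#' the INFO `AA` tag so that [read_phased_vcf()] restores the polarization.
#'
#' @param haps A [haplotype_set()].
#' @param path Output file.
#' @param derived_allele Symbol used for the derived (1-coded) allele.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(haps, path, derived_allele = "G") {
  map <- haps$map
  ref <- ifelse(is.na(map$ancestral), "A", map$ancestral)
  alt <- rep(derived_allele, nrow(map))
  alt[alt == ref] <- "T"
  info <- ifelse(is.na(map$ancestral), ".", paste0("AA=", map$ancestral))
  n_ind <- nrow(haps$alleles) / 2L
  ind_names <- paste0(haps$pop[seq(1L, 2L * n_ind, by = 2L)], "_ind", seq_len(n_ind))
  gt_left <- t(haps$alleles[seq(1L, 2L * n_ind, by = 2L), , drop = FALSE])
  gt_right <- t(haps$alleles[seq(2L, 2L * n_ind, by = 2L), , drop = FALSE])
  gt <- matrix(paste0(gt_left, "|", gt_right), nrow = nrow(map))
  body <- cbind(map$chrom, format(map$pos_bp, scientific = FALSE, trim = TRUE),
                map$snp_id, ref, alt, ".", "PASS", info, "GT", gt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ind_names), collapse = "\t")
  )
  writeLines(c(header, apply(body, 1L, paste, collapse = "\t")), path)
  invisible(path)
}

# ---- haplotype table -------------------------------------------------------

#' Read/write the plain haplotype-table format
#'
#' A TSV dialect that round-trips a [haplotype_set()] losslessly. Map
#' metadata travels in `##snp` comment lines
#' (`##snp<TAB>id<TAB>chrom<TAB>pos_bp<TAB>pos_cm<TAB>ancestral`), followed by
#' a header `pop<TAB>hap_id<TAB><snp ids...>` and one row of 0/1 alleles per
#' haplotype.
#'
#' @param path File path.
#' @return For `read_hap_table()`, a list with `haps` and `map`.
#' @export
read_hap_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort("no haplotypes: file is empty")
  is_map <- startsWith(lines, "##snp\t")
  map_lines <- lines[is_map]
  lines <- lines[!startsWith(lines, "##")]
  if (length(lines) < 2L) abort("no haplotypes: need a header and at least one row")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 3L || header[1] != "pop" || header[2] != "hap_id") {
    abort("malformed header: expected 'pop<TAB>hap_id<TAB><snp ids...>'")
  }
  ids <- header[-(1:2)]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  n_field <- lengths(rows)
  bad <- which(n_field != length(header))
  if (length(bad)) {
    abort(sprintf("ragged row %d: %d fields where %d expected",
                  bad[1] + 1L, n_field[bad[1]], length(header)))
  }
  pop <- vapply(rows, `[[`, "", 1L)
  hap_id <- vapply(rows, `[[`, "", 2L)
  tokens <- t(vapply(rows, function(r) r[-(1:2)], character(length(ids))))
  if (length(ids) == 1L) tokens <- matrix(tokens, ncol = 1L)
  ok <- tokens %in% c("0", "1")
  if (!all(ok)) {
    bad <- which(!matrix(ok, nrow = nrow(tokens)), arr.ind = TRUE)[1, ]
    abort(sprintf("non-binary allele token '%s' at row %d, SNP %s",
                  tokens[bad[1], bad[2]], bad[1] + 1L, ids[bad[2]]))
  }
  alleles <- matrix(as.integer(tokens), nrow = nrow(tokens))
  if (length(map_lines)) {
    parts <- strsplit(map_lines, "\t", fixed = TRUE)
    map <- snp_map(
      chrom = vapply(parts, `[[`, "", 3L),
      pos_bp = as.numeric(vapply(parts, `[[`, "", 4L)),
      pos_cm = suppressWarnings(as.numeric(vapply(parts, `[[`, "", 5L))),
      snp_id = vapply(parts, `[[`, "", 2L),
      ancestral = {
        a <- vapply(parts, `[[`, "", 6L)
        a[a == "."] <- NA_character_
        a
      }
    )
    if (!identical(map$snp_id, ids)) abort("##snp lines do not match the header SNP ids")
  } else {
    warn("no ##snp map lines: building a stub map (chrom '1', 1 kb spacing)")
    map <- snp_map(chrom = "1", pos_bp = 1000 * seq_along(ids), snp_id = ids)
  }
  haps <- haplotype_set(alleles, pop = pop, map = map, hap_id = hap_id)
  list(haps = haps, map = map)
}

#' @rdname read_hap_table
#' @param haps A [haplotype_set()].
#' @export
write_hap_table <- function(haps, path) {
  map <- haps$map
  anc <- ifelse(is.na(map$ancestral), ".", map$ancestral)
  cm <- ifelse(is.na(map$pos_cm), "NA", format(map$pos_cm, digits = 15, trim = TRUE))
  map_lines <- paste("##snp", map$snp_id, map$chrom,
                     format(map$pos_bp, scientific = FALSE, trim = TRUE), cm, anc,
                     sep = "\t")
  header <- paste(c("pop", "hap_id", map$snp_id), collapse = "\t")
  body <- paste(haps$pop, haps$hap_id,
                apply(haps$alleles, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(map_lines, header, body), path)
  invisible(path)
}

# ---- genetic map -----------------------------------------------------------

#' Interpolate genetic positions from a 3-column map
#'
#' The map file holds `chrom pos_bp pos_cm` points (whitespace separated,
#' optional header). SNPs between points are linearly interpolated; SNPs
#' beyond the first/last point are extrapolated at the terminal cM/bp rate.
#'
#' @param map A [snp_map()].
#' @param path Genetic-map file.
#' @return The map with `pos_cm` filled in.
#' @export
read_genetic_map <- function(map, path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (!is.numeric(tab[[2]])) tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) abort("genetic map needs >= 3 columns: chrom, pos_bp, pos_cm")
  names(tab)[1:3] <- c("chrom", "pos_bp", "pos_cm")
  tab$chrom <- as.character(tab$chrom)
  absent <- setdiff(unique(map$chrom), unique(tab$chrom))
  if (length(absent)) {
    abort(paste0("chromosome(s) absent from the genetic map: ",
                 paste(absent, collapse = ", ")))
  }
  out <- map
  for (ch in unique(map$chrom)) {
    pts <- tab[tab$chrom == ch, , drop = FALSE]
    pts <- pts[order(pts$pos_bp), , drop = FALSE]
    if (nrow(pts) < 2L) abort(paste0("need >= 2 map points on chromosome ", ch))
    sel <- map$chrom == ch
    x <- map$pos_bp[sel]
    y <- stats::approx(pts$pos_bp, pts$pos_cm, xout = x, rule = 2, ties = "ordered")$y
    k <- nrow(pts)
    lo_rate <- (pts$pos_cm[2] - pts$pos_cm[1]) / (pts$pos_bp[2] - pts$pos_bp[1])
    hi_rate <- (pts$pos_cm[k] - pts$pos_cm[k - 1]) / (pts$pos_bp[k] - pts$pos_bp[k - 1])
    below <- x < pts$pos_bp[1]
    above <- x > pts$pos_bp[k]
    y[below] <- pts$pos_cm[1] + (x[below] - pts$pos_bp[1]) * lo_rate
    y[above] <- pts$pos_cm[k] + (x[above] - pts$pos_bp[k]) * hi_rate
    out$pos_cm[sel] <- y
  }
  validate_snp_map(out)
}

# ---- gene annotation -------------------------------------------------------

#' Read gene annotation from BED or GFF3
#'
#' BED intervals (0-based half-open) are converted to the internal 1-based
#' inclusive convention; from GFF3 only `gene` features are kept. The result
#' is sorted by (chrom, start) and deduplicated by `gene_id`.
#'
#' @param path Annotation file.
#' @param format `"bed"` or `"gff3"`.
#' @return A tibble with columns `chrom`, `start_bp`, `end_bp`, `gene_id`,
#'   `gene_name`.
#' @export
read_gene_annotation <- function(path, format = c("bed", "gff3")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(paste0("unknown annotation format: ",
                                                      format[1])))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (format == "bed") {
    parts <- strsplit(lines, "\\s+")
    genes <- tibble(
      chrom = vapply(parts, `[[`, "", 1L),
      start0 = as.numeric(vapply(parts, `[[`, "", 2L)),
      end_bp = as.numeric(vapply(parts, `[[`, "", 3L)),
      gene_id = vapply(parts, function(p) if (length(p) >= 4L) p[4L] else NA_character_, "")
    )
    genes$gene_id[is.na(genes$gene_id)] <- paste0("gene_", which(is.na(genes$gene_id)))
    zero_len <- genes$end_bp <= genes$start0
    if (any(zero_len)) {
      warn(sprintf("rejected %d zero-length BED interval(s)", sum(zero_len)))
      genes <- genes[!zero_len, , drop = FALSE]
    }
    genes <- dplyr::mutate(genes, start_bp = .data$start0 + 1, gene_name = .data$gene_id)
    genes$start0 <- NULL
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    keep <- vapply(parts, function(p) length(p) >= 9L && p[3L] == "gene", TRUE)
    parts <- parts[keep]
    attr_get <- function(attrs, key) {
      m <- regmatches(attrs, regexpr(paste0("(?:^|;)", key, "=[^;]+"), attrs))
      if (length(m)) sub(paste0("^;?", key, "="), "", m) else NA_character_
    }
    genes <- tibble(
      chrom = vapply(parts, `[[`, "", 1L),
      start_bp = as.numeric(vapply(parts, `[[`, "", 4L)),
      end_bp = as.numeric(vapply(parts, `[[`, "", 5L)),
      gene_id = vapply(parts, function(p) attr_get(p[9L], "ID"), ""),
      gene_name = vapply(parts, function(p) {
        nm <- attr_get(p[9L], "Name")
        if (is.na(nm)) attr_get(p[9L], "ID") else nm
      }, "")
    )
  }
  if (any(genes$start_bp > genes$end_bp)) abort("gene with start_bp > end_bp")
  genes %>%
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) %>%
    dplyr::arrange(.data$chrom, .data$start_bp)
}

# ---- score tracks ----------------------------------------------------------

#' Read/write a per-SNP score track
#'
#' TSV with comment headers `##test=`, `##population=`, `##orientation=`
#' followed by columns `chrom`, `pos_bp`, `snp_id`, `value` (`NA` for
#' missing). Every position must exist in the supplied SNP map; SNPs of the
#' map absent from the file read back as `NA`. This is also the import path
#' for externally computed tests (e.g. SelEstim selection coefficients or
#' XP-CLR composite-likelihood scores).
#'
#' @param track A track tibble from [score_track()] (one test x population).
#' @param path File path.
#' @param map A [snp_map()] the track must align to.
#' @return For `read_score_track()`, a track tibble aligned to `map`.
#' @export
write_score_track <- function(track, path) {
  stopifnot(length(unique(track$test)) == 1L, length(unique(track$population)) == 1L)
  header <- c(paste0("##test=", track$test[1]),
              paste0("##population=", track$population[1]),
              paste0("##orientation=", track$orientation[1]),
              "chrom\tpos_bp\tsnp_id\tvalue")
  body <- paste(track$chrom, format(track$pos_bp, scientific = FALSE, trim = TRUE),
                track$snp_id,
                ifelse(is.na(track$value), "NA", format(track$value, digits = 17)),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_score_track
#' @export
read_score_track <- function(path, map) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "##")]
  get_meta <- function(key, default = NA_character_) {
    hit <- meta[startsWith(meta, paste0("##", key, "="))]
    if (length(hit)) sub(paste0("##", key, "="), "", hit[1], fixed = TRUE) else default
  }
  orientation <- get_meta("orientation")
  if (is.na(orientation)) {
    warn("no ##orientation header: defaulting to high_is_evidence")
    orientation <- "high_is_evidence"
  }
  body <- lines[!startsWith(lines, "##")]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA")
  key_file <- paste(tab$chrom, sprintf("%.0f", tab$pos_bp))
  key_map <- paste(map$chrom, sprintf("%.0f", map$pos_bp))
  orphan <- !(key_file %in% key_map)
  if (any(orphan)) {
    abort(sprintf("%d track position(s) absent from the SNP map", sum(orphan)))
  }
  values <- rep(NA_real_, nrow(map))
  values[match(key_file, key_map)] <- tab$value
  score_track(map, test = get_meta("test", "external"),
              population = get_meta("population", "all"),
              values = values, orientation = orientation)
}
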