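# Readers/writers and the shared domain containers.

test_that("phased VCF parses, polarizes by AA and rejects bad records", {
  skip_if_not_installed("vcfR")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\trs1\tA\tG\t.\tPASS\tAA=A\tGT\t0|1\t1|1",
    "1\t200\trs2\tC\tT\t.\tPASS\tAA=T\tGT\t0|0\t0|1",   # AA equals ALT: flipped
    "1\t300\trs3\tG\tC\t.\tPASS\t.\tGT\t1|0\t0|0",      # no AA: kept, NA ancestral
    "1\t400\trs4\tA\tG\t.\tPASS\tAA=C\tGT\t0|0\t0|0",   # AA matches neither: dropped
    "1\t500\trs5\tT\tA\t.\tPASS\tAA=T\tGT\t1|1\t0|1"
  )
  writeLines(lines, vcf)
  res <- suppressMessages(read_phased_vcf(vcf))
  expect_equal(nrow(res$map), 4L)  # rs4 dropped
  expect_equal(res$map$snp_id, c("rs1", "rs2", "rs3", "rs5"))
  expect_equal(dim(res$haps$alleles), c(4L, 4L))
  # rs1: ALT-coded equals derived-coded (AA == REF)
  expect_equal(unname(res$haps$alleles[, 1]), c(0L, 1L, 1L, 1L))
  # rs2: AA == ALT so coding flips relative to REF/ALT
  expect_equal(unname(res$haps$alleles[, 2]), c(1L, 1L, 1L, 0L))
  expect_true(is.na(res$map$ancestral[3]))
  expect_equal(res$map$ancestral[2], "T")

  # brute-force recode of a toy VCF: derived dosage equals ALT dosage where
  # AA == REF and 1 - ALT dosage where AA == ALT
  alt_dosage <- rbind(c(0, 1, 1, 1), c(0, 0, 0, 1), c(1, 0, 0, 0), c(1, 1, 0, 1))
  flip <- c(FALSE, TRUE, FALSE, FALSE)
  expected <- sapply(seq_len(4), function(j) {
    if (flip[j]) 1 - alt_dosage[j, ] else alt_dosage[j, ]
  })
  expect_equal(unname(res$haps$alleles), unname(expected))

  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(lines[1:4], "1\t600\trs6\tA\tG\t.\tPASS\tAA=A\tGT\t0/1\t0|0"), bad)
  expect_error(read_phased_vcf(bad), "unphased.*600", ignore.case = TRUE)
})

test_that("VCF -> hap table -> read round-trips alleles, labels and order", {
  skip_if_not_installed("vcfR")
  set.seed(1)
  map <- make_map(20)
  haps <- haplotype_set(random_alleles(12, 20), rep(c("A", "B"), each = 6), map)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_phased_vcf(haps, vcf)
  back <- read_phased_vcf(vcf, pop_of_sample = NULL)
  expect_equal(unname(back$haps$alleles), unname(haps$alleles))
  expect_equal(back$map$pos_bp, map$pos_bp)
  expect_equal(back$map$ancestral, map$ancestral)

  tab <- withr::local_tempfile(fileext = ".tsv")
  write_hap_table(haps, tab)
  rt <- read_hap_table(tab)
  expect_equal(unname(rt$haps$alleles), unname(haps$alleles))
  expect_equal(rt$haps$pop, haps$pop)
  expect_equal(rt$map$pos_bp, map$pos_bp)
  expect_equal(rt$map$pos_cm, map$pos_cm)
})

test_that("hap table reader rejects empty, ragged and non-binary input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), f)
  expect_error(read_hap_table(f), "no haplotypes")
  writeLines(c("pop\thap_id\ts1\ts2", "A\th1\t0\t1", "A\th2\t0"), f)
  expect_error(read_hap_table(f), "ragged row 3")
  writeLines(c("pop\thap_id\ts1\ts2", "A\th1\t0\t2", "A\th2\t0\t1"), f)
  expect_error(read_hap_table(f), "non-binary.*'2'")
})

test_that("haplotype_set enforces binarity, alignment and even populations", {
  map <- make_map(3)
  expect_error(haplotype_set(matrix(c(0, 2, 1, 0, 1, 0), 2), c("A", "A"), map),
               "0/1")
  expect_error(haplotype_set(matrix(0L, 2, 4), c("A", "A"), map), "columns")
  expect_error(haplotype_set(matrix(0L, 3, 3), c("A", "A", "B"), map), "odd")
})

test_that("genetic map interpolation is linear with terminal-rate extrapolation", {
  map <- make_map(5, spacing_bp = 5e5)  # 0.5 .. 2.5 Mb
  f <- withr::local_tempfile()
  writeLines(c("1 1000000 1.0", "1 2000000 2.0"), f)
  out <- read_genetic_map(map, f)
  expect_equal(out$pos_cm, c(0.5, 1.0, 1.5, 2.0, 2.5))  # interp + extrap at 1 cM/Mb
  # SNP exactly on a map point keeps that point's cM
  expect_equal(out$pos_cm[out$pos_bp == 1e6], 1.0)
  # constant-rate map over 100 SNPs reproduces direct 1 cM/Mb computation
  map2 <- make_map(100, spacing_bp = 12345)
  out2 <- read_genetic_map(map2, f)
  expect_equal(out2$pos_cm, map2$pos_bp / 1e6, tolerance = 1e-12)
  writeLines(c("2 1 0", "2 10 1"), f)
  expect_error(read_genetic_map(map, f), "absent.*1")
})

test_that("gene annotation readers convert coordinates and deduplicate", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t2000\tgeneA", "chr1\t500\t500\tgeneB",
               "chr2\t0\t100\tgeneC"), bed)
  expect_warning(genes <- read_gene_annotation(bed, "bed"), "zero-length")
  expect_equal(genes$start_bp[genes$gene_id == "geneA"], 1000)
  expect_equal(genes$end_bp[genes$gene_id == "geneA"], 2000)
  expect_false("geneB" %in% genes$gene_id)
  expect_equal(genes$start_bp[genes$gene_id == "geneC"], 1)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t900\t.\t+\t.\tID=g1;Name=GENE1",
               "chr1\tsrc\tmRNA\t100\t900\t.\t+\t.\tID=m1;Parent=g1",
               "chr1\tsrc\tmRNA\t120\t800\t.\t+\t.\tID=m2;Parent=g1"), gff)
  g2 <- read_gene_annotation(gff, "gff3")
  expect_equal(nrow(g2), 1L)
  expect_equal(g2$gene_name, "GENE1")
  expect_error(read_gene_annotation(bed, "vcfish"), "unknown annotation format")
})

test_that("score tracks round-trip with missingness and orientation", {
  map <- make_map(8)
  vals <- c(1.5, NA, -2, 0, NA, 3, NA, 0.25)
  tr <- score_track(map, "TajimaD", "popA", vals, "low_is_evidence")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_score_track(tr, f)
  back <- read_score_track(f, map)
  expect_equal(back$value, vals)
  expect_equal(back$orientation[1], "low_is_evidence")
  expect_equal(back$test[1], "TajimaD")

  # orphan position
  lines <- readLines(f)
  lines <- c(lines, "1\t999999\tsX\t1.0")
  writeLines(lines, f)
  expect_error(read_score_track(f, map), "absent from the SNP map")

  # missing orientation header defaults with a warning
  writeLines(grep("##orientation", readLines(f)[1:12], value = TRUE,
                  invert = TRUE), f)
  expect_warning(out <- read_score_track(f, map), "high_is_evidence")
  expect_equal(out$orientation[1], "high_is_evidence")
})

test_that("BED coordinate conversion composed with its inverse is identity", {
  regions <- tibble::tibble(test = "axis1", population = "p", chrom = "1",
                            start_bp = c(1, 1000), end_bp = c(500, 2000),
                            n_top_snps = 1L, peak_snp = "s", peak_value = 1,
                            rule = "strict_0.1pct")
  f <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(regions, f)
  bed <- read.table(f, sep = "\t")
  expect_equal(bed$V2 + 1, regions$start_bp)  # 0-based half-open -> 1-based
  expect_equal(bed$V3, regions$end_bp)
})
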