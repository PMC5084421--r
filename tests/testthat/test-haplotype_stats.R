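# EHH curves, iHH integrals, iHS/nSL standardized tracks, H12 and XP-EHH.

test_that("EHH is 1 at the core, matches pair counting, and flags edges", {
  # 4 carriers; at offset +1 exactly 2 of 6 pairs are still identical
  X <- rbind(
    c(1, 0, 0, 1, 0, 0),
    c(1, 0, 0, 1, 1, 0),
    c(1, 0, 1, 1, 1, 1),
    c(1, 0, 1, 1, 1, 1)
  )
  haps <- make_haps(X)
  cv <- ehh(haps, "pop1", core = 2, allele = "ancestral", truncation = 0)
  expect_equal(cv$ehh[cv$offset == 0], 1)
  expect_equal(cv$ehh[cv$offset == 1], 1 / 3)
  for (k in which(cv$offset != 0)) {
    expect_equal(cv$ehh[k],
                 oracle_ehh_at(X, 1:4, 2, 2 + cv$offset[k]))
  }
  # identical carriers: EHH = 1 everywhere, edge-truncated on both sides
  Y <- matrix(rep(c(1, 0, 1, 1, 0), each = 4), nrow = 4)
  cid <- ehh(make_haps(Y), "pop1", core = 3, allele = "derived", truncation = 0.05)
  expect_true(all(cid$ehh == 1))
  expect_true(attr(cid, "edge_left") && attr(cid, "edge_right"))
  # fewer than 2 carriers: undefined
  expect_null(ehh(make_haps(rbind(c(1, 0), c(0, 0), c(0, 1), c(0, 0))),
                  "pop1", core = 1, allele = "derived"))
})

test_that("every emitted EHH curve is non-increasing outward", {
  set.seed(11)
  for (i in 1:50) {
    X <- random_alleles(sample(4:10, 1) * 2, 25)
    haps <- make_haps(X)
    core <- sample(5:20, 1)
    for (al in c("ancestral", "derived")) {
      cv <- ehh(haps, "pop1", core, al, truncation = 0)
      if (is.null(cv)) next
      left <- cv$ehh[cv$offset <= 0][order(cv$offset[cv$offset <= 0],
                                           decreasing = TRUE)]
      right <- cv$ehh[cv$offset >= 0]
      expect_true(all(diff(left) <= 1e-12))
      expect_true(all(diff(right) <= 1e-12))
    }
  }
})

test_that("iHH integrates the decay curve trapezoidally", {
  # EHH identically 1 over 1 cM each side: rectangle of area 2
  Y <- matrix(rep(c(1, 1, 1), each = 4), nrow = 4)
  map <- snp_map("1", c(1e6, 2e6, 3e6), c(0, 1, 2), paste0("s", 1:3), "A")
  cv <- ehh(haplotype_set(Y, rep("p", 4), map), "p", 2, "derived",
            max_gap_bp = Inf)
  expect_equal(ihh(cv), 2)
  # one-sided two-point decay 1 -> 0.5 over 1 cM: trapezoid 0.75
  X <- cbind(rep(1, 4), c(0, 0, 0, 1))
  map2 <- snp_map("1", c(1e6, 2e6), c(0, 1), c("a", "b"), "A")
  cv2 <- ehh(haplotype_set(X, rep("p", 4), map2), "p", 1, "derived",
             max_gap_bp = Inf)
  expect_equal(cv2$ehh[cv2$offset == 1], 0.5)
  expect_equal(ihh(cv2), 0.75)
  expect_equal(ihh(NULL), NA_real_)
})

test_that("EHH and SL fast paths equal pair-enumeration oracles on random fixtures", {
  set.seed(202)
  for (i in 1:120) {
    n <- 2L * sample(2:4, 1)
    m <- sample(6:20, 1)
    X <- random_alleles(n, m, p = runif(1, 0.2, 0.8))
    core <- sample(seq_len(m), 1)
    carriers <- which(X[, core] == 1L)
    if (length(carriers) < 2) next
    haps <- make_haps(X)
    cv <- ehh(haps, "pop1", core, "derived", truncation = 0, max_gap_bp = Inf)
    for (k in which(cv$offset != 0)) {
      expect_equal(cv$ehh[k], oracle_ehh_at(X, carriers, core, core + cv$offset[k]))
    }
    res <- sweepaxes:::cpp_nsl_sl(X, core - 1L, rep(1L, m), 200L)
    anc <- which(X[, core] == 0L)
    if (length(anc) >= 2 && length(carriers) >= 2) {
      expect_equal(res$sl_der, oracle_sl(X, carriers, core))
      expect_equal(res$sl_anc, oracle_sl(X, anc, core))
    }
  }
})

test_that("standardization yields per-bin mean 0 and sd 1", {
  set.seed(4)
  vals <- rnorm(5000)
  freq <- runif(5000, 0.05, 0.95)
  std <- sweepaxes:::standardize_by_freq(vals, freq, n_bins = 10L, min_bin = 20L)
  bins <- findInterval(freq, seq(0, 1, length.out = 11), rightmost.closed = TRUE,
                       all.inside = TRUE)
  for (b in unique(bins)) {
    expect_equal(mean(std[bins == b]), 0, tolerance = 1e-9)
    expect_equal(sd(std[bins == b]), 1, tolerance = 1e-9)
  }
})

test_that("mirror-image allele classes give unstandardized iHS and nSL of zero", {
  set.seed(9)
  half <- random_alleles(4, 41)
  X <- rbind(cbind(half[, 1:20], 1L, half[, 21:40]),
             cbind(half[, 1:20], 0L, half[, 21:40]))
  # derived and ancestral classes at the core (column 21) are mirror images
  res <- sweepaxes:::cpp_ihs_ihh(X, 20L, 1000 * (1:41), (1:41) / 1000,
                                 rep(1L, 41), 0.05, 2e5, Inf)
  expect_equal(res$ihh_anc, res$ihh_der)
  sl <- sweepaxes:::cpp_nsl_sl(X, 20L, rep(1L, 41), 200L)
  expect_equal(sl$sl_anc, sl$sl_der)
})

test_that("two identical carrier haplotypes extend SL to the cap or the edge", {
  set.seed(13)
  pat <- c(1L, rep(0L, 9))
  X <- rbind(pat, pat, random_alleles(2, 10))
  X[3:4, 1] <- 0L  # ancestral at the core
  sl <- sweepaxes:::cpp_nsl_sl(X, 0L, rep(1L, 10), 200L)
  expect_equal(sl$sl_der, 10)  # core + 9 SNPs to the chromosome edge
  # with a cap below the chromosome length, SL stops at the cap
  sl2 <- sweepaxes:::cpp_nsl_sl(X, 0L, rep(1L, 10), 4L)
  expect_equal(sl2$sl_der, 5)  # core + 4 capped steps
})

test_that("H12 implements the printed pooled-top-two formula", {
  map <- make_map(20)
  # 10 haplotypes in classes of 4/3/2/1 distinct patterns
  pats <- rbind(rep(0L, 20), rep(1L, 20), rep(c(0L, 1L), 10), rep(c(1L, 0L), 10))
  X <- pats[rep(1:4, times = c(4, 3, 2, 1)), ]
  tr <- h12_tracks(haplotype_set(X, rep("p", 10), map), window = 10L)
  vals <- tr$value[!is.na(tr$value)]
  expect_equal(unique(round(vals, 10)), (0.4 + 0.3)^2 + 0.2^2 + 0.1^2)
  # all haplotypes identical: H12 = 1
  tr1 <- h12_tracks(make_haps(matrix(1L, 6, 20)), window = 10L)
  expect_true(all(tr1$value[!is.na(tr1$value)] == 1))
  # two equally frequent classes: combined top-two gives 1
  X2 <- pats[rep(1:2, each = 3), ]
  tr2 <- h12_tracks(haplotype_set(X2, rep("p", 6), map), window = 10L)
  expect_true(all(tr2$value[!is.na(tr2$value)] == 1))
})

test_that("XP-EHH is zero for identical populations and antisymmetric", {
  set.seed(21)
  X <- random_alleles(6, 40)
  haps <- haplotype_set(rbind(X, X), rep(c("A", "B"), each = 6), make_map(40))
  res <- sweepaxes:::cpp_xpehh_ihh(haps$alleles, 0:5, 6:11, 0:39,
                                   haps$map$pos_bp, haps$map$pos_cm,
                                   rep(1L, 40), 0.05, 2e5, Inf)
  expect_equal(res$ihh_a, res$ihh_b)
  # swapping A and B flips the sign of ln(IHH_A/IHH_B)
  Y <- random_alleles(6, 40)
  haps2 <- haplotype_set(rbind(X, Y), rep(c("A", "B"), each = 6), make_map(40))
  ab <- sweepaxes:::cpp_xpehh_ihh(haps2$alleles, 0:5, 6:11, 0:39,
                                  haps2$map$pos_bp, haps2$map$pos_cm,
                                  rep(1L, 40), 0.05, 2e5, Inf)
  ba <- sweepaxes:::cpp_xpehh_ihh(haps2$alleles, 6:11, 0:5, 0:39,
                                  haps2$map$pos_bp, haps2$map$pos_cm,
                                  rep(1L, 40), 0.05, 2e5, Inf)
  expect_equal(log(ab$ihh_a / ab$ihh_b), -log(ba$ihh_a / ba$ihh_b))
  # the averaged per-population track is mean 0 / sd 1 for two populations
  tr <- xpehh_tracks(haps2)
  za <- tr$value[tr$population == "A"]
  expect_equal(mean(za, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_equal(sd(za, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_equal(za, -tr$value[tr$population == "B"])
})

test_that("a long shared haplotype private to one population dominates its XP-EHH", {
  set.seed(31)
  L <- 80
  map <- make_map(L)
  # pop A: all haplotypes share a long identical stretch around the middle
  core_span <- 31:50
  A <- random_alleles(8, L)
  A[, core_span] <- matrix(rep(rep(c(1L, 0L), 10), each = 8), nrow = 8)
  B <- random_alleles(8, L)
  C <- random_alleles(8, L)
  haps <- haplotype_set(rbind(A, B, C), rep(c("A", "B", "C"), each = 8), map)
  tr <- xpehh_tracks(haps)
  a <- tr[tr$population == "A", ]
  mid <- abs(a$pos_bp - map$pos_bp[40]) <= 10000
  expect_gt(mean(a$value[mid], na.rm = TRUE),
            mean(a$value[!mid], na.rm = TRUE))
})
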