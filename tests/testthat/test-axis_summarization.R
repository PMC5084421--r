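# Transform, score matrix, correlation structure, factor model and scores.

toy_tracks <- function(n_snps = 200, pops = c("P1", "P2"), tests = 4,
                       seed = 17, missing = 0) {
  set.seed(seed)
  map <- make_map(n_snps)
  purrr::map_dfr(pops, function(p) {
    purrr::map_dfr(seq_len(tests), function(k) {
      v <- rnorm(n_snps)
      if (missing > 0) v[sample(n_snps, missing)] <- NA
      score_track(map, paste0("t", k), p, v, "high_is_evidence")
    })
  })
}

test_that("the transform is orientation-aware and monotone in evidence", {
  map <- make_map(3)
  tj <- score_track(map, "TajimaD", "p", c(-2, 0, 1), "low_is_evidence")
  out <- transform_tracks(tj)
  expect_equal(out$value[1], log(3))   # evidence +2 -> ln(1 + 2)
  expect_equal(out$value[3], -log(2))
  h12 <- score_track(map, "H12", "p", c(1, 0.5, 0), "high_is_evidence")
  expect_equal(transform_tracks(h12)$value[1], log(2))
  xp <- score_track(map, "XPEHH", "p", c(-3, 2, 0), "abs_is_evidence")
  expect_equal(transform_tracks(xp)$value, c(log(4), log(3), 0))
  # monotonicity on a grid of evidence values
  v <- seq(-5, 5, by = 0.25)
  tr <- transform_tracks(score_track(make_map(length(v)), "x", "p", v,
                                     "high_is_evidence"))
  expect_true(all(diff(tr$value) > 0))
  # plain ln requires positive evidence
  expect_equal(transform_tracks(h12[1:2, ], method = "ln")$value, log(c(1, 0.5)))
  expect_error(transform_tracks(tj, method = "ln"), "strictly positive")
  bad <- tj; bad$orientation <- "whatever"
  expect_error(transform_tracks(bad), "orientation")
})

test_that("the score matrix stacks populations, z-scores and masks incomplete rows", {
  tr <- toy_tracks(n_snps = 10, tests = 3)
  m <- suppressMessages(build_score_matrix(transform_tracks(tr)))
  expect_equal(nrow(m), 20L)  # 2 pops x 10 SNPs
  expect_equal(attr(m, "tests"), c("t1", "t2", "t3"))
  for (tn in attr(m, "tests")) {
    expect_equal(mean(m[[tn]][m$complete]), 0, tolerance = 1e-12)
    expect_equal(sd(m[[tn]][m$complete]), 1, tolerance = 1e-12)
  }
  # one SNP missing in one track drops that SNP's row for that population only
  tr2 <- toy_tracks(n_snps = 10, tests = 3)
  tr2$value[tr2$test == "t1" & tr2$population == "P1" & tr2$snp_id == "s4"] <- NA
  m2 <- suppressMessages(build_score_matrix(transform_tracks(tr2)))
  expect_false(m2$complete[m2$population == "P1" & m2$snp_id == "s4"])
  expect_true(m2$complete[m2$population == "P2" & m2$snp_id == "s4"])
  # a missing (test, population) combination is an error naming the gap
  expect_error(build_score_matrix(tr[!(tr$test == "t2" & tr$population == "P2"), ]),
               "t2/P2")
})

test_that("correlation matrix flags constant columns and clusters blocks", {
  tr <- toy_tracks(n_snps = 300, tests = 3)
  # duplicate a column: correlation exactly 1
  dup <- tr[tr$test == "t1", ]
  dup$test <- "t4"
  m <- suppressMessages(build_score_matrix(dplyr::bind_rows(tr, dup)))
  co <- correlation_matrix(m)
  expect_equal(co$corr["t1", "t4"], 1)
  cst <- tr
  cst$value[cst$test == "t3"] <- 5
  expect_error(
    correlation_matrix(suppressMessages(build_score_matrix(transform_tracks(cst)))),
    "zero variance|constant")
})

block_tracks <- function(n_snps = 20000, loading = 0.8, seed = 29) {
  set.seed(seed)
  map <- make_map(n_snps)
  f <- matrix(rnorm(3 * n_snps), ncol = 3)
  purrr::map_dfr(1:9, function(k) {
    block <- (k - 1) %/% 3 + 1
    v <- loading * f[, block] + sqrt(1 - loading^2) * rnorm(n_snps)
    score_track(map, paste0("t", k), "P1", v, "high_is_evidence")
  })
}

test_that("block-structured tracks correlate within blocks and load on one axis each", {
  tr <- block_tracks(n_snps = 8000)
  m <- suppressMessages(build_score_matrix(tr))
  co <- correlation_matrix(m)
  blocks <- rep(1:3, each = 3)
  within <- co$corr[outer(blocks, blocks, "==") & row(co$corr) != col(co$corr)]
  between <- co$corr[outer(blocks, blocks, "!=")]
  expect_gt(min(within), max(between))
  fa <- factor_analysis(co$corr, 3)
  # each test loads > 0.85 on exactly one axis, < 0.15 elsewhere (block r = 0.8^2)
  top <- apply(abs(fa$loadings), 1L, max)
  rest <- apply(abs(fa$loadings), 1L, function(x) sort(x, decreasing = TRUE)[2])
  expect_true(all(top > 0.8))
  expect_true(all(rest < 0.15))
  # the three axes pick up the three blocks
  expect_equal(sort(unname(apply(abs(fa$loadings), 2L,
                                 function(x) unique(blocks[x > 0.5])))), 1:3)
})

test_that("the factor model is orthogonal, communality-preserving and matches stats::varimax", {
  set.seed(37)
  for (i in 1:12) {
    p <- sample(6:11, 1)
    R <- cor(matrix(rnorm(300 * p), 300, p) %*% matrix(rnorm(p * p), p))
    fa <- factor_analysis(R, 3)
    expect_equal(crossprod(fa$rotation), diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
    ei <- eigen(R, symmetric = TRUE)
    L0 <- ei$vectors[, 1:3] %*% diag(sqrt(ei$values[1:3]))
    expect_equal(unname(rowSums(fa$loadings^2)), rowSums(L0^2), tolerance = 1e-9)
    ref <- unclass(stats::varimax(L0, normalize = TRUE, eps = 1e-14)$loadings)
    M <- abs(crossprod(fa$loadings, ref))
    perm <- apply(M, 1L, which.max)
    expect_equal(unname(sort(perm)), 1:3)
    for (j in 1:3) {
      d <- min(max(abs(fa$loadings[, j] - ref[, perm[j]])),
               max(abs(fa$loadings[, j] + ref[, perm[j]])))
      expect_lt(d, 1e-6)
    }
    expect_true(all(fa$communalities <= 1 + 1e-9))
    expect_lte(sum(fa$explained), 1 + 1e-9)
  }
  expect_error(factor_analysis(matrix(c(1, 2, 2, 1), 2), 3), "smaller")
  expect_error(factor_analysis(matrix(c(1, 3, 3, 1), 2) , 1), "positive semidefinite")
})

test_that("already-varimax-optimal loadings are a fixed point up to sign/order", {
  L <- rbind(diag(3) * 0.9, diag(3) * 0.8)  # perfectly simple structure
  Tm <- sweepaxes:::varimax_rotation_matrix(L)
  P <- abs(Tm)
  expect_equal(P[P > 0.5], rep(1, 3), tolerance = 1e-7)
  expect_equal(crossprod(Tm), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("factor scores are unit-variance, zero for mean rows, and block-faithful", {
  tr <- block_tracks(n_snps = 5000, seed = 31)
  m <- suppressMessages(build_score_matrix(tr))
  fa <- factor_analysis(correlation_matrix(m)$corr, 3)
  sc <- factor_scores(m, fa)
  for (ax in unique(sc$test)) {
    v <- sc$value[sc$test == ax]
    expect_equal(mean(v, na.rm = TRUE), 0, tolerance = 1e-6)
    expect_equal(var(v, na.rm = TRUE), 1, tolerance = 1e-6)
  }
  # a row equal to the column means (all zeros after z-scoring) scores (0,0,0)
  z <- as.matrix(m[1, attr(m, "tests")])
  z[] <- 0
  expect_equal(as.numeric(z %*% fa$weights), c(0, 0, 0))
  # SNPs extreme in block-k tests score highest on the block-k axis
  blocks <- rep(1:3, each = 3)
  X <- as.matrix(m[m$complete, attr(m, "tests")])
  S <- X %*% fa$weights
  axis_of_block <- sapply(1:3, function(b) {
    which.max(colMeans(abs(fa$loadings[blocks == b, , drop = FALSE])))
  })
  for (b in 1:3) {
    extreme <- rowMeans(X[, blocks == b, drop = FALSE]) > 1
    expect_gt(mean(abs(S[extreme, axis_of_block[b]])),
              mean(abs(S[extreme, setdiff(1:3, axis_of_block[b])])))
  }
  # mismatched test sets are rejected
  fa2 <- fa; fa2$tests <- c(fa$tests[-1], "zzz")
  expect_error(factor_scores(m, fa2), "different test sets")
})

test_that("axis correlations between populations behave for shared and independent signals", {
  set.seed(53)
  n <- 2000
  map <- make_map(n)
  shared <- rnorm(n)
  mk <- function(pop, v) tibble::tibble(test = "axis1", population = pop,
                                        chrom = map$chrom, pos_bp = map$pos_bp,
                                        snp_id = map$snp_id, value = v,
                                        orientation = "high_is_evidence")
  sc <- dplyr::bind_rows(
    mk("A", shared + 0.5 * rnorm(n)),
    mk("B", shared + 0.5 * rnorm(n)),
    mk("C", rnorm(n))
  )
  res <- axis_population_correlations(sc)
  r <- function(a, b) res$pairs$r[res$pairs$pop_a == a & res$pairs$pop_b == b]
  expect_gt(r("A", "B"), 0.6)
  expect_lt(abs(r("A", "C")), 0.1)
  expect_lt(abs(r("B", "C")), 0.1)
  # identical tracks correlate exactly 1
  sc2 <- dplyr::bind_rows(mk("A", shared), mk("B", shared))
  expect_equal(axis_population_correlations(sc2)$pairs$r, 1)
})

test_that("scale invariance: positive rescaling leaves the model unchanged under plain ln", {
  set.seed(59)
  map <- make_map(3000)
  base <- purrr::map_dfr(1:4, function(k) {
    score_track(map, paste0("t", k), "P", exp(rnorm(3000)), "high_is_evidence")
  })
  scaled <- dplyr::mutate(base, value = value * 7.3)
  m1 <- suppressMessages(build_score_matrix(transform_tracks(base, "ln")))
  m2 <- suppressMessages(build_score_matrix(transform_tracks(scaled, "ln")))
  co1 <- correlation_matrix(m1)$corr
  co2 <- correlation_matrix(m2)$corr
  expect_equal(co1, co2, tolerance = 1e-12)
  expect_equal(factor_analysis(co1, 2)$loadings, factor_analysis(co2, 2)$loadings,
               tolerance = 1e-9)
})

test_that("axis family labels follow the dominant loadings", {
  L <- matrix(0, 9, 3, dimnames = list(
    c("TajimaD", "FuLiD", "FayWuH", "iHS", "nSL", "H12", "FST", "XPEHH", "VarLD"),
    paste0("axis", 1:3)))
  L[1:3, 2] <- 0.8; L[4:5, 3] <- 0.9; L[6:9, 1] <- 0.7
  model <- structure(list(loadings = L, tests = rownames(L), n_factors = 3L),
                     class = "sweep_axes_fa")
  fam <- axis_families(model)
  expect_equal(unname(fam), c("differentiation", "sfs", "haplotype_length"))
})
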