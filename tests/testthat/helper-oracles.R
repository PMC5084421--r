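# Brute-force reference implementations used as independent oracles, plus
# small fixture builders. Oracles are deliberately naive (explicit pair
# enumeration, dense eigensolves) and independent of the package's fast
# paths.

make_map <- function(L, chrom = "1", spacing_bp = 1000, cm_per_mb = 1,
                     ancestral = "A") {
  snp_map(chrom = chrom, pos_bp = spacing_bp * seq_len(L),
          pos_cm = spacing_bp * seq_len(L) / 1e6 * cm_per_mb,
          snp_id = paste0("s", seq_len(L)), ancestral = ancestral)
}

make_haps <- function(alleles, pop = "pop1", map = NULL, ...) {
  alleles <- as.matrix(alleles)
  if (is.null(map)) map <- make_map(ncol(alleles), ...)
  haplotype_set(alleles, pop = rep_len(pop, nrow(alleles)), map = map)
}

random_alleles <- function(n, m, p = 0.5) {
  matrix(rbinom(n * m, 1L, p), nrow = n)
}

# ---- SFS oracles (pair enumeration / direct spectrum) ----------------------

oracle_thetas <- function(X, polarized = rep(TRUE, ncol(X))) {
  n <- nrow(X)
  cnt <- colSums(X)
  seg <- cnt > 0 & cnt < n
  # theta_pi via exhaustive pair enumeration
  pair_diffs <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) pair_diffs <- pair_diffs + sum(X[i, ] != X[j, ])
  }
  theta_pi <- pair_diffs / choose(n, 2)
  a1 <- 0
  for (k in seq_len(n - 1)) a1 <- a1 + 1 / k
  th_h <- 0
  for (j in which(seg & polarized)) th_h <- th_h + 2 * cnt[j]^2 / (n * (n - 1))
  eta <- sum(seg & pmin(cnt, n - cnt) == 1)
  list(n = n, S = sum(seg), S_pol = sum(seg & polarized),
       theta_pi = theta_pi, theta_w = sum(seg) / a1, theta_h = th_h,
       eta_s = eta)
}

oracle_tajima_d <- function(th) {
  if (th$S == 0) return(NA_real_)
  n <- th$n
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  e1 <- (b1 - 1 / a1) / a1
  e2 <- (b2 - (n + 2) / (a1 * n) + a2 / a1^2) / (a1^2 + a2)
  den <- sqrt(e1 * th$S + e2 * th$S * (th$S - 1))
  num <- th$theta_pi - th$theta_w
  if (den == 0) return(if (abs(num) < 1e-12) 0 else NA_real_)
  num / den
}

oracle_fu_li_dstar <- function(th) {
  n <- th$n
  if (th$S == 0 || n < 3) return(NA_real_)
  an <- sum(1 / (1:(n - 1)))
  bn <- sum(1 / (1:(n - 1))^2)
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vd <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  ud <- (n / (n - 1)) * (an - n / (n - 1)) - vd
  ((n / (n - 1)) * th$S - an * th$eta_s) / sqrt(ud * th$S + vd * th$S^2)
}

# ---- EHH / SL oracles (explicit pair scans) --------------------------------

# fraction of carrier pairs identical over SNP columns core..j (inclusive)
oracle_ehh_at <- function(X, carriers, core, j) {
  span <- seq(min(core, j), max(core, j))
  k <- length(carriers)
  good <- 0
  for (a in seq_len(k - 1)) {
    for (b in seq(a + 1, k)) {
      if (all(X[carriers[a], span] == X[carriers[b], span])) good <- good + 1
    }
  }
  good / choose(k, 2)
}

# mean over carrier pairs of the identical-run length in SNPs (core
# included), both directions, each capped at max_ext
oracle_sl <- function(X, carriers, core, max_ext = 200L) {
  k <- length(carriers)
  L <- ncol(X)
  tot <- 0
  for (a in seq_len(k - 1)) {
    for (b in seq(a + 1, k)) {
      len <- 1
      j <- core - 1
      while (j >= 1 && core - j <= max_ext && all(X[carriers[a], j:core] == X[carriers[b], j:core])) {
        len <- len + 1
        j <- j - 1
      }
      j <- core + 1
      while (j <= L && j - core <= max_ext && all(X[carriers[a], core:j] == X[carriers[b], core:j])) {
        len <- len + 1
        j <- j + 1
      }
      tot <- tot + len
    }
  }
  tot / choose(k, 2)
}

# ---- differentiation oracles ----------------------------------------------

oracle_fst <- function(count_a, n_a, count_b, n_b) {
  p_a <- count_a / n_a
  p_b <- count_b / n_b
  p_t <- (count_a + count_b) / (n_a + n_b)
  h_t <- 2 * p_t * (1 - p_t)
  if (h_t == 0) return(NA_real_)
  h_s <- mean(c(2 * p_a * (1 - p_a), 2 * p_b * (1 - p_b)))
  (h_t - h_s) / h_t
}

oracle_varld_raw <- function(A, B) {
  corr0 <- function(X) {
    C <- suppressWarnings(stats::cor(X))
    C[is.na(C)] <- 0
    diag(C) <- 1
    C
  }
  ev <- function(X) sort(eigen(corr0(X), symmetric = TRUE, only.values = TRUE)$values)
  sum(abs(ev(A) - ev(B)))
}

# ---- misc ------------------------------------------------------------------

expect_tracks_tibble <- function(tr, map) {
  expect_s3_class(tr, "tbl_df")
  expect_true(all(c("test", "population", "chrom", "pos_bp", "snp_id",
                    "value", "orientation") %in% names(tr)))
  expect_true(all(table(tr$test, tr$population) == nrow(map)))
}
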