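# Site-frequency-spectrum statistics over sliding windows of SNPs:
# Tajima's D, Fay & Wu's H (unstandardized) and Fu & Li's D*, one score
# track per population.

# Tajima (1989) normalizing constants for a sample of n haplotypes.
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# Fu & Li (1993) D* constants, in the corrected form of Simonsen,
# Churchill & Aquadro (1995). Defined for n >= 3.
fu_li_dstar_constants <- function(n) {
  i <- seq_len(n - 1)
  an <- sum(1 / i)
  bn <- sum(1 / i^2)
  an1 <- an + 1 / n
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  v <- ((n / (n - 1))^2 * bn + an^2 * dn -
          2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  u <- (n / (n - 1)) * (an - n / (n - 1)) - v
  list(an = an, u = u, v = v)
}

#' Per-window site-frequency-spectrum summaries
#'
#' Computes, for one window of phased haplotypes from a single population,
#' the quantities the SFS tests are built from: the segregating-site count
#' `S`, the mean-pairwise-difference estimator `theta_pi`, Watterson's
#' `theta_w`, Fay & Wu's homozygosity-weighted `theta_h` (over sites with a
#' known ancestral state only), and the (any-allele, minor) singleton count
#' `eta_s`.
#'
#' With `n` haplotypes and derived count `i` at a site,
#' `theta_pi = sum 2 i (n - i) / (n (n - 1))`,
#' `theta_w = S / a1` with `a1 = sum_{k<n} 1/k`, and
#' `theta_h = sum 2 i^2 / (n (n - 1))`.
#'
#' @param alleles 0/1 matrix, haplotypes x SNPs (one population, >= 2 rows).
#' @param polarized Logical per SNP column: is the ancestral state known?
#'   Unpolarized sites still count toward `S`, `theta_pi`, `theta_w` and
#'   `eta_s`, but never toward `theta_h` or `derived_counts`.
#' @return A one-row tibble with columns `n_hap`, `S`, `S_pol`, `theta_pi`,
#'   `theta_w`, `theta_h`, `eta_s` and a list column `derived_counts`.
#' @export
window_thetas <- function(alleles, polarized = NULL) {
  alleles <- as.matrix(alleles)
  n <- nrow(alleles)
  if (n < 2L) abort("need >= 2 haplotypes")
  if (is.null(polarized)) polarized <- rep(TRUE, ncol(alleles))
  cnt <- colSums(alleles)
  seg <- cnt > 0L & cnt < n
  S <- sum(seg)
  a1 <- sum(1 / seq_len(n - 1))
  theta_pi <- sum(2 * cnt[seg] * (n - cnt[seg])) / (n * (n - 1))
  theta_w <- S / a1
  pol_seg <- seg & polarized
  theta_h <- sum(2 * cnt[pol_seg]^2) / (n * (n - 1))
  eta_s <- sum(seg & (cnt == 1L | cnt == n - 1L))
  tibble(
    n_hap = n, S = S, S_pol = sum(pol_seg),
    theta_pi = theta_pi, theta_w = theta_w, theta_h = theta_h,
    eta_s = eta_s,
    derived_counts = list(as.integer(cnt[pol_seg]))
  )
}

#' Tajima's D from window summaries
#'
#' The classical 1989 standardization
#' `D = (theta_pi - theta_w) / sqrt(e1 S + e2 S (S - 1))`. Windows with
#' `S = 0` yield `NA`. For `n = 2` the two estimators coincide and `D = 0`
#' whenever `S >= 1`.
#'
#' @param stats A tibble from [window_thetas()] (rows may come from many
#'   windows of a fixed `n_hap`).
#' @return Numeric vector of D values.
#' @export
tajima_d <- function(stats) {
  out <- rep(NA_real_, nrow(stats))
  for (n in unique(stats$n_hap)) {
    k <- tajima_constants(n)
    sel <- stats$n_hap == n & stats$S > 0
    S <- stats$S[sel]
    num <- stats$theta_pi[sel] - stats$theta_w[sel]
    den <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
    d <- num / den
    d[den == 0 & abs(num) < 1e-12] <- 0
    out[sel] <- d
  }
  out
}

#' Fay & Wu's H from window summaries
#'
#' The unstandardized difference `H = theta_pi - theta_h`. Windows without
#' any polarizable segregating site yield `NA`.
#'
#' @inheritParams tajima_d
#' @return Numeric vector of H values.
#' @export
fay_wu_h <- function(stats) {
  ifelse(stats$S_pol > 0, stats$theta_pi - stats$theta_h, NA_real_)
}

#' Fu & Li's D* from window summaries
#'
#' The within-sample (no outgroup) variant: a standardized difference between
#' the total number of segregating sites and the number of singletons,
#' `D* = ((n/(n-1)) S - a_n eta_s) / sqrt(u S + v S^2)`, with the published
#' normalizing constants. Defined for `n >= 3`; windows with `S = 0` yield
#' `NA`.
#'
#' @inheritParams tajima_d
#' @return Numeric vector of D* values.
#' @export
fu_li_d <- function(stats) {
  out <- rep(NA_real_, nrow(stats))
  for (n in unique(stats$n_hap)) {
    if (n < 3L) next
    k <- fu_li_dstar_constants(n)
    sel <- stats$n_hap == n & stats$S > 0
    S <- stats$S[sel]
    num <- (n / (n - 1)) * S - k$an * stats$eta_s[sel]
    out[sel] <- num / sqrt(k$u * S + k$v * S^2)
  }
  out
}

# window geometry shared by every 100-SNP sliding statistic: 0-based centers
# w/2 .. L - w/2 - 1 (the first and last w/2 SNPs of a chromosome get NA);
# the window of center c covers [c - w/2, c + w/2 - 1].
window_centers <- function(L, window, step = 1L) {
  half <- window %/% 2L
  if (L < window) return(integer(0))
  seq.int(half, L - half - 1L, by = step)
}

window_sum <- function(x, window, centers) {
  half <- window %/% 2L
  cs <- c(0, cumsum(x))
  cs[centers - half + 1L + window] - cs[centers - half + 1L]
}

#' Sliding-window SFS score tracks
#'
#' Computes Tajima's D, Fay & Wu's H and Fu & Li's D* over sliding windows of
#' `window` SNPs for each population, assigning each window's value to its
#' central SNP. The first and last `window/2` SNPs of each chromosome are
#' `NA`; chromosomes shorter than `window` are entirely `NA` (with a
#' warning). All three tracks are oriented `low_is_evidence` (strongly
#' negative values are the sweep signal).
#'
#' @param haps A [haplotype_set()].
#' @param populations Populations to scan (default: all).
#' @param window Window size in SNPs.
#' @param step Step between window centers, in SNPs.
#' @return A tidy track tibble (tests `TajimaD`, `FayWuH`, `FuLiD`).
#' @export
sfs_tracks <- function(haps, populations = NULL, window = 100L, step = 1L) {
  map <- haps$map
  if (is.null(populations)) populations <- populations(haps)
  polarized <- !is.na(map$ancestral)
  purrr::map_dfr(populations, function(p) {
    X <- pop_alleles(haps, p)
    n <- nrow(X)
    kt <- tajima_constants(n)
    kf <- if (n >= 3L) fu_li_dstar_constants(n) else NULL
    d_vals <- h_vals <- f_vals <- rep(NA_real_, nrow(map))
    cnt <- colSums(X)
    seg <- as.numeric(cnt > 0L & cnt < n)
    pi_site <- 2 * cnt * (n - cnt) / (n * (n - 1)) * seg
    h_site <- 2 * cnt^2 / (n * (n - 1)) * seg * polarized
    pol_seg <- seg * polarized
    sing <- seg * (cnt == 1L | cnt == n - 1L)
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch)
      L <- length(idx)
      if (L < window) {
        warn(sprintf("chromosome %s has %d SNPs (< window %d): SFS tracks set to NA",
                     ch, L, window))
        next
      }
      centers <- window_centers(L, window, step)
      S <- window_sum(seg[idx], window, centers)
      th_pi <- window_sum(pi_site[idx], window, centers)
      th_h <- window_sum(h_site[idx], window, centers)
      S_pol <- window_sum(pol_seg[idx], window, centers)
      eta <- window_sum(sing[idx], window, centers)
      pos <- S > 0
      th_w <- S / kt$a1
      den <- sqrt(kt$e1 * S + kt$e2 * S * (S - 1))
      d <- ifelse(pos & den > 0, (th_pi - th_w) / den, NA_real_)
      d[pos & den == 0 & abs(th_pi - th_w) < 1e-12] <- 0
      d_vals[idx[centers + 1L]] <- d
      h_vals[idx[centers + 1L]] <- ifelse(S_pol > 0, th_pi - th_h, NA_real_)
      if (!is.null(kf)) {
        num <- (n / (n - 1)) * S - kf$an * eta
        f_vals[idx[centers + 1L]] <-
          ifelse(pos, num / sqrt(kf$u * S + kf$v * S^2), NA_real_)
      }
    }
    dplyr::bind_rows(
      score_track(map, "TajimaD", p, d_vals, "low_is_evidence"),
      score_track(map, "FayWuH", p, h_vals, "low_is_evidence"),
      score_track(map, "FuLiD", p, f_vals, "low_is_evidence")
    )
  })
}
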