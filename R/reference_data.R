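# Published reference values from a genome scan of seven Spanish
# autochthonous beef cattle populations (BovineHD genotypes, eleven
# selection tests summarized into three varimax-rotated canonical axes).
# Used as worked-example input for the reporting arithmetic the package
# implements; none of it feeds any computation on user data.

#' Published cattle-scan factor table
#'
#' Per selection test, the reported score weights on the three canonical
#' axes, the correlations between the test and each axis, and the printed
#' percentage of the test's variance explained by the three axes, from a
#' varimax-rotated three-factor analysis of eleven genome-scan statistics in
#' seven Spanish beef cattle populations. The communality identity checked
#' by [communality_pct()] holds these columns together:
#' `pct_variance ~ 100 * (r1^2 + r2^2 + r3^2)` up to integer rounding.
#'
#' @return A tibble with columns `test`, `w1..w3` (weights), `r1..r3`
#'   (test-axis correlations) and `pct_variance`.
#' @export
cattle_axis_table <- function() {
  tibble(
    test = c("Tajima", "Fu-Li", "Fay-Wu", "Selestim", "XPCLR", "H12",
             "IHS", "NSL", "FST", "XP-EHH", "VarLD"),
    w1 = c(-0.07, -0.08, -0.05, 0.28, 0.22, 0.29, -0.06, -0.04, 0.38, 0.17, 0.31),
    w2 = c(0.42, 0.35, 0.38, -0.10, 0.06, 0.08, -0.04, -0.02, -0.10, 0.14, -0.11),
    w3 = c(-0.01, -0.05, 0.00, 0.02, -0.02, -0.04, 0.53, 0.52, -0.03, 0.01, -0.10),
    r1 = c(0.07, -0.02, 0.09, 0.58, 0.51, 0.67, 0.07, 0.11, 0.77, 0.47, 0.59),
    r2 = c(0.85, 0.68, 0.77, -0.05, 0.24, 0.32, 0.03, 0.07, -0.02, 0.40, -0.09),
    r3 = c(0.06, -0.04, 0.07, 0.13, 0.06, 0.06, 0.95, 0.94, 0.08, 0.13, -0.08),
    pct_variance = c(73, 47, 61, 36, 32, 55, 90, 89, 60, 40, 36)
  )
}

#' Published cattle-scan genotyping summary
#'
#' Post-quality-control marker panel of the same scan: autosomal SNP count,
#' covered genome length and the quoted mean inter-SNP spacing.
#'
#' @return A one-row tibble with `n_snps`, `covered_kb`, `mean_spacing_kb`.
#' @export
cattle_panel_summary <- function() {
  tibble(n_snps = 703707, covered_kb = 2510606, mean_spacing_kb = 3.567)
}

#' Communality as a percentage from axis correlations
#'
#' `100 * sum(r_j^2)`: the percentage of a test's variance explained by the
#' retained axes, recomputable from its printed test-axis correlations.
#'
#' @param r1,r2,r3 Test-axis correlations.
#' @return Numeric vector of percentages.
#' @export
communality_pct <- function(r1, r2, r3) 100 * (r1^2 + r2^2 + r3^2)

#' Mean inter-SNP spacing of a panel
#'
#' @param covered_kb Covered genome length in kb.
#' @param n_snps Number of SNPs.
#' @return Mean spacing in kb per SNP.
#' @export
mean_snp_spacing_kb <- function(covered_kb, n_snps) covered_kb / n_snps
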