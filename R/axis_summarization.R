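# Summarization of the per-SNP scan results: orientation-aware log
# transform, cross-test correlation structure, three-factor principal-axis
# extraction with varimax rotation, per-SNP axis scores and
# between-population axis correlations.

TEST_FAMILIES <- list(
  sfs = c("TajimaD", "FuLiD", "FayWuH"),
  haplotype_length = c("iHS", "nSL"),
  differentiation = c("FST", "SelEstim", "XPCLR", "XPEHH", "VarLD", "H12")
)

#' Orientation-aware log transform of score tracks
#'
#' Each track's values are first mapped to an "evidence" scale on which
#' larger always means stronger evidence of selection (`x`, `-x` or `|x|`
#' according to the declared orientation), then log-transformed. The default
#' transform `sign(v) * ln(1 + |v|)` is monotone in evidence and defined for
#' the negative values the SFS tests produce; `method = "ln"` applies a plain
#' logarithm and requires strictly positive evidence values.
#'
#' @param tracks A tidy track tibble.
#' @param method `"signed_log1p"` (default) or `"ln"`.
#' @return The tracks with `value` transformed and orientation set to
#'   `high_is_evidence`.
#' @export
transform_tracks <- function(tracks, method = c("signed_log1p", "ln")) {
  method <- match.arg(method)
  if (any(is.na(tracks$orientation)) || !all(tracks$orientation %in% ORIENTATIONS)) {
    abort("every track must declare an orientation")
  }
  v <- dplyr::case_when(
    tracks$orientation == "high_is_evidence" ~ tracks$value,
    tracks$orientation == "low_is_evidence" ~ -tracks$value,
    TRUE ~ abs(tracks$value)
  )
  if (method == "signed_log1p") {
    tracks$value <- sign(v) * log1p(abs(v))
  } else {
    if (any(v[!is.na(v)] <= 0)) {
      abort("method 'ln' requires strictly positive evidence values")
    }
    tracks$value <- log(v)
  }
  tracks$orientation <- "high_is_evidence"
  tracks
}

#' Stack transformed tracks into a (SNP x population) by test score matrix
#'
#' Rows are (population, SNP) pairs stacked over populations; columns are
#' tests. Every (test, population) combination must be present. Each test
#' column is z-scored to mean 0 / sd 1 over the complete rows (rows with no
#' missing entry), which are the rows the correlation matrix and factor
#' analysis consume.
#'
#' @param tracks A transformed track tibble (see [transform_tracks()]).
#' @return A tibble with columns `population`, `snp_id`, `chrom`, `pos_bp`,
#'   `complete`, then one column per test; attribute `tests` holds the test
#'   names. Class `score_matrix`.
#' @export
build_score_matrix <- function(tracks) {
  tests <- unique(tracks$test)
  pops <- unique(tracks$population)
  have <- unique(tracks[c("test", "population")])
  want <- tidyr::expand_grid(test = tests, population = pops)
  gaps <- dplyr::anti_join(want, have, by = c("test", "population"))
  if (nrow(gaps)) {
    abort(paste0("missing (test, population) combinations: ",
                 paste(paste(gaps$test, gaps$population, sep = "/"), collapse = ", ")))
  }
  wide <- tracks %>%
    dplyr::select("population", "snp_id", "chrom", "pos_bp", "test", "value") %>%
    tidyr::pivot_wider(names_from = "test", values_from = "value")
  wide$complete <- stats::complete.cases(wide[tests])
  inform(sprintf("score matrix: %d rows, %d complete cases over %d tests",
                 nrow(wide), sum(wide$complete), length(tests)))
  for (tn in tests) {
    x <- wide[[tn]][wide$complete]
    m <- mean(x)
    s <- stats::sd(x)
    if (is.na(s) || s == 0) abort(paste0("test has zero variance over complete rows: ", tn))
    wide[[tn]] <- (wide[[tn]] - m) / s
  }
  wide <- dplyr::relocate(wide, "complete", .after = "pos_bp")
  attr(wide, "tests") <- tests
  class(wide) <- unique(c("score_matrix", class(wide)))
  wide
}

#' Cross-test correlation matrix with clustering order
#'
#' Pearson correlations between the transformed tests over the complete rows
#' of the score matrix, plus an average-linkage hierarchical clustering on
#' the distance `1 - r` used to order heatmaps.
#'
#' @param m A [build_score_matrix()] result.
#' @return A list of class `score_correlations` with elements `corr` (tests
#'   x tests), `hclust` and `order`.
#' @export
correlation_matrix <- function(m) {
  tests <- attr(m, "tests")
  X <- as.matrix(m[m$complete, tests, drop = FALSE])
  if (nrow(X) < 3L) abort("need >= 3 complete rows")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("constant test column(s): ", paste(tests[sds == 0], collapse = ", ")))
  }
  corr <- stats::cor(X)
  hc <- stats::hclust(stats::as.dist(1 - corr), method = "average")
  structure(list(corr = corr, hclust = hc, order = hc$order),
            class = "score_correlations")
}

#' @export
print.score_correlations <- function(x, ...) {
  cat("<score_correlations>\n")
  print(round(x$corr[x$order, x$order], 2))
  invisible(x)
}

# Classical iterative pairwise varimax rotation with Kaiser normalization.
# Returns the rotation matrix T (loadings %*% T are the rotated loadings).
varimax_rotation_matrix <- function(loadings, eps = 1e-10, max_sweeps = 1000L) {
  p <- nrow(loadings)
  k <- ncol(loadings)
  h <- sqrt(rowSums(loadings^2))
  h[h == 0] <- 1
  A <- loadings / h
  Tm <- diag(k)
  criterion <- function(A) sum(apply(A^2, 2L, function(c2) mean(c2^2) - mean(c2)^2))
  last <- criterion(A)
  for (sweep in seq_len(max_sweeps)) {
    max_phi <- 0
    for (i in seq_len(k - 1)) {
      for (j in seq((i + 1), k)) {
        x <- A[, i]; y <- A[, j]
        u <- x^2 - y^2
        v <- 2 * x * y
        num <- 2 * (p * sum(u * v) - sum(u) * sum(v))
        den <- p * sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2)
        phi <- atan2(num, den) / 4
        max_phi <- max(max_phi, abs(phi))
        if (abs(phi) < 1e-15) next
        G <- diag(k)
        G[i, i] <- cos(phi); G[j, j] <- cos(phi)
        G[i, j] <- -sin(phi); G[j, i] <- sin(phi)
        A <- A %*% G
        Tm <- Tm %*% G
      }
    }
    now <- criterion(A)
    if (abs(now - last) < eps * max(1, abs(now)) && max_phi < 1e-9) break
    last <- now
  }
  Tm
}

#' Principal-axis factor model with varimax rotation
#'
#' Extracts the top `n_factors` principal components of the test correlation
#' matrix (unrotated loading column `j` is `sqrt(lambda_j) * v_j`) and
#' rotates them with the classical iterative pairwise varimax algorithm
#' (Kaiser normalization on, criterion change below 1e-10, at most 1000
#' sweeps). Axes are ordered by explained variance and sign-fixed so each
#' axis' largest-|loading| entry is positive. Score weights are
#' `corr^{-1} %*% loadings`, so per-SNP axis scores are unit variance over
#' the rows the correlation was computed from.
#'
#' @param corr A symmetric positive semidefinite test correlation matrix
#'   (e.g. `correlation_matrix(m)$corr`).
#' @param n_factors Number of axes (fewer than the number of tests).
#' @return An object of class `sweep_axes_fa` with elements `loadings`
#'   (tests x axes; the correlations between each test and each axis),
#'   `weights` (score coefficients), `rotation` (orthogonal), `explained`
#'   (per-axis proportion of total variance), `communalities`, `eigenvalues`
#'   and `tests`. See [tidy.sweep_axes_fa()], [glance.sweep_axes_fa()].
#' @export
factor_analysis <- function(corr, n_factors = 3L) {
  if (inherits(corr, "score_correlations")) corr <- corr$corr
  corr <- as.matrix(corr)
  p <- ncol(corr)
  if (n_factors >= p) abort("n_factors must be smaller than the number of tests")
  if (max(abs(corr - t(corr))) > 1e-8) abort("correlation matrix is not symmetric")
  ei <- eigen((corr + t(corr)) / 2, symmetric = TRUE)
  if (min(ei$values) < -1e-8) {
    abort(sprintf("correlation matrix is not positive semidefinite (min eigenvalue %.3g)",
                  min(ei$values)))
  }
  lam <- pmax(ei$values[seq_len(n_factors)], 0)
  L0 <- ei$vectors[, seq_len(n_factors), drop = FALSE] %*% diag(sqrt(lam), n_factors)
  Tm <- varimax_rotation_matrix(L0)
  L <- L0 %*% Tm
  # order axes by explained variance, sign-fix on the largest |loading|
  expl <- colSums(L^2) / p
  ord <- order(expl, decreasing = TRUE)
  P <- diag(n_factors)[, ord, drop = FALSE]
  L <- L[, ord, drop = FALSE]
  sgn <- vapply(seq_len(n_factors), function(j) sign(L[which.max(abs(L[, j])), j]), 0)
  sgn[sgn == 0] <- 1
  L <- sweep(L, 2L, sgn, `*`)
  Tm <- Tm %*% P %*% diag(sgn, n_factors)
  tests <- colnames(corr)
  if (is.null(tests)) tests <- paste0("test", seq_len(p))
  dimnames(L) <- list(tests, paste0("axis", seq_len(n_factors)))
  W <- solve(corr, L)
  dimnames(W) <- dimnames(L)
  structure(list(
    loadings = L, weights = W, rotation = Tm,
    explained = stats::setNames(colSums(L^2) / p, colnames(L)),
    communalities = stats::setNames(rowSums(L^2), tests),
    eigenvalues = ei$values, tests = tests, n_factors = n_factors
  ), class = "sweep_axes_fa")
}

#' @export
print.sweep_axes_fa <- function(x, ...) {
  cat(sprintf("<sweep_axes_fa> %d tests, %d axes, %.0f%% of variance explained\n",
              length(x$tests), x$n_factors, 100 * sum(x$explained)))
  tab <- cbind(round(x$weights, 2), round(x$loadings, 2),
               `%var` = round(100 * x$communalities))
  colnames(tab) <- c(paste0("w", seq_len(x$n_factors)),
                     paste0("r", seq_len(x$n_factors)), "%var")
  print(tab)
  invisible(x)
}

#' Tidy a fitted factor model
#'
#' One row per (test, axis) with the score weight and the test-axis
#' correlation (loading).
#'
#' @param x A `sweep_axes_fa` object.
#' @param ... Unused.
#' @return A tibble with columns `test`, `axis`, `weight`, `loading`.
#' @export
tidy.sweep_axes_fa <- function(x, ...) {
  tibble(
    test = rep(x$tests, times = x$n_factors),
    axis = rep(colnames(x$loadings), each = length(x$tests)),
    weight = as.numeric(x$weights),
    loading = as.numeric(x$loadings)
  )
}

#' @rdname tidy.sweep_axes_fa
#' @return For `glance()`: a one-row tibble with the number of tests, axes,
#'   per-axis and total explained variance.
#' @export
glance.sweep_axes_fa <- function(x, ...) {
  out <- tibble(n_tests = length(x$tests), n_axes = x$n_factors,
                total_explained = sum(x$explained))
  for (j in seq_len(x$n_factors)) out[[paste0("explained_", j)]] <- x$explained[j]
  out
}

#' Post-hoc axis family labels
#'
#' Labels each axis by the test family (site-frequency-spectrum,
#' haplotype-length or differentiation) whose tests load most strongly on
#' it, as a report annotation. Tests outside the known families are ignored.
#'
#' @param model A `sweep_axes_fa` object.
#' @return Named character vector, one family label per axis.
#' @export
axis_families <- function(model) {
  fam_load <- vapply(TEST_FAMILIES, function(members) {
    rows <- model$tests %in% members
    if (!any(rows)) return(rep(NA_real_, model$n_factors))
    colMeans(abs(model$loadings[rows, , drop = FALSE]))
  }, numeric(model$n_factors))
  stats::setNames(colnames(fam_load)[apply(fam_load, 1L, which.max)],
                  colnames(model$loadings))
}

#' Per-SNP canonical-axis score tracks
#'
#' Row scores are the z-scored score-matrix rows times the model's score
#' weights; rows with any missing test are missing. Scores have mean 0 and
#' unit variance over the complete rows the model was fitted on.
#'
#' @param m A [build_score_matrix()] result.
#' @param model A [factor_analysis()] fit on the same tests.
#' @return A tidy track tibble with tests `axis1..axisK`.
#' @export
factor_scores <- function(m, model) {
  tests <- attr(m, "tests")
  if (!setequal(tests, model$tests)) {
    abort("score matrix and factor model cover different test sets")
  }
  X <- as.matrix(m[, model$tests, drop = FALSE])
  S <- matrix(NA_real_, nrow(X), model$n_factors)
  S[m$complete, ] <- X[m$complete, , drop = FALSE] %*% model$weights
  purrr::map_dfr(seq_len(model$n_factors), function(j) {
    tibble(
      test = colnames(model$loadings)[j], population = m$population,
      chrom = m$chrom, pos_bp = m$pos_bp, snp_id = m$snp_id,
      value = S[, j], orientation = "high_is_evidence"
    )
  })
}

#' Between-population correlations of axis scores
#'
#' Pearson correlation of per-SNP axis scores between each population pair,
#' per axis, over the SNPs where both populations have a score; plus the
#' per-axis average over pairs.
#'
#' @param scores Axis tracks from [factor_scores()].
#' @return A list with `pairs` (tibble: axis, pop_a, pop_b, n_snps, r) and
#'   `average` (tibble: axis, mean_r).
#' @export
axis_population_correlations <- function(scores) {
  pops <- sort(unique(scores$population))
  if (length(pops) < 2L) abort("need >= 2 populations with axis scores")
  axes <- unique(scores$test)
  prs <- utils::combn(pops, 2L, simplify = FALSE)
  pairs <- purrr::map_dfr(axes, function(ax) {
    wide <- scores %>%
      dplyr::filter(.data$test == ax) %>%
      dplyr::select("population", "snp_id", "value") %>%
      tidyr::pivot_wider(names_from = "population", values_from = "value")
    purrr::map_dfr(prs, function(pr) {
      ok <- stats::complete.cases(wide[pr])
      if (sum(ok) < 100L) {
        warn(sprintf("axis %s, pair %s-%s: only %d shared SNPs", ax, pr[1], pr[2],
                     sum(ok)))
      }
      tibble(axis = ax, pop_a = pr[1], pop_b = pr[2], n_snps = sum(ok),
             r = stats::cor(wide[[pr[1]]][ok], wide[[pr[2]]][ok]))
    })
  })
  average <- pairs %>%
    dplyr::group_by(.data$axis) %>%
    dplyr::summarise(mean_r = mean(.data$r), .groups = "drop")
  list(pairs = pairs, average = average)
}
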