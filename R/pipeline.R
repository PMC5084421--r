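# End-to-end orchestration: simulate (or load) -> scan -> summarize ->
# regions -> genes, from one config, with a checksummed output manifest.

INTERNAL_TESTS <- c("TajimaD", "FayWuH", "FuLiD", "iHS", "nSL", "H12",
                    "FST", "XPEHH", "VarLD")

#' Pipeline configuration
#'
#' Either `preset`/`sim` (simulated input) or `hap_table` (a
#' [read_hap_table()] file) must be given. External score tracks (e.g.
#' SelEstim or XP-CLR output converted to the track TSV format) are listed
#' as file paths and joined to the internally computed tests before the
#' factor analysis.
#'
#' @param preset `"neutral"`, `"sweep"` or `"seven_pops"` (ignored when
#'   `sim` or `hap_table` is given).
#' @param sim A [sim_config()] overriding `preset`.
#' @param hap_table Path to a haplotype-table input.
#' @param genetic_map Optional genetic-map path (see [read_genetic_map()]).
#' @param annotation,annotation_format Optional gene annotation for the
#'   overlap stage.
#' @param tests Internal tests to run (subset of
#'   `r paste(INTERNAL_TESTS, collapse = ", ")`).
#' @param external_tracks Character vector of track-TSV paths.
#' @param window,step Sliding-window geometry (SNPs).
#' @param transform `"signed_log1p"` or `"ln"`.
#' @param n_factors Number of canonical axes.
#' @param q_strict,min_snps,bin_bp Strict region rule parameters.
#' @param q_relaxed,merge_gap_bp Relaxed region rule parameters.
#' @param out_dir Output directory (created).
#' @param seed Top-level seed; all stage randomness derives from it.
#' @return A `run_config` list.
#' @export
run_config <- function(preset = "neutral", sim = NULL, hap_table = NULL,
                       genetic_map = NULL, annotation = NULL,
                       annotation_format = "bed", tests = INTERNAL_TESTS,
                       external_tracks = character(), window = 100L, step = 1L,
                       transform = "signed_log1p", n_factors = 3L,
                       q_strict = 0.001, min_snps = 25L, bin_bp = 1e6,
                       q_relaxed = 0.05, merge_gap_bp = 1e6,
                       out_dir = "sweepaxes_run", seed = 1L) {
  bad <- setdiff(tests, INTERNAL_TESTS)
  if (length(bad)) abort(paste0("unknown test(s): ", paste(bad, collapse = ", ")))
  for (f in c(hap_table, genetic_map, annotation, external_tracks)) {
    if (!file.exists(f)) abort(paste0("configured file does not exist: ", f))
  }
  n_tracks <- length(tests) + length(external_tracks)
  if (n_tracks < 3L) abort("need >= 3 tests for the factor analysis")
  structure(list(
    preset = preset, sim = sim, hap_table = hap_table,
    genetic_map = genetic_map, annotation = annotation,
    annotation_format = annotation_format, tests = tests,
    external_tracks = external_tracks, window = as.integer(window),
    step = as.integer(step), transform = transform,
    n_factors = as.integer(n_factors), q_strict = q_strict,
    min_snps = as.integer(min_snps), bin_bp = bin_bp, q_relaxed = q_relaxed,
    merge_gap_bp = merge_gap_bp, out_dir = out_dir, seed = as.integer(seed)
  ), class = "run_config")
}

#' @rdname run_config
#' @param path A YAML file whose keys are `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the whole scan-and-summarize pipeline
#'
#' Executes input acquisition (simulation or file loading), the per-SNP
#' scans, the transform/correlation/factor-analysis summary, outlier region
#' calling and (when annotation is configured) gene overlap, writing every
#' artifact under `config$out_dir` together with a checksum manifest.
#' Rerunning an identical config reproduces identical checksums.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`haps`, `tracks`,
#'   `correlations`, `model`, `axis_scores`, `regions_strict`,
#'   `regions_relaxed`, `genes`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(name, writer) {
    p <- file.path(config$out_dir, name)
    writer(p)
    paths[[name]] <<- p
    p
  }

  input <- run_stage("input", {
    if (!is.null(config$hap_table)) {
      inp <- read_hap_table(config$hap_table)
      if (!is.null(config$genetic_map)) {
        inp$map <- read_genetic_map(inp$map, config$genetic_map)
        inp$haps$map <- inp$map
      }
      inp
    } else {
      sim <- config$sim
      if (is.null(sim)) {
        sim <- switch(config$preset,
          neutral = preset_neutral(seed = config$seed),
          sweep = preset_sweep(seed = config$seed),
          seven_pops = preset_seven_pops(seed = config$seed),
          abort(paste0("unknown preset: ", config$preset))
        )
      }
      out <- simulate_populations(sim)
      emit("hap_table.tsv", function(p) write_hap_table(out$haps, p))
      emit("truth_sweeps.tsv", function(p) readr::write_tsv(out$truth$sweeps, p))
      out
    }
  })
  haps <- input$haps
  truth <- input$truth

  tracks <- run_stage("scan", {
    tr <- list()
    if (any(config$tests %in% c("TajimaD", "FayWuH", "FuLiD"))) {
      sfs <- sfs_tracks(haps, window = config$window, step = config$step)
      tr <- c(tr, list(sfs[sfs$test %in% config$tests, ]))
    }
    if ("iHS" %in% config$tests) tr <- c(tr, list(ihs_tracks(haps)))
    if ("nSL" %in% config$tests) tr <- c(tr, list(nsl_tracks(haps)))
    if ("H12" %in% config$tests) {
      tr <- c(tr, list(h12_tracks(haps, window = config$window, step = config$step)))
    }
    if ("XPEHH" %in% config$tests) tr <- c(tr, list(xpehh_tracks(haps)))
    if ("FST" %in% config$tests) {
      tr <- c(tr, list(fst_tracks(haps, window = config$window, step = config$step)))
    }
    if ("VarLD" %in% config$tests) {
      tr <- c(tr, list(varld_tracks(haps, window = config$window, step = config$step)))
    }
    for (f in config$external_tracks) {
      ext <- read_score_track(f, haps$map)
      if (ext$population[1] == "all") {
        ext <- purrr::map_dfr(populations(haps), function(p) {
          dplyr::mutate(ext, population = p)
        })
      }
      tr <- c(tr, list(ext))
    }
    dplyr::bind_rows(tr)
  })
  emit("tracks.tsv", function(p) readr::write_tsv(tracks, p))

  summary <- run_stage("summarize", {
    m <- build_score_matrix(transform_tracks(tracks, method = config$transform))
    cors <- correlation_matrix(m)
    model <- factor_analysis(cors$corr, n_factors = config$n_factors)
    scores <- factor_scores(m, model)
    list(m = m, cors = cors, model = model, scores = scores)
  })
  emit("correlations.tsv", function(p) {
    readr::write_tsv(as_tibble(summary$cors$corr, rownames = "test"), p)
  })
  emit("factor_model.tsv", function(p) {
    readr::write_tsv(factor_model_table(summary$model), p)
  })
  emit("axis_scores.tsv", function(p) readr::write_tsv(summary$scores, p))

  regions <- run_stage("regions", {
    strict <- call_strict_regions(summary$scores, q = config$q_strict,
                                  min_snps = config$min_snps, bin_bp = config$bin_bp)
    relaxed <- call_relaxed_regions(summary$scores, q = config$q_relaxed,
                                    merge_gap_bp = config$merge_gap_bp)
    list(strict = strict, relaxed = relaxed)
  })
  emit("regions_strict.bed", function(p) write_regions_bed(regions$strict, p))
  paths[["regions_strict.tsv"]] <- file.path(config$out_dir, "regions_strict.tsv")
  emit("regions_relaxed.bed", function(p) write_regions_bed(regions$relaxed, p))
  paths[["regions_relaxed.tsv"]] <- file.path(config$out_dir, "regions_relaxed.tsv")

  genes <- NULL
  if (!is.null(config$annotation)) {
    genes <- run_stage("genes", {
      ann <- read_gene_annotation(config$annotation, config$annotation_format)
      g_strict <- overlap_genes(regions$strict, ann)
      g_relaxed <- overlap_genes(regions$relaxed, ann)
      list(strict = g_strict, relaxed = g_relaxed)
    })
    emit("genes_strict.txt", function(p) writeLines(genes$strict$gene_universe, p))
    emit("gene_universe_relaxed.txt", function(p) {
      writeLines(genes$relaxed$gene_universe, p)
    })
  }

  manifest <- tibble(
    file = names(paths),
    md5 = unname(tools::md5sum(unlist(paths)))
  )
  readr::write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  invisible(list(haps = haps, truth = truth, tracks = tracks,
                 score_matrix = summary$m, correlations = summary$cors,
                 model = summary$model, axis_scores = summary$scores,
                 regions_strict = regions$strict, regions_relaxed = regions$relaxed,
                 genes = genes, manifest = manifest))
}

#' Factor model in reporting layout
#'
#' One row per test: per-axis score weight with the test-axis correlation in
#' parentheses, plus the percentage of the test's variance the axes explain
#' (its communality x 100).
#'
#' @param model A `sweep_axes_fa` object.
#' @return A tibble.
#' @export
factor_model_table <- function(model) {
  out <- tibble(test = model$tests)
  for (j in seq_len(model$n_factors)) {
    out[[colnames(model$loadings)[j]]] <-
      sprintf("%.2f (%.2f)", model$weights[, j], model$loadings[, j])
  }
  out$pct_variance <- round(100 * model$communalities)
  out
}
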