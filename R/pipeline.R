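#' Default pipeline configuration
#'
#' One nested list with a section per stage. `validateConfig()` merges a
#' user config (R list or YAML file) over these defaults, rejecting
#' unknown keys and checking cross-field constraints; every stochastic
#' stage carries an explicit seed.
#'
#' @return Nested named list of class "PipelineConfig".
#' @export
defaultPipelineConfig <- function() {
  structure(list(
    outdir = "clonexpr_run",
    simulate = list(enabled = TRUE, config = unclass(simConfig())),
    inputs = list(counts_mtx = NULL, genes = NULL, cells = NULL,
                  cell_metadata = NULL, gene_annotation = NULL,
                  tcr = NULL, gmt = NULL, signature = NULL),
    qc = list(min_mapping_rate = 0.30, min_reads = 100000,
              min_genes = 1800, max_genes = 15000,
              max_mito_fraction = 0.125, min_cells_per_gene = 10),
    normalize = list(pseudocount = 1),
    de = list(test = "hurdle", fdr_max = 0.05, min_fc = 1.5),
    gsea = list(min_size = 15, max_size = 500, n_perm = 1000,
                seed = 7, weight = 1),
    score = list(layer = "scaled"),
    clones = list(use_aa = FALSE, include_nonproductive = FALSE),
    clonesim = list(layer = "lognorm", seed = 11, exclude_intra = TRUE,
                    exclude_duplicates = TRUE)
  ), class = "PipelineConfig")
}

# Recursive merge of user values over defaults; unknown keys error with
# their dotted path. Explicit NULLs survive (so a nulled-out seed is
# caught by the seed check rather than silently restored).
merge_config <- function(default, user, path = character()) {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(default))
  if (length(unknown))
    stopf("unknown config key(s): %s",
          paste(paste(c(path, ""), collapse = "."), unknown,
                sep = "", collapse = ", "))
  out <- default
  for (nm in names(user)) {
    if (is.list(default[[nm]]) && !is.null(names(default[[nm]])) &&
        !is.data.frame(default[[nm]]) && !is.data.frame(user[[nm]])) {
      out[nm] <- list(merge_config(default[[nm]], user[[nm]], c(path, nm)))
    } else {
      out[nm] <- user[nm]
    }
  }
  out
}

#' Validate and normalize a pipeline configuration
#'
#' @param config a nested list, a YAML file path, or NULL (pure defaults).
#' @return Validated config of class "PipelineConfig" with defaults
#'   filled. All errors (unknown keys, inconsistent thresholds, missing
#'   seeds, unresolvable input paths) are reported together.
#' @export
validateConfig <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  cfg <- merge_config(defaultPipelineConfig(), config)
  errs <- character()
  if (!is.null(cfg$qc$min_genes) && !is.null(cfg$qc$max_genes) &&
      !(cfg$qc$min_genes < cfg$qc$max_genes))
    errs <- c(errs, sprintf("qc: min_genes (%s) must be below max_genes (%s)",
                            cfg$qc$min_genes, cfg$qc$max_genes))
  for (s in list(c("simulate", "config", "seed"), c("gsea", "seed"),
                 c("clonesim", "seed"))) {
    v <- cfg[[s]]
    if (is.null(v) || !is.numeric(v))
      errs <- c(errs, sprintf("missing seed: %s", paste(s, collapse = ".")))
  }
  if (!cfg$simulate$enabled) {
    have_mtx <- !is.null(cfg$inputs$counts_mtx)
    if (!have_mtx)
      errs <- c(errs, "simulate disabled but no inputs$counts_mtx given")
    for (nm in c("counts_mtx", "genes", "cells", "cell_metadata", "tcr")) {
      p <- cfg$inputs[[nm]]
      if (!is.null(p) && !file.exists(p))
        errs <- c(errs, sprintf("inputs$%s: file not found: %s", nm, p))
    }
  }
  if (length(errs))
    stopf("invalid pipeline config:\n  - %s", paste(errs, collapse = "\n  - "))
  structure(cfg, class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (or load inputs), qc, normalize, de,
#' gsea, score, clones, clonesim. Every stage writes its outputs under
#' `config$outdir` and records parameters and output checksums in a run
#' manifest (`manifest.json`). All randomness flows from the per-stage
#' seeds in the config, so two runs with the same config are
#' byte-identical. Passing a `stages` subset that omits "simulate" resumes
#' from the fixture already present in the output directory.
#'
#' @param config a [validateConfig()]-acceptable configuration.
#' @param stages character vector of stages to run (default: all).
#' @return Invisibly, a list with the in-memory results (`sce`, `de`,
#'   `gsea`, `scores`, `partition`, `similarity`) and the `manifest`.
#' @export
runAll <- function(config = NULL,
                   stages = c("simulate", "qc", "normalize", "de", "gsea",
                              "score", "clones", "clonesim")) {
  cfg <- validateConfig(if (inherits(config, "PipelineConfig"))
    unclass(config) else config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  fixture_dir <- file.path(cfg$outdir, "fixture")
  # a resumed run extends the manifest of the run it resumes from
  mpath <- file.path(cfg$outdir, "manifest.json")
  manifest <- if (file.exists(mpath)) jsonlite::read_json(mpath) else list()
  note <- function(stage, params, files) {
    sums <- tools::md5sum(files)
    manifest[[stage]] <<- list(
      parameters = params,
      outputs = as.list(setNames(unname(sums), basename(files))))
  }

  ## ---- inputs: simulate or load ----
  if ("simulate" %in% stages && cfg$simulate$enabled) {
    ds <- generateDataset(do.call(simConfig, cfg$simulate$config))
    writeFixture(ds, fixture_dir)
    sets <- makeFixtureGeneSets(ds, seed = cfg$simulate$config$seed)
    writeGmt(sets, file.path(fixture_dir, "sets.gmt"))
    if (nrow(ds$truth$de_genes)) {
      writeSignature(
        SignedSignature("planted_program", up = ds$truth$de_genes$gene),
        file.path(fixture_dir, "signature_planted.tsv"))
    }
    note("simulate", cfg$simulate$config,
         list.files(fixture_dir, full.names = TRUE))
    sce <- ds$sce
    tcr <- ds$tcr
    gmt_path <- file.path(fixture_dir, "sets.gmt")
    sig_path <- file.path(fixture_dir, "signature_planted.tsv")
  } else if (cfg$simulate$enabled) {
    # resume: reload the fixture written by a previous simulate stage
    verifyFixture(fixture_dir)
    sce <- readExpressionMatrix(file.path(fixture_dir, "counts.mtx"),
                                genes = file.path(fixture_dir, "counts.genes.txt"),
                                cells = file.path(fixture_dir, "counts.cells.txt"))
    cd <- readCellTable(file.path(fixture_dir, "cell_metadata.tsv"))
    SummarizedExperiment::colData(sce) <-
      S4Vectors::DataFrame(cd, row.names = cd$cell_id)[colnames(sce), ]
    rd <- read.delim(file.path(fixture_dir, "gene_annotation.tsv"),
                     stringsAsFactors = FALSE)
    SummarizedExperiment::rowData(sce) <-
      S4Vectors::DataFrame(rd, row.names = rd$gene_id)[rownames(sce), ]
    tcr <- readTcrTable(file.path(fixture_dir, "tcr_chains.tsv"))
    gmt_path <- file.path(fixture_dir, "sets.gmt")
    sig_path <- file.path(fixture_dir, "signature_planted.tsv")
  } else {
    sce <- readExpressionMatrix(cfg$inputs$counts_mtx,
                                genes = cfg$inputs$genes,
                                cells = cfg$inputs$cells)
    cd <- readCellTable(cfg$inputs$cell_metadata)
    SummarizedExperiment::colData(sce) <-
      S4Vectors::DataFrame(cd, row.names = cd$cell_id)[colnames(sce), ]
    if (!is.null(cfg$inputs$gene_annotation)) {
      rd <- read.delim(cfg$inputs$gene_annotation, stringsAsFactors = FALSE)
      SummarizedExperiment::rowData(sce) <-
        S4Vectors::DataFrame(rd, row.names = rd$gene_id)[rownames(sce), ]
    }
    tcr <- readTcrTable(cfg$inputs$tcr)
    gmt_path <- cfg$inputs$gmt
    sig_path <- cfg$inputs$signature
  }
  out <- list()

  ## ---- qc ----
  th <- do.call(qcThresholds, cfg$qc)
  if ("qc" %in% stages) {
    qc <- filterCells(sce, th)
    sce <- sce[, qc$pass]
    keep <- filterGenes(sce, th)
    sce <- sce[keep, ]
    f1 <- file.path(cfg$outdir, "qc_cells.tsv")
    write_tsv(data.frame(cell_id = rownames(qc$flags),
                         pass = !rownames(qc$flags) %in% qc$fail,
                         qc$flags, check.names = FALSE), f1)
    f2 <- file.path(cfg$outdir, "qc_summary.json")
    jsonlite::write_json(
      list(n_input = nrow(qc$flags), n_pass = length(qc$pass),
           n_fail = length(qc$fail), n_genes_retained = length(keep),
           failures_per_criterion = as.list(qc$report)),
      f2, auto_unbox = TRUE, pretty = TRUE)
    note("qc", unclass(th), c(f1, f2))
  }

  ## ---- normalize ----
  if ("normalize" %in% stages) {
    sce <- normalizeExpression(sce, pseudocount = cfg$normalize$pseudocount)
  }
  out$sce <- sce

  ## ---- differential expression ----
  if ("de" %in% stages) {
    de <- runDE(sce, "tetramer_label", test = cfg$de$test)
    out$de <- de
    degs <- selectDegs(de, cfg$de$fdr_max, cfg$de$min_fc)
    f1 <- file.path(cfg$outdir, "de_results.tsv")
    write_tsv(as.data.frame(de), f1)
    ranked <- rankMetric(de)
    f2 <- file.path(cfg$outdir, "de_ranked.tsv")
    write_tsv(data.frame(gene = names(ranked), rank_score = unname(ranked)),
              f2)
    f3 <- file.path(cfg$outdir, "de_selected.tsv")
    write_tsv(data.frame(gene = degs), f3)
    note("de", cfg$de, c(f1, f2, f3))
  }

  ## ---- gsea ----
  if ("gsea" %in% stages && !is.null(gmt_path) && file.exists(gmt_path)) {
    ranked <- rankMetric(out$de)
    sets <- readGmt(gmt_path)
    gs <- runGsea(ranked, sets, min_size = cfg$gsea$min_size,
                  max_size = cfg$gsea$max_size, p = cfg$gsea$weight,
                  n_perm = cfg$gsea$n_perm, seed = cfg$gsea$seed)
    out$gsea <- gs
    f <- file.path(cfg$outdir, "gsea_results.tsv")
    tab <- as.data.frame(gs[, setdiff(colnames(gs), "leading_edge")])
    tab$leading_edge <- vapply(gs$leading_edge, paste, character(1),
                               collapse = ",")
    write_tsv(tab, f)
    note("gsea", cfg$gsea[setdiff(names(cfg$gsea), "weight")], f)
  }

  ## ---- signature scoring ----
  if ("score" %in% stages && !is.null(sig_path) && file.exists(sig_path)) {
    sig <- readSignature(sig_path)
    sc <- scoreCells(sce, sig, layer = cfg$score$layer)
    out$scores <- sc
    cmp <- compareScores(
      sc$score, get_cell_table(sce)$tetramer_label[
        match(sc$cell_id, colnames(sce))])
    f1 <- file.path(cfg$outdir, "signature_scores.tsv")
    write_tsv(sc, f1)
    f2 <- file.path(cfg$outdir, "signature_comparison.json")
    jsonlite::write_json(
      list(signature = sig@name, wilcoxon_w = cmp$statistic,
           p_value = cmp$p_value, method = cmp$method),
      f2, auto_unbox = TRUE, pretty = TRUE)
    note("score", cfg$score, c(f1, f2))
  }

  ## ---- clonotypes ----
  if ("clones" %in% stages) {
    tcr_qc <- tcr[tcr$cell_id %in% colnames(sce), , drop = FALSE]
    part <- assignClones(tcr_qc, sce, use_aa = cfg$clones$use_aa,
                         include_nonproductive = cfg$clones$include_nonproductive)
    out$partition <- part
    summ <- cloneSummary(part, sce)
    f1 <- file.path(cfg$outdir, "clone_assignment.tsv")
    a <- cloneAssignment(part)
    sz <- cloneSizes(part)
    write_tsv(data.frame(cell_id = names(a), clone_id = unname(a),
                         clone_size = unname(sz[a])), f1)
    f2 <- file.path(cfg$outdir, "clone_summary.json")
    jsonlite::write_json(summ$global, f2, auto_unbox = TRUE, pretty = TRUE)
    note("clones", cfg$clones, c(f1, f2))
  }

  ## ---- clonal similarity ----
  if ("clonesim" %in% stages) {
    cs <- cloneSimilarityTest(sce, out$partition,
                              seed = cfg$clonesim$seed,
                              layer = cfg$clonesim$layer,
                              exclude_intra = cfg$clonesim$exclude_intra,
                              exclude_duplicates = cfg$clonesim$exclude_duplicates)
    out$similarity <- cs
    f1 <- file.path(cfg$outdir, "clone_similarity_pairs.tsv")
    write_tsv(cs$pairs, f1)
    f2 <- file.path(cfg$outdir, "clone_similarity.json")
    r <- cs$result
    jsonlite::write_json(
      list(t = r@statistic, df = r@df, p_value = r@p_value,
           mean_intra = mean(r@correlations_intra),
           mean_random = mean(r@correlations_random),
           n_pairs = length(r@correlations_intra),
           n_shared_cell_pairs = as.list(cs$n_shared_cell_pairs)),
      f2, auto_unbox = TRUE, pretty = TRUE)
    note("clonesim", cfg$clonesim, c(f1, f2))
  }

  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
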