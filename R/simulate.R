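#' Simulation configuration
#'
#' Defines the statistical structure of a synthetic tetramer-sort
#' experiment: negative-binomial counts with log-normal gene means and
#' cell size factors, logistic dropout indexed on the gene-cell mean,
#' a planted tetramer-positive expression program, planted TCR clones
#' whose members share both an identical receptor and a clone-private
#' expression shift, TR/MT/ribosomal gene categories, and per-cell QC
#' covariates with a controlled fraction of single-criterion violators.
#'
#' @param n_patients number of patient batches (default 4).
#' @param cells_per_patient cells per patient (default 250).
#' @param fraction_tetramer_positive fraction of each patient's cells
#'   sorted as tetramer-positive (default 0.5).
#' @param n_genes total genes (default 10000).
#' @param n_tr_genes T-cell receptor locus genes, named TRAV/TRAJ/TRBV/
#'   TRBJ (default 120).
#' @param n_mt_genes mitochondrial genes, named MT- (default 13).
#' @param n_ribo_genes ribosomal genes, named RPL/RPS (default 80).
#' @param nb_mean_log_mu,nb_mean_log_sigma log-normal parameters of the
#'   per-gene mean expression (defaults 2 and 1.5, giving an expected
#'   per-cell total of roughly 2e5 counts at 10,000 genes, consistent
#'   with the read-depth covariates the generator draws).
#' @param nb_dispersion negative-binomial size parameter theta (default 2).
#' @param dropout_logit_intercept,dropout_logit_slope dropout probability
#'   is `plogis(intercept + slope * log(mu))` at gene-cell mean `mu`
#'   (defaults -1 and -0.5: low-mean genes drop out more).
#' @param size_factor_sdlog sd(log) of the per-cell size factor
#'   (default 0.3).
#' @param group_effect_genes,group_log2fc number of genes and log2 fold
#'   change added in tetramer-positive cells (defaults 100 and 1).
#' @param clone_size_distribution clone sizes planted per patient: either
#'   a numeric vector of sizes or a data.frame(size, count). Default
#'   `data.frame(size = c(4, 3, 2), count = c(2, 4, 7))`, i.e. 13 clones
#'   covering 34 cells per patient, emulating an expanded repertoire with
#'   mostly small clones.
#' @param clone_effect_genes,clone_effect_log2fc per-clone private
#'   expression program: each clone draws its own gene subset of this
#'   size and shifts it by this log2 fold change in member cells
#'   (defaults 1000 genes — about 10% of the default transcriptome,
#'   since clonal identity in T cells tracks broad activation and
#'   differentiation programs rather than a handful of markers — at
#'   log2 fold change 1).
#' @param effect_gene_min_mu expression floor for planted effect genes:
#'   group and clone programs are drawn from ordinary genes with mean
#'   expression above this value (default 4 counts), since a fold change
#'   on a gene averaging well under one count per cell is invisible at
#'   plate-based sequencing depth and expressed genes are what real DEG
#'   lists contain.
#' @param qc_violation_fraction fraction of cells given metadata (or, for
#'   the detected-gene rule, counts) violating exactly one QC criterion
#'   (default 0.15).
#' @param qc_min_genes the detected-gene floor the planted violations are
#'   aimed at (default 1800, the patient-profile threshold): gene-count
#'   violators are sparsified to half this many detected genes. Override
#'   together with any non-default [qcThresholds()] `min_genes`.
#' @param tcr_detection_rate probability that a non-clone cell has
#'   reconstructed chains (default 0.83); clone members always do.
#' @param seed RNG seed (default 1).
#' @return Named list of class "SimulationConfig".
#' @export
simConfig <- function(n_patients = 4, cells_per_patient = 250,
                      fraction_tetramer_positive = 0.5,
                      n_genes = 10000, n_tr_genes = 120, n_mt_genes = 13,
                      n_ribo_genes = 80,
                      nb_mean_log_mu = 2, nb_mean_log_sigma = 1.5,
                      nb_dispersion = 2,
                      dropout_logit_intercept = -1,
                      dropout_logit_slope = -0.5,
                      size_factor_sdlog = 0.3,
                      group_effect_genes = 100, group_log2fc = 1,
                      clone_size_distribution =
                        data.frame(size = c(4, 3, 2), count = c(2, 4, 7)),
                      clone_effect_genes = 1000, clone_effect_log2fc = 1,
                      effect_gene_min_mu = 4,
                      qc_violation_fraction = 0.15,
                      qc_min_genes = 1800,
                      tcr_detection_rate = 0.83,
                      seed = 1) {
  cfg <- as.list(environment())
  for (nm in c("n_patients", "cells_per_patient", "n_genes"))
    if (!is_count(cfg[[nm]]) || cfg[[nm]] < 1)
      stopf("'%s' must be a positive integer", nm)
  for (nm in c("fraction_tetramer_positive", "qc_violation_fraction",
               "tcr_detection_rate"))
    if (!is_fraction(cfg[[nm]])) stopf("'%s' must lie in [0, 1]", nm)
  if (cfg$nb_dispersion <= 0) stopf("'nb_dispersion' must be positive")
  sizes <- clone_sizes_vector(cfg$clone_size_distribution)
  n_pos <- round(cfg$cells_per_patient * cfg$fraction_tetramer_positive)
  if (sum(sizes) > n_pos)
    stopf("clone sizes (%d cells) exceed tetramer-positive cells per patient (%d)",
          sum(sizes), n_pos)
  if (cfg$n_tr_genes + cfg$n_mt_genes + cfg$n_ribo_genes >= cfg$n_genes)
    stopf("category gene counts must leave room for ordinary genes")
  structure(cfg, class = "SimulationConfig")
}

clone_sizes_vector <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("size", "count") %in% names(x)))
      stopf("clone_size_distribution data.frame needs columns size, count")
    sizes <- rep(x$size, x$count)
  } else {
    sizes <- as.numeric(x)
  }
  if (any(sizes < 1 | sizes != floor(sizes)))
    stopf("clone sizes must be positive integers")
  sort(as.integer(sizes), decreasing = TRUE)
}

# Standard genetic code, used to translate simulated CDR3 nucleotide
# sequences (codons are drawn from the 61 non-stop codons).
genetic_code <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aa, codons)
})

translate_nt <- function(nt) {
  cods <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  paste(genetic_code[cods], collapse = "")
}

# Draw one never-seen CDR3 nucleotide sequence (10-15 stop-free codons).
draw_cdr3 <- function(used) {
  sense <- names(genetic_code)[genetic_code != "*"]
  repeat {
    nt <- paste(sample(sense, sample(10:15, 1), replace = TRUE),
                collapse = "")
    if (!(nt %in% used$set)) {
      used$set <- c(used$set, nt)
      return(nt)
    }
  }
}

#' Generate a synthetic tetramer-sort dataset
#'
#' Draws counts for gene g in cell c as negative binomial with mean
#' `mu_g * s_c * 2^(planted effects)` and dispersion theta, then zeroes
#' each entry with probability `plogis(intercept + slope * log(mean))`
#' (dropout). Tetramer-positive cells receive the group program; members
#' of each planted clone additionally receive that clone's private
#' program and share an identical productive TRA + TRB chain pair (unique
#' per clone). A configured fraction of cells violates exactly one QC
#' criterion; detected-gene violators are created by sparsifying their
#' counts so the violation is visible in the matrix itself.
#'
#' @param config a [simConfig()] object.
#' @return List with components:
#'   \describe{
#'     \item{sce}{[SingleCellExperiment::SingleCellExperiment]; counts
#'       assay, colData = per-cell QC covariates and study labels,
#'       rowData = gene annotation with a `category` column
#'       (TR/MT/RIBOSOMAL/OTHER).}
#'     \item{tcr}{TCR chain table ([readTcrTable()] shape).}
#'     \item{truth}{ground truth: `de_genes` (gene, log2fc),
#'       `clone_assignment` (named cell -> clone vector),
#'       `clone_effect_genes` (per-clone gene lists), `qc_should_fail`
#'       (data.frame cell_id, rule).}
#'   }
#' @export
generateDataset <- function(config = simConfig()) {
  if (!inherits(config, "SimulationConfig"))
    config <- do.call(simConfig, config)
  cfg <- config
  with_seed(cfg$seed, {
    ## ---- gene universe ----
    n_tra_v <- ceiling(cfg$n_tr_genes / 4)
    tr <- c(sprintf("TRAV%d", seq_len(n_tra_v)),
            sprintf("TRAJ%d", seq_len(n_tra_v)),
            sprintf("TRBV%d", seq_len(n_tra_v)),
            sprintf("TRBJ%d", seq_len(n_tra_v)))[seq_len(cfg$n_tr_genes)]
    mt <- sprintf("MT-G%02d", seq_len(cfg$n_mt_genes))
    ribo <- c(sprintf("RPL%d", seq_len(ceiling(cfg$n_ribo_genes / 2))),
              sprintf("RPS%d", seq_len(ceiling(cfg$n_ribo_genes / 2))))[
                seq_len(cfg$n_ribo_genes)]
    n_other <- cfg$n_genes - length(tr) - length(mt) - length(ribo)
    other <- sprintf("GENE%05d", seq_len(n_other))
    genes <- c(tr, mt, ribo, other)
    category <- rep(c("TR", "MT", "RIBOSOMAL", "OTHER"),
                    c(length(tr), length(mt), length(ribo), length(other)))

    mu <- rlnorm(cfg$n_genes, cfg$nb_mean_log_mu, cfg$nb_mean_log_sigma)

    ## ---- cells ----
    patients <- sprintf("P%d", seq_len(cfg$n_patients))
    n_pos <- round(cfg$cells_per_patient * cfg$fraction_tetramer_positive)
    cell_df <- do.call(rbind, lapply(patients, function(p) {
      tet <- rep(c("positive", "negative"),
                 c(n_pos, cfg$cells_per_patient - n_pos))
      data.frame(
        cell_id = sprintf("%s_cell%04d", p, seq_len(cfg$cells_per_patient)),
        patient = p,
        plate = sprintf("%s_plate%d", p, ifelse(tet == "positive", 1L, 2L)),
        tetramer_label = tet,
        stringsAsFactors = FALSE)
    }))
    n_cells <- nrow(cell_df)
    s <- rlnorm(n_cells, 0, cfg$size_factor_sdlog)

    ## ---- planted effects ----
    other_idx <- which(category == "OTHER")
    eff_pool <- other_idx[mu[other_idx] > cfg$effect_gene_min_mu]
    if (length(eff_pool) < max(cfg$group_effect_genes, cfg$clone_effect_genes))
      eff_pool <- other_idx
    n_grp <- min(cfg$group_effect_genes, length(eff_pool))
    n_cle <- min(cfg$clone_effect_genes, length(eff_pool))
    if (n_grp < cfg$group_effect_genes || n_cle < cfg$clone_effect_genes)
      warnf("effect-gene pool (%d ordinary genes) smaller than requested program; capped",
            length(eff_pool))
    grp_idx <- if (n_grp > 0) sort(sample(eff_pool, n_grp)) else integer()
    clone_members <- list()
    clone_genes <- list()
    for (p in patients) {
      sizes <- clone_sizes_vector(cfg$clone_size_distribution)
      pool <- cell_df$cell_id[cell_df$patient == p &
                                cell_df$tetramer_label == "positive"]
      for (k in seq_along(sizes)) {
        cid <- sprintf("%s_k%02d", p, k)
        mem <- sample(pool, sizes[k])
        pool <- setdiff(pool, mem)
        clone_members[[cid]] <- sort(mem)
        clone_genes[[cid]] <- if (n_cle > 0)
          sort(sample(eff_pool, n_cle)) else integer()
      }
    }
    cell_clone <- if (length(clone_members)) {
      setNames(rep(names(clone_members), lengths(clone_members)),
               unlist(clone_members, use.names = FALSE))
    } else {
      setNames(character(0), character(0))
    }

    ## ---- counts ----
    counts <- matrix(0, cfg$n_genes, n_cells,
                     dimnames = list(genes, cell_df$cell_id))
    is_pos <- cell_df$tetramer_label == "positive"
    for (j in seq_len(n_cells)) {
      e <- numeric(cfg$n_genes)
      if (is_pos[j] && length(grp_idx)) e[grp_idx] <- cfg$group_log2fc
      cl <- unname(cell_clone[cell_df$cell_id[j]])
      if (length(cl) == 1L && !is.na(cl) && length(clone_genes[[cl]]))
        e[clone_genes[[cl]]] <- e[clone_genes[[cl]]] + cfg$clone_effect_log2fc
      mu_j <- mu * s[j] * 2^e
      x <- rnbinom(cfg$n_genes, size = cfg$nb_dispersion, mu = mu_j)
      drop <- runif(cfg$n_genes) <
        plogis(cfg$dropout_logit_intercept +
                 cfg$dropout_logit_slope * log(mu_j))
      x[drop] <- 0L
      counts[, j] <- x
    }

    ## ---- QC covariates and planted violators ----
    cell_df$mapping_rate <- pmin(pmax(rbeta(n_cells, 24, 5), 0.5), 0.99)
    cell_df$total_reads <- as.integer(pmax(
      round(rlnorm(n_cells, log(1e6), 0.35)), 150000))
    cell_df$mito_fraction <- pmin(rbeta(n_cells, 2, 30), 0.11)
    k_viol <- round(cfg$qc_violation_fraction * n_cells)
    qc_fail <- data.frame(cell_id = character(), rule = character(),
                          stringsAsFactors = FALSE)
    if (k_viol > 0) {
      viol <- sample(cell_df$cell_id, k_viol)
      rules <- rep(c("mapping_rate", "total_reads", "n_genes_detected",
                     "mito_fraction"), length.out = k_viol)
      for (i in seq_len(k_viol)) {
        ci <- match(viol[i], cell_df$cell_id)
        switch(rules[i],
          mapping_rate = {
            cell_df$mapping_rate[ci] <- runif(1, 0.05, 0.25)
          },
          total_reads = {
            cell_df$total_reads[ci] <- as.integer(runif(1, 20000, 90000))
          },
          mito_fraction = {
            cell_df$mito_fraction[ci] <- runif(1, 0.15, 0.40)
          },
          n_genes_detected = {
            nz <- which(counts[, ci] > 0)
            keep <- sample(nz, min(floor(cfg$qc_min_genes / 2), length(nz)))
            counts[setdiff(nz, keep), ci] <- 0
          })
      }
      qc_fail <- data.frame(cell_id = viol, rule = rules,
                            stringsAsFactors = FALSE)
    }
    cell_df$n_genes_detected <- as.integer(colSums(counts > 0))

    ## ---- TCR chains ----
    used <- new.env(); used$set <- character()
    vnames <- list(TRA = grep("^TRAV", tr, value = TRUE),
                   TRB = grep("^TRBV", tr, value = TRUE))
    jnames <- list(TRA = grep("^TRAJ", tr, value = TRUE),
                   TRB = grep("^TRBJ", tr, value = TRUE))
    make_chain <- function(cell, locus, productive = TRUE) {
      nt <- draw_cdr3(used)
      data.frame(cell_id = cell, locus = locus,
                 v_gene = sample(vnames[[locus]], 1),
                 j_gene = sample(jnames[[locus]], 1),
                 cdr3_nt = nt, cdr3_aa = translate_nt(nt),
                 productive = productive, stringsAsFactors = FALSE)
    }
    rows <- list()
    for (cid in names(clone_members)) {
      a <- make_chain("template", "TRA")
      b <- make_chain("template", "TRB")
      for (cell in clone_members[[cid]]) {
        a$cell_id <- cell; b$cell_id <- cell
        rows[[length(rows) + 1L]] <- a
        rows[[length(rows) + 1L]] <- b
      }
    }
    in_clone <- cell_df$cell_id %in% names(cell_clone)
    detected <- runif(n_cells) < cfg$tcr_detection_rate
    for (j in which(!in_clone & detected)) {
      cell <- cell_df$cell_id[j]
      rows[[length(rows) + 1L]] <- make_chain(cell, "TRA")
      rows[[length(rows) + 1L]] <- make_chain(cell, "TRB")
      if (runif(1) < 0.1)
        rows[[length(rows) + 1L]] <- make_chain(cell, "TRB",
                                                productive = FALSE)
    }
    tcr <- do.call(rbind, rows)
    rownames(tcr) <- NULL

    ## ---- assemble ----
    annot <- S4Vectors::DataFrame(gene_id = genes, symbol = genes,
                                  category = category, row.names = genes)
    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = as(counts, "CsparseMatrix")),
      colData = S4Vectors::DataFrame(cell_df, row.names = cell_df$cell_id),
      rowData = annot)
    truth <- list(
      de_genes = if (length(grp_idx))
        data.frame(gene = genes[grp_idx], log2fc = cfg$group_log2fc,
                   stringsAsFactors = FALSE)
      else data.frame(gene = character(), log2fc = numeric()),
      clone_assignment = cell_clone,
      clone_effect_genes = lapply(clone_genes, function(i) genes[i]),
      qc_should_fail = qc_fail)
    list(sce = sce, tcr = tcr, truth = truth, config = cfg)
  })
}

#' Write a generated dataset as a plain-text fixture directory
#'
#' Emits the Matrix Market counts triplet, cell metadata, gene annotation,
#' TCR chain table and ground-truth tables, plus a `manifest.json` listing
#' every file with its MD5 checksum.
#'
#' @param dataset output of [generateDataset()].
#' @param out_dir directory (created if needed).
#' @return Invisibly, the manifest as a named list of checksums.
#' @export
writeFixture <- function(dataset, out_dir) {
  if (!ncol(dataset$sce))
    stopf("refusing to write an empty dataset (0 cells)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  files <- c(files, writeExpressionMatrix(
    dataset$sce, file.path(out_dir, "counts"), format = "mtx"))
  cd <- as.data.frame(SummarizedExperiment::colData(dataset$sce))
  f <- file.path(out_dir, "cell_metadata.tsv"); write_tsv(cd, f)
  files <- c(files, f)
  rd <- as.data.frame(SummarizedExperiment::rowData(dataset$sce))
  f <- file.path(out_dir, "gene_annotation.tsv"); write_tsv(rd, f)
  files <- c(files, f)
  f <- file.path(out_dir, "tcr_chains.tsv"); write_tsv(dataset$tcr, f)
  files <- c(files, f)
  f <- file.path(out_dir, "truth_de_genes.tsv")
  write_tsv(dataset$truth$de_genes, f); files <- c(files, f)
  f <- file.path(out_dir, "truth_clones.tsv")
  write_tsv(data.frame(cell_id = names(dataset$truth$clone_assignment),
                       clone_id = unname(dataset$truth$clone_assignment)), f)
  files <- c(files, f)
  f <- file.path(out_dir, "truth_qc.tsv")
  write_tsv(dataset$truth$qc_should_fail, f); files <- c(files, f)
  sums <- tools::md5sum(files)
  names(sums) <- basename(names(sums))
  jsonlite::write_json(as.list(sums),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(as.list(sums))
}

#' Verify a fixture directory against its manifest
#'
#' @param dir fixture directory written by [writeFixture()].
#' @return TRUE invisibly if all checksums match; otherwise an error
#'   naming the mismatching or missing files.
#' @export
verifyFixture <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stopf("no manifest.json in %s", dir)
  sums <- jsonlite::read_json(mf, simplifyVector = TRUE)
  bad <- character()
  for (nm in names(sums)) {
    f <- file.path(dir, nm)
    if (!file.exists(f)) bad <- c(bad, paste0(nm, " (missing)"))
    else if (unname(tools::md5sum(f)) != sums[[nm]])
      bad <- c(bad, paste0(nm, " (checksum mismatch)"))
  }
  if (length(bad))
    stopf("fixture verification failed: %s", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Build gene sets matched to a generated dataset
#'
#' Random gene sets drawn from the dataset's gene universe plus one set
#' holding the planted tetramer-positive program ("PLANTED_UP"), for
#' exercising preranked enrichment on a fixture with a known positive.
#'
#' @param dataset output of [generateDataset()].
#' @param n_random number of random sets (default 25).
#' @param size_range inclusive size range for random sets (default 20-200).
#' @param seed RNG seed.
#' @return Named list of gene sets with a description attribute, ready for
#'   [writeGmt()].
#' @export
makeFixtureGeneSets <- function(dataset, n_random = 25,
                                size_range = c(20, 200), seed = 1) {
  genes <- rownames(dataset$sce)
  with_seed(seed, {
    sets <- lapply(seq_len(n_random), function(i) {
      sample(genes, sample(size_range[1]:size_range[2], 1))
    })
    names(sets) <- sprintf("RANDOM_SET_%02d", seq_len(n_random))
    if (nrow(dataset$truth$de_genes))
      sets$PLANTED_UP <- dataset$truth$de_genes$gene
    attr(sets, "description") <-
      setNames(rep("synthetic", length(sets)), names(sets))
    sets
  })
}
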