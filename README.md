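# clonexpr

Clonotype-aware single-cell transcriptomics of tetramer-sorted T cells.

## What this package is for

Peptide–MHC tetramer staining isolates the T cells whose receptor
recognizes one specific antigen. Sorting tetramer-positive and
tetramer-negative effector-memory CD4+ T cells onto plates and
sequencing full-length transcripts (SMART-seq2 style) yields, for every
cell, both its transcriptome and — because reads span whole
transcripts — its reconstructed T-cell receptor (TCR). `clonexpr` is an
R/Bioconductor-style package implementing the complete downstream
analysis for this design:

* **QC**: the four per-cell criteria (mapping rate > 30%, reads
  > 100,000, detected genes 1,800–15,000, mitochondrial fraction
  < 12.5%) plus the ≥ 10-cell per-gene prevalence filter.
* **Normalization**: full-quantile normalization across cells, log
  transform, per-gene scaling — attached as assays of a
  `SingleCellExperiment`.
* **Differential expression** between tetramer-positive and -negative
  cells with a two-part (hurdle) likelihood-ratio test — a binomial
  component on detection rates plus a Gaussian component on positive
  values — Benjamini–Hochberg FDR, Seurat-style average log2 fold
  change, and the signed significance ranking
  `-sign(log2FC) * log10(p)` for preranked enrichment.
* **Preranked GSEA** written from scratch: weighted running-sum
  enrichment score, seeded gene-tag permutation null, NES, BH FDR, with
  the 15–500 intersected-size filter.
* **Signature scoring**: signed (+1/−1) gene signatures projected onto
  cells as size-normalized weighted sums of scaled expression, compared
  between groups by the Wilcoxon rank-sum test.
* **Clonotype assignment**: within each patient, cells sharing an
  identical productive chain — (locus, V, J, CDR3-nucleotide) — are
  linked and clonotypes are the connected components (transitive
  closure across alpha and beta chains).
* **Clonal similarity test**: all intra-clone cell pairs versus a
  size-matched random set of same-patient tetramer-positive pairs;
  Pearson correlation over all genes except TR-locus genes; Welch
  two-sample t-test on the two correlation sets.
* **Synthetic data**: a seeded generator (negative binomial + logistic
  dropout, planted group and clone expression programs, planted QC
  violators, shared TCR chains per clone) providing ground truth for
  every stage, and a config-driven `runAll()` pipeline with manifested,
  byte-reproducible outputs.

## Worked example

```r
library(clonexpr)

ds <- generateDataset(simConfig(n_patients = 2, cells_per_patient = 100,
  n_genes = 2000, n_tr_genes = 40, n_mt_genes = 10, n_ribo_genes = 20,
  clone_size_distribution = rep(4, 6), qc_min_genes = 600, seed = 42))

qc <- filterCells(ds$sce, qcThresholds(min_genes = 600, max_genes = 2000))
qc$report
#>     mapping_rate      total_reads n_genes_detected    mito_fraction
#>                8                8                7                7

sce <- ds$sce[, qc$pass]
sce <- normalizeExpression(sce[filterGenes(sce), ])

de <- runDE(sce, "tetramer_label")
length(selectDegs(de))   # FDR < 0.05 and |FC| > 1.5
#> [1] 91

part <- assignClones(ds$tcr[ds$tcr$cell_id %in% colnames(sce), ], sce)
part
#> ClonePartition: 148 cells in 120 clonotypes (2 patients)
#>   expanded (size >= 2): 12 clones covering 40 cells
#>   singletons: 108; cells without usable chains: 22

cloneSimilarityTest(sce, part, seed = 7)$result
#> Welch two-sample t-test: intra-clone vs random-clone correlations
#>   n pairs: 50 intra, 50 random
#>   mean r: intra 0.7033, random 0.6638
#>   t = 8.252, df = 71.7, p-value = 5.32e-12
```

Reading the output: 30 of 200 simulated cells were planted as
single-criterion QC violators and the report counts them per criterion;
91 genes pass the DEG thresholds (the generator planted a 100-gene
2-fold program in tetramer-positive cells); the 12 planted clones of 4
cells are recovered from shared chains (some members fell to QC); and
the intra-clone pairs are clearly more correlated than random
same-patient pairs (t = 8.25, p = 5e-12) because each planted clone
carries a private expression program covering roughly half the
expressed genes at this reduced 2,000-gene demonstration scale.

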