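---
title: "Methods: clonotype-aware analysis of tetramer-sorted T cells"
author: "clonexpr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonotype-aware analysis of tetramer-sorted T cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonexpr)
```

# The analysis problem

Antigen-specific CD4+ T cells can be isolated by staining with
peptide–MHC tetramers and index-sorted onto plates for full-length
(SMART-seq2 style) single-cell RNA sequencing. Because the reads cover
whole transcripts, the rearranged T-cell receptor (TCR) of each cell can
be assembled from the same libraries, linking every transcriptome to a
clonotype. `clonexpr` implements the complete downstream analysis for
such experiments: per-cell quality control, normalization, differential
expression between tetramer-positive and tetramer-negative cells,
preranked gene-set enrichment, projection of signed gene signatures onto
cells, clonotype assignment from shared TCR chains, and a
constructed-null test of whether clonally related cells are
transcriptionally more similar than random same-patient pairs.

The package also ships a synthetic-data generator that emulates the
statistical structure such a study produces, with known ground truth at
every stage. All tests and the acceptance script run on generated data;
no patient data are included or required.

# Quality control

Cells are filtered by four criteria evaluated on per-cell covariates:

* mapping rate strictly greater than 30%,
* more than 100,000 reads,
* between 1,800 and 15,000 detected genes (inclusive on both ends),
* mitochondrial read fraction strictly below 12.5%.

The first two and the last are strict inequalities, the gene range is
inclusive; these boundary readings are literal, and every bound is a
`qcThresholds()` parameter so any alternative convention is one argument
away. A second named profile (`profile = "healthy_donor"`) carries the
looser preselection used for public healthy-donor effector-memory
reference cells (reads > 2,400, detected genes 850–2,000).

After cell filtering, genes detected (count > 0) in fewer than 10
passing cells are removed. The order — cells first, then genes — is part
of the contract: a gene detected in 10 cells of which 3 fail QC drops
out, and the test suite pins this ordering.

`filterCells()` reports failure counts per criterion non-exclusively (a
cell failing two criteria is counted under both).

# Normalization

Three derived layers are attached to the
`SingleCellExperiment` by `normalizeExpression()`:

1. **quantile_norm** — full-quantile normalization across cells: within
   each cell the value of rank $r$ is replaced by the mean across cells
   of the $r$-th order statistic, so every cell shares one empirical
   distribution. Ties within a cell receive the mean of the reference
   quantiles the tie block spans. With tied data (counts have many
   zeros) this tie rule necessarily breaks exact multiset equality
   across cells — cells with different numbers of zeros map their zero
   blocks to slightly different averages — so the exact
   equal-distribution property is asserted on tie-free input only.
2. **lognorm** — natural log of (value + pseudocount), pseudocount 1 by
   default so zeros map to zero.
3. **scaled** — per-gene standardization (mean 0, sd 1 across cells,
   $n-1$ divisor). Zero-variance genes map to all-zeros with a warning.

Scaling uses all retained cells jointly; per-batch integration (mutual
nearest neighbors/CCA) is deliberately out of scope — the clonal
similarity test pairs cells within patients, which makes batch
correction unnecessary for the quantities this package computes, and
embedding coordinates for visualization can come from any off-the-shelf
tool.

# Differential expression

`runDE()` tests each gene between the two sorted populations with a
covariate-free two-part (hurdle) likelihood-ratio test in the style of
single-cell hurdle models:

* a **discrete** component compares detection rates (value > 0) by a
  binomial likelihood-ratio chi-square (1 df);
* a **continuous** component compares Gaussian models of the positive
  values with and without a group mean difference (1 df);
* the combined statistic is the sum of the available components,
  referred to a chi-square with matching degrees of freedom. A
  component is omitted (df reduced) when degenerate: all cells
  detected, none detected, fewer than two positive values, or positives
  confined to one group (the group contrast is then inestimable in the
  continuous part). An all-degenerate gene gets p = 1.

The study design has no further covariates, so the full regression
framework of hurdle-model packages is unnecessary; a Wilcoxon rank-sum
alternative (`test = "wilcoxon"`) is provided for sensitivity checks.

Fold change is the Seurat-style linear-scale average:
$\log_2\!\frac{\overline{e^{x_1}-1} + 1}{\overline{e^{x_2}-1} + 1}$
on the log-normalized layer. Genes are selected at FDR
(Benjamini–Hochberg) strictly below 0.05 and absolute average fold
change strictly above 1.5 — compared against the exact
$\log_2 1.5 = 0.584962\ldots$, not its rounded display value 0.58
(`selectDegs(min_abs_fc=)` accepts any other convention). A p-value of
exactly 0 is clamped to 1e-300 before taking logs.

For enrichment, the full result is ordered by the signed significance
score $-\operatorname{sign}(\log_2\mathrm{FC})\cdot\log_{10} p$,
descending, so the most significantly up-regulated gene is first. Ties
are broken by gene id for determinism.

Under the generator's null (2,000 genes, 100 cells per group, negative
binomial with dropout) the empirical type-I error at p < 0.05 sits near
0.05–0.06, and planted 2-fold genes on expressed genes are recovered at
FDR < 0.05 with sensitivity above 0.8; both are recomputed by the test
suite and the acceptance script, not quoted from elsewhere.

# Preranked gene-set enrichment

`runGsea()` re-implements the weighted Kolmogorov–Smirnov running-sum
statistic on the ranked list. Gene sets are first intersected with the
ranked universe and kept when the intersection has 15–500 genes
(GSEA-style convention: size is measured after intersection). Walking
the list, hits add $|r_i|^p / \sum_{hits}|r|^p$ and misses subtract
$1/(N-|S|)$; the enrichment score (ES) is the signed extremum of the
running sum, and the leading edge is the set of hits at or before a
positive extremum (at or after a negative one). When the positive and
negative extremes tie in magnitude (to 1e-9) the positive one is taken,
deterministically. The weight exponent defaults to $p=1$.

The null is a seeded gene-tag permutation (the only permutation scheme
available for a preranked list): hit positions are redrawn `n_perm`
times (default 1,000), NES is the observed ES divided by the mean |ES|
of same-sign permutations, and
$p = (1 + \#\{|ES_{perm}| \ge |ES|,\ \text{same sign}\}) /
(1 + \#\{\text{same sign}\})$.
Collection-level FDR is Benjamini–Hochberg over the permutation
p-values — statistically standard and deterministic, in place of the
pooled-NES FDR of the desktop GSEA implementations; this is a
documented deviation, not an emulation.

# Signature scoring

A `SignedSignature` assigns +1 to up-regulated and −1 to down-regulated
genes (e.g. from a bulk RNA-seq DEG list, or the Th1/Th2/Th17/Tfh/Treg
marker sets). `scoreCells()` projects it onto cells:
$\text{score}_c = \frac{1}{|G|}\sum_{g \in G} w_g\, x_{gc}$
over the signature genes present in the matrix, with $x$ the per-gene
scaled layer by default. Using scaled expression makes scores
comparable across signatures of different sizes and different absolute
expression; weighting by the raw log-normalized layer is available via
`layer = "lognorm"`. Random-signature background correction (as in
latent-space autocorrelation frameworks) is not implemented.

Score distributions between the two sorted populations are compared with
a two-sided Wilcoxon rank-sum test (`compareScores()`): exact
enumeration when both groups have at most 10 tie-free values, otherwise
the normal approximation with tie and continuity correction.

# Clonotype assignment

Within each patient, cells with at least one productive chain are
connected whenever they share an identical chain —
(locus, V gene, J gene, CDR3) with nucleotide CDR3 by default — and
clonotypes are the connected components, so chain sharing closes
transitively. Amino-acid matching (`use_aa = TRUE`) and inclusion of
non-productive chains are available as the looser alternatives.
Identical chains observed in two patients are treated as convergent
recombination and never merged. Single-chain sharing suffices to join a
clone (requiring both chains would be stricter; the chosen default
follows the reading that sharing at least one identical chain defines
clonal relation, and per-patient confinement makes the looser rule
safe in practice).

# The clonal transcriptome-similarity test

The question: are cells of the same clone transcriptionally more similar
than unrelated cells from the same patient? The construction:

1. **Intra-clone pairs** — all unordered pairs of eligible cells (passed
   QC, at least one reconstructed chain) within each clone of size ≥ 2.
2. **Random-clone pairs** — for each patient, exactly as many random
   unordered pairs of eligible tetramer-positive cells as that patient
   contributed intra pairs. Draws that land on clone-mates, or
   duplicate an already-drawn pair, are rejected and redrawn (both
   exclusions can be disabled; without them the null is contaminated by
   true clone pairs). Sampling is seeded.
3. **Correlations** — Pearson correlation between the two cells of each
   pair over all retained genes except TR-locus genes, which clone
   members share by construction and which would trivially inflate
   intra-clone similarity. TR genes are identified from the annotation
   category, or by the symbol pattern `^TR[ABGD][VDJC]`, or by an
   explicit list. Correlations use the log-normalized (pre-scaling)
   layer by default: per-patient pairing removes the need for batch
   correction, and per-gene scaling would distort per-cell covariance.
4. **Test** — Welch two-sample t-test (Satterthwaite df, two-sided)
   comparing the intra-clone and random-clone correlation sets.

Pairs sharing a cell are not independent; the package reproduces the
test as designed and additionally reports the count of shared-cell
pairs (`n_shared_cell_pairs`) so the reader can judge the degree of
dependence. Under the generator's null (no clone-private expression
program) the rejection rate at $\alpha = 0.05$ over 200 replicates
stays within a few percent of nominal despite this dependence; with a
planted clone program (2-fold over 100 genes, 10 clones of size 4 among
200 cells) the test rejects in ≥ 90% of replicates, with intra-clone
mean correlation above the random-clone mean in every rejecting
replicate. Both rates are recomputed by the acceptance tests.

# The synthetic-data generator

`generateDataset()` draws counts for gene $g$ in cell $c$ as

$$K_{gc} \sim \mathrm{NB}(\mu_g\, s_c\, 2^{e_{gc}},\ \theta), \qquad
  K_{gc} \to 0 \text{ with probability }
  \mathrm{logit}^{-1}(a + b \log \mu_{gc}),$$

with log-normal gene means $\mu_g$, log-normal cell size factors $s_c$,
dispersion $\theta = 2$, and dropout parameters $a = -1$, $b = -0.5$
(low-mean genes drop out more). Negative binomial plus logistic dropout
is the minimal model reproducing the overdispersion and zero inflation
of plate-based counts. Planted effects $e_{gc}$ comprise a
tetramer-positive program (default: 100 genes at log2FC 1) and a
private program per planted clone (default: 1,000 genes — about 10% of
the default transcriptome, since clonal identity in T cells tracks
broad activation and differentiation programs rather than a handful of
markers — at log2FC 1 in member cells). Effect genes are drawn from ordinary (non-TR, non-MT,
non-ribosomal) genes with $\mu_g > 4$: a fold change on a gene
averaging well below one count per cell is invisible at this depth, and
real DEG lists consist of expressed genes.

Default scale: 4 patients × 250 cells (half tetramer-positive),
10,000 genes with an expected per-cell total near $2\times10^5$ counts —
consistent with the drawn read-depth covariates (log-normal around
$10^6$ reads) and the read-count QC rule. Per patient, the default
clone structure plants 13 clones (2×4, 4×3, 7×2 cells) among
tetramer-positive cells, emulating an expanded repertoire dominated by
small clones; clone members share an identical productive TRA + TRB
pair, unique per clone, and 83% of remaining cells receive unique
chains (matching a realistic chain-reconstruction rate). CDR3s are
random in-frame stop-free nucleotide sequences of 30–45 nt; V(D)J
recombination biology is not simulated. A configured fraction of cells
(default 15%) violates exactly one QC criterion; detected-gene
violators are created by sparsifying their counts so the violation is
real in the matrix, and the planting is aimed at the `qc_min_genes`
threshold (override it together with a non-default QC profile).

Mapping rate and total reads are drawn independently of the count
matrix (they are upstream of quantification), while detected genes are
computed from the matrix itself.

What the generator does **not** emulate: batch effects requiring
integration, amplification-length biases, correlated gene programs
beyond the planted ones, realistic TCR repertoire structure, or
doublets. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
artefact of real plate data.

# Numerical and design choices

* All randomness is seeded per operation (`seed` arguments); no function
  leaves global RNG state perturbed. Identical configs give
  byte-identical pipeline outputs.
* Quantile-normalization ties: mean of spanned reference quantiles
  (block average), not interpolation.
* Hurdle test: a perfect within-group fit in the continuous part
  (residual sum of squares 0) is floored to keep the statistic finite.
* Rank-metric ties broken lexicographically by gene id; ranked-list
  sorting is stable on (score desc, gene asc).
* ES extremum magnitude ties (to 1e-9) resolve to the positive extreme.
* Wilcoxon comparisons switch from exact enumeration to the corrected
  normal approximation beyond 10 cells per group or in the presence of
  ties.
* Problem sizes used by the test suite: QC exactness on the default
  1,000-cell fixture; DE calibration on 2,000 genes × 200 cells;
  clonal-similarity calibration on 200 replicates of 1,000 genes × 200
  cells with 10 planted clones of 4; enrichment-score oracle on all
  subsets of 8- and 12-gene universes. These sizes give stable Monte
  Carlo estimates while keeping the suite fast.

# Known limitations

* The hurdle test is covariate-free; plate or patient effects on
  detection are not modeled (the study design confounds patient with
  batch, which integration — out of scope — would address for
  visualization).
* The pair test inherits the non-independence of pairs sharing a cell;
  a mixed-model or cell-level permutation alternative would be the
  statistically rigorous extension.
* GSEA FDR is BH over permutation p-values, not the pooled-NES scheme
  of desktop GSEA; NES values are comparable within a run only.
* Quantile normalization with heavily tied counts equalizes
  distributions only approximately (see above); this is a property of
  the tie rule, not an implementation artifact.
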