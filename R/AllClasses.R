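#' Signed gene signature
#'
#' A named set of genes each carrying a weight of +1 (up-regulated in the
#' condition of interest) or -1 (down-regulated), used to project bulk-derived
#' differential-expression results onto single cells via [scoreCells()].
#'
#' @slot name single character, signature identifier.
#' @slot weights named numeric vector; names are gene symbols, values +1 or -1.
#'
#' @seealso [SignedSignature()], [makeSignatureFromDegs()], [scoreCells()]
#' @export
setClass("SignedSignature",
         representation(name = "character", weights = "numeric"))

setValidity("SignedSignature", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msgs <- c(msgs, "'name' must be a single non-empty string")
  w <- object@weights
  if (length(w) < 1L)
    msgs <- c(msgs, "signature must contain at least one gene")
  if (is.null(names(w)) || any(!nzchar(names(w))) || anyNA(names(w)))
    msgs <- c(msgs, "'weights' must be named by gene symbol")
  if (anyDuplicated(names(w)))
    msgs <- c(msgs, sprintf("genes with both signs or duplicated: %s",
                            paste(unique(names(w)[duplicated(names(w))]),
                                  collapse = ", ")))
  if (!all(w %in% c(-1, 1)))
    msgs <- c(msgs, "all weights must be +1 or -1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SignedSignature
#'
#' @param name signature identifier.
#' @param up character vector of up-weighted (+1) gene symbols.
#' @param down character vector of down-weighted (-1) gene symbols.
#' @return A [SignedSignature-class] object.
#' @examples
#' sig <- SignedSignature("bulk_degs", up = c("IFNG", "CTLA4"), down = "SELL")
#' signatureWeights(sig)
#' @export
SignedSignature <- function(name, up = character(), down = character()) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  both <- intersect(up, down)
  if (length(both))
    stopf("genes present in both up and down lists: %s",
          paste(both, collapse = ", "))
  w <- c(rep(1, length(up)), rep(-1, length(down)))
  names(w) <- c(up, down)
  new("SignedSignature", name = name, weights = w)
}

#' @describeIn SignedSignature genes in the signature.
#' @param object,x a `SignedSignature`.
#' @export
signatureGenes <- function(object) names(object@weights)

#' @describeIn SignedSignature named vector of +1/-1 weights.
#' @export
signatureWeights <- function(object) object@weights

#' @export
setMethod("length", "SignedSignature", function(x) length(x@weights))

setMethod("show", "SignedSignature", function(object) {
  w <- object@weights
  cat(sprintf("SignedSignature '%s': %d genes (%d up, %d down)\n",
              object@name, length(w), sum(w > 0), sum(w < 0)))
  cat("  up:  ", paste(head(names(w)[w > 0], 5), collapse = ", "),
      if (sum(w > 0) > 5) "..." else "", "\n")
  if (any(w < 0))
    cat("  down:", paste(head(names(w)[w < 0], 5), collapse = ", "),
        if (sum(w < 0) > 5) "..." else "", "\n")
})

#' Partition of cells into TCR clonotypes
#'
#' Disjoint assignment of cells (those with at least one usable TCR chain) to
#' clonotypes, produced by [assignClones()]. Clones never span patients.
#'
#' @slot assignment named character vector mapping cell_id to clone_id.
#' @slot clones DataFrame with one row per clone: clone_id, patient, size.
#' @slot unassigned character vector of cell ids with no usable chain.
#'
#' @seealso [assignClones()], [cloneSummary()], [enumerateIntraPairs()]
#' @export
setClass("ClonePartition",
         representation(assignment = "character",
                        clones = "DataFrame",
                        unassigned = "character"))

setValidity("ClonePartition", function(object) {
  msgs <- character()
  a <- object@assignment
  cl <- object@clones
  if (length(a) && (is.null(names(a)) || anyDuplicated(names(a))))
    msgs <- c(msgs, "assignment must be uniquely named by cell_id")
  if (!all(c("clone_id", "patient", "size") %in% colnames(cl)))
    msgs <- c(msgs, "clones table needs columns clone_id, patient, size")
  else {
    if (anyDuplicated(cl$clone_id))
      msgs <- c(msgs, "duplicate clone ids")
    tab <- table(factor(a, levels = cl$clone_id))
    if (length(a) && !identical(as.integer(tab[cl$clone_id]),
                                as.integer(cl$size)))
      msgs <- c(msgs, "clone sizes inconsistent with assignment")
    if (sum(cl$size) != length(a))
      msgs <- c(msgs, "sum of clone sizes must equal number of assigned cells")
  }
  if (length(intersect(names(a), object@unassigned)))
    msgs <- c(msgs, "a cell cannot be both assigned and unassigned")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ClonePartition named cell_id -> clone_id vector.
#' @param object,x a `ClonePartition`.
#' @export
cloneAssignment <- function(object) object@assignment

#' @describeIn ClonePartition named integer vector of clone sizes.
#' @export
cloneSizes <- function(object) {
  structure(as.integer(object@clones$size), names = object@clones$clone_id)
}

#' @describeIn ClonePartition cells with no usable chain.
#' @export
unassignedCells <- function(object) object@unassigned

#' @describeIn ClonePartition ids of clones with two or more cells.
#' @export
expandedClones <- function(object) {
  object@clones$clone_id[object@clones$size >= 2L]
}

#' @describeIn ClonePartition per-clone table (clone_id, patient, size).
#' @export
cloneTable <- function(object) object@clones

#' @export
setMethod("length", "ClonePartition", function(x) nrow(x@clones))

setMethod("show", "ClonePartition", function(object) {
  sz <- cloneSizes(object)
  cat(sprintf("ClonePartition: %d cells in %d clonotypes (%d patients)\n",
              length(object@assignment), length(sz),
              length(unique(object@clones$patient))))
  cat(sprintf("  expanded (size >= 2): %d clones covering %d cells\n",
              sum(sz >= 2), sum(sz[sz >= 2])))
  cat(sprintf("  singletons: %d; cells without usable chains: %d\n",
              sum(sz == 1), length(object@unassigned)))
})

#' Result of the clonal transcriptome-similarity test
#'
#' Pairwise Pearson correlations (TR genes excluded) for intra-clone and
#' size-matched random same-patient cell pairs, with the Welch two-sample
#' t-test comparing the two sets. Produced by [welchTest()] /
#' [cloneSimilarityTest()].
#'
#' @slot correlations_intra numeric, one correlation per intra-clone pair.
#' @slot correlations_random numeric, one per random-clone pair.
#' @slot statistic Welch t statistic.
#' @slot df Welch-Satterthwaite degrees of freedom.
#' @slot p_value two-sided p value.
#' @export
setClass("PairTestResult",
         representation(correlations_intra = "numeric",
                        correlations_random = "numeric",
                        statistic = "numeric",
                        df = "numeric",
                        p_value = "numeric"))

setValidity("PairTestResult", function(object) {
  msgs <- character()
  ok_r <- function(r) all(is.finite(r)) && all(r >= -1 - 1e-12) &&
    all(r <= 1 + 1e-12)
  if (length(object@correlations_intra) && !ok_r(object@correlations_intra))
    msgs <- c(msgs, "intra-clone correlations must lie in [-1, 1]")
  if (length(object@correlations_random) && !ok_r(object@correlations_random))
    msgs <- c(msgs, "random-clone correlations must lie in [-1, 1]")
  if (length(object@df) == 1L && is.finite(object@df) && object@df <= 0)
    msgs <- c(msgs, "degrees of freedom must be positive")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PairTestResult", function(object) {
  cat("Welch two-sample t-test: intra-clone vs random-clone correlations\n")
  cat(sprintf("  n pairs: %d intra, %d random\n",
              length(object@correlations_intra),
              length(object@correlations_random)))
  cat(sprintf("  mean r: intra %.4f, random %.4f\n",
              mean(object@correlations_intra),
              mean(object@correlations_random)))
  cat(sprintf("  t = %.3f, df = %.1f, p-value = %.3g\n",
              object@statistic, object@df, object@p_value))
})
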