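#' Build a signed signature from differential-expression results
#'
#' Up-regulated genes receive weight +1 and down-regulated genes -1,
#' mirroring how a bulk DEG list is turned into a per-cell scoring
#' signature. Accepts either a [runDE()] result (split by sign of log2fc
#' among selected genes) or explicit up/down gene lists.
#'
#' @param x a [runDE()] DataFrame, or a character vector of up genes.
#' @param down character vector of down genes (when `x` is a gene list).
#' @param name signature name.
#' @param fdr_max,min_abs_fc selection thresholds applied when `x` is a DE
#'   result (passed to [selectDegs()]).
#' @return A [SignedSignature-class].
#' @export
makeSignatureFromDegs <- function(x, down = character(), name = "deg_signature",
                                  fdr_max = 0.05, min_abs_fc = 1.5) {
  if (is(x, "DataFrame") || is.data.frame(x)) {
    sel <- selectDegs(x, fdr_max = fdr_max, min_abs_fc = min_abs_fc)
    sub <- x[match(sel, x$gene), , drop = FALSE]
    SignedSignature(name, up = sub$gene[sub$log2fc > 0],
                    down = sub$gene[sub$log2fc < 0])
  } else {
    SignedSignature(name, up = x, down = down)
  }
}

#' Project a signed signature onto single cells
#'
#' Each cell's score is the signature-size-normalized weighted sum of its
#' expression over the signature genes present in the matrix:
#' `score_c = (1/|G|) * sum_g w_g * x_gc` with `x` taken from the scaled
#' layer by default (per-gene standardized), so scores are comparable
#' across signatures of different sizes. Signature genes absent from the
#' matrix are dropped with a warning; zero overlap is an error.
#'
#' @param x SingleCellExperiment (with the chosen layer) or matrix.
#' @param signature a [SignedSignature-class], or a list of them.
#' @param layer expression layer to weight by ("scaled", the default, or
#'   "lognorm").
#' @return data.frame with columns cell_id, signature_name, score (one row
#'   per cell and signature).
#' @export
scoreCells <- function(x, signature, layer = "scaled") {
  if (is.list(signature)) {
    out <- lapply(signature, function(s) scoreCells(x, s, layer))
    return(do.call(rbind, out))
  }
  m <- get_layer(x, layer)
  w <- signatureWeights(signature)
  present <- names(w) %in% rownames(m)
  if (!any(present))
    stopf("no signature gene found in the matrix; missing: %s",
          paste(names(w), collapse = ", "))
  if (any(!present))
    warnf("signature '%s': %d gene(s) absent from the matrix and dropped",
          signature@name, sum(!present))
  w <- w[present]
  sc <- colSums(m[names(w), , drop = FALSE] * w) / length(w)
  data.frame(cell_id = colnames(m),
             signature_name = signature@name,
             score = unname(sc),
             stringsAsFactors = FALSE)
}

#' Compare signature scores between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test; exact enumeration when both groups
#' have at most 10 cells and the scores are tie-free, otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param scores numeric vector of per-cell scores.
#' @param group logical or two-level vector aligned with `scores`.
#' @return List with `statistic` (rank-sum W), `p_value`, `method`.
#' @export
compareScores <- function(scores, group) {
  g1 <- group_mask(group, length(scores))
  x <- scores[g1]; y <- scores[!g1]
  if (!length(x) || !length(y)) stopf("both groups must be non-empty")
  exact <- length(x) <= 10 && length(y) <= 10 &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}
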