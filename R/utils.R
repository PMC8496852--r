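#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats pchisq pt cor p.adjust rnbinom rlnorm rbeta runif rbinom
#'   t.test wilcox.test plogis sd quantile ks.test
#' @importFrom utils read.delim write.table head modifyList
NULL

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
# All stochastic operations in the package route their `seed` argument here so
# that no function perturbs global RNG state as a side effect.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# Extract a dense numeric matrix from an SCE assay or pass a matrix through.
get_layer <- function(x, layer = "counts") {
  if (is(x, "SummarizedExperiment")) {
    if (!layer %in% SummarizedExperiment::assayNames(x)) {
      stopf("layer '%s' not found; available: %s", layer,
            paste(SummarizedExperiment::assayNames(x), collapse = ", "))
    }
    m <- SummarizedExperiment::assay(x, layer)
  } else {
    m <- x
  }
  as.matrix(m)
}

# Per-cell metadata as a plain data.frame whether given an SCE or a table.
get_cell_table <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    df <- as.data.frame(SummarizedExperiment::colData(x))
    if (!"cell_id" %in% names(df)) df$cell_id <- colnames(x)
    df
  } else {
    as.data.frame(x)
  }
}
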