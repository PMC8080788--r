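#' Remove low-coverage cells
#'
#' Drops columns (cells/samples) whose total count is below `min_total`
#' mapped reads. The boundary itself is kept: a cell with exactly
#' `min_total` reads survives.
#'
#' @param counts Numeric genes x cells matrix of non-negative counts with
#'   dimnames.
#' @param min_total Minimum total count per cell (default 1000).
#' @return The matrix with failing columns removed; a message reports how
#'   many were dropped. Error if nothing survives.
#' @export
filter_cells <- function(counts, min_total = 1000) {
  stopifnot(is.matrix(counts), min(counts) >= 0)
  totals <- colSums(counts)
  keep <- totals >= min_total
  if (!any(keep)) stop("all cells fall below ", min_total, " total reads")
  if (any(!keep)) message(sum(!keep), " cell(s) below ", min_total,
                          " total reads removed")
  counts[, keep, drop = FALSE]
}

#' Depth-normalize and log counts
#'
#' Each cell's counts are divided by the cell total and multiplied by the
#' maximum total across cells, then a pseudocount of one is added and the
#' result logged base 2: `log2(v / total_c * max_total + 1)`.
#'
#' @param counts Genes x cells count matrix; every column total must be
#'   positive (run [filter_cells()] first).
#' @return Matrix of the same shape with attribute `layer_kind` set to
#'   `"log_expression"`.
#' @export
normalize_counts <- function(counts) {
  stopifnot(is.matrix(counts), min(counts) >= 0)
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("cell(s) with zero total count: ",
                             paste(colnames(counts)[totals <= 0], collapse = ", "))
  out <- log2(sweep(counts, 2L, totals, "/") * max(totals) + 1)
  attr(out, "layer_kind") <- "log_expression"
  out
}

#' Relative expression (delta-e) by median subtraction
#'
#' Fold changes are computed against a within-data-set surrogate for the
#' unobserved control: each gene's logged expression minus its median
#' across all samples/cells. Genes switched off in most samples thus sit
#' near zero rather than at an extreme.
#'
#' @param log_expr Genes x samples matrix of logged expression.
#' @param min_samples Minimum number of columns for the median to be
#'   meaningful (default 3); set lower to override.
#' @return Matrix of the same shape; per-gene medians of the result are
#'   zero. Attribute `layer_kind` is `"delta_e"`.
#' @export
fold_changes <- function(log_expr, min_samples = 3L) {
  stopifnot(is.matrix(log_expr))
  if (ncol(log_expr) < min_samples) {
    stop("need at least ", min_samples,
         " samples to form a per-gene median (got ", ncol(log_expr), ")")
  }
  med <- apply(log_expr, 1L, stats::median)
  out <- log_expr - med
  attr(out, "layer_kind") <- "delta_e"
  out
}

#' Rank genes of one sample by relative expression
#'
#' Orders genes ascending by delta-e so the most repressed gene comes
#' first. Two tie conventions are kept side by side: the full *ordering*
#' breaks ties by gene identifier (stable and platform-independent, which
#' matters for walk-based statistics on sparse data with massive zero
#' ties), while the *ranks* are midranks, as rank-based statistics
#' require.
#'
#' @param delta_e Named numeric vector of relative expression for one
#'   sample; names are gene identifiers.
#' @return List of class `ranked_genes`: `gene_ids` (ordering, most
#'   repressed first), `order` (integer permutation into the input), and
#'   `midranks` (aligned with the *input* vector).
#' @export
rank_genes <- function(delta_e) {
  stopifnot(is.numeric(delta_e), !is.null(names(delta_e)))
  o <- order(delta_e, names(delta_e), method = "radix")
  structure(list(gene_ids = names(delta_e)[o], order = o,
                 midranks = rank(delta_e, ties.method = "average")),
            class = "ranked_genes")
}

#' @export
print.ranked_genes <- function(x, ...) {
  n <- length(x$gene_ids)
  cat("Ranked gene list:", n, "genes; most repressed:",
      paste(utils::head(x$gene_ids, 3L), collapse = ", "), "...\n")
  invisible(x)
}
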