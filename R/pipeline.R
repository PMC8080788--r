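#' End-to-end miRNA activity pipeline
#'
#' Ties the stages together: UTR selection and length filtering, seed and
#' motif derivation, optional cell filtering and normalization, relative
#' expression by median subtraction, null motif probabilities, and
#' per-sample enrichment into a samples x miRNAs activity matrix.
#'
#' @param expression Genes x samples matrix. `layer = "counts"` runs the
#'   cell filter and depth normalization first; `layer = "logexpr"`
#'   treats values as already normalized logged expression (the typical
#'   bulk input).
#' @param utrs_raw Raw UTR records ([read_utr_fasta()]) or an already
#'   selected/filtered UTR set.
#' @param mirnas miRNA table ([read_mirna_fasta()] output or a motif
#'   table from [mirna_motifs()]).
#' @param layer `"counts"` or `"logexpr"`.
#' @param method Enrichment statistic, see [compute_activity()].
#' @param targets Target table for `method = "tarbase"`.
#' @param min_cell_reads Cell filter threshold (counts layer only).
#' @param utr_min,utr_max UTR length bounds.
#' @param prob_table Optional precomputed [probability_table()].
#' @param cache Cache policy for the probability table.
#' @param drop_zero_genes Drop genes with zero expression everywhere
#'   before ranking (default `FALSE`: they dilute but do not bias).
#' @return Samples x miRNAs activity score matrix.
#' @export
mir_activity <- function(expression, utrs_raw, mirnas,
                         layer = c("counts", "logexpr"),
                         method = "mrs", targets = NULL,
                         min_cell_reads = 1000, utr_min = 20L,
                         utr_max = 10000L, prob_table = NULL,
                         cache = "binned", drop_zero_genes = FALSE) {
  layer <- match.arg(layer)
  utrs <- if (all(c("length", "fA") %in% names(utrs_raw))) utrs_raw
          else select_longest_utr(utrs_raw)
  utrs <- filter_utr_length(utrs, utr_min, utr_max)
  if (!"target_motif" %in% names(mirnas)) mirnas <- mirna_motifs(mirnas)
  motif_map <- dedupe_motifs(mirnas)
  expr <- expression
  if (layer == "counts") {
    expr <- filter_cells(expr, min_total = min_cell_reads)
    expr <- normalize_counts(expr)
  }
  if (drop_zero_genes) {
    expr <- expr[rowSums(abs(expr)) > 0, , drop = FALSE]
  }
  delta <- fold_changes(expr)
  compute_activity(delta, utrs, motif_map, prob_table = prob_table,
                   method = method, targets = targets, cache = cache)
}
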