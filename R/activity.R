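#' Signed activity score from an enrichment p-value
#'
#' `score = -log10(p) * direction`, with the p-value floored at 1e-300 so
#' scores stay finite (|score| <= 300).
#'
#' @param p P-value in (0, 1\].
#' @param direction +1 (motif enriched among repressed genes) or -1.
#' @return Signed score.
#' @examples
#' score_from_pvalue(0.01, +1)
#' @export
score_from_pvalue <- function(p, direction) {
  stopifnot(is.numeric(p), length(p) == length(direction))
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (!all(direction %in% c(-1L, 1L))) stop("direction must be -1 or +1")
  -log10(pmax(p, 1e-300)) * direction
}

#' Per-sample miRNA activity matrix
#'
#' For every sample, genes are ranked by relative expression (most
#' repressed first) and every unique target motif is tested for
#' association with the ranking using the chosen statistic; motif scores
#' are broadcast to all miRNAs sharing the motif. The gene universe is
#' the intersection of the expression genes and the UTR genes — genes
#' without a usable 3'UTR are excluded from the ranking rather than
#' scored as motif-absent, because missing sequence is not evidence of a
#' missing site. In `"tarbase"` mode the universe is the full expression
#' gene set and `targets` supplies the per-miRNA gene sets.
#'
#' Motifs present in every gene or in none carry no contrast; they
#' receive a score of 0 (p = 1) with a single warning.
#'
#' @param delta_e Genes x samples matrix of relative expression from
#'   [fold_changes()].
#' @param utrs Filtered UTR set (ignored in `"tarbase"` mode).
#' @param motif_map Named list motif -> miRNA names from
#'   [dedupe_motifs()]; in `"tarbase"` mode a character vector of miRNA
#'   names may be given instead.
#' @param prob_table Optional precomputed [probability_table()]
#'   (genes x motifs); computed on the fly when `NULL`. Only used by
#'   `"mrs"` and `"bb"`.
#' @param method One of `"mrs"`, `"bb"`, `"hypergeom"`, `"tarbase"`.
#' @param targets For `"tarbase"`: `data.frame` with columns
#'   `mirna_name`, `gene_id`.
#' @param cache Cache policy passed to [probability_table()].
#' @return Samples x miRNAs numeric score matrix with attributes
#'   `method`, `n_genes` (universe size), and `n_motifs`.
#' @export
compute_activity <- function(delta_e, utrs, motif_map, prob_table = NULL,
                             method = c("mrs", "bb", "hypergeom", "tarbase"),
                             targets = NULL, cache = "binned") {
  method <- match.arg(method)
  stopifnot(is.matrix(delta_e), !is.null(rownames(delta_e)),
            !is.null(colnames(delta_e)))
  if (method == "tarbase") {
    return(activity_tarbase(delta_e, motif_map, targets))
  }
  stopifnot(is.list(motif_map), !is.null(names(motif_map)))
  genes <- intersect(rownames(delta_e), utrs$gene_id)
  if (length(genes) == 0L) stop("no genes shared between expression and UTRs")
  utrs <- utrs[match(genes, utrs$gene_id), , drop = FALSE]
  de <- delta_e[genes, , drop = FALSE]
  motifs <- names(motif_map)
  I <- motif_indicators(motifs, utrs)
  K <- colSums(I)
  usable <- K > 0L & K < length(genes)
  if (any(!usable)) {
    warning(sum(!usable), " motif(s) without contrast (present in all or ",
            "no UTRs) scored 0: ",
            paste(utils::head(motifs[!usable], 5L), collapse = ", "))
  }
  if (method %in% c("mrs", "bb")) {
    if (is.null(prob_table)) {
      prob_table <- probability_table(motifs, utrs, cache = cache)
    }
    P <- prob_table[genes, motifs, drop = FALSE]
  }
  n <- length(genes)
  scores <- matrix(0, nrow = ncol(de), ncol = length(motifs),
                   dimnames = list(colnames(de), motifs))
  if (method == "mrs") {
    D <- I - P
    V <- P * (1 - P)
    for (s in seq_len(ncol(de))) {
      cg <- (n + 1) / 2 - rank(de[, s], ties.method = "average")
      Tvec <- as.numeric(cg %*% D)
      Vvec <- as.numeric((cg^2) %*% V)
      z <- ifelse(Vvec > 0, Tvec / sqrt(Vvec), 0)
      p <- pmin(1, 2 * stats::pnorm(-abs(z)))
      scores[s, ] <- score_from_pvalue(p, ifelse(z >= 0, 1L, -1L))
      scores[s, !usable] <- 0
    }
  } else if (method == "bb") {
    for (s in seq_len(ncol(de))) {
      o <- rank_genes(de[, s])$order
      Io <- I[o, , drop = FALSE]
      Po <- P[o, , drop = FALSE]
      for (j in which(usable)) {
        res <- bb_test(Io[, j], Po[, j])
        scores[s, j] <- res$score
      }
    }
  } else if (method == "hypergeom") {
    for (s in seq_len(ncol(de))) {
      o <- rank_genes(de[, s])$order
      Io <- I[o, , drop = FALSE]
      for (j in which(usable)) {
        res <- hypergeom_landscape(Io[, j])
        scores[s, j] <- res$score
      }
    }
  }
  broadcast_to_mirnas(scores, motif_map, method,
                      n_genes = n, n_motifs = length(motifs))
}

activity_tarbase <- function(delta_e, mirnas, targets) {
  stopifnot(is.data.frame(targets),
            all(c("mirna_name", "gene_id") %in% names(targets)))
  if (is.list(mirnas)) mirnas <- unique(unlist(mirnas, use.names = FALSE))
  mirnas <- unique(as.character(mirnas))
  genes <- rownames(delta_e)
  n <- length(genes)
  scores <- matrix(0, nrow = ncol(delta_e), ncol = length(mirnas),
                   dimnames = list(colnames(delta_e), mirnas))
  sets <- split(targets$gene_id, targets$mirna_name)
  for (s in seq_len(ncol(delta_e))) {
    r <- rank(delta_e[, s], ties.method = "average")
    for (j in seq_along(mirnas)) {
      tg <- genes %in% sets[[mirnas[j]]]
      if (!any(tg)) {
        stop("no target genes of '", mirnas[j],
             "' found among the ranked genes")
      }
      if (all(tg)) stop("target set of '", mirnas[j], "' covers all genes")
      scores[s, j] <- targetset_ranksum(r, tg)$score
    }
  }
  attr(scores, "method") <- "tarbase"
  attr(scores, "n_genes") <- n
  attr(scores, "n_motifs") <- length(mirnas)
  scores
}

broadcast_to_mirnas <- function(motif_scores, motif_map, method,
                                n_genes, n_motifs) {
  mirna_names <- unlist(motif_map, use.names = FALSE)
  motif_of <- rep(names(motif_map), lengths(motif_map))
  out <- motif_scores[, motif_of, drop = FALSE]
  colnames(out) <- mirna_names
  attr(out, "method") <- method
  attr(out, "n_genes") <- n_genes
  attr(out, "n_motifs") <- n_motifs
  out
}

#' Correlation between activity and an expression vector
#'
#' Pearson (default) or Spearman correlation between a miRNA's activity
#' scores and a matched expression vector, with the two-sided test
#' p-value.
#'
#' @param activity,expression Equal-length numeric vectors; at least 3
#'   complete pairs.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `r` and `p`; both `NA` (with a warning) when either
#'   vector is constant.
#' @export
activity_expression_correlation <- function(activity, expression,
                                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(activity) == length(expression))
  ok <- is.finite(activity) & is.finite(expression)
  if (sum(ok) < 3L) stop("need at least 3 finite pairs")
  if (stats::sd(activity[ok]) == 0 || stats::sd(expression[ok]) == 0) {
    warning("constant vector: correlation undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(activity[ok], expression[ok], method = method))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Cell-type specificity of miRNA activity
#'
#' Flags (miRNA, cell type) pairs whose activity distribution is an
#' outlier relative to the whole data set:
#' `robust_z = (median(type) - median(all)) / (1.4826 * MAD(all))`.
#'
#' @param activity Samples x miRNAs score matrix.
#' @param cell_labels Character/factor vector of cell types, one per
#'   sample (row of `activity`).
#' @param min_cells Minimum cells per type (default 5); smaller types are
#'   dropped with a message.
#' @param z_threshold Absolute robust z at or above which a pair is
#'   flagged (default 3).
#' @return `data.frame` with `mirna`, `cell_type`, `robust_z`, `flagged`.
#'   miRNAs with zero global MAD are skipped with a warning.
#' @export
celltype_specificity <- function(activity, cell_labels, min_cells = 5L,
                                 z_threshold = 3) {
  stopifnot(is.matrix(activity), length(cell_labels) == nrow(activity))
  cell_labels <- as.character(cell_labels)
  sizes <- table(cell_labels)
  keep_types <- names(sizes)[sizes >= min_cells]
  if (length(keep_types) < 2L) {
    stop("need at least 2 cell types with >= ", min_cells, " cells")
  }
  if (length(keep_types) < length(sizes)) {
    message(length(sizes) - length(keep_types),
            " cell type(s) below ", min_cells, " cells dropped")
  }
  res <- list()
  skipped <- character(0)
  for (m in colnames(activity)) {
    x <- activity[, m]
    gmed <- stats::median(x)
    gmad <- stats::mad(x, constant = 1)  # raw MAD; 1.4826 applied below
    if (gmad == 0) { skipped <- c(skipped, m); next }
    for (ct in keep_types) {
      z <- (stats::median(x[cell_labels == ct]) - gmed) / (1.4826 * gmad)
      res[[length(res) + 1L]] <- data.frame(
        mirna = m, cell_type = ct, robust_z = z,
        flagged = abs(z) >= z_threshold, stringsAsFactors = FALSE)
    }
  }
  if (length(skipped) > 0L) {
    warning(length(skipped), " miRNA(s) with zero global MAD skipped: ",
            paste(utils::head(skipped, 5L), collapse = ", "))
  }
  if (length(res) == 0L) {
    return(data.frame(mirna = character(0), cell_type = character(0),
                      robust_z = numeric(0), flagged = logical(0)))
  }
  do.call(rbind, res)
}
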