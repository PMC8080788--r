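#' Read a genes x samples expression matrix from TSV
#'
#' Expects a header row and gene identifiers in the first column;
#' gzip-transparent via [data.table::fread()].
#'
#' @param path TSV path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  if (ncol(dt) < 2L) stop("expression TSV needs a gene column plus samples")
  genes <- as.character(dt[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene ids in expression TSV")
  m <- as.matrix(dt[, -1L])
  if (!is.numeric(m)) stop("non-numeric expression values in '", path, "'")
  rownames(m) <- genes
  m
}

#' Write a genes x samples matrix as TSV
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param gene_col Name of the first (gene id) column.
#' @export
write_expression_tsv <- function(m, path, gene_col = "gene_id") {
  dt <- data.table::data.table(gene = rownames(m))
  data.table::setnames(dt, "gene", gene_col)
  data.table::fwrite(cbind(dt, data.table::as.data.table(m)), path,
                     sep = "\t")
  invisible(path)
}

#' Read an expression matrix in MTX triplet form
#'
#' Reads a MatrixMarket sparse matrix plus one-column gene and barcode
#' files (the common single-cell triplet layout) and returns a dense
#' matrix.
#'
#' @param mtx_path MatrixMarket file.
#' @param genes_path,barcodes_path One identifier per line; row or first
#'   column used.
#' @return Numeric genes x cells matrix.
#' @export
read_expression_mtx <- function(mtx_path, genes_path, barcodes_path) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  genes <- utils::read.table(genes_path, sep = "\t",
                             stringsAsFactors = FALSE)[[1L]]
  cells <- utils::read.table(barcodes_path, sep = "\t",
                             stringsAsFactors = FALSE)[[1L]]
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    stop("MTX dimensions (", nrow(m), " x ", ncol(m),
         ") do not match gene/barcode files")
  }
  dimnames(m) <- list(genes, cells)
  m
}

#' Read a TarBase-style target table
#'
#' Two-column TSV (miRNA name, gene id), with or without a header.
#'
#' @param path TSV path.
#' @return `data.frame` with columns `mirna_name`, `gene_id`.
#' @export
read_targets_tsv <- function(path) {
  dt <- data.table::fread(path, header = "auto")
  if (ncol(dt) < 2L) stop("target table needs two columns (miRNA, gene)")
  out <- data.frame(mirna_name = as.character(dt[[1L]]),
                    gene_id = as.character(dt[[2L]]),
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Read a cell-label table
#'
#' Two-column TSV (cell id, label) with a header.
#'
#' @param path TSV path.
#' @param cells Optional cell ids to order/validate against.
#' @return Named character vector label per cell.
#' @export
read_labels_tsv <- function(path, cells = NULL) {
  dt <- data.table::fread(path, header = TRUE)
  lab <- stats::setNames(as.character(dt[[2L]]), as.character(dt[[1L]]))
  if (!is.null(cells)) {
    if (!all(cells %in% names(lab))) stop("labels missing for some cells")
    lab <- lab[cells]
  }
  lab
}

#' Write an activity matrix as TSV with a metadata header
#'
#' Metadata (method, gene/motif counts, any extra fields) is written as
#' `#key: value` comment lines above the table.
#'
#' @param activity Samples x miRNAs score matrix.
#' @param path Output path.
#' @param extra Named list of additional metadata fields.
#' @export
write_activity_tsv <- function(activity, path, extra = list()) {
  meta <- c(list(method = attr(activity, "method"),
                 n_genes = attr(activity, "n_genes"),
                 n_motifs = attr(activity, "n_motifs")), extra)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) writeLines(paste0("#", k, ": ", meta[[k]]), con)
  utils::write.table(
    data.frame(sample_id = rownames(activity), activity,
               check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an activity matrix written by [write_activity_tsv()]
#'
#' @param path TSV path.
#' @return Samples x miRNAs matrix; metadata lines are restored as
#'   attributes where recognized.
#' @export
read_activity_tsv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  dt <- data.table::fread(text = lines[setdiff(seq_along(lines), meta_lines)],
                          header = TRUE)
  m <- as.matrix(dt[, -1L])
  rownames(m) <- as.character(dt[[1L]])
  for (ml in lines[meta_lines]) {
    kv <- sub("^#", "", ml)
    k <- sub(":.*$", "", kv)
    v <- trimws(sub("^[^:]*:", "", kv))
    if (k %in% c("n_genes", "n_motifs")) v <- as.integer(v)
    attr(m, k) <- v
  }
  m
}
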