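#' Read 3'UTR sequences from a FASTA file
#'
#' Loads raw (gene, transcript, sequence) records from a FASTA file of 3'UTR
#' sequences. Headers are split on a separator character; the first field is
#' the gene identifier and the second, when present, the transcript
#' identifier. Sequences are uppercased and U is converted to T so that
#' downstream motif matching works on a single DNA alphabet. Records
#' containing characters outside A/C/G/T/N are kept but flagged.
#'
#' @param path Path to a FASTA file (plain or gzip-compressed).
#' @param header_sep Single character separating header fields
#'   (default `"|"`, i.e. headers like `">GENE1|TX1"`).
#' @return A `data.frame` with columns `gene_id`, `transcript_id` (`NA` when
#'   the header has a single field), `sequence`, and logical `flagged` for
#'   sequences with non-A/C/G/T/N characters.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1|t1", "acgu", ">g1|t2", "ACGTACGT"), fa)
#' read_utr_fasta(fa)
#' @export
read_utr_fasta <- function(path, header_sep = "|") {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no sequences")
  headers <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  fields <- strsplit(headers, header_sep, fixed = TRUE)
  gene_id <- vapply(fields, `[[`, character(1), 1L)
  transcript_id <- vapply(fields, function(f)
    if (length(f) >= 2L) f[[2L]] else NA_character_, character(1))
  seqs <- chartr("U", "T", toupper(as.character(set)))
  key <- paste(gene_id, transcript_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (gene, transcript) pair: ",
         gsub("\r", "|", dup, fixed = TRUE))
  }
  flagged <- grepl("[^ACGTN]", seqs)
  data.frame(gene_id = gene_id, transcript_id = transcript_id,
             sequence = unname(seqs), flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Select the longest 3'UTR per gene
#'
#' When a gene has several transcripts with different 3'UTR lengths the
#' longest form is used. Length ties are broken by the lexicographically
#' smallest transcript identifier so that selection is deterministic.
#'
#' @param raw A `data.frame` as returned by [read_utr_fasta()] (columns
#'   `gene_id`, `transcript_id`, `sequence`; extra columns ignored).
#' @return A UTR set: a `data.frame` with one row per gene and columns
#'   `gene_id`, `sequence`, `length`, and base frequencies `fA`, `fC`,
#'   `fG`, `fT` computed over non-N positions. Rows are ordered by
#'   `gene_id` so the result is a set keyed by gene.
#' @export
select_longest_utr <- function(raw) {
  stopifnot(is.data.frame(raw), all(c("gene_id", "sequence") %in% names(raw)))
  tx <- if ("transcript_id" %in% names(raw)) as.character(raw$transcript_id)
        else rep(NA_character_, nrow(raw))
  tx[is.na(tx)] <- ""
  len <- nchar(raw$sequence)
  # longest first, then smallest transcript id; stable within gene
  o <- order(raw$gene_id, -len, tx, method = "radix")
  keep <- o[!duplicated(raw$gene_id[o])]
  keep <- keep[order(raw$gene_id[keep], method = "radix")]
  seqs <- raw$sequence[keep]
  comp <- t(vapply(seqs, base_composition, numeric(4), USE.NAMES = FALSE))
  out <- data.frame(gene_id = raw$gene_id[keep], sequence = seqs,
                    length = nchar(seqs),
                    fA = comp[, 1L], fC = comp[, 2L],
                    fG = comp[, 3L], fT = comp[, 4L],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter a UTR set by length
#'
#' Removes UTRs shorter than `min_len` or longer than `max_len` bases;
#' the bounds themselves are kept. Defaults retain lengths in
#' \[20, 10000\].
#'
#' @param utrs UTR set from [select_longest_utr()].
#' @param min_len,max_len Inclusive length bounds in nucleotides.
#' @return The filtered UTR set; a message reports how many were removed.
#' @export
filter_utr_length <- function(utrs, min_len = 20L, max_len = 10000L) {
  stopifnot(is.data.frame(utrs), "length" %in% names(utrs))
  keep <- utrs$length >= min_len & utrs$length <= max_len
  if (any(!keep)) {
    message(sum(!keep), " UTR(s) removed by length filter [",
            min_len, ", ", max_len, "]")
  }
  out <- utrs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Base composition of a DNA sequence
#'
#' Frequencies of A, C, G, T among non-N positions. N bases are excluded
#' from both numerator and denominator: they never match a motif position,
#' and the null sequence model should not be distorted by them.
#'
#' @param sequence A single uppercase DNA string.
#' @return Named numeric vector `c(A=, C=, G=, T=)` summing to 1.
#' @examples
#' base_composition("AACG")
#' @export
base_composition <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("empty sequence has no base composition")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  counts <- table(factor(chars, levels = c("A", "C", "G", "T")))
  n <- sum(counts)
  if (n == 0L) stop("sequence has no unambiguous A/C/G/T bases")
  stats::setNames(as.numeric(counts) / n, c("A", "C", "G", "T"))
}
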