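#' Read mature miRNA sequences from a FASTA file
#'
#' Accepts miRBase-style mature sequence FASTA in either RNA or DNA
#' alphabet; sequences are stored uppercase as RNA (T converted to U).
#' Names are the first whitespace-delimited token of the header, kept
#' verbatim. Matures shorter than 8 nt have no defined seed and are
#' skipped with a warning. The same name appearing twice with identical
#' sequence is collapsed; with different sequences it is an error.
#'
#' @param path Path to the FASTA file (plain or gzip-compressed).
#' @return A `data.frame` with columns `mirna_name` and `mature_seq`.
#' @export
read_mirna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no sequences")
  nm <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  seqs <- chartr("T", "U", toupper(as.character(set)))
  short <- nchar(seqs) < 8L
  if (any(short)) {
    warning(sum(short), " mature sequence(s) shorter than 8 nt skipped: ",
            paste(nm[short], collapse = ", "))
    nm <- nm[!short]; seqs <- seqs[!short]
  }
  df <- unique(data.frame(mirna_name = nm, mature_seq = unname(seqs),
                          stringsAsFactors = FALSE))
  if (anyDuplicated(df$mirna_name)) {
    bad <- df$mirna_name[duplicated(df$mirna_name)][1L]
    stop("miRNA name '", bad, "' appears with different mature sequences")
  }
  if (nrow(df) == 0L) stop("no usable mature sequences in '", path, "'")
  rownames(df) <- NULL
  df
}

#' Extract the seed from a mature miRNA sequence
#'
#' The seed is the 7-mer at mature positions 2-8 (1-based, from the
#' 5' end), the primary determinant of target recognition.
#'
#' @param mature_seq Mature miRNA sequence (RNA alphabet), length >= 8.
#' @return The 7-nt seed string.
#' @examples
#' extract_seed("UAGCUAGCUAGC")
#' @export
extract_seed <- function(mature_seq) {
  stopifnot(is.character(mature_seq), length(mature_seq) == 1L)
  if (nchar(mature_seq) < 8L) {
    stop("mature sequence shorter than 8 nt; seed (positions 2-8) undefined")
  }
  substr(mature_seq, 2L, 8L)
}

#' Target motif for a miRNA seed
#'
#' The DNA 7-mer a target 3'UTR must contain, read 5' to 3': the reverse
#' complement of the seed with U transliterated to T. Seed pairing is
#' antiparallel, so "complementary" means reverse complement on the
#' message strand.
#'
#' @param seed 7-mer seed over the RNA alphabet A/C/G/U (N allowed and
#'   mapped to N).
#' @return 7-mer DNA motif string.
#' @examples
#' seed_to_target_motif("AGCUAGC")
#' @export
seed_to_target_motif <- function(seed) {
  stopifnot(is.character(seed), length(seed) == 1L)
  if (grepl("[^ACGUN]", seed)) {
    stop("seed '", seed, "' contains characters outside the RNA alphabet")
  }
  comp <- chartr("ACGUN", "TGCAN", seed)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Build the miRNA motif table
#'
#' Derives, for every mature sequence, its seed (positions 2-8) and the
#' DNA target motif (reverse complement of the seed).
#'
#' @param mirnas `data.frame` with columns `mirna_name`, `mature_seq`
#'   (as from [read_mirna_fasta()]).
#' @return The input with `seed` and `target_motif` columns appended.
#' @export
mirna_motifs <- function(mirnas) {
  stopifnot(is.data.frame(mirnas),
            all(c("mirna_name", "mature_seq") %in% names(mirnas)))
  mirnas$seed <- vapply(mirnas$mature_seq, extract_seed, character(1),
                        USE.NAMES = FALSE)
  mirnas$target_motif <- vapply(mirnas$seed, seed_to_target_motif,
                                character(1), USE.NAMES = FALSE)
  mirnas
}

#' Group miRNAs sharing a target motif
#'
#' miRNA family members share seeds, so several matures can map to one
#' motif. Enrichment is computed once per unique motif and the score
#' broadcast to every member, which changes nothing in the results but
#' avoids redundant computation.
#'
#' @param motif_table Output of [mirna_motifs()].
#' @return Named list: `target_motif` -> character vector of
#'   `mirna_name`s sharing it.
#' @export
dedupe_motifs <- function(motif_table) {
  stopifnot(is.data.frame(motif_table))
  if (nrow(motif_table) == 0L) return(stats::setNames(list(), character(0)))
  split(motif_table$mirna_name, motif_table$target_motif)
}
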