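BASES <- c("A", "C", "G", "T")

#' Build the string-matching automaton for a 7-mer motif
#'
#' States 0..7 track the length of the longest motif prefix matching the
#' current sequence suffix (KMP failure-function construction); state 7
#' means the motif has occurred and is absorbing. The transition table is
#' built by direct definition: `next(k, b)` is the length of the longest
#' motif prefix that is a suffix of `prefix_k + b`.
#'
#' @param motif 7-mer DNA string over A/C/G/T.
#' @return Object of class `motif_automaton`: list with `motif` and an
#'   8 x 4 integer `transitions` matrix (rows states 0..7, columns
#'   A, C, G, T; entries are destination states 0..7).
#' @export
build_motif_automaton <- function(motif) {
  stopifnot(is.character(motif), length(motif) == 1L)
  if (nchar(motif) != 7L || grepl("[^ACGT]", motif)) {
    stop("motif must be a 7-mer over A/C/G/T, got '", motif, "'")
  }
  m <- nchar(motif)
  trans <- matrix(0L, nrow = m + 1L, ncol = 4L,
                  dimnames = list(0L:m, BASES))
  for (k in 0L:(m - 1L)) {
    for (b in seq_along(BASES)) {
      s <- paste0(substr(motif, 1L, k), BASES[b])
      ns <- nchar(s)
      for (len in min(m, ns):0L) {
        if (len == 0L ||
            substr(motif, 1L, len) == substr(s, ns - len + 1L, ns)) {
          trans[k + 1L, b] <- len
          break
        }
      }
    }
  }
  trans[m + 1L, ] <- m  # occurrence state is absorbing
  structure(list(motif = motif, transitions = trans),
            class = "motif_automaton")
}

#' Probability that a random sequence contains a motif
#'
#' Exact probability that an i.i.d. random sequence of the given length
#' and base composition contains at least one occurrence of the
#' automaton's motif. The automaton is embedded as a Markov chain: an
#' 8 x 8 one-step matrix is formed by weighting transitions with the base
#' frequencies and raised to the sequence length by repeated squaring;
#' the mass in the absorbing state is the occurrence probability.
#'
#' @param automaton A [build_motif_automaton()] result.
#' @param length Sequence length in nucleotides (non-negative integer).
#' @param base_freqs Numeric vector of four A/C/G/T frequencies summing
#'   to 1.
#' @return Probability in \[0, 1\]; 0 whenever `length` < motif length.
#' @examples
#' a <- build_motif_automaton("AAAAAAA")
#' occurrence_probability(a, 7, rep(0.25, 4))  # 4^-7
#' @export
occurrence_probability <- function(automaton, length, base_freqs) {
  stopifnot(inherits(automaton, "motif_automaton"))
  if (length < 0) stop("negative sequence length")
  base_freqs <- as.numeric(base_freqs)
  if (length(base_freqs) != 4L || any(base_freqs < 0) ||
      abs(sum(base_freqs) - 1) > 1e-8) {
    stop("base_freqs must be four non-negative frequencies summing to 1")
  }
  m <- nchar(automaton$motif)
  if (length < m) return(0)
  M <- transition_matrix(automaton, base_freqs)
  v <- c(1, rep(0, m))
  p <- (v %*% mat_power(M, as.integer(length)))[1L, m + 1L]
  min(max(p, 0), 1)
}

# one-step state-transition probability matrix under i.i.d. base draws
transition_matrix <- function(automaton, base_freqs) {
  tr <- automaton$transitions
  n <- nrow(tr)
  M <- matrix(0, n, n)
  for (b in 1:4) {
    idx <- cbind(seq_len(n), tr[, b] + 1L)
    M[idx] <- M[idx] + base_freqs[b]
  }
  M
}

# matrix power by repeated squaring
mat_power <- function(M, k) {
  R <- diag(nrow(M))
  while (k > 0L) {
    if (k %% 2L == 1L) R <- R %*% M
    M <- M %*% M
    k <- k %/% 2L
  }
  R
}

#' Motif occurrence probabilities for a set of UTRs
#'
#' Computes, for every (motif, gene) pair, the probability that a random
#' sequence matching the gene's 3'UTR in length and base composition
#' contains the motif at least once. These are the per-gene null
#' probabilities consumed by the modified rank-sum and Brownian-bridge
#' statistics.
#'
#' With `cache = "binned"` (default) the base composition is rounded to
#' two decimals per base before keying the computation, so UTRs with
#' near-identical composition and equal length share one evaluation;
#' `cache = "exact"` evaluates each UTR at its exact composition.
#'
#' @param motifs Character vector of 7-mer DNA motifs (deduplicated).
#' @param utrs UTR set from [select_longest_utr()]/[filter_utr_length()].
#' @param cache `"binned"` or `"exact"`.
#' @return Numeric genes x motifs matrix of probabilities, with gene ids
#'   as rownames and motifs as colnames.
#' @export
probability_table <- function(motifs, utrs, cache = c("binned", "exact")) {
  cache <- match.arg(cache)
  stopifnot(is.data.frame(utrs),
            all(c("gene_id", "length", "fA", "fC", "fG", "fT") %in% names(utrs)))
  motifs <- unique(as.character(motifs))
  P <- matrix(0, nrow = nrow(utrs), ncol = length(motifs),
              dimnames = list(utrs$gene_id, motifs))
  if (length(motifs) == 0L || nrow(utrs) == 0L) return(P)
  freqs <- as.matrix(utrs[, c("fA", "fC", "fG", "fT")])
  keyfreqs <- if (cache == "binned") round(freqs, 2L) else freqs
  # renormalize binned frequencies so each key is a proper distribution
  keyfreqs <- keyfreqs / rowSums(keyfreqs)
  key <- paste(utrs$length, keyfreqs[, 1L], keyfreqs[, 2L],
               keyfreqs[, 3L], keyfreqs[, 4L], sep = ",")
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  for (j in seq_along(motifs)) {
    aut <- build_motif_automaton(motifs[j])
    pu <- vapply(which(uk), function(i)
      occurrence_probability(aut, utrs$length[i], keyfreqs[i, ]),
      numeric(1))
    P[, j] <- pu[idx]
  }
  P
}

#' Motif presence indicators for a set of UTRs
#'
#' Marks, for every (gene, motif) pair, whether the gene's 3'UTR contains
#' the motif as an exact substring. N positions never match.
#'
#' @param motifs Character vector of DNA motifs.
#' @param utrs UTR set with `gene_id` and `sequence` columns.
#' @return Integer 0/1 genes x motifs matrix.
#' @export
motif_indicators <- function(motifs, utrs) {
  stopifnot(is.data.frame(utrs),
            all(c("gene_id", "sequence") %in% names(utrs)))
  motifs <- unique(as.character(motifs))
  I <- matrix(0L, nrow = nrow(utrs), ncol = length(motifs),
              dimnames = list(utrs$gene_id, motifs))
  for (j in seq_along(motifs)) {
    I[, j] <- as.integer(grepl(motifs[j], utrs$sequence, fixed = TRUE))
  }
  I
}
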