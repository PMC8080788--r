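# shared helpers: write tiny FASTA files and build small fixtures in code

write_fasta <- function(headers, seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(paste0(">", headers, "\n", seqs), path)
  path
}

# brute-force automaton transition: longest motif prefix that is a
# suffix of prefix_k + base (independent of the KMP construction)
brute_next_state <- function(motif, k, base) {
  s <- paste0(substr(motif, 1L, k), base)
  ns <- nchar(s)
  for (len in min(nchar(motif), ns):0L) {
    if (len == 0L) return(0L)
    if (substr(motif, 1L, len) == substr(s, ns - len + 1L, ns)) return(len)
  }
}

# Monte-Carlo presence probability for a motif in iid sequences
mc_presence <- function(motif, len, freqs, n_draws, seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  m <- matrix(sample(bases, n_draws * len, replace = TRUE, prob = freqs),
              nrow = n_draws)
  seqs <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  mean(grepl(motif, seqs, fixed = TRUE))
}

# small standard fixture reused across tests
small_fixture <- function(seed = 7L) {
  generate_fixture(n_genes = 300L, n_cells = 24L, n_mirnas = 6L,
                   n_targets = 50L, n_active = 12L, delta = 1.5,
                   library_size = 5e4, seed = seed)
}
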