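#' Generate random 3'UTR sequences
#'
#' I.i.d. sequences at a specified GC content with lengths drawn
#' uniformly from a range; the building block of the synthetic test bed.
#'
#' @param n_genes Number of genes.
#' @param length_range Two integers inside \[20, 10000\].
#' @param gc_content Target GC fraction (A and T share `1 - gc` equally;
#'   G and C share `gc`).
#' @param seed Integer seed.
#' @return UTR set `data.frame` (as from [select_longest_utr()]) with
#'   gene ids `g0001`, `g0002`, ...
#' @export
generate_utrs <- function(n_genes, length_range = c(200L, 2000L),
                          gc_content = 0.5, seed = 1L) {
  stopifnot(n_genes >= 1, length(length_range) == 2L,
            length_range[1L] >= 20L, length_range[2L] <= 10000L,
            length_range[1L] <= length_range[2L],
            gc_content >= 0, gc_content <= 1)
  set.seed(seed)
  lens <- sample(length_range[1L]:length_range[2L], n_genes, replace = TRUE)
  probs <- c((1 - gc_content) / 2, gc_content / 2,
             gc_content / 2, (1 - gc_content) / 2)
  seqs <- vapply(lens, function(L)
    paste(sample(BASES, L, replace = TRUE, prob = probs), collapse = ""),
    character(1))
  raw <- data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)),
                    transcript_id = NA_character_, sequence = seqs,
                    stringsAsFactors = FALSE)
  select_longest_utr(raw)
}

#' Generate random mature miRNA sequences
#'
#' Random 22-nt RNA matures named `syn-miR-<i>-5p`, with distinct seeds
#' (and hence distinct target motifs) guaranteed by rejection.
#'
#' @param n Number of miRNAs.
#' @param seed Integer seed.
#' @return `data.frame` with `mirna_name`, `mature_seq`.
#' @export
generate_mirnas <- function(n, seed = 1L) {
  set.seed(seed)
  rna <- c("A", "C", "G", "U")
  seqs <- character(0)
  seeds_seen <- character(0)
  while (length(seqs) < n) {
    s <- paste(sample(rna, 22L, replace = TRUE), collapse = "")
    sd7 <- substr(s, 2L, 8L)
    if (!(sd7 %in% seeds_seen)) {
      seqs <- c(seqs, s)
      seeds_seen <- c(seeds_seen, sd7)
    }
  }
  data.frame(mirna_name = sprintf("syn-miR-%d-5p", seq_len(n)),
             mature_seq = seqs, stringsAsFactors = FALSE)
}

#' Plant a motif into target UTRs
#'
#' Inserts the motif (overwriting, so lengths are preserved) at random
#' positions in each target gene's UTR. Non-target UTRs that contain the
#' motif by chance are re-drawn at the same length and composition
#' parameters until motif-free, so the indicator contrast is clean by
#' construction.
#'
#' @param utrs UTR set.
#' @param motif 7-mer DNA motif.
#' @param target_genes Gene ids to receive the motif.
#' @param copies Insertions per target (non-overlapping positions).
#' @param seed Integer seed.
#' @param max_retries Redraw attempts per non-target before giving up.
#' @return List: `utrs` (modified set, compositions recomputed) and
#'   `truth` (`data.frame` of gene, planted logical).
#' @export
plant_motif <- function(utrs, motif, target_genes, copies = 1L, seed = 1L,
                        max_retries = 50L) {
  stopifnot(all(target_genes %in% utrs$gene_id), nchar(motif) == 7L)
  set.seed(seed)
  m <- nchar(motif)
  is_target <- utrs$gene_id %in% target_genes
  for (i in which(is_target)) {
    L <- utrs$length[i]
    if (L < copies * m) stop("UTR of ", utrs$gene_id[i],
                             " too short for ", copies, " insertion(s)")
    # choose non-overlapping start positions
    repeat {
      starts <- sort(sample.int(L - m + 1L, copies))
      if (copies == 1L || all(diff(starts) >= m)) break
    }
    s <- utrs$sequence[i]
    for (st in starts) substr(s, st, st + m - 1L) <- motif
    utrs$sequence[i] <- s
  }
  # rejection: keep non-targets motif-free
  for (i in which(!is_target)) {
    tries <- 0L
    while (grepl(motif, utrs$sequence[i], fixed = TRUE)) {
      tries <- tries + 1L
      if (tries > max_retries) {
        stop("could not draw a motif-free sequence for ", utrs$gene_id[i],
             " after ", max_retries, " attempts")
      }
      comp <- base_composition(utrs$sequence[i])
      utrs$sequence[i] <- paste(
        sample(BASES, utrs$length[i], replace = TRUE, prob = comp),
        collapse = "")
    }
  }
  comp <- t(vapply(utrs$sequence, base_composition, numeric(4),
                   USE.NAMES = FALSE))
  utrs$fA <- comp[, 1L]; utrs$fC <- comp[, 2L]
  utrs$fG <- comp[, 3L]; utrs$fT <- comp[, 4L]
  list(utrs = utrs,
       truth = data.frame(gene_id = utrs$gene_id, planted = is_target,
                          stringsAsFactors = FALSE))
}

#' Simulate a single-cell count matrix with planted miRNA repression
#'
#' Per-gene baseline log2 means are drawn from a normal distribution; in
#' cells where the planted miRNA is active, the means of its target genes
#' are reduced by `delta` log2 units (repression acts on the mean in log
#' space, the signal the relative-expression ranking detects). Counts are
#' drawn gamma-Poisson (negative binomial) at the stated dispersion and
#' then scaled to the exact library size by a multinomial draw.
#'
#' @param gene_ids Gene identifiers (rows).
#' @param n_cells Number of cells.
#' @param target_genes Genes repressed in active cells.
#' @param active_cells Integer or logical index of active cells.
#' @param delta Repression effect size in log2 units.
#' @param baseline_mean,baseline_sd Normal distribution of per-gene
#'   baseline log2 mean expression.
#' @param library_size Exact total count per cell.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param seed Integer seed.
#' @return List: `counts` (genes x cells integer matrix, columns
#'   `c0001`...), `truth` (list of all parameters plus `active_cells`
#'   logical vector).
#' @export
simulate_counts <- function(gene_ids, n_cells, target_genes, active_cells,
                            delta = 1.0, baseline_mean = 4, baseline_sd = 2,
                            library_size = 1e5, dispersion = 0.3,
                            seed = 1L) {
  stopifnot(n_cells >= 1, delta >= 0, dispersion > 0, library_size >= 1)
  set.seed(seed)
  n_genes <- length(gene_ids)
  active <- logical(n_cells)
  active[active_cells] <- TRUE
  is_target <- gene_ids %in% target_genes
  mu0 <- 2^stats::rnorm(n_genes, baseline_mean, baseline_sd)
  counts <- matrix(0L, n_genes, n_cells,
                   dimnames = list(gene_ids,
                                   sprintf("c%04d", seq_len(n_cells))))
  size <- 1 / dispersion
  for (c in seq_len(n_cells)) {
    mu <- mu0
    if (active[c]) mu[is_target] <- mu[is_target] * 2^(-delta)
    x <- stats::rnbinom(n_genes, size = size, mu = mu)
    if (sum(x) == 0) x <- rep(1, n_genes)  # degenerate draw guard
    counts[, c] <- drop(stats::rmultinom(1L, size = as.integer(library_size),
                                         prob = x))
  }
  truth <- list(active_cells = active, target_genes = target_genes,
                delta = delta, baseline_mean = baseline_mean,
                baseline_sd = baseline_sd, library_size = library_size,
                dispersion = dispersion, seed = seed)
  list(counts = counts, truth = truth)
}

#' Generate a complete synthetic fixture with planted miRNA activity
#'
#' Assembles random UTRs, a panel of random miRNAs, and a count matrix in
#' which the first miRNA ("the planted miRNA") represses its target genes
#' in a subset of active cells. The planted miRNA's target motif is
#' inserted into the target UTRs and excluded from all others; a decoy
#' "-3p" mature — the reverse complement of the planted mature, i.e. the
#' opposite strand of the same duplex — is appended to probe strand
#' specificity.
#'
#' Defaults are the study conditions used throughout the package's
#' validation: 2000 genes, 200 cells of which 100 active, 200 target
#' genes, library size 100000, effect size 1 log2 unit, NB dispersion
#' 0.3.
#'
#' @param n_genes,n_cells,n_mirnas,n_targets,n_active,delta,library_size,dispersion
#'   Generator parameters, see [simulate_counts()].
#' @param gc_content,length_range UTR parameters, see [generate_utrs()].
#' @param seed Integer seed; fully determines the fixture.
#' @return List with `utrs`, `mirnas` (motif table incl. decoy), `counts`,
#'   `labels` (`active`/`inactive` per cell), and `truth` (planted and
#'   decoy names, target genes, active cells, all parameters).
#' @export
generate_fixture <- function(n_genes = 2000L, n_cells = 200L,
                             n_mirnas = 25L, n_targets = 200L,
                             n_active = 100L, delta = 1.0,
                             library_size = 1e5, dispersion = 0.3,
                             gc_content = 0.5,
                             length_range = c(200L, 2000L), seed = 1L) {
  stopifnot(n_targets <= n_genes, n_active <= n_cells, n_mirnas >= 2L)
  utrs <- generate_utrs(n_genes, length_range, gc_content, seed = seed)
  mirnas <- generate_mirnas(n_mirnas, seed = seed + 1L)
  planted <- mirnas$mirna_name[1L]
  # decoy: opposite strand of the planted duplex (reverse complement)
  decoy_seq <- chartr("ACGU", "UGCA", mirnas$mature_seq[1L])
  decoy_seq <- paste(rev(strsplit(decoy_seq, "", fixed = TRUE)[[1L]]),
                     collapse = "")
  decoy <- sub("-5p$", "-3p", planted)
  mirnas <- rbind(mirnas,
                  data.frame(mirna_name = decoy, mature_seq = decoy_seq,
                             stringsAsFactors = FALSE))
  mirnas <- mirna_motifs(mirnas)
  if (anyDuplicated(mirnas$target_motif)) {
    stop("motif collision in generated miRNA panel; change the seed")
  }
  set.seed(seed + 2L)
  target_genes <- sample(utrs$gene_id, n_targets)
  planted_res <- plant_motif(utrs, mirnas$target_motif[1L], target_genes,
                             seed = seed + 3L)
  utrs <- planted_res$utrs
  active_cells <- seq_len(n_active)
  sim <- simulate_counts(utrs$gene_id, n_cells, target_genes, active_cells,
                         delta = delta, library_size = library_size,
                         dispersion = dispersion, seed = seed + 4L)
  labels <- ifelse(sim$truth$active_cells, "active", "inactive")
  truth <- c(sim$truth,
             list(planted_mirna = planted, decoy_mirna = decoy,
                  planted_motif = mirnas$target_motif[1L],
                  decoy_motif = mirnas$target_motif[nrow(mirnas)],
                  n_genes = n_genes, n_mirnas = n_mirnas,
                  gc_content = gc_content, length_range = length_range,
                  fixture_seed = seed))
  list(utrs = utrs, mirnas = mirnas, counts = sim$counts,
       labels = labels, truth = truth)
}

#' Write a fixture to a directory
#'
#' Emits `utrs.fa`, `mirnas.fa`, `counts.tsv`, `labels.tsv`, and
#' `truth.json` so a fixture can round-trip through the package's file
#' readers.
#'
#' @param fixture Output of [generate_fixture()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLines(paste0(">", fixture$utrs$gene_id, "|t1\n", fixture$utrs$sequence),
             file.path(dir, "utrs.fa"))
  writeLines(paste0(">", fixture$mirnas$mirna_name, "\n",
                    fixture$mirnas$mature_seq),
             file.path(dir, "mirnas.fa"))
  write_expression_tsv(fixture$counts, file.path(dir, "counts.tsv"))
  utils::write.table(
    data.frame(cell_id = colnames(fixture$counts), label = fixture$labels),
    file.path(dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fixture$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
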