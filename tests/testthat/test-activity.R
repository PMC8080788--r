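test_that("score transform is -log10(p) times direction with a p floor", {
  expect_equal(score_from_pvalue(0.01, 1L), 2)
  expect_equal(score_from_pvalue(1, -1L), 0)
  expect_equal(score_from_pvalue(1e-320, 1L), 300)
  expect_error(score_from_pvalue(0, 1L))
  expect_error(score_from_pvalue(1.5, 1L))
  expect_error(score_from_pvalue(0.5, 2))
})

test_that("activity matrix matches per-motif mrs tests and broadcasts shared motifs", {
  fx <- small_fixture()
  utrs <- filter_utr_length(fx$utrs)
  # add a second miRNA sharing the planted seed
  mir <- fx$mirnas
  twin <- mir[1, ]
  twin$mirna_name <- "twin-5p"
  twin$mature_seq <- paste0(substr(mir$mature_seq[1], 1, 8), "AAAAAAAAAAAAAA")
  mir <- mirna_motifs(rbind(mir[, c("mirna_name", "mature_seq")],
                            twin[, c("mirna_name", "mature_seq")]))
  mot <- dedupe_motifs(mir)
  expect_lt(length(mot), nrow(mir))
  norm <- normalize_counts(fx$counts)
  delta <- fold_changes(norm)
  pt <- probability_table(names(mot), utrs, cache = "exact")
  act <- suppressWarnings(
    compute_activity(delta, utrs, mot, prob_table = pt, method = "mrs"))
  # shared motif -> identical columns
  expect_equal(act[, "twin-5p"], act[, mir$mirna_name[1]],
               ignore_attr = TRUE)
  # spot-check two cells against the standalone statistic
  genes <- intersect(rownames(delta), utrs$gene_id)
  I <- motif_indicators(names(mot), utrs[match(genes, utrs$gene_id), ])
  for (cell in c(1L, nrow(act))) {
    r <- rank(delta[genes, cell], ties.method = "average")
    for (m in names(mot)) {
      K <- sum(I[, m])
      if (K == 0 || K == length(genes)) next
      ref <- mrs_test(r, I[, m], pt[genes, m])
      expect_equal(act[cell, mot[[m]][1]], ref$score, tolerance = 1e-9)
    }
  }
})

test_that("identical samples score identically and sample permutation permutes rows", {
  fx <- small_fixture(seed = 11L)
  utrs <- filter_utr_length(fx$utrs)
  counts <- fx$counts
  counts[, 2] <- counts[, 1]  # duplicate a cell
  norm <- normalize_counts(counts)
  delta <- fold_changes(norm)
  mot <- dedupe_motifs(fx$mirnas)
  pt <- probability_table(names(mot), utrs)
  act <- suppressWarnings(
    compute_activity(delta, utrs, mot, prob_table = pt))
  expect_equal(unname(act[1, ]), unname(act[2, ]))
  # permuting columns permutes score rows identically (medians unchanged)
  perm <- rev(seq_len(ncol(counts)))
  act_p <- suppressWarnings(
    compute_activity(fold_changes(normalize_counts(counts[, perm])),
                     utrs, mot, prob_table = pt))
  expect_equal(act_p, act[perm, ], ignore_attr = TRUE)
})

test_that("all enrichment methods run end-to-end and point the same way on strong signal", {
  fx <- small_fixture(seed = 21L)
  utrs <- filter_utr_length(fx$utrs)
  pl <- fx$truth$planted_mirna
  active <- fx$truth$active_cells
  targets <- data.frame(mirna_name = pl,
                        gene_id = fx$truth$target_genes,
                        stringsAsFactors = FALSE)
  for (m in c("mrs", "bb", "hypergeom")) {
    act <- suppressWarnings(
      mir_activity(fx$counts, utrs, fx$mirnas, layer = "counts", method = m))
    expect_gt(mean(act[active, pl]), mean(act[!active, pl]))
  }
  # tarbase mode with target set == motif-bearing genes agrees in direction
  act_tb <- mir_activity(fx$counts, utrs, fx$mirnas[1, , drop = FALSE],
                         layer = "counts", method = "tarbase",
                         targets = targets)
  act_mrs <- suppressWarnings(
    mir_activity(fx$counts, utrs, fx$mirnas, layer = "counts"))
  agree <- sign(act_tb[, pl]) == sign(act_mrs[, pl])
  expect_gt(mean(agree[abs(act_mrs[, pl]) > 1]), 0.9)
  expect_error(
    mir_activity(fx$counts, utrs, fx$mirnas[1, , drop = FALSE],
                 layer = "counts", method = "tarbase",
                 targets = data.frame(mirna_name = pl, gene_id = "absent")),
    "target genes")
})

test_that("activity-expression correlation handles linear, antilinear and degenerate input", {
  x <- 1:20
  expect_equal(activity_expression_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(activity_expression_correlation(x, -x)$r, -1)
  set.seed(30)
  indep <- activity_expression_correlation(rnorm(1000), rnorm(1000))
  expect_lt(abs(indep$r), 0.1)
  expect_warning(res <- activity_expression_correlation(rep(1, 10), 1:10),
                 "constant")
  expect_true(is.na(res$r))
  expect_error(activity_expression_correlation(1:2, 1:2))
  # spearman flag
  sp <- activity_expression_correlation(x, exp(x), method = "spearman")
  expect_equal(sp$r, 1)
})

test_that("cell-type specificity flags the shifted type and only it", {
  set.seed(31)
  n <- 60
  labels <- rep(c("hepatocyte", "endothelial", "kupffer"), each = n / 3)
  act <- matrix(rnorm(n * 2, 0, 0.5), nrow = n,
                dimnames = list(paste0("c", 1:n), c("miR-a", "miR-b")))
  act[labels == "hepatocyte", "miR-a"] <- act[labels == "hepatocyte", "miR-a"] + 10
  res <- celltype_specificity(act, labels)
  flagged <- res[res$flagged, ]
  expect_equal(nrow(flagged), 1L)
  expect_equal(flagged$mirna, "miR-a")
  expect_equal(flagged$cell_type, "hepatocyte")
  expect_gt(flagged$robust_z, 3)
  # identical distributions -> nothing flagged
  act2 <- matrix(rnorm(n * 2), nrow = n,
                 dimnames = list(paste0("c", 1:n), c("miR-a", "miR-b")))
  expect_false(any(celltype_specificity(act2, labels)$flagged))
  expect_error(celltype_specificity(act, rep("one", n)), "at least 2")
  # zero-MAD miRNA skipped with warning
  act3 <- act2
  act3[, "miR-b"] <- 0
  expect_warning(res3 <- celltype_specificity(act3, labels), "MAD")
  expect_false("miR-b" %in% res3$mirna)
})
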