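test_that("modified rank sum reproduces hand-computed small cases", {
  # N = 3, ranks (1,2,3), centered weights (1,0,-1)
  res <- mrs_test(c(1, 2, 3), c(1, 0, 0), rep(0.1, 3))
  expect_equal(res$statistic, 1 / sqrt(0.18), tolerance = 1e-6)
  expect_equal(res$p_value, 2 * pnorm(-1 / sqrt(0.18)), tolerance = 1e-12)
  expect_equal(res$direction, 1L)
  # motif genes symmetric around the middle rank -> no signal
  sym <- mrs_test(1:5, c(1, 0, 0, 0, 1), rep(0.2, 5))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)
  expect_equal(sym$direction, 1L)  # zero maps to +1 by convention
  expect_error(mrs_test(1:3, c(1, 1, 1), rep(0.1, 3)), "no contrast")
  expect_error(mrs_test(1:3, c(0, 0, 0), rep(0.1, 3)), "no contrast")
  expect_error(mrs_test(1:3, c(1, 0, 0), c(0, 0, 0)), "variance")
})

test_that("modified rank sum agrees with a permutation oracle", {
  set.seed(100)
  n <- 40
  pg <- runif(n, 0.05, 0.5)
  ind <- rbinom(n, 1, pg)
  obs <- mrs_test(sample(n), ind, pg)
  t_perm <- replicate(4000, {
    cg <- (n + 1) / 2 - sample(n)
    sum(cg * (ind - pg)) / sqrt(sum(cg^2 * pg * (1 - pg)))
  })
  p_perm <- mean(abs(t_perm) >= abs(obs$statistic))
  expect_lt(abs(obs$p_value - p_perm), 0.05)
})

test_that("null-probability weighting keeps mrs calibrated where a naive rank sum inflates", {
  # p_g correlated with rank: motif-prone genes pile up at the induced end
  set.seed(99)
  n <- 300
  reps <- 300
  pg <- seq(0.05, 0.6, length.out = n)
  rej_mrs <- rej_naive <- 0L
  for (i in seq_len(reps)) {
    ind <- rbinom(n, 1, pg)
    if (all(ind == 0) || all(ind == 1)) next
    r <- seq_len(n)  # ordering aligned with the p_g gradient
    rej_mrs <- rej_mrs + (mrs_test(r, ind, pg)$p_value < 0.05)
    p_naive <- wilcox.test(r[ind == 1], r[ind == 0],
                           exact = FALSE, correct = FALSE)$p.value
    rej_naive <- rej_naive + (p_naive < 0.05)
  }
  expect_lte(rej_mrs / reps, 0.10)   # calibrated despite the correlation
  expect_gte(rej_naive / reps, 0.50) # unweighted test badly inflated
})

test_that("Kolmogorov sup-bridge tail is exact at the boundaries and monotone", {
  expect_equal(kolmogorov_sup_pvalue(0), 1)
  # direct series evaluation at d = 3: 2(e^-18 - e^-72 + ...)
  expect_equal(kolmogorov_sup_pvalue(3),
               2 * sum((-1)^(0:9) * exp(-2 * (1:10)^2 * 9)),
               tolerance = 1e-15)
  ds <- c(0.5, 1, 1.5, 2)
  ps <- vapply(ds, kolmogorov_sup_pvalue, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_lt(kolmogorov_sup_pvalue(10), 1e-80)
  expect_gt(kolmogorov_sup_pvalue(10), 0)
  expect_error(kolmogorov_sup_pvalue(-1))
})

test_that("Brownian-bridge test signs and errors follow the walk", {
  # all motif genes at the repressed end -> positive direction
  ind <- c(rep(1, 5), rep(0, 45))
  pg <- rep(0.1, 50)
  res <- bb_test(ind, pg)
  expect_equal(res$direction, 1L)
  expect_lt(res$p_value, 0.01)
  # mirrored arrangement flips the sign
  res2 <- bb_test(rev(ind), pg)
  expect_equal(res2$direction, -1L)
  expect_error(bb_test(rep(1, 20), rep(0.1, 20)), "no contrast")
  expect_error(bb_test(c(1, 0, 1, 0), c(0, 0, 0, 0)), "zero variance")
  expect_warning(bb_test(c(1, 0, 1, 0, 1), rep(0.3, 5)), "fewer than 10")
})

test_that("hypergeometric landscape matches exact enumeration and reduces to a plain test", {
  # N=10, K=4, n=5, k=3: p_over = (C(4,3)C(6,2)+C(4,4)C(6,1))/C(10,5)
  ind <- c(1, 1, 0, 1, 0, 0, 1, 0, 0, 0)  # 3 of first 5
  res <- hypergeom_landscape(ind, cutoffs = 5L)
  expect_equal(res$landscape$p_over, 66 / 252, tolerance = 1e-12)
  expect_equal(res$landscape$k, 3)
  # singleton grid equals a plain two-tail hypergeometric test
  expect_equal(res$p_value,
               min(phyper(2, 4, 6, 5, lower.tail = FALSE), phyper(3, 4, 6, 5)))
  # depletion at the top -> direction -1
  ind2 <- c(rep(0, 30), rep(1, 20))
  res2 <- hypergeom_landscape(ind2)
  expect_equal(res2$direction, -1L)
  expect_error(hypergeom_landscape(rep(1, 10)), "no contrast")
  expect_error(hypergeom_landscape(rep(0, 10)), "no contrast")
})

test_that("hypergeometric tails equal brute-force combinatorial sums for all small cases", {
  for (n_genes in c(5L, 9L, 12L)) {
    for (K in 1:(n_genes - 1L)) {
      for (n in 1:(n_genes - 1L)) {
        ks <- max(0L, n + K - n_genes):min(K, n)
        pmf <- choose(K, ks) * choose(n_genes - K, n - ks) /
          choose(n_genes, n)
        for (k in ks) {
          expect_equal(
            phyper(k - 1, K, n_genes - K, n, lower.tail = FALSE),
            sum(pmf[ks >= k]), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("target-set rank sum direction and p match an independent Wilcoxon route", {
  # targets at ranks {1,2,3} of 6: maximally repressed
  r <- 1:6
  tg <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  res <- targetset_ranksum(r, tg)
  expect_equal(res$direction, 1L)
  expect_gt(res$statistic, 0)
  # cross-check against stats::wilcox.test normal approximation
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(30)
    ranks <- rank(x, ties.method = "average")
    tg <- seq_along(x) %in% sample(30, 12)
    mine <- targetset_ranksum(ranks, tg)
    ref <- wilcox.test(x[tg], x[!tg], exact = FALSE, correct = FALSE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
  expect_error(targetset_ranksum(1:5, rep(TRUE, 5)), "contrast|every")
  expect_error(targetset_ranksum(1:5, rep(FALSE, 5)), "target set")
})

test_that("bb p-values are roughly uniform under permuted null orderings", {
  set.seed(42)
  n <- 200
  pg <- runif(n, 0.05, 0.4)
  pv <- replicate(400, {
    ind <- rbinom(n, 1, pg)
    o <- sample(n)
    bb_test(ind[o], pg[o])$p_value
  })
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})
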