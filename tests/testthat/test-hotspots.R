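test_that("residual scoring matches a brute-force oracle on random vectors", {
  set.seed(14)
  for (r in 1:20) {
    n <- sample(10:1000, 1)
    obs <- rpois(n, 50)
    expd <- obs + rnorm(n, 0, 10)
    tab <- score_residuals(obs, expd, cohort = "X")
    tab <- tab[order(tab$window), ]
    resid <- obs - expd
    z <- (resid - mean(resid)) / sd(resid)
    p <- vapply(z, oracle_norm_upper, numeric(1))
    expect_equal(tab$residual, resid, tolerance = 1e-12)
    expect_equal(tab$p, p, tolerance = 1e-12)
    expect_equal(tab$q, oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("residual z-scores use the sample standard deviation", {
  # residuals (0,0,...,10): for 4 effective values the hand-computed z of the
  # outlier is (10 - 2.5)/5 = 1.5; embed the same structure at n >= 10 and
  # check against the direct formula
  obs <- c(rep(5, 11), 15)
  expd <- rep(5, 12)
  tab <- score_residuals(obs, expd)
  resid <- obs - expd
  z_last <- (10 - mean(resid)) / sd(resid)
  expect_equal(tab$z[tab$window == 12], z_last)
  expect_equal(tab$p[tab$window == 12], pnorm(z_last, lower.tail = FALSE))
  # a residual equal to the mean residual sits at z = 0, p = 0.5
  expect_equal(unique(tab$p[tab$window != 12]), pnorm((0 - mean(resid)) / sd(resid),
                                                      lower.tail = FALSE))
  # ordering: q ascending with residual as tie-break
  expect_true(all(diff(tab$q) >= 0))
  expect_error(score_residuals(rep(5, 12), rep(4, 12)), "zero residual variance")
  expect_error(score_residuals(1:5, 1:5 + 0.5), "at least 10")
})

test_that("gene annotation takes the minimum p over overlapping windows", {
  obs <- c(10, 30, 10, rep(10, 9))
  g2 <- build_windows(c(chrA = 1.2e7), 1e6)
  tab <- score_residuals(obs, rep(10, 12), g2)
  genes <- data.frame(gene_id = c("inside", "spanning", "outside"),
                      chrom = "chrA",
                      start = c(1.2e6, 1.9e6, 5e6),
                      end = c(1.5e6, 2.2e6, 5.1e6),
                      is_cancer_gene = c(TRUE, FALSE, FALSE))
  ann <- annotate_genes(tab, genes)
  gt <- ann$genes
  p_win2 <- tab$p[tab$window == 2]
  # gene fully inside the hot window inherits its p
  expect_equal(gt$p[gt$gene_id == "inside"], p_win2)
  # gene spanning windows 2 and 3 takes the smaller p
  expect_equal(gt$p[gt$gene_id == "spanning"], p_win2)
  expect_true(gt$is_cancer_gene[gt$gene_id == "inside"])
  # per-window gene lists carry every overlapping gene
  hot_row <- ann$hotspots[ann$hotspots$window == 2, ]
  expect_setequal(strsplit(hot_row$genes, ",")[[1]], c("inside", "spanning"))
  # a gene over no retained window is absent
  tab10 <- score_residuals(obs[1:10], rep(10, 10), build_windows(c(chrA = 1e7), 1e6))
  # disjoint chromosome sets make GenomicRanges warn about seqlevels
  suppressWarnings(
    ann2 <- annotate_genes(tab10, data.frame(gene_id = "gone", chrom = "chrB",
                                             start = 0, end = 100,
                                             is_cancer_gene = FALSE)))
  expect_equal(nrow(ann2$genes), 0)
})

test_that("hypergeometric enrichment matches enumeration and handles edge cases", {
  # N = 4, K = 2, n = 2: P(X >= 1) = 5/6 by enumerating the 6 draws
  r <- fisher_enrichment(1, 2, 2, 4)
  expect_equal(r$p, 5 / 6, tolerance = 1e-12)
  expect_equal(r$expected, 1)
  # every item labelled: enrichment impossible
  expect_equal(fisher_enrichment(3, 3, 10, 10)$p, 1)
  expect_error(fisher_enrichment(5, 4, 10, 20), "inconsistent")
  expect_error(fisher_enrichment(3, 4, 2, 20), "inconsistent")
  # two-sided option delegates to Fisher's exact test
  r2 <- fisher_enrichment(8, 10, 20, 100, alternative = "two.sided")
  expect_true(r2$p > 0 && r2$p < 1)
  # one-sided tail agrees with direct pmf summation on random tables
  set.seed(5)
  for (i in 1:20) {
    N <- sample(20:200, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
    lo <- max(0, n + K - N); hi <- min(n, K)
    k <- lo + sample.int(hi - lo + 1, 1) - 1
    expect_equal(fisher_enrichment(k, n, K, N)$p, oracle_hyper_tail(k, K, N, n),
                 tolerance = 1e-12)
  }
})
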