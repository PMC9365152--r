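make_sig_inputs <- function() {
  g <- build_windows(c(chrA = 2e6), 1e6)
  snvs <- data.frame(chrom = "chrA", pos = c(100, 200),
                     ref = "C", alt = "T",
                     sample_id = c("s1", "s2"), cohort = "X")
  probs <- data.frame(chrom = "chrA", pos = c(100, 200),
                      sample_id = c("s1", "s2"),
                      A = c(0.7, 0.2), B = c(0.3, 0.8))
  list(g = g, snvs = snvs, probs = probs)
}

test_that("probabilistic signature burden adds per-SNV probabilities", {
  d <- make_sig_inputs()
  sb <- signature_burden(d$snvs, d$probs, d$g, "X")
  expect_equal(sb$A$counts, c(0.9, 0))
  expect_equal(sb$B$counts, c(1.1, 0))

  # conservation: signature burdens sum to the all-SNV count per window
  b <- count_burden(d$snvs, d$g, "X")
  expect_equal(sb$A$counts + sb$B$counts, b$counts, tolerance = 1e-12)

  # degenerate multinomial: probability 1 on one signature equals counting
  probs1 <- d$probs
  probs1$A <- 1; probs1$B <- 0
  sb1 <- signature_burden(d$snvs, probs1, d$g, "X")
  expect_equal(sb1$A$counts, b$counts)

  # missing probability rows are an error naming the offenders
  expect_error(signature_burden(d$snvs, d$probs[1, ], d$g, "X"),
               "without signature probabilities")
})

test_that("top-ranked assignment gives whole counts with lexicographic ties", {
  d <- make_sig_inputs()
  tb <- top_signature_burden(d$snvs, d$probs, d$g, "X")
  expect_equal(tb$A$counts, c(1, 0))  # SNV1 argmax A, SNV2 argmax B
  expect_equal(tb$B$counts, c(1, 0))
  expect_equal(tb$A$counts + tb$B$counts,
               count_burden(d$snvs, d$g, "X")$counts)

  # exact tie goes to the lexicographically first signature id
  tie <- d$probs
  tie$A <- 0.5; tie$B <- 0.5
  tt <- top_signature_burden(d$snvs, tie, d$g, "X")
  expect_equal(tt$A$counts, c(2, 0))
  expect_equal(tt$B$counts, c(0, 0))
})

test_that("signature filter is inclusive at the 20,000-SNV boundary", {
  mk <- function(total) burden_vector("X", "s", c(total / 2, total / 2))
  burdens <- list(lo = mk(19999), hi = mk(20000), big = mk(50000))
  expect_setequal(filter_signatures(burdens), c("hi", "big"))
  expect_warning(kept <- filter_signatures(list(lo = mk(10))), "no signature")
  expect_length(kept, 0)
})

test_that("expected-value burden is an unbiased estimate of true label counts", {
  g <- generate_grid(80, 1e6, n_chrom = 2)
  tr <- generate_tracks(g, n_cancer = 1, n_normal = 1, n_rt = 1, seed = 3)
  errs <- sapply(1:5, function(r) {
    mut <- generate_mutations(g, tr$truth, n_hotspots = 0, mean_burden = 80,
                              seed = 30 + r)
    sb <- signature_burden(mut$snvs, mut$probs, g, "synthetic")
    w_idx <- match(paste(mut$snvs$chrom, floor((mut$snvs$pos - 1) / 1e6) * 1e6),
                   paste(g$chrom, g$start))
    sig <- names(sb)[1]
    true_counts <- tabulate(w_idx[mut$true_signatures == sig], nbins = nrow(g))
    mean(sb[[sig]]$counts - true_counts)
  })
  # mean window-level error shrinks toward zero across replicates
  expect_lt(abs(mean(errs)), 0.5)
})

test_that("class accuracy comparison adjusts for burden covariate", {
  set.seed(9)
  n <- 30
  tab0 <- data.frame(cohort = "X",
                     signature = rep(c("s1", "s2", "s3", "s4"), length.out = n),
                     adjR2 = rnorm(n, 0.5, 0.05))
  cmap <- c(s1 = "carcinogen", s2 = "carcinogen", s3 = "APOBEC", s4 = "APOBEC")
  covar <- runif(n, 10, 20)

  # identical distributions: class effect not significant
  r0 <- class_accuracy_test(tab0, cmap, covar)
  expect_gt(r0$class_p, 0.05)

  # well-separated class means at matched covariate: significant
  tab1 <- tab0
  tab1$adjR2 <- tab1$adjR2 + ifelse(cmap[tab1$signature] == "carcinogen", 0.4, 0)
  r1 <- class_accuracy_test(tab1, cmap, covar)
  expect_lt(r1$class_p, 1e-6)
  expect_true(any(grepl("carcinogen", r1$contrasts$contrast)))

  # difference fully carried by the covariate: class term goes quiet
  covar2 <- ifelse(cmap[tab0$signature] == "carcinogen", 20, 10) + rnorm(n, 0, 0.1)
  tab2 <- tab0
  tab2$adjR2 <- 0.02 * covar2 + rnorm(n, 0, 0.002)
  r2 <- class_accuracy_test(tab2, cmap, covar2)
  expect_gt(r2$class_p, 0.05)

  # singular designs are refused
  expect_error(class_accuracy_test(tab0[1:2, ], cmap, covar[1:2]),
               "insufficient replication")
})
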