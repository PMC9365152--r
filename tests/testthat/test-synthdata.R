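test_that("generators are bit-identical under a fixed seed", {
  g <- generate_grid(60, 1e6, n_chrom = 3)
  t1 <- generate_tracks(g, n_cancer = 2, n_normal = 2, n_rt = 2, seed = 5)
  t2 <- generate_tracks(g, n_cancer = 2, n_normal = 2, n_rt = 2, seed = 5)
  expect_identical(t1, t2)
  m1 <- generate_mutations(g, t1$truth, seed = 6)
  m2 <- generate_mutations(g, t1$truth, seed = 6)
  expect_identical(m1, m2)
  g1 <- generate_genes(g, m1$hotspot_windows, n_genes = 30, n_cancer_genes = 5, seed = 7)
  g2 <- generate_genes(g, m1$hotspot_windows, n_genes = 30, n_cancer_genes = 5, seed = 7)
  expect_identical(g1, g2)
})

test_that("track construction reflects loadings, classes and noise", {
  g <- generate_grid(200, 1e6)
  # zero noise and unit loading reproduces the latent field exactly
  tr0 <- generate_tracks(g, n_cancer = 1, n_normal = 0, n_rt = 0,
                         a_cancer = 1, noise_sd = 0, seed = 2)
  expect_equal(tr0$tracks[[1]]$values, tr0$truth$latent_ca)

  # track-latent correlation decreases monotonically with noise
  cors <- sapply(c(0.2, 0.8, 2), function(s) {
    tr <- generate_tracks(g, n_cancer = 1, n_normal = 0, n_rt = 0,
                          noise_sd = s, seed = 3)
    cor(tr$tracks[[1]]$values, tr$truth$latent_ca)
  })
  expect_true(all(diff(cors) < 0))

  # classes, phases, and truth bookkeeping
  tr <- generate_tracks(g, n_cancer = 2, n_normal = 1, n_rt = 6, n_noise = 1, seed = 4)
  meta <- tracks_metadata(tr$tracks)
  expect_equal(sum(meta$feature_class == "cancer_CA"), 2)
  expect_equal(sum(meta$feature_class == "RT"), 6)
  expect_setequal(meta$rt_phase[meta$feature_class == "RT"],
                  c("G1b", "S1", "S2", "S3", "S4", "G2"))
  expect_equal(unname(tr$truth$effects[meta$tissue == "noise"]), 0)
  late <- meta$track_id[!is.na(meta$rt_phase) & meta$rt_phase %in% c("S3", "S4", "G2")]
  expect_true(all(tr$truth$effects[late] > 0))
})

test_that("mutation generation plants hotspots and exact posteriors", {
  g <- generate_grid(120, 1e6, n_chrom = 3)
  tr <- generate_tracks(g, n_cancer = 1, n_normal = 1, n_rt = 1, seed = 8)
  mut <- generate_mutations(g, tr$truth, hotspot_factor = 3, n_hotspots = 5, seed = 9)

  expect_length(mut$hotspot_windows, 5)
  expect_equal(mut$mu[mut$hotspot_windows], 3 * mut$mu_base[mut$hotspot_windows])
  # hotspots sit away from chromosome ends
  first_last <- unlist(tapply(seq_len(nrow(g)), g$chrom, function(i) range(i)))
  expect_false(any(mut$hotspot_windows %in% first_last))

  sig_cols <- names(mut$params$exposures)
  expect_equal(rowSums(mut$probs[, sig_cols]), rep(1, nrow(mut$probs)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # positions stay inside their windows and records validate
  expect_true(all(mut$snvs$pos >= 1))
  expect_silent(validate_mutations(mut$snvs))
  expect_true(all(mut$snvs$ref == substr(mut$snvs$context, 2, 2)))
  expect_true(all(mut$snvs$ref != mut$snvs$alt))

  # null scenario: no planted structure
  m0 <- generate_mutations(g, tr$truth, beta_ca = 0, beta_rt = 0,
                           n_hotspots = 0, seed = 10)
  expect_length(m0$hotspot_windows, 0)
  expect_equal(var(m0$mu), 0)
})

test_that("generated data round-trip through the pipeline file formats", {
  g <- generate_grid(40, 1e6, n_chrom = 2)
  tr <- generate_tracks(g, n_cancer = 1, n_normal = 1, n_rt = 1, seed = 11)
  mut <- generate_mutations(g, tr$truth, seed = 12)
  td <- tempfile(); dir.create(td)

  mut_path <- file.path(td, "snvs.tsv")
  write.table(mut$snvs, mut_path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_mutations(mut_path)
  expect_equal(nrow(back), nrow(mut$snvs))
  expect_equal(back$pos, mut$snvs$pos)

  probs_path <- file.path(td, "probs.tsv")
  write.table(mut$probs, probs_path, sep = "\t", quote = FALSE, row.names = FALSE)
  probs_back <- read_signature_probs(probs_path)
  sb1 <- signature_burden(mut$snvs, mut$probs, g, "synthetic")
  sb2 <- signature_burden(back, probs_back, g, "synthetic")
  expect_equal(sb1$SBSa$counts, sb2$SBSa$counts, tolerance = 1e-9)

  write_windows_bed(g, file.path(td, "win.bed"))
  bed <- read.table(file.path(td, "win.bed"), sep = "\t")
  expect_equal(nrow(bed), nrow(g))
  expect_equal(bed[[2]], g$start)
  unlink(td, recursive = TRUE)
})

test_that("gene flags concentrate on hotspots only when biased", {
  g <- generate_grid(200, 1e6)
  tr <- generate_tracks(g, n_cancer = 1, n_normal = 1, n_rt = 1, seed = 13)
  mut <- generate_mutations(g, tr$truth, n_hotspots = 10, seed = 14)
  genes_flat <- generate_genes(g, mut$hotspot_windows, n_genes = 150,
                               n_cancer_genes = 15, hotspot_bias = 0, seed = 15)
  genes_hot <- generate_genes(g, mut$hotspot_windows, n_genes = 150,
                              n_cancer_genes = 15, hotspot_bias = 100, seed = 15)
  on_hot <- function(genes) {
    gidx <- match(paste(genes$chrom, floor(genes$start / 1e6) * 1e6),
                  paste(g$chrom, g$start))
    sum(genes$is_cancer_gene & gidx %in% mut$hotspot_windows)
  }
  expect_gt(on_hot(genes_hot), on_hot(genes_flat))
  expect_equal(sum(genes_hot$is_cancer_gene), 15)
  # genes never overlap each other (at most one per window)
  expect_false(any(duplicated(paste(genes_hot$chrom, floor(genes_hot$start / 1e6)))))
})
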