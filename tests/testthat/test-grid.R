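test_that("window tiling drops partial trailing windows and counts add up", {
  g <- build_windows(c(chrA = 2.5e6), 1e6)
  expect_equal(nrow(g), 2)
  expect_equal(g$start, c(0, 1e6))
  expect_equal(g$end, c(1e6, 2e6))

  expect_equal(nrow(build_windows(c(chrA = 1e6), 1e6)), 1)

  g2 <- build_windows(c(chrA = 3e6, chrB = 1.5e6), 1e6)
  expect_equal(nrow(g2), 4)
  expect_equal(table(g2$chrom)[["chrA"]], 3)

  # invariant: total windows = sum of floor(length / window_size)
  sizes <- c(a = 7.3e6, b = 2.9e6, c = 0.4e6)
  g3 <- build_windows(sizes, 1e6)
  expect_equal(nrow(g3), sum(floor(sizes / 1e6)))

  expect_error(build_windows(numeric(0)), "no chromosomes")
  expect_error(build_windows(c(chrA = -5)), "positive")
})

test_that("mappability filtering keeps only windows strictly above threshold", {
  g <- build_windows(c(chrA = 3e6), 1e6)
  g <- assign_mappability(g, c(0.9, 0.8, 0.81))
  f <- filter_windows(g, min_mappability = 0.8)
  expect_equal(f$start, c(0, 2e6))  # the 0.80 window is excluded

  # empty exclude list leaves the mappability rule as the only filter
  f2 <- filter_windows(g, 0.8, exclude = data.frame(chrom = character(),
                                                    start = numeric()))
  expect_identical(f2$start, f$start)

  # explicit exclusion removes exactly the named window
  f3 <- filter_windows(g, 0, exclude = data.frame(chrom = "chrA", start = 1e6))
  expect_equal(f3$start, c(0, 2e6))
  expect_warning(filter_windows(g, 0, exclude = data.frame(chrom = "chrZ", start = 0)),
                 "matched no window")
})

test_that("track aggregation computes length-weighted means with zero fill", {
  g <- build_windows(c(chrA = 2e6), 1e6)
  # constant signal across a window
  cov <- data.frame(chrom = "chrA", start = 0, end = 2e6, value = 5)
  expect_equal(aggregate_track(cov, g), c(5, 5))

  # 0 on first half, 10 on second half
  cov2 <- data.frame(chrom = "chrA", start = c(0, 5e5), end = c(5e5, 1e6),
                     value = c(0, 10))
  expect_equal(aggregate_track(cov2, g)[1], 5)

  # partial coverage: 4 over 250 kb of a 1 Mb window, uncovered bases are 0
  cov3 <- data.frame(chrom = "chrA", start = 0, end = 2.5e5, value = 4)
  expect_equal(aggregate_track(cov3, g)[1], 1.0)

  # invariance to splitting an interval into abutting pieces of equal value
  whole <- data.frame(chrom = "chrA", start = 1e5, end = 9e5, value = 3)
  split <- data.frame(chrom = "chrA", start = c(1e5, 4e5, 6e5),
                      end = c(4e5, 6e5, 9e5), value = 3)
  expect_equal(aggregate_track(whole, g), aggregate_track(split, g))

  # interval beyond the chromosome end is clipped with a warning
  over <- data.frame(chrom = "chrA", start = 1.5e6, end = 2.5e6, value = 2)
  expect_warning(v <- aggregate_track(over, g), "clipped")
  expect_equal(v[2], 1)

  # deterministic: identical inputs give identical output
  expect_identical(aggregate_track(cov2, g), aggregate_track(cov2, g))
})

test_that("bedGraph input via rtracklayer matches data.frame input", {
  g <- build_windows(c(chr1 = 1e6), 1e6)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t500000\t4", "chr1\t500000\t1000000\t6"), path)
  gr <- read_bedgraph(path)
  df <- data.frame(chrom = "chr1", start = c(0, 5e5), end = c(5e5, 1e6),
                   value = c(4, 6))
  expect_equal(aggregate_track(gr, g), aggregate_track(df, g))
  expect_equal(aggregate_track(gr, g), 5)
})

test_that("track profiles validate class, phase and alignment", {
  expect_error(track_profile("t", "RT", 1:3), "rt_phase")
  expect_error(track_profile("t", "cancer_CA", 1:3, rt_phase = "G2"),
               "only valid for RT")
  expect_error(track_profile("t", "cancer_CA", c(1, NA)), "finite")
  t1 <- track_profile("a", "cancer_CA", c(1, 2))
  t2 <- track_profile("b", "RT", c(3, 4), rt_phase = "G2")
  m <- tracks_matrix(list(t1, t2))
  expect_equal(dim(m), c(2, 2))
  expect_equal(colnames(m), c("a", "b"))
  meta <- tracks_metadata(list(t1, t2))
  expect_equal(meta$rt_phase, c(NA, "G2"))
  expect_error(tracks_matrix(list(t1, track_profile("c", "RT", 1:3, rt_phase = "S1"))),
               "lengths differ")
})
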