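#' Build a genome-wide grid of fixed-size windows
#'
#' Tiles each chromosome with consecutive non-overlapping windows of
#' `window_size` base pairs, starting at position 0. A trailing remainder
#' shorter than `window_size` is dropped, so every window has exactly
#' `window_size` bases. Coordinates are 0-based half-open (BED convention).
#'
#' @param chrom_sizes Either a two-column data.frame (`chrom`, `length`) or a
#'   named numeric vector of chromosome lengths in bp.
#' @param window_size Window width in bp. Defaults to 1 Mbp; 1e5 gives the
#'   finer 100-kbp grid used for gene-level residual analysis.
#' @param mappability Initial per-window mappability score in `[0, 1]`,
#'   recycled across windows. Replace with measured scores via
#'   [assign_mappability()] before filtering.
#' @return A `window_grid`: a data.frame with columns `chrom`, `start`,
#'   `end`, `mappability`, carrying the window size and chromosome sizes as
#'   attributes.
#' @examples
#' grid <- build_windows(c(chr1 = 3e6, chr2 = 1.5e6), window_size = 1e6)
#' nrow(grid)  # 4 windows: 3 on chr1, 1 on chr2
#' @export
build_windows <- function(chrom_sizes, window_size = 1e6, mappability = 1) {
  if (is.data.frame(chrom_sizes)) {
    stopifnot(ncol(chrom_sizes) >= 2)
    sizes <- structure(as.numeric(chrom_sizes[[2]]), names = as.character(chrom_sizes[[1]]))
  } else {
    sizes <- chrom_sizes
  }
  if (length(sizes) == 0L) stop("no chromosomes")
  if (is.null(names(sizes)) || any(!nzchar(names(sizes)))) stop("chromosome names required")
  if (any(sizes <= 0)) stop("chromosome lengths must be positive")
  if (window_size <= 0) stop("window_size must be positive")

  per_chrom <- lapply(names(sizes), function(ch) {
    n <- floor(sizes[[ch]] / window_size)
    if (n == 0L) return(NULL)
    start <- (seq_len(n) - 1) * window_size
    data.frame(chrom = ch, start = start, end = start + window_size,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, per_chrom)
  if (is.null(grid)) {
    grid <- data.frame(chrom = character(), start = numeric(), end = numeric())
  }
  grid$mappability <- rep_len(mappability, nrow(grid))
  structure(grid,
            window_size = window_size,
            chrom_sizes = sizes,
            class = c("window_grid", "data.frame"))
}

#' Attach per-window mappability scores to a grid
#'
#' @param grid A [build_windows()] grid.
#' @param scores Either a numeric vector aligned with the grid rows, or a
#'   data.frame with columns `chrom`, `start`, `mappability` matched to
#'   windows by position.
#' @return The grid with its `mappability` column replaced.
#' @export
assign_mappability <- function(grid, scores) {
  stopifnot(inherits(grid, "window_grid"))
  if (is.data.frame(scores)) {
    key <- paste(grid$chrom, grid$start)
    idx <- match(key, paste(scores$chrom, scores$start))
    if (anyNA(idx)) stop("mappability missing for ", sum(is.na(idx)), " windows")
    vals <- scores$mappability[idx]
  } else {
    if (length(scores) != nrow(grid)) stop("mappability length mismatch")
    vals <- as.numeric(scores)
  }
  if (any(!is.finite(vals)) || any(vals < 0 | vals > 1)) {
    stop("mappability must be finite and in [0, 1]")
  }
  grid$mappability <- vals
  grid
}

#' Filter windows by mappability and explicit exclusion
#'
#' Windows are retained only when mappability strictly exceeds
#' `min_mappability` (the default reproduces the rule that windows at or
#' below 80 percent uniquely-mappable bases are removed). Windows listed in
#' `exclude` — such as the immunoglobulin loci at chr2 89 Mbp and chr22
#' 23 Mbp removed for lymphoid cohorts — are dropped regardless of score.
#'
#' @param grid A `window_grid`.
#' @param min_mappability Retention threshold; kept iff mappability is
#'   strictly greater. Default 0.8.
#' @param exclude Optional data.frame with columns `chrom`, `start` naming
#'   windows to remove. Entries matching no window raise a warning only.
#' @return The filtered `window_grid`, order preserved.
#' @export
filter_windows <- function(grid, min_mappability = 0.8, exclude = NULL) {
  stopifnot(inherits(grid, "window_grid"))
  if (anyNA(grid$mappability)) stop("mappability not populated")
  keep <- grid$mappability > min_mappability
  if (!is.null(exclude) && nrow(exclude) > 0) {
    key <- paste(grid$chrom, grid$start)
    ex_key <- paste(exclude$chrom, exclude$start)
    hit <- key %in% ex_key
    missing <- setdiff(ex_key, key)
    if (length(missing) > 0) {
      warning("exclude entries matched no window: ", paste(missing, collapse = ", "))
    }
    keep <- keep & !hit
  }
  out <- grid[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)$window_size <- attr(grid, "window_size")
  attributes(out)$chrom_sizes <- attr(grid, "chrom_sizes")
  class(out) <- c("window_grid", "data.frame")
  out
}

#' Convert a window grid to GRanges
#'
#' @param grid A `window_grid`.
#' @return A [GenomicRanges::GRanges] with 1-based closed coordinates.
#' @export
grid_as_granges <- function(grid) {
  GenomicRanges::GRanges(
    seqnames = grid$chrom,
    ranges = IRanges::IRanges(start = grid$start + 1, end = grid$end)
  )
}

#' Aggregate an interval coverage track to per-window mean signal
#'
#' Computes, for each window, the length-weighted mean of the signal over
#' all bases in the window. Bases covered by no interval contribute signal
#' 0 (sparse bedGraph convention), so a window covered on 250 kb of 1 Mb at
#' value 4 averages to 1. Intervals extending past the chromosome end are
#' clipped with a warning.
#'
#' @param coverage Either a `GRanges` with a `score` column (as returned by
#'   [rtracklayer::import] for bedGraph) or a data.frame with columns
#'   `chrom`, `start`, `end`, `value` in 0-based half-open coordinates.
#' @param grid A `window_grid`.
#' @return Numeric vector of per-window mean signal, aligned with the grid.
#' @export
aggregate_track <- function(coverage, grid) {
  stopifnot(inherits(grid, "window_grid"))
  if (methods::is(coverage, "GRanges")) {
    cov <- data.frame(chrom = as.character(GenomicRanges::seqnames(coverage)),
                      start = GenomicRanges::start(coverage) - 1,
                      end = GenomicRanges::end(coverage),
                      value = as.numeric(coverage$score))
  } else {
    cov <- coverage[, c("chrom", "start", "end", "value")]
  }
  if (any(!is.finite(cov$value))) stop("coverage values must be finite")

  sizes <- attr(grid, "chrom_sizes")
  if (!is.null(sizes)) {
    known <- cov$chrom %in% names(sizes)
    if (any(known)) {
      lim <- sizes[cov$chrom[known]]
      over <- cov$end[known] > lim
      if (any(over)) {
        warning(sum(over), " interval(s) extend past the chromosome end; clipped")
        cov$end[known][over] <- lim[over]
      }
    }
  }
  cov <- cov[cov$end > cov$start, , drop = FALSE]

  win <- grid_as_granges(grid)
  cg <- GenomicRanges::GRanges(cov$chrom,
                               IRanges::IRanges(start = cov$start + 1, end = cov$end))
  hits <- GenomicRanges::findOverlaps(cg, win)
  vals <- numeric(nrow(grid))
  if (length(hits) > 0) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    inter <- GenomicRanges::pintersect(cg[qi], win[si])
    w <- GenomicRanges::width(inter)
    contrib <- cov$value[qi] * w
    sums <- tapply(contrib, si, sum)
    vals[as.integer(names(sums))] <- as.numeric(sums)
  }
  vals / attr(grid, "window_size")
}

#' Construct an epigenome track profile
#'
#' A track profile is one genome-wide predictor: per-window mean signal of a
#' chromatin-accessibility (ATAC-seq) or replication-timing (RepliSeq)
#' experiment, labelled with the class used to assemble model arms.
#'
#' @param track_id Unique identifier.
#' @param feature_class One of `"cancer_CA"`, `"normal_CA"`,
#'   `"cancer_cell_line_CA"`, `"RT"`.
#' @param values Per-window mean signal, aligned with the analysis grid.
#' @param tissue Tissue or cell-type tag.
#' @param rt_phase Cell-cycle phase (`"G1b"`, `"S1"`..`"S4"`, `"G2"`);
#'   required iff `feature_class == "RT"`.
#' @return A `track_profile` object.
#' @export
track_profile <- function(track_id, feature_class, values, tissue = NA_character_,
                          rt_phase = NULL) {
  feature_class <- match.arg(feature_class, c("cancer_CA", "normal_CA",
                                              "cancer_cell_line_CA", "RT"))
  if (feature_class == "RT") {
    if (is.null(rt_phase)) stop("RT tracks require rt_phase")
    rt_phase <- match.arg(rt_phase, c("G1b", "S1", "S2", "S3", "S4", "G2"))
  } else if (!is.null(rt_phase)) {
    stop("rt_phase only valid for RT tracks")
  }
  if (any(!is.finite(values))) stop("track values must be finite")
  structure(list(track_id = track_id, feature_class = feature_class,
                 tissue = tissue, rt_phase = rt_phase,
                 values = as.numeric(values)),
            class = "track_profile")
}

#' Assemble a feature matrix from track profiles
#'
#' @param tracks List of [track_profile()] objects over the same grid.
#' @return Numeric matrix, windows x tracks, with track ids as column names.
#' @export
tracks_matrix <- function(tracks) {
  stopifnot(length(tracks) > 0)
  n <- length(tracks[[1]]$values)
  bad <- vapply(tracks, function(t) length(t$values) != n, logical(1))
  if (any(bad)) stop("track value lengths differ")
  m <- vapply(tracks, function(t) t$values, numeric(n))
  colnames(m) <- vapply(tracks, function(t) t$track_id, character(1))
  if (anyDuplicated(colnames(m))) stop("duplicate track ids")
  m
}

#' Track metadata table
#'
#' @param tracks List of `track_profile` objects.
#' @return data.frame with `track_id`, `feature_class`, `tissue`, `rt_phase`.
#' @export
tracks_metadata <- function(tracks) {
  data.frame(
    track_id = vapply(tracks, function(t) t$track_id, character(1)),
    feature_class = vapply(tracks, function(t) t$feature_class, character(1)),
    tissue = vapply(tracks, function(t) as.character(t$tissue), character(1)),
    rt_phase = vapply(tracks, function(t)
      if (is.null(t$rt_phase)) NA_character_ else t$rt_phase, character(1)),
    stringsAsFactors = FALSE
  )
}
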