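#' Remove hypermutated samples
#'
#' Samples carrying more than `max_snvs` SNVs are excluded; the default of
#' 90,000 (about 30 mutations per Mbp) stabilises regional burden estimates
#' against hypermutator genomes. The inequality is strict: a sample with
#' exactly `max_snvs` mutations is retained.
#'
#' @param per_sample_counts Named integer vector (or two-column data.frame
#'   `sample_id`, `n_snvs`) of SNV counts per sample.
#' @param max_snvs Exclusion threshold, default 90000.
#' @return Character vector of retained sample ids.
#' @export
filter_hypermutators <- function(per_sample_counts, max_snvs = 90000) {
  if (is.data.frame(per_sample_counts)) {
    counts <- structure(per_sample_counts[[2]], names = as.character(per_sample_counts[[1]]))
  } else {
    counts <- per_sample_counts
  }
  if (any(counts < 0)) stop("negative sample counts")
  names(counts)[counts <= max_snvs]
}

#' Select cohorts with sufficient sample size
#'
#' Cohorts (cancer types) with at least `min_samples` sequenced genomes are
#' analysed individually; all samples regardless of cohort feed the
#' pan-cancer pool, which is always emitted.
#'
#' @param per_cohort_sample_counts Named integer vector (or two-column
#'   data.frame) of sample counts per cohort.
#' @param min_samples Minimum cohort size, default 25 (inclusive).
#' @return List with `cohorts` (character vector of retained cohorts) and
#'   `pan_cancer` (the pseudo-cohort label, always present).
#' @export
select_cohorts <- function(per_cohort_sample_counts, min_samples = 25) {
  if (is.data.frame(per_cohort_sample_counts)) {
    counts <- structure(per_cohort_sample_counts[[2]],
                        names = as.character(per_cohort_sample_counts[[1]]))
  } else {
    counts <- per_cohort_sample_counts
  }
  if (length(counts) > 0 && any(counts < 0)) stop("negative cohort counts")
  list(cohorts = names(counts)[counts >= min_samples], pan_cancer = "pancancer")
}

#' Count per-window SNV burden for a cohort
#'
#' Assigns each SNV to the window containing its position (1-based input
#' positions against the 0-based half-open grid: position `p` falls in the
#' window with `start < p <= end`). SNVs on chromosomes absent from the grid
#' trigger a warning and are skipped; SNVs on known chromosomes but outside
#' any retained window are silently ignored and tallied in the `skipped`
#' attribute, so that counted + skipped equals the cohort input size.
#'
#' @param snvs data.frame of mutation records with columns `chrom`, `pos`
#'   (1-based), `sample_id`, `cohort` (plus `ref`/`alt`, unused here).
#' @param grid A `window_grid` (already filtered).
#' @param cohort Cohort label, or `"pancancer"` to pool all records.
#' @return A `burden_vector`: list with `cohort`, `mutation_class = "all"`,
#'   integer `counts` per window and attribute `skipped`.
#' @export
count_burden <- function(snvs, grid, cohort) {
  stopifnot(inherits(grid, "window_grid"))
  rec <- if (identical(cohort, "pancancer")) snvs else snvs[snvs$cohort == cohort, , drop = FALSE]
  n_in <- nrow(rec)
  counts <- integer(nrow(grid))
  skipped <- 0L
  if (n_in > 0) {
    unknown <- !(rec$chrom %in% unique(grid$chrom))
    if (any(unknown)) {
      warning(sum(unknown), " SNV(s) on chromosomes absent from the grid; skipped")
      skipped <- skipped + sum(unknown)
      rec <- rec[!unknown, , drop = FALSE]
    }
    if (nrow(rec) > 0) {
      gr <- GenomicRanges::GRanges(rec$chrom, IRanges::IRanges(rec$pos, rec$pos))
      hits <- GenomicRanges::findOverlaps(gr, grid_as_granges(grid))
      tab <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(grid))
      counts <- as.integer(tab)
      skipped <- skipped + (nrow(rec) - length(hits))
    }
  }
  if (skipped > 0) message(skipped, " SNV(s) outside retained windows for cohort ", cohort)
  burden_vector(cohort, "all", counts, skipped = skipped)
}

#' Construct a per-window burden vector
#'
#' @param cohort Cohort label.
#' @param mutation_class `"all"` or an SBS signature id.
#' @param counts Non-negative per-window counts; integers when
#'   `mutation_class == "all"`, expected (fractional) counts for signatures.
#' @param skipped Number of input SNVs not assigned to any window.
#' @return A `burden_vector` object.
#' @export
burden_vector <- function(cohort, mutation_class, counts, skipped = 0L) {
  if (any(counts < 0)) stop("burden counts must be non-negative")
  if (identical(mutation_class, "all") &&
      any(abs(counts - round(counts)) > 1e-9)) {
    stop("all-SNV burden must be integer")
  }
  structure(list(cohort = cohort, mutation_class = mutation_class,
                 counts = as.numeric(counts)),
            skipped = skipped, class = "burden_vector")
}
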