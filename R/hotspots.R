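#' Score windows for mutation excess over model expectation
#'
#' Residuals (observed minus expected counts) are Z-transformed within the
#' cohort using the sample standard deviation; one-tailed upper-tail normal
#' p-values are corrected across all windows by Benjamini-Hochberg FDR.
#' Windows with small q and large positive residuals are candidate driver
#' regions or targets of focal mutational processes not captured by the
#' epigenome model. Typically run on the finer 100-kbp grid with
#' out-of-bag expected counts from a full-data forest fit.
#'
#' @param observed A `burden_vector` (or numeric counts per window).
#' @param expected Model-expected counts per window (e.g.
#'   `fit$oob_predictions`).
#' @param grid Optional `window_grid` supplying coordinates for the table.
#' @param cohort Cohort label (taken from `observed` when available).
#' @return A `hotspot_table` data.frame with `observed`, `expected`,
#'   `residual`, `z`, `p`, `q` (and window coordinates when `grid` is
#'   given), sorted by `q` then residual descending. Attribute `order`
#'   maps rows back to grid positions.
#' @export
score_residuals <- function(observed, expected, grid = NULL, cohort = NULL) {
  obs <- if (inherits(observed, "burden_vector")) observed$counts else as.numeric(observed)
  if (is.null(cohort) && inherits(observed, "burden_vector")) cohort <- observed$cohort
  if (is.null(cohort)) cohort <- NA_character_
  stopifnot(length(expected) == length(obs))
  if (length(obs) < 10) stop("need at least 10 windows")
  resid <- obs - expected
  s <- stats::sd(resid)
  if (s == 0) stop("zero residual variance")
  z <- (resid - mean(resid)) / s
  p <- stats::pnorm(z, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  tab <- data.frame(window = seq_along(obs), cohort = cohort,
                    observed = obs, expected = expected,
                    residual = resid, z = z, p = p, q = q,
                    stringsAsFactors = FALSE)
  if (!is.null(grid)) {
    stopifnot(nrow(grid) == length(obs))
    tab <- cbind(data.frame(chrom = grid$chrom, start = grid$start,
                            end = grid$end, stringsAsFactors = FALSE), tab)
  }
  ord <- order(tab$q, -tab$residual)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("hotspot_table", "data.frame")
  tab
}

#' Annotate hotspot windows with overlapping genes
#'
#' A gene overlaps a window when their half-open intervals intersect. Each
#' hotspot row gains a comma-separated gene list; the companion gene-level
#' table assigns each gene the minimum p-value over the windows it
#' overlaps, the form consumed by downstream pathway-enrichment tools.
#'
#' @param hits A `hotspot_table` carrying `chrom`, `start`, `end` columns
#'   (i.e. scored with a grid).
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `is_cancer_gene`.
#' @return List with `hotspots` (the annotated table) and `genes`
#'   (gene-level data.frame: `gene_id`, `p`, `q_min`, `is_cancer_gene`).
#' @export
annotate_genes <- function(hits, genes) {
  stopifnot(all(c("chrom", "start", "end") %in% names(hits)))
  win <- GenomicRanges::GRanges(hits$chrom,
                                IRanges::IRanges(hits$start + 1, hits$end))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1, genes$end))
  ov <- GenomicRanges::findOverlaps(gg, win)
  gi <- S4Vectors::queryHits(ov)
  wi <- S4Vectors::subjectHits(ov)

  gene_lists <- rep("", nrow(hits))
  if (length(ov) > 0) {
    per_window <- tapply(genes$gene_id[gi], wi, paste, collapse = ",")
    gene_lists[as.integer(names(per_window))] <- as.character(per_window)
  }
  hits$genes <- gene_lists

  gene_tab <- data.frame(gene_id = character(), p = numeric(),
                         q_min = numeric(), is_cancer_gene = logical(),
                         stringsAsFactors = FALSE)
  if (length(ov) > 0) {
    p_min <- tapply(hits$p[wi], genes$gene_id[gi], min)
    q_min <- tapply(hits$q[wi], genes$gene_id[gi], min)
    ids <- names(p_min)
    flag <- if ("is_cancer_gene" %in% names(genes)) {
      genes$is_cancer_gene[match(ids, genes$gene_id)]
    } else rep(FALSE, length(ids))
    gene_tab <- data.frame(gene_id = ids, p = as.numeric(p_min),
                           q_min = as.numeric(q_min), is_cancer_gene = flag,
                           stringsAsFactors = FALSE)
    gene_tab <- gene_tab[order(gene_tab$p), , drop = FALSE]
    rownames(gene_tab) <- NULL
  }
  list(hotspots = hits, genes = gene_tab)
}

#' Hypergeometric enrichment of a labelled class among hits
#'
#' One-sided Fisher's exact test (upper-tail hypergeometric): given `n_hits`
#' draws from a population of `N_total` items of which `K_labelled_total`
#' carry the label, is observing `k_hits_labelled` labelled items among the
#' hits more than expected? Used for the enrichment of cancer-CA profiles
#' among significant predictors and of known cancer genes among hotspot
#' genes.
#'
#' @param k_hits_labelled Labelled items among the hits.
#' @param n_hits Total hits.
#' @param K_labelled_total Labelled items in the population.
#' @param N_total Population size.
#' @param alternative `"greater"` (one-sided, default) or `"two.sided"`
#'   (delegated to [stats::fisher.test]).
#' @return List with `expected` (`n*K/N`), `odds_ratio`, and `p`.
#' @examples
#' fisher_enrichment(111, 166, 421, 869)  # expected ~80.4, p ~8.7e-8
#' @export
fisher_enrichment <- function(k_hits_labelled, n_hits, K_labelled_total,
                              N_total, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  k <- k_hits_labelled; n <- n_hits; K <- K_labelled_total; N <- N_total
  if (k < 0 || n < 0 || K < 0 || N < 0 || k > n || k > K || n > N || K > N) {
    stop("inconsistent counts")
  }
  expected <- n * K / N
  tab <- matrix(c(k, n - k, K - k, N - K - (n - k)), nrow = 2)
  if (any(tab < 0)) stop("inconsistent counts")
  if (alternative == "greater") {
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  }
  or <- (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2])
  list(expected = expected, odds_ratio = or, p = p)
}
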