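#' Probabilistic per-window mutational-signature burden
#'
#' For each signature, the expected number of its mutations in a window is
#' the sum of that signature's per-SNV probabilities over all SNVs falling
#' in the window — the mean of the underlying multinomial assignment, so
#' every potential signature exposure of an SNV contributes rather than
#' only its top-ranking signature. Per window, signature burdens sum
#' exactly to the all-SNV count.
#'
#' @param snvs Cohort-filtered mutation records (`chrom`, `pos`,
#'   `sample_id`, `cohort`).
#' @param probs Signature probability table from [read_signature_probs()]:
#'   key columns `chrom`, `pos`, `sample_id` plus one column per signature.
#' @param grid A filtered `window_grid`.
#' @param cohort Cohort label, or `"pancancer"` to pool all records.
#' @return Named list of `burden_vector`s, one per signature
#'   (`mutation_class` set to the signature id).
#' @export
signature_burden <- function(snvs, probs, grid, cohort) {
  asg <- .assign_signature_rows(snvs, probs, grid, cohort)
  sig_cols <- asg$sig_cols
  burdens <- lapply(sig_cols, function(s) {
    counts <- numeric(nrow(grid))
    if (length(asg$window) > 0) {
      sums <- tapply(asg$probs[[s]], asg$window, sum)
      counts[as.integer(names(sums))] <- as.numeric(sums)
    }
    burden_vector(cohort, s, counts)
  })
  names(burdens) <- sig_cols
  burdens
}

#' Top-ranked per-window signature burden
#'
#' Alternative assignment: each SNV contributes a full count of 1 to its
#' maximum-probability signature. Ties are broken by lexicographic
#' signature id for determinism. Per window, the top-ranked burdens sum
#' exactly to the integer SNV count.
#'
#' @inheritParams signature_burden
#' @return Named list of `burden_vector`s, one per signature.
#' @export
top_signature_burden <- function(snvs, probs, grid, cohort) {
  asg <- .assign_signature_rows(snvs, probs, grid, cohort)
  sig_cols <- sort(asg$sig_cols)
  pm <- as.matrix(asg$probs[, sig_cols, drop = FALSE])
  top <- if (nrow(pm) > 0) sig_cols[max.col(pm, ties.method = "first")] else character(0)
  burdens <- lapply(asg$sig_cols, function(s) {
    counts <- numeric(nrow(grid))
    sel <- top == s
    if (any(sel)) {
      tab <- table(asg$window[sel])
      counts[as.integer(names(tab))] <- as.numeric(tab)
    }
    burden_vector(cohort, s, counts)
  })
  names(burdens) <- asg$sig_cols
  burdens
}

# Shared lookup: map cohort SNVs to windows and to their probability rows.
.assign_signature_rows <- function(snvs, probs, grid, cohort) {
  stopifnot(inherits(grid, "window_grid"))
  rec <- if (identical(cohort, "pancancer")) snvs else snvs[snvs$cohort == cohort, , drop = FALSE]
  key <- c("chrom", "pos", "sample_id")
  sig_cols <- setdiff(names(probs), key)
  idx <- match(paste(rec$chrom, rec$pos, rec$sample_id),
               paste(probs$chrom, probs$pos, probs$sample_id))
  if (anyNA(idx)) {
    bad <- paste(rec$chrom, rec$pos, rec$sample_id)[is.na(idx)]
    stop("SNVs without signature probabilities: ",
         paste(utils::head(bad, 5), collapse = "; "),
         if (sum(is.na(idx)) > 5) sprintf(" (and %d more)", sum(is.na(idx)) - 5) else "")
  }
  gr <- GenomicRanges::GRanges(rec$chrom, IRanges::IRanges(rec$pos, rec$pos))
  hits <- GenomicRanges::findOverlaps(gr, grid_as_granges(grid))
  qh <- S4Vectors::queryHits(hits)
  list(window = S4Vectors::subjectHits(hits),
       probs = probs[idx[qh], , drop = FALSE],
       sig_cols = sig_cols)
}

#' Filter low-frequency signatures by genome-wide burden
#'
#' A signature is retained in a cohort only when its summed (probabilistic)
#' burden reaches `min_total_snvs` genome wide; the default of 20,000
#' removes signatures too sparse for stable regional modelling. The bound
#' is inclusive: exactly 20,000 expected SNVs is kept.
#'
#' @param burdens Named list of signature `burden_vector`s for one cohort.
#' @param min_total_snvs Retention threshold, default 20000.
#' @return Character vector of retained signature ids (possibly empty, with
#'   a warning).
#' @export
filter_signatures <- function(burdens, min_total_snvs = 20000) {
  totals <- vapply(burdens, function(b) sum(b$counts), numeric(1))
  keep <- names(totals)[totals >= min_total_snvs]
  if (length(keep) == 0) warning("no signature passes the burden filter")
  keep
}

#' Compare model accuracy across signature etiology classes
#'
#' Fits `adjR2 ~ class + covariate` by ordinary least squares, where the
#' covariate is the average per-window signature burden, so that classes
#' are compared at matched overall mutation load. Reports the ANOVA F-test
#' for the class term and pairwise class contrasts (emmeans, Tukey
#' adjusted).
#'
#' @param accuracy_table data.frame with columns `cohort`, `signature`,
#'   `adjR2`.
#' @param class_map Named character vector mapping signature id to etiology
#'   class (e.g. AID/APOBEC, DNA-repair, carcinogen, unknown/other, SBS5/40,
#'   SBS1).
#' @param covariate Numeric vector aligned with `accuracy_table` rows:
#'   mean per-window burden of that (cohort, signature).
#' @return List with `class_p` (F-test p-value for the class term),
#'   `anova` (the ANOVA table) and `contrasts` (pairwise class contrasts).
#' @export
class_accuracy_test <- function(accuracy_table, class_map, covariate) {
  cls <- class_map[accuracy_table$signature]
  if (anyNA(cls)) stop("signatures missing from class map: ",
                       paste(unique(accuracy_table$signature[is.na(cls)]), collapse = ", "))
  dat <- data.frame(adjR2 = accuracy_table$adjR2, class = factor(cls),
                    covariate = covariate)
  if (nlevels(dat$class) < 2) stop("insufficient replication")
  if (any(table(dat$class) < 2)) stop("insufficient replication")
  fit <- stats::lm(adjR2 ~ class + covariate, data = dat)
  if (any(is.na(stats::coef(fit)))) stop("insufficient replication")
  an <- stats::anova(fit)
  # marginal F-test for the class term, adjusted for the burden covariate
  marg <- stats::drop1(fit, scope = ~class, test = "F")
  emm <- emmeans::emmeans(fit, "class")
  ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise"))
  list(class_p = marg[["Pr(>F)"]][2], anova = an, contrasts = ctr)
}
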