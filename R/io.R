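#' Read a chrom.sizes table
#'
#' @param path Two-column headerless TSV: chromosome name, length in bp.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  structure(tab$length, names = tab$chrom)
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph file (0-based half-open intervals with a value).
#' @return GRanges with a `score` column, suitable for [aggregate_track()].
#' @export
read_bedgraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' Read somatic SNVs from a tab-separated table
#'
#' Expects a header with columns `chrom`, `pos`, `ref`, `alt`, `sample_id`,
#' `cohort`; an optional `context` column (3-mer) is carried through.
#' Indels (multi-base or missing alleles) and variants on sex chromosomes
#' are rejected at parse time. Positions are 1-based (VCF convention).
#'
#' @param path Path to the TSV.
#' @return data.frame of validated mutation records.
#' @export
read_mutations <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  validate_mutations(tab)
}

#' Validate a mutation record table
#'
#' Applies the parse-time exclusions: single-base ref/alt in `{A,C,G,T}`
#' with `ref != alt`, and no sex-chromosome variants.
#'
#' @param tab data.frame with at least `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`, `cohort`.
#' @return The filtered, validated data.frame.
#' @export
validate_mutations <- function(tab) {
  need <- c("chrom", "pos", "ref", "alt", "sample_id", "cohort")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) stop("missing mutation columns: ", paste(missing, collapse = ", "))
  bases <- c("A", "C", "G", "T")
  snv <- tab$ref %in% bases & tab$alt %in% bases & tab$ref != tab$alt
  if (any(!snv)) {
    message(sum(!snv), " non-SNV record(s) (indels or invalid alleles) removed")
    tab <- tab[snv, , drop = FALSE]
  }
  sex <- tab$chrom %in% c("chrX", "chrY", "X", "Y")
  if (any(sex)) {
    message(sum(sex), " sex-chromosome variant(s) removed")
    tab <- tab[!sex, , drop = FALSE]
  }
  if (any(tab$pos < 1)) stop("positions must be 1-based positive")
  rownames(tab) <- NULL
  tab
}

#' Read per-SNV signature probabilities
#'
#' @param path TSV with key columns `chrom`, `pos`, `sample_id` followed by
#'   one numeric column per signature; each row must sum to 1 (within 1e-6).
#' @return data.frame with key columns and signature probability columns.
#' @export
read_signature_probs <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  key <- c("chrom", "pos", "sample_id")
  if (!all(key %in% names(tab))) stop("signature table needs chrom/pos/sample_id keys")
  sig_cols <- setdiff(names(tab), key)
  if (length(sig_cols) == 0) stop("no signature columns")
  sums <- rowSums(tab[, sig_cols, drop = FALSE])
  if (any(abs(sums - 1) > 1e-6)) stop("signature probabilities must sum to 1 per SNV")
  tab
}

#' Read gene annotations from BED
#'
#' @param path BED file (>= 4 columns: chrom, start, end, name), 0-based
#'   half-open.
#' @param cancer_genes Optional character vector (or path to a one-id-per-line
#'   file) of known cancer gene ids used to set `is_cancer_gene`.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `is_cancer_gene`.
#' @export
read_genes_bed <- function(path, cancer_genes = NULL) {
  bed <- rtracklayer::import(path, format = "BED")
  genes <- data.frame(gene_id = bed$name,
                      chrom = as.character(GenomicRanges::seqnames(bed)),
                      start = GenomicRanges::start(bed) - 1,
                      end = GenomicRanges::end(bed),
                      stringsAsFactors = FALSE)
  if (!is.null(cancer_genes)) {
    if (length(cancer_genes) == 1 && file.exists(cancer_genes)) {
      cancer_genes <- readLines(cancer_genes)
    }
    genes$is_cancer_gene <- genes$gene_id %in% cancer_genes
  } else {
    genes$is_cancer_gene <- FALSE
  }
  genes
}

#' Write the window grid as BED4
#'
#' @param grid A `window_grid`.
#' @param path Output path; names are `chrom:start-end`.
#' @export
write_windows_bed <- function(grid, path) {
  bed <- data.frame(grid$chrom, format(grid$start, scientific = FALSE, trim = TRUE),
                    format(grid$end, scientific = FALSE, trim = TRUE),
                    sprintf("%s:%s-%s", grid$chrom,
                            format(grid$start, scientific = FALSE, trim = TRUE),
                            format(grid$end, scientific = FALSE, trim = TRUE)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Write per-window track matrix and its metadata companion
#'
#' @param tracks List of `track_profile` objects.
#' @param grid The `window_grid` they are aligned to.
#' @param matrix_path Output TSV (rows = windows, columns = track ids).
#' @param meta_path Output TSV (`track_id`, `feature_class`, `tissue`,
#'   `rt_phase`).
#' @export
write_track_matrix <- function(tracks, grid, matrix_path, meta_path) {
  m <- tracks_matrix(tracks)
  out <- data.frame(window = sprintf("%s:%s-%s", grid$chrom,
                                     format(grid$start, scientific = FALSE, trim = TRUE),
                                     format(grid$end, scientific = FALSE, trim = TRUE)),
                    m, check.names = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tracks_metadata(tracks), meta_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Write a burden vector keyed by window
#'
#' @param burden A `burden_vector`.
#' @param grid Its `window_grid`.
#' @param path Output TSV path.
#' @export
write_burden <- function(burden, grid, path) {
  out <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                    cohort = burden$cohort, mutation_class = burden$mutation_class,
                    count = burden$counts)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
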