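# Extract one ranger tree into the flat arrays the C++ attribution code uses.
.ranger_tree_arrays <- function(forest, tree_idx) {
  ti <- ranger::treeInfo(forest, tree_idx)
  leaf <- ti$terminal
  list(left = as.integer(ifelse(leaf, -1L, ti$leftChild)),
       right = as.integer(ifelse(leaf, -1L, ti$rightChild)),
       feature = as.integer(ifelse(leaf, -1L, ti$splitvarID)),
       threshold = as.numeric(ifelse(leaf, 0, ti$splitval)),
       value = as.numeric(ifelse(leaf, ti$prediction, 0)))
}

#' SHAP attributions for a burden forest
#'
#' Computes exact tree-path-dependent Shapley additive attributions for
#' every window and track: the signed contribution of each epigenome track
#' to the model's predicted burden in each window. Attributions satisfy
#' local accuracy — for every window, `base_value` plus the row sum of the
#' attribution matrix equals the ensemble prediction.
#'
#' The model should be trained on all windows (a full-data fit), and
#' attributions are computed for those same windows by default.
#'
#' @param fit A [fit_forest()] result.
#' @param features Matrix of windows to explain; defaults to the training
#'   windows. Columns must match the fit's features exactly.
#' @param tracks Optional character vector restricting the returned
#'   columns (e.g. significant predictors only); the attribution is always
#'   computed from the full model.
#' @return A `shap_matrix`: windows x tracks attribution matrix with
#'   attribute `base_value`.
#' @export
shap_attributions <- function(fit, features = fit$features, tracks = NULL) {
  stopifnot(inherits(fit, "burden_fit"))
  features <- as.matrix(features)
  if (!identical(colnames(features), colnames(fit$features))) {
    stop("feature matrix misaligned with the fitted model")
  }
  trees <- lapply(seq_len(fit$forest$num.trees),
                  function(t) .ranger_tree_arrays(fit$forest, t))
  res <- .treeshap_forest(trees, fit$features, features)
  phi <- res$phi
  colnames(phi) <- colnames(fit$features)
  if (!is.null(tracks)) {
    missing <- setdiff(tracks, colnames(phi))
    if (length(missing) > 0) stop("unknown tracks: ", paste(missing, collapse = ", "))
    phi <- phi[, tracks, drop = FALSE]
  }
  structure(phi, base_value = res$base_value, class = c("shap_matrix", "matrix"))
}

#' Correlate a track's values with its own SHAP attributions
#'
#' The sign of the Spearman correlation between a track's per-window
#' signal and its attribution column summarises the direction of its
#' association with regional burden: chromatin-accessibility tracks are
#' expected to correlate negatively (open chromatin, fewer mutations),
#' late-replication tracks positively.
#'
#' @param shap A `shap_matrix` from [shap_attributions()].
#' @param track_values Per-window signal of the track (aligned windows).
#' @param track_id Column of `shap` to use.
#' @return List with `rho` and `p` (Spearman); both `NA` with a message
#'   when either input is constant.
#' @export
shap_track_correlation <- function(shap, track_values, track_id) {
  stopifnot(track_id %in% colnames(shap))
  attr_col <- shap[, track_id]
  if (length(track_values) != length(attr_col)) stop("window counts differ")
  if (stats::sd(track_values) == 0 || stats::sd(attr_col) == 0) {
    message("constant input: correlation undefined for ", track_id)
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(track_values, attr_col,
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
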