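# Per-tree out-of-bag machinery shared by incMSE and its resampling wrappers.
.oob_tree_mse <- function(forest, x, y) {
  preds <- predict(forest, data = x, predict.all = TRUE,
                   num.threads = 1)$predictions
  inbag <- forest$inbag.counts
  vapply(seq_along(inbag), function(t) {
    oob <- inbag[[t]] == 0
    mean((y[oob] - preds[oob, t])^2)
  }, numeric(1))
}

#' Permutation feature importance (incMSE)
#'
#' The classic forest importance: for each track, its values are permuted
#' across windows and the out-of-bag mean squared error is recomputed per
#' tree; incMSE is the percent increase of the mean OOB MSE relative to the
#' unpermuted model, averaged over `n_repeat` independent permutations. A
#' track unrelated to the response scores around zero; an informative track
#' scores large and positive.
#'
#' @param fit A [fit_forest()] result.
#' @param n_repeat Number of permutation repeats averaged per track.
#' @param seed Seed for the permutations (defaults to the fit's spec seed).
#' @return Named numeric vector of incMSE percentages, one per track.
#' @export
inc_mse <- function(fit, n_repeat = 5, seed = fit$spec$seed) {
  stopifnot(inherits(fit, "burden_fit"))
  x <- fit$features
  y <- fit$response
  mse_orig <- mean(.oob_tree_mse(fit$forest, x, y))
  set.seed(seed)
  n <- nrow(x)
  out <- vapply(seq_len(ncol(x)), function(j) {
    inc <- vapply(seq_len(n_repeat), function(r) {
      xp <- x
      xp[, j] <- x[sample.int(n), j]
      mean(.oob_tree_mse(fit$forest, xp, y))
    }, numeric(1))
    100 * (mean(inc) - mse_orig) / mse_orig
  }, numeric(1))
  names(out) <- colnames(x)
  out
}

#' Permutation-refit null distribution for track importance
#'
#' Fits the forest `n_perm` times on randomly permuted response vectors
#' (burden reassigned across windows), recording each track's incMSE under
#' the null of no association. A track is called significant when its
#' observed incMSE strictly exceeds every null value — empirical
#' `P < 1/n_perm` (`P < 0.001` at the full 1000 permutations). Ties with
#' the null maximum are not significant.
#'
#' @param features Windows x tracks matrix.
#' @param response `burden_vector` or numeric response.
#' @param spec A [model_spec()].
#' @param n_perm Number of response permutations (refits).
#' @param n_repeat Permutation repeats inside each incMSE evaluation
#'   (1 for the null refits keeps the cost linear in `n_perm`).
#' @return data.frame (`importance_result`) with `track_id`,
#'   `inc_mse`, `empirical_p`, `significant`; the null matrix
#'   (`n_perm` x tracks) is attached as attribute `null_values`.
#' @export
permutation_null <- function(features, response, spec = model_spec(),
                             n_perm = 1000, n_repeat = 1) {
  y <- if (inherits(response, "burden_vector")) response$counts else as.numeric(response)
  features <- as.matrix(features)
  if (n_perm < 20) warning("null too coarse: n_perm < 20")
  obs_fit <- fit_forest(features, y, spec)
  observed <- inc_mse(obs_fit, n_repeat = max(n_repeat, 1), seed = spec$seed)

  set.seed(spec$seed + 1L)
  perm_seeds <- sample.int(.Machine$integer.max, n_perm)
  null_mat <- matrix(NA_real_, n_perm, ncol(features),
                     dimnames = list(NULL, colnames(features)))
  for (k in seq_len(n_perm)) {
    set.seed(perm_seeds[k])
    y_perm <- y[sample.int(length(y))]
    sub_spec <- spec
    sub_spec$seed <- perm_seeds[k]
    null_fit <- fit_forest(features, y_perm, sub_spec)
    null_mat[k, ] <- inc_mse(null_fit, n_repeat = n_repeat, seed = perm_seeds[k])
  }
  emp_p <- vapply(seq_len(ncol(features)), function(j) {
    mean(null_mat[, j] >= observed[j])
  }, numeric(1))
  res <- data.frame(track_id = colnames(features),
                    inc_mse = as.numeric(observed),
                    empirical_p = emp_p,
                    significant = vapply(seq_len(ncol(features)), function(j) {
                      observed[j] > max(null_mat[, j])
                    }, logical(1)),
                    stringsAsFactors = FALSE)
  attr(res, "null_values") <- null_mat
  attr(res, "n_perm") <- n_perm
  class(res) <- c("importance_result", "data.frame")
  res
}

#' Bootstrap confidence intervals for track importance
#'
#' Windows (predictor and response values jointly) are resampled with
#' replacement; the forest is refit and incMSE recorded per iteration,
#' yielding percentile confidence intervals and standard deviations of the
#' importance of each track.
#'
#' @inheritParams permutation_null
#' @param n_boot Number of bootstrap resamples.
#' @return data.frame with `track_id`, `mean`, `sd`, `ci_low`, `ci_high`
#'   (2.5/97.5 percentiles); the per-iteration matrix is attached as
#'   attribute `boot_values`. A single-iteration run is flagged degenerate.
#' @export
bootstrap_importance <- function(features, response, spec = model_spec(),
                                 n_boot = 1000, n_repeat = 1) {
  y <- if (inherits(response, "burden_vector")) response$counts else as.numeric(response)
  features <- as.matrix(features)
  n <- nrow(features)
  set.seed(spec$seed + 2L)
  boot_seeds <- sample.int(.Machine$integer.max, n_boot)
  boot_mat <- matrix(NA_real_, n_boot, ncol(features),
                     dimnames = list(NULL, colnames(features)))
  for (k in seq_len(n_boot)) {
    set.seed(boot_seeds[k])
    idx <- sample.int(n, n, replace = TRUE)
    sub_spec <- spec
    sub_spec$seed <- boot_seeds[k]
    bfit <- fit_forest(features[idx, , drop = FALSE], y[idx], sub_spec)
    boot_mat[k, ] <- inc_mse(bfit, n_repeat = n_repeat, seed = boot_seeds[k])
  }
  degenerate <- n_boot < 2
  if (degenerate) warning("n_boot < 2: confidence interval degenerate")
  res <- data.frame(track_id = colnames(features),
                    mean = colMeans(boot_mat),
                    sd = apply(boot_mat, 2, stats::sd),
                    ci_low = apply(boot_mat, 2, stats::quantile, 0.025),
                    ci_high = apply(boot_mat, 2, stats::quantile, 0.975),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "boot_values") <- boot_mat
  attr(res, "degenerate") <- degenerate
  res
}
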