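#' Random-forest model specification
#'
#' Hyperparameters of the regional-burden regressions. Defaults are the
#' full-scale analysis settings: 1000 trees, one third of predictors tried
#' at each split, and 1000 Monte-Carlo cross-validation splits holding out
#' 20 percent of windows. Reduced settings (e.g. `n_trees = 100`,
#' `n_splits = 100`) are appropriate for exploratory runs and are used
#' throughout the test suite.
#'
#' @param n_trees Number of trees per forest.
#' @param mtry_fraction Fraction of predictors tried at each split; the
#'   per-fit `mtry` is `max(1, floor(p * mtry_fraction))`.
#' @param seed Master seed; every downstream source of randomness (splits,
#'   tree growing, permutations) is derived from it.
#' @param train_fraction Fraction of windows used for training per split.
#' @param n_splits Number of Monte-Carlo cross-validation splits.
#' @return A `model_spec` list.
#' @export
model_spec <- function(n_trees = 1000, mtry_fraction = 1 / 3, seed = 1,
                       train_fraction = 0.8, n_splits = 1000) {
  stopifnot(n_trees >= 1, mtry_fraction > 0, mtry_fraction <= 1,
            train_fraction > 0, train_fraction < 1, n_splits >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry_fraction = mtry_fraction,
                 seed = as.integer(seed), train_fraction = train_fraction,
                 n_splits = as.integer(n_splits)),
            class = "model_spec")
}

.mtry <- function(p, spec) max(1L, floor(p * spec$mtry_fraction))

#' Adjusted R-squared
#'
#' Variance explained, penalised for model complexity:
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)` with
#' `R2 = 1 - SSres / SStot`. Here `p` is the number of epigenome profiles
#' used as predictors.
#'
#' @param observed Observed response values.
#' @param predicted Model predictions on the same windows.
#' @param p_predictors Number of predictors in the model.
#' @return The adjusted R-squared (at most 1; negative when the model is
#'   worse than the mean).
#' @examples
#' adjusted_r2(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8), 1)  # 0.97
#' @export
adjusted_r2 <- function(observed, predicted, p_predictors) {
  n <- length(observed)
  stopifnot(length(predicted) == n)
  if (n <= p_predictors + 1) stop("adjustment undefined: n <= p + 1")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed response has zero variance")
  r2 <- 1 - sum((observed - predicted)^2) / ss_tot
  1 - (1 - r2) * (n - 1) / (n - p_predictors - 1)
}

#' Fit a random-forest regression of burden on epigenome tracks
#'
#' @param features Numeric matrix, windows x tracks (column names = track
#'   ids).
#' @param response A `burden_vector` or numeric vector aligned with the
#'   feature rows.
#' @param spec A [model_spec()].
#' @return A `burden_fit`: the ranger ensemble plus out-of-bag predictions
#'   and residuals (`observed - OOB prediction`) per window. Deterministic
#'   given `spec$seed`.
#' @export
fit_forest <- function(features, response, spec = model_spec()) {
  y <- if (inherits(response, "burden_vector")) response$counts else as.numeric(response)
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(y))
  if (ncol(features) < 2) stop("at least 2 features required")
  if (stats::var(y) == 0) stop("degenerate response")
  fit <- ranger::ranger(y = y, x = features,
                        num.trees = spec$n_trees,
                        mtry = .mtry(ncol(features), spec),
                        seed = spec$seed, num.threads = 1,
                        keep.inbag = TRUE)
  oob <- fit$predictions
  structure(list(forest = fit, features = features, response = y,
                 oob_predictions = oob, residuals = y - oob, spec = spec),
            class = "burden_fit")
}

#' Predict from a burden fit
#'
#' @param object A `burden_fit`.
#' @param newdata Feature matrix; defaults to the training windows.
#' @param ... Unused.
#' @return Numeric vector of ensemble predictions.
#' @export
predict.burden_fit <- function(object, newdata = object$features, ...) {
  ranger::predictions(predict(object$forest, data = as.matrix(newdata),
                              num.threads = 1))
}

#' Paired comparison of cancer vs normal epigenome predictors
#'
#' Runs two random-forest regressions in a joint Monte-Carlo
#' cross-validation: at each split one shared random partition of windows
#' (80/20 by default) trains a cancer-arm model (cancer CA tracks + the
#' shared RT tracks) and a normal-arm model (normal CA tracks + the same
#' RT tracks) on identical training windows, and
#' `delta = adjR2(cancer arm) - adjR2(normal arm)` is evaluated on the
#' identical held-out windows. The per-split delta distribution yields the
#' median, a 95 percent percentile confidence interval, and an empirical
#' p-value: the fraction of splits whose delta falls strictly on the
#' opposite side of zero from the median (splits with delta exactly zero
#' count half). When no split crosses zero the p-value is reported as
#' below `1/n_splits`.
#'
#' Both arm fits within a split use the same forest seed, so swapping the
#' arms negates the delta distribution exactly.
#'
#' @param cancer_features Matrix of cancer-CA tracks (windows x tracks).
#' @param normal_features Matrix of normal-CA tracks.
#' @param rt_features Matrix of RT tracks shared by both arms (may have
#'   zero columns).
#' @param response `burden_vector` or numeric response per window.
#' @param spec A [model_spec()].
#' @return An `mccv_comparison`: `delta` (per split), `median_delta`,
#'   `ci` (2.5/97.5 percentiles), `p` and `p_report`, and the per-split
#'   adjusted R-squared of each arm.
#' @export
mccv_compare <- function(cancer_features, normal_features, rt_features,
                         response, spec = model_spec()) {
  y <- if (inherits(response, "burden_vector")) response$counts else as.numeric(response)
  cancer_features <- as.matrix(cancer_features)
  normal_features <- as.matrix(normal_features)
  rt_features <- as.matrix(rt_features)
  if (ncol(cancer_features) == 0 || ncol(normal_features) == 0) {
    stop("both comparison arms must be non-empty")
  }
  n <- length(y)
  stopifnot(nrow(cancer_features) == n, nrow(normal_features) == n)
  if (ncol(rt_features) > 0) stopifnot(nrow(rt_features) == n)
  arm_c <- cbind(cancer_features, rt_features)
  arm_n <- cbind(normal_features, rt_features)
  n_train <- round(spec$train_fraction * n)
  if (n - n_train < 10) stop("fewer than 10 test windows")

  set.seed(spec$seed)
  splits <- replicate(spec$n_splits, sample.int(n, n_train), simplify = FALSE)
  fit_seeds <- sample.int(.Machine$integer.max, spec$n_splits)

  adj_c <- adj_n <- numeric(spec$n_splits)
  for (i in seq_len(spec$n_splits)) {
    tr <- splits[[i]]
    te <- setdiff(seq_len(n), tr)
    adj_c[i] <- .arm_adjr2(arm_c, y, tr, te, spec, fit_seeds[i])
    adj_n[i] <- .arm_adjr2(arm_n, y, tr, te, spec, fit_seeds[i])
  }
  delta <- adj_c - adj_n
  med <- stats::median(delta)
  if (med > 0) {
    opp <- sum(delta < 0) + 0.5 * sum(delta == 0)
  } else if (med < 0) {
    opp <- sum(delta > 0) + 0.5 * sum(delta == 0)
  } else {
    opp <- spec$n_splits / 2
  }
  p <- opp / spec$n_splits
  structure(list(delta = delta, median_delta = med,
                 ci = stats::quantile(delta, c(0.025, 0.975), names = FALSE),
                 p = p,
                 p_report = if (opp == 0) sprintf("< %g", 1 / spec$n_splits)
                            else format(p),
                 adjr2_cancer = adj_c, adjr2_normal = adj_n,
                 n_splits = spec$n_splits),
            class = "mccv_comparison")
}

.arm_adjr2 <- function(arm, y, tr, te, spec, seed) {
  fit <- ranger::ranger(y = y[tr], x = arm[tr, , drop = FALSE],
                        num.trees = spec$n_trees,
                        mtry = .mtry(ncol(arm), spec),
                        seed = seed, num.threads = 1, oob.error = FALSE)
  pred <- ranger::predictions(predict(fit, data = arm[te, , drop = FALSE],
                                      num.threads = 1))
  adjusted_r2(y[te], pred, ncol(arm))
}

#' @export
print.mccv_comparison <- function(x, ...) {
  cat("Paired MCCV comparison (", x$n_splits, " splits)\n", sep = "")
  cat(sprintf("  median delta adj.R2: %.4f  [95%% CI %.4f, %.4f]\n",
              x$median_delta, x$ci[1], x$ci[2]))
  cat(sprintf("  empirical p: %s\n", x$p_report))
  cat(sprintf("  median adj.R2 cancer arm: %.4f, normal arm: %.4f\n",
              stats::median(x$adjr2_cancer), stats::median(x$adjr2_normal)))
  invisible(x)
}

#' Down-sample the larger arm to balance predictor counts
#'
#' To verify that an accuracy difference between arms is not driven by one
#' arm simply containing more tracks, the larger arm is randomly subsampled
#' without replacement to the smaller arm's size, repeatedly.
#'
#' @param cancer_ids Character vector of cancer-arm track ids.
#' @param normal_ids Character vector of normal-arm track ids.
#' @param n_iter Number of subsampling iterations.
#' @param seed Seed making the subset sequence reproducible.
#' @return List of length `n_iter`; each element has `cancer` and `normal`
#'   id vectors of equal length.
#' @export
downsample_arms <- function(cancer_ids, normal_ids, n_iter = 1000, seed = 1) {
  stopifnot(length(cancer_ids) > 0, length(normal_ids) > 0)
  k <- min(length(cancer_ids), length(normal_ids))
  set.seed(seed)
  lapply(seq_len(n_iter), function(i) {
    list(cancer = if (length(cancer_ids) > k) sample(cancer_ids, k) else cancer_ids,
         normal = if (length(normal_ids) > k) sample(normal_ids, k) else normal_ids)
  })
}
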