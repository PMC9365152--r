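#' Generate a synthetic window grid
#'
#' Builds a deterministic grid of `n_windows` equal windows spread over
#' `n_chrom` synthetic chromosomes (an extra sub-window remainder is added
#' to each chromosome so trailing-window dropping is exercised).
#'
#' @param n_windows Total number of windows.
#' @param window_size Window width in bp.
#' @param n_chrom Number of chromosomes to spread the windows over.
#' @return A `window_grid` with mappability 1 everywhere.
#' @export
generate_grid <- function(n_windows = 500, window_size = 1e6, n_chrom = 5) {
  per <- rep(n_windows %/% n_chrom, n_chrom)
  extra <- n_windows %% n_chrom
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  sizes <- per * window_size + floor(window_size / 3)
  names(sizes) <- paste0("chr", seq_len(n_chrom))
  build_windows(sizes, window_size)
}

#' Generate synthetic epigenome tracks with planted effects
#'
#' Draws a latent per-window accessibility field `L` and a latent
#' replication-timing field `R` (standard normal, independent). Each CA
#' track is `a * L + noise`; cancer-CA tracks get a larger loading `a`
#' than normal-CA tracks by default, emulating the finding that cancer and
#' normal epigenomes both track regional burden but cancer CA does so more
#' faithfully. RT tracks alternate early/late cell-cycle phases with
#' opposite loadings on `R` (late positive). Optional pure-noise tracks
#' have loading 0.
#'
#' @param grid A `window_grid`.
#' @param n_cancer,n_normal Number of cancer-CA / normal-CA tracks.
#' @param n_rt Number of RT tracks (phases cycle G1b, S1, S2, S3, S4, G2;
#'   G1b/S1/S2 load negatively on `R`, S3/S4/G2 positively).
#' @param n_noise Number of additional tracks with zero loading.
#' @param a_cancer,a_normal Latent loadings of the CA classes.
#' @param a_rt Absolute latent loading of the RT tracks.
#' @param noise_sd Standard deviation of the per-track Gaussian noise.
#' @param seed Seed; identical seeds reproduce tracks bit-identically.
#' @return List with `tracks` (list of `track_profile`) and `truth`
#'   (latent fields, per-track loadings — 0 for noise tracks — and all
#'   parameters).
#' @export
generate_tracks <- function(grid, n_cancer = 20, n_normal = 20, n_rt = 6,
                            n_noise = 0, a_cancer = 1, a_normal = 0.1,
                            a_rt = 1, noise_sd = 0.5, seed = 1) {
  n <- nrow(grid)
  set.seed(seed)
  latent_ca <- stats::rnorm(n)
  latent_rt <- stats::rnorm(n)
  phases <- c("G1b", "S1", "S2", "S3", "S4", "G2")
  late <- c("S3", "S4", "G2")

  tracks <- list()
  effects <- numeric(0)
  add <- function(id, class, a, latent, tissue, phase = NULL) {
    vals <- a * latent + stats::rnorm(n, sd = noise_sd)
    tracks[[length(tracks) + 1]] <<- track_profile(id, class, vals,
                                                   tissue = tissue,
                                                   rt_phase = phase)
    effects[id] <<- a
  }
  for (i in seq_len(n_cancer)) {
    add(sprintf("cancerCA_%02d", i), "cancer_CA", a_cancer, latent_ca, "tumourA")
  }
  for (i in seq_len(n_normal)) {
    add(sprintf("normalCA_%02d", i), "normal_CA", a_normal, latent_ca, "tissueA")
  }
  for (i in seq_len(n_rt)) {
    ph <- phases[(i - 1) %% 6 + 1]
    sign <- if (ph %in% late) 1 else -1
    add(sprintf("RT_%s_%02d", ph, i), "RT", sign * a_rt, latent_rt,
        "cellline", phase = ph)
  }
  for (i in seq_len(n_noise)) {
    add(sprintf("noise_%02d", i), "normal_CA", 0, latent_ca, "noise")
  }
  truth <- list(latent_ca = latent_ca, latent_rt = latent_rt,
                effects = effects, seed = seed,
                params = list(n_cancer = n_cancer, n_normal = n_normal,
                              n_rt = n_rt, n_noise = n_noise,
                              a_cancer = a_cancer, a_normal = a_normal,
                              a_rt = a_rt, noise_sd = noise_sd))
  list(tracks = tracks, truth = truth)
}

#' Generate synthetic somatic mutations with planted hotspots and signatures
#'
#' Per-window mean burden follows a log-linear model on the latent fields:
#' `mu_w = mean_burden * exp(-beta_ca * L_w + beta_rt * R_w - c)` with `c`
#' centring the expectation at `mean_burden` — chromatin accessibility
#' suppresses mutations, late replication elevates them. A set of
#' `n_hotspots` windows (placed away from chromosome ends) has its mean
#' multiplied by `hotspot_factor`. Per-sample window counts are negative
#' binomial (overdispersed, as real regional burden is); SNV positions are
#' uniform and unique within each window.
#'
#' Each SNV carries a true signature label drawn from the cohort exposures
#' modulated spatially by `L` (`w_s(w) proportional to exposure_s *
#' exp(gamma_s * L_w)`) and a trinucleotide context drawn from its true
#' signature's context preference; the emitted probability vectors are the
#' exact posteriors `P(s | window, context)` under the generating mixture.
#'
#' @param grid A `window_grid`.
#' @param truth Truth object from [generate_tracks()] (supplies the latent
#'   fields).
#' @param n_samples Number of tumour genomes in the cohort.
#' @param mean_burden Expected SNV count per window (cohort total).
#' @param dispersion Negative-binomial size parameter per sample (smaller
#'   is more overdispersed).
#' @param beta_ca,beta_rt Log-scale effects of the latent CA / RT fields.
#' @param n_hotspots Number of planted excess-burden windows.
#' @param hotspot_factor Multiplicative burden excess in hotspot windows
#'   (1 disables planting).
#' @param exposures Named vector of cohort signature exposures (sums to 1).
#' @param gamma Named vector (same names) of spatial modulation strengths.
#' @param context_fidelity Probability that an SNV shows its true
#'   signature's preferred trinucleotide context.
#' @param cohort Cohort label stamped on the records.
#' @param seed Seed; full determinism.
#' @return List with `snvs` (mutation records incl. `context`), `probs`
#'   (exact per-SNV signature posteriors), `true_signatures` (per-SNV
#'   labels), `hotspot_windows` (grid row indices), `mu` (planted
#'   per-window expectation) and `mu_base` (without hotspots).
#' @export
generate_mutations <- function(grid, truth, n_samples = 50, mean_burden = 50,
                               dispersion = 2, beta_ca = 0.3, beta_rt = 0.2,
                               n_hotspots = 10, hotspot_factor = 3,
                               exposures = c(SBSa = 0.45, SBSb = 0.3, SBSc = 0.25),
                               gamma = c(SBSa = 0.8, SBSb = -0.8, SBSc = 0),
                               context_fidelity = 0.6,
                               cohort = "synthetic", seed = 1) {
  stopifnot(abs(sum(exposures) - 1) < 1e-8,
            identical(sort(names(exposures)), sort(names(gamma))),
            n_samples > 0, mean_burden > 0, dispersion > 0, hotspot_factor > 0)
  n <- nrow(grid)
  L <- truth$latent_ca
  R <- truth$latent_rt
  stopifnot(length(L) == n)
  set.seed(seed)

  mu_base <- mean_burden * exp(-beta_ca * L + beta_rt * R -
                                 (beta_ca^2 + beta_rt^2) / 2)
  hotspot_windows <- integer(0)
  if (n_hotspots > 0) {
    interior <- which(stats::ave(seq_len(n), grid$chrom, FUN = function(i) {
      seq_along(i) > 1 & seq_along(i) < length(i)
    }) == 1)
    hotspot_windows <- sort(sample(interior, n_hotspots))
  }
  mu <- mu_base
  mu[hotspot_windows] <- mu[hotspot_windows] * hotspot_factor

  counts <- matrix(stats::rnbinom(n * n_samples, size = dispersion,
                                  mu = rep(mu / n_samples, n_samples)),
                   nrow = n)
  per_window <- rowSums(counts)

  sigs <- names(exposures)
  n_sig <- length(sigs)
  # signature mixture per window and its preferred contexts
  wmat <- exp(outer(L, gamma[sigs]) + rep(log(exposures[sigs]), each = n))
  wmat <- wmat / rowSums(wmat)
  contexts <- c("ACA", "CCG", "TCT", "GCG", "ACG", "TCA")[seq_len(n_sig)]
  theta <- matrix((1 - context_fidelity) / (n_sig - 1), n_sig, n_sig,
                  dimnames = list(sigs, contexts))
  diag(theta) <- context_fidelity

  window_size <- attr(grid, "window_size")
  bases <- c("A", "C", "G", "T")
  total <- sum(per_window)
  w_idx <- rep.int(seq_len(n), per_window)
  # unique positions within each window (loop is over windows only)
  pos <- unlist(lapply(which(per_window > 0), function(w) {
    grid$start[w] + sample.int(window_size, per_window[w])
  }), use.names = FALSE)
  sample_ids <- sprintf("s%03d", seq_len(n_samples))
  sample_id <- rep.int(rep(sample_ids, n), as.vector(t(counts)))

  # true signature per SNV from its window mixture, context from its
  # signature's preference; all categorical draws vectorised via inverse CDF
  cw <- t(apply(wmat, 1, cumsum))
  si <- max.col(stats::runif(total) <= cw[w_idx, , drop = FALSE],
                ties.method = "first")
  cth <- t(apply(theta, 1, cumsum))
  ci <- max.col(stats::runif(total) <= cth[si, , drop = FALSE],
                ties.method = "first")
  true_sig <- sigs[si]
  ctx <- contexts[ci]
  ref <- substr(ctx, 2, 2)
  alt_choices <- t(vapply(bases, function(b) setdiff(bases, b), character(3)))
  alt <- alt_choices[cbind(match(ref, bases),
                           sample.int(3, total, replace = TRUE))]
  # exact posterior over signatures given window and context
  post <- wmat[w_idx, , drop = FALSE] * t(theta)[ci, , drop = FALSE]
  post <- post / rowSums(post)
  colnames(post) <- sigs

  snvs <- data.frame(chrom = grid$chrom[w_idx], pos = pos, ref = ref,
                     alt = alt, sample_id = sample_id, cohort = cohort,
                     context = ctx, stringsAsFactors = FALSE)
  probs <- data.frame(snvs[, c("chrom", "pos", "sample_id")], post,
                      stringsAsFactors = FALSE)
  rownames(snvs) <- rownames(probs) <- NULL
  list(snvs = snvs, probs = probs, true_signatures = true_sig,
       hotspot_windows = hotspot_windows, mu = mu, mu_base = mu_base,
       params = list(n_samples = n_samples, mean_burden = mean_burden,
                     dispersion = dispersion, beta_ca = beta_ca,
                     beta_rt = beta_rt, n_hotspots = n_hotspots,
                     hotspot_factor = hotspot_factor, exposures = exposures,
                     gamma = gamma, context_fidelity = context_fidelity,
                     seed = seed))
}

#' Generate synthetic gene annotations with cancer-gene flags
#'
#' Places one gene per randomly chosen window (guaranteeing non-overlap),
#' with a random sub-interval inside the window. Cancer-gene flags are
#' drawn without replacement with sampling weight `1 + hotspot_bias` for
#' genes on planted hotspot windows, so high bias concentrates flagged
#' genes on hotspots.
#'
#' @param grid A `window_grid`.
#' @param hotspot_windows Integer grid row indices of planted hotspots.
#' @param n_genes Number of genes (at most the number of windows).
#' @param n_cancer_genes Number of genes to flag.
#' @param hotspot_bias Additional flag weight on hotspot windows (0 =
#'   flags independent of hotspots).
#' @param seed Seed.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `is_cancer_gene`.
#' @export
generate_genes <- function(grid, hotspot_windows = integer(0), n_genes = 300,
                           n_cancer_genes = 30, hotspot_bias = 100, seed = 1) {
  stopifnot(n_cancer_genes <= n_genes, n_genes <= nrow(grid))
  set.seed(seed)
  win <- sort(sample.int(nrow(grid), n_genes))
  window_size <- attr(grid, "window_size")
  glen <- pmin(sample(seq(1e4, 5e4, by = 1e3), n_genes, replace = TRUE),
               window_size - 2)
  gstart <- grid$start[win] +
    vapply(glen, function(l) sample.int(window_size - l, 1), integer(1))
  weights <- 1 + hotspot_bias * (win %in% hotspot_windows)
  flagged <- sample.int(n_genes, n_cancer_genes, prob = weights)
  data.frame(gene_id = sprintf("G%04d", seq_len(n_genes)),
             chrom = grid$chrom[win], start = gstart, end = gstart + glen,
             is_cancer_gene = seq_len(n_genes) %in% flagged,
             stringsAsFactors = FALSE)
}

#' The default synthetic study scenario
#'
#' Bundles grid, tracks, mutations and genes at the package's reference
#' conditions: 500 windows of 1 Mbp, 20 cancer-CA + 20 normal-CA + 6 RT
#' tracks, 50 tumour genomes with about 50 SNVs per window, and 10 planted
#' hotspot windows with threefold excess burden biased onto flagged cancer
#' genes.
#'
#' @param seed Master seed; sub-seeds for each generator are derived from
#'   it.
#' @param n_windows,window_size Grid dimensions.
#' @param ... Overrides forwarded to [generate_mutations()].
#' @return List with `grid`, `tracks`, `truth`, `mutations`, `genes`.
#' @export
default_scenario <- function(seed = 1, n_windows = 500, window_size = 1e6, ...) {
  grid <- generate_grid(n_windows = n_windows, window_size = window_size)
  tr <- generate_tracks(grid, seed = seed)
  mut <- generate_mutations(grid, tr$truth, seed = seed + 1L, ...)
  n_genes <- min(300L, round(0.6 * n_windows))
  genes <- generate_genes(grid, mut$hotspot_windows, n_genes = n_genes,
                          n_cancer_genes = max(2L, round(0.1 * n_genes)),
                          seed = seed + 2L)
  list(grid = grid, tracks = tr$tracks, truth = tr$truth,
       mutations = mut, genes = genes)
}
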