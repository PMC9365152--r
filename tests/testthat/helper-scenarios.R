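# Shared small scenario builders (all deterministic under the given seed).

small_burden_scenario <- function(seed = 1, n_windows = 150, n_chrom = 3, ...) {
  grid <- generate_grid(n_windows, 1e6, n_chrom = n_chrom)
  tr <- generate_tracks(grid, n_cancer = 3, n_normal = 3, n_rt = 2, seed = seed)
  mut <- generate_mutations(grid, tr$truth, seed = seed + 1, ...)
  burden <- count_burden(mut$snvs, grid, "synthetic")
  list(grid = grid, tracks = tr$tracks, truth = tr$truth, mutations = mut,
       burden = burden, features = tracks_matrix(tr$tracks))
}

# two informative tracks on independent latents plus pure-noise tracks;
# used where importance splitting among collinear tracks must be avoided
independent_signal_scenario <- function(seed = 1, n_windows = 150) {
  grid <- generate_grid(n_windows, 1e6, n_chrom = 3)
  tr <- generate_tracks(grid, n_cancer = 1, n_normal = 0, n_rt = 1, n_noise = 4,
                        a_cancer = 1, a_rt = 1, noise_sd = 0.4, seed = seed)
  mut <- generate_mutations(grid, tr$truth, beta_ca = 0.5, beta_rt = 0.4,
                            mean_burden = 100, n_hotspots = 0, seed = seed + 1000)
  burden <- count_burden(mut$snvs, grid, "synthetic")
  list(grid = grid, tracks = tr$tracks, truth = tr$truth,
       burden = burden, features = tracks_matrix(tr$tracks),
       informative = names(tr$truth$effects)[tr$truth$effects != 0])
}
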