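# Shared fixtures, built in code at test time.

# Random canonical parameter sets drawn from the default sampling ranges.
random_params <- function(n, seed = 1L) {
  sample_labels(n, label_ranges(), seed = seed)
}

# Small clean dataset for fast regressor tests.
tiny_dataset <- function(n = 80L, seed = 7L, corruption = NULL,
                         split_fracs = c(train = 0.8, val = 0.2, test = 0),
                         grid = chi_grid(90L)) {
  labels <- sample_labels(n, seed = seed)
  build_dataset(labels,
    grid = grid, corruption = corruption,
    split_fracs = split_fracs, seed = seed
  )
}

# A unit-max wrapped-Gaussian bump used by peak-detection tests.
bump_curve <- function(center, sigma = 6, grid = chi_grid()) {
  d <- (grid$chi_centers - center + 180) %% 360 - 180
  ichi_curve(exp(-d^2 / (2 * sigma^2)), grid = grid)
}
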