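#' Corruption pipeline configuration
#'
#' Settings for the three-step corruption that makes clean simulated curves
#' statistically resemble experimental ones: Poisson counting noise, circular
#' blockwise masking, and random scaling of the maximum intensity.
#'
#' @param counts_level_range min/max expected peak counts for the Poisson
#'   step; the per-curve level is drawn log-uniformly from this interval.
#'   Use `c(Inf, Inf)` to disable the noise step.
#' @param mask_ratio fraction of bins to mask, in \[0, 1). Default 0.3, the
#'   ratio giving the lowest reconstruction error on experimental curves.
#' @param block_len_range min/max masked-block length in bins; spans
#'   beamstop-sized to module-gap-sized occlusions on a 360-bin grid.
#' @param scale_range interval for the random maximum intensity (default
#'   +/- 5 percent around 1).
#' @param noise one of `"poisson"` (default), `"gaussian"`,
#'   `"poisson+gaussian"` or `"none"`; alternatives are provided for noise
#'   ablations.
#' @param gaussian_sd relative sd of the Gaussian noise options.
#' @param seed integer seed from which per-step sub-seeds are derived.
#' @return an object of class `corruption_config`.
#' @export
corruption_config <- function(counts_level_range = c(200, 20000),
                              mask_ratio = 0.3,
                              block_len_range = c(5L, 60L),
                              scale_range = c(0.95, 1.05),
                              noise = c("poisson", "gaussian",
                                        "poisson+gaussian", "none"),
                              gaussian_sd = 0.02,
                              seed = 1L) {
  noise <- match.arg(noise)
  if (mask_ratio < 0 || mask_ratio >= 1) abort("`mask_ratio` must be in [0, 1).")
  if (length(block_len_range) != 2L || block_len_range[1] < 1 ||
      diff(block_len_range) < 0) {
    abort("`block_len_range` must be c(min, max) with min >= 1.")
  }
  if (length(scale_range) != 2L || diff(scale_range) < 0 ||
      scale_range[1] <= 0) {
    abort("`scale_range` must be a positive interval.")
  }
  structure(
    list(
      counts_level_range = counts_level_range,
      mask_ratio = mask_ratio,
      block_len_range = as.integer(block_len_range),
      scale_range = scale_range,
      noise = noise,
      gaussian_sd = gaussian_sd,
      seed = as.integer(seed)
    ),
    class = "corruption_config"
  )
}

#' Add Poisson counting noise to a curve
#'
#' Each bin is replaced by a Poisson draw with mean
#' `intensity / max(intensity) * counts_level` and rescaled back to the
#' original intensity scale, emulating photon-counting statistics at a given
#' peak count level. The validity mask is unchanged.
#'
#' @param curve an [ichi_curve()].
#' @param counts_level expected counts at the curve maximum (> 0); `Inf`
#'   returns the curve unchanged.
#' @param seed integer seed.
#' @return corrupted [ichi_curve()].
#' @export
add_poisson_noise <- function(curve, counts_level, seed = 1L) {
  stopifnot(inherits(curve, "ichi_curve"))
  if (counts_level <= 0) abort("`counts_level` must be > 0.")
  if (any(curve$intensity < 0)) abort("intensities must be >= 0.")
  m <- max(curve$intensity)
  if (m == 0 || is.infinite(counts_level)) {
    return(curve)
  }
  lam <- curve$intensity / m * counts_level
  draw <- with_seed(seed, rpois(length(lam), lam))
  ichi_curve(draw / counts_level * m,
    grid = curve$grid, valid_mask = curve$valid_mask,
    q_label = curve$q_label, degenerate = curve$degenerate
  )
}

# Gaussian noise option used in noise ablations (sd relative to curve max).
add_gaussian_noise <- function(curve, sd_rel, seed = 1L) {
  stopifnot(inherits(curve, "ichi_curve"))
  m <- max(curve$intensity)
  if (m == 0 || sd_rel <= 0) {
    return(curve)
  }
  noisy <- with_seed(seed, curve$intensity + rnorm(curve$grid$n_bins, 0, sd_rel * m))
  ichi_curve(pmax(noisy, 0),
    grid = curve$grid, valid_mask = curve$valid_mask,
    q_label = curve$q_label, degenerate = curve$degenerate
  )
}

#' Circular blockwise masking of a curve
#'
#' Invalidates exactly `round(mask_ratio * n_bins)` bins by repeatedly
#' drawing a random start bin and a block length from `block_len_range` on
#' the circular grid; blocks may wrap past the last bin to the first,
#' mirroring the fact that the head and tail of an I(chi) profile are
#' connected. The final block is truncated so the target count is met
#' exactly. Masked bins have intensity set to 0 and `valid_mask` FALSE.
#'
#' @param curve an [ichi_curve()].
#' @param mask_ratio fraction of bins to mask, in \[0, 1).
#' @param block_len_range min/max block length in bins.
#' @param seed integer seed.
#' @return masked [ichi_curve()].
#' @export
blockwise_mask <- function(curve, mask_ratio, block_len_range = c(5L, 60L),
                           seed = 1L) {
  stopifnot(inherits(curve, "ichi_curve"))
  n <- curve$grid$n_bins
  if (mask_ratio < 0 || mask_ratio >= 1) abort("`mask_ratio` must be in [0, 1).")
  if (block_len_range[1] < 1 || block_len_range[2] > n) {
    abort("`block_len_range` must lie within [1, n_bins].")
  }
  target <- round(mask_ratio * n)
  if (target == 0L) {
    return(curve)
  }
  masked <- rep(FALSE, n)
  with_seed(seed, {
    guard <- 0L
    while (sum(masked) < target) {
      start <- sample.int(n, 1L) - 1L # 0-based start bin
      len <- sample.int(
        block_len_range[2] - block_len_range[1] + 1L, 1L
      ) + block_len_range[1] - 1L
      block <- (start + seq_len(len) - 1L) %% n + 1L
      need <- target - sum(masked)
      fresh <- block[!masked[block]]
      if (length(fresh) > need) fresh <- fresh[seq_len(need)] # truncate
      masked[fresh] <- TRUE
      guard <- guard + 1L
      if (guard > 100000L) abort("blockwise masking failed to reach target.")
    }
  })
  intensity <- curve$intensity
  intensity[masked] <- 0
  ichi_curve(intensity,
    grid = curve$grid, valid_mask = curve$valid_mask & !masked,
    q_label = curve$q_label, degenerate = curve$degenerate
  )
}

#' Randomly scale the curve maximum
#'
#' Instead of normalizing every curve to exactly unit maximum, the maximum
#' is scaled to a random value drawn uniformly from `scale_range`,
#' compensating for signal fluctuation between acquisitions.
#'
#' @param curve an [ichi_curve()] with positive maximum.
#' @param scale_range interval for the new maximum.
#' @param seed integer seed.
#' @return scaled [ichi_curve()]; the new maximum equals the drawn value.
#' @export
random_scale <- function(curve, scale_range = c(0.95, 1.05), seed = 1L) {
  stopifnot(inherits(curve, "ichi_curve"))
  m <- max(curve$intensity)
  if (m <= 0) abort("degenerate input: curve has no positive maximum.")
  s <- with_seed(seed, runif(1L, scale_range[1], scale_range[2]))
  ichi_curve(curve$intensity * (s / m),
    grid = curve$grid, valid_mask = curve$valid_mask,
    q_label = curve$q_label, degenerate = curve$degenerate
  )
}

#' Apply the full corruption pipeline
#'
#' Noise, blockwise masking and random scaling, in that order, with
#' independent sub-seeds derived from `config$seed`. The per-curve Poisson
#' counts level is drawn log-uniformly from `counts_level_range`.
#'
#' @param curve an [ichi_curve()].
#' @param config a [corruption_config()].
#' @return corrupted [ichi_curve()].
#' @export
corrupt <- function(curve, config = corruption_config()) {
  stopifnot(inherits(curve, "ichi_curve"), inherits(config, "corruption_config"))
  s <- vapply(1:4, function(i) derive_seed(config$seed, i), integer(1))
  out <- curve
  clr <- config$counts_level_range
  if (config$noise %in% c("poisson", "poisson+gaussian") && all(is.finite(clr))) {
    level <- with_seed(s[1], exp(runif(1L, log(clr[1]), log(clr[2]))))
    out <- add_poisson_noise(out, level, seed = s[2])
  }
  if (config$noise %in% c("gaussian", "poisson+gaussian")) {
    out <- add_gaussian_noise(out, config$gaussian_sd, seed = s[2] + 1L)
  }
  out <- blockwise_mask(out, config$mask_ratio, config$block_len_range,
    seed = s[3]
  )
  if (max(out$intensity) > 0 &&
      !(config$scale_range[1] == 1 && config$scale_range[2] == 1)) {
    out <- random_scale(out, config$scale_range, seed = s[4])
  }
  out
}
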