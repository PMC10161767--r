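#' Label sampling ranges
#'
#' Closed intervals from which the nine orientation labels are sampled.
#' The defaults describe a sectioned cuticle specimen mounted with its
#' morphological surface close to normal to the beam: small plane tilts
#' (`alpha` within a few degrees, `beta` within ten), a mean in-plane fiber
#' angle `gamma` covering its full 180-degree period, fan spreads from a
#' narrow bundle (5 degrees) up to a wide fan (120 degrees; far beyond that
#' a fan degenerates toward an isotropic ring and the mean angle loses
#' meaning), and quantity ratios from 1:5 to 5:1 (sampled log-uniformly so
#' reciprocal ratios are equally likely). The methods vignette derives
#' these defaults from the per-label accuracy statistics the task is known
#' to support; any range can be overridden.
#'
#' @param alpha,beta,gamma,dgamma,lam_ratio length-2 numeric ranges; the
#'   same range is used for both groups.
#' @param sampler `"uniform"` (random, default) or `"grid"`.
#' @return an object of class `label_ranges`.
#' @export
label_ranges <- function(alpha = c(-4, 4), beta = c(-10, 10),
                         gamma = c(-90, 90), dgamma = c(5, 120),
                         lam_ratio = c(0.2, 5),
                         sampler = c("uniform", "grid")) {
  sampler <- match.arg(sampler)
  for (r in list(alpha, beta, gamma, dgamma, lam_ratio)) {
    if (length(r) != 2L || r[1] > r[2]) abort("ranges must be c(lo, hi) with lo <= hi.")
  }
  if (dgamma[1] < 0 || dgamma[2] > 180) abort("`dgamma` range must lie in [0, 180].")
  if (lam_ratio[1] <= 0) abort("`lam_ratio` range must be positive.")
  structure(
    list(
      alpha = alpha, beta = beta, gamma = gamma, dgamma = dgamma,
      lam_ratio = lam_ratio, sampler = sampler
    ),
    class = "label_ranges"
  )
}

#' Sample orientation labels
#'
#' Draws `n` orientation-parameter sets covering the configured ranges.
#' The uniform sampler draws each angle independently and the quantity
#' ratio log-uniformly; the grid sampler lays an approximately uniform
#' lattice over the nine-dimensional box. Every returned set is
#' canonically ordered (`gamma1 >= gamma2`), which preserves the marginal
#' distributions of tilts, spreads and ratio but makes the two gamma
#' columns order statistics of the underlying uniform pair.
#'
#' @param n number of parameter sets (>= 1).
#' @param ranges a [label_ranges()].
#' @param seed integer seed.
#' @return canonical parameter tibble with `n` rows.
#' @examples
#' sample_labels(3, seed = 42)
#' @export
sample_labels <- function(n, ranges = label_ranges(), seed = 1L) {
  stopifnot(inherits(ranges, "label_ranges"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) abort("`n` must be >= 1.")
  draw_angle <- function(r, k) runif(k, r[1], r[2])
  p <- with_seed(seed, {
    if (ranges$sampler == "uniform") {
      tibble::tibble(
        alpha1 = draw_angle(ranges$alpha, n),
        beta1 = draw_angle(ranges$beta, n),
        gamma1 = draw_angle(ranges$gamma, n),
        dgamma1 = draw_angle(ranges$dgamma, n),
        alpha2 = draw_angle(ranges$alpha, n),
        beta2 = draw_angle(ranges$beta, n),
        gamma2 = draw_angle(ranges$gamma, n),
        dgamma2 = draw_angle(ranges$dgamma, n),
        lam_ratio = exp(runif(n, log(ranges$lam_ratio[1]), log(ranges$lam_ratio[2])))
      )
    } else {
      # per-dimension lattice with enough points to cover n combinations
      k <- max(2L, ceiling(n^(1 / 9)))
      lattice <- function(r, k) seq(r[1], r[2], length.out = k)
      full <- expand.grid(
        alpha1 = lattice(ranges$alpha, k), beta1 = lattice(ranges$beta, k),
        gamma1 = lattice(ranges$gamma, k), dgamma1 = lattice(ranges$dgamma, k),
        alpha2 = lattice(ranges$alpha, k), beta2 = lattice(ranges$beta, k),
        gamma2 = lattice(ranges$gamma, k), dgamma2 = lattice(ranges$dgamma, k),
        lam_ratio = exp(lattice(log(ranges$lam_ratio), k))
      )
      tibble::as_tibble(full[sample.int(nrow(full), n), ])
    }
  })
  canonical_order(p)
}

#' Build a paired (curve, label) training dataset
#'
#' Simulates every parameter set with the forward model, applies the
#' corruption pipeline with a per-sample sub-seed, encodes the labels, and
#' assigns train/validation/test splits. Everything is reproducible from
#' `seed`.
#'
#' @param labels canonical parameter tibble (e.g. from [sample_labels()]).
#' @param grid a [chi_grid()].
#' @param corruption a [corruption_config()], or `NULL` to disable
#'   corruption entirely.
#' @param split_fracs train/validation/test fractions summing to 1.
#' @param seed integer seed controlling corruption sub-seeds and the split.
#' @param smear_width,n_quad,geometry,weighting forward-model settings, see
#'   [simulate_ichi()].
#' @return an object of class `fiber_dataset`: list with `curves` (n x bins
#'   intensity matrix, post-corruption), `masks` (logical matrix, TRUE =
#'   observed), `clean` (pre-corruption intensity matrix), `labels` (n x 17
#'   encoded matrix), `params` (tibble), `split` (factor), `grid`, `seed`
#'   and `provenance` (config snapshot).
#' @export
build_dataset <- function(labels, grid = chi_grid(),
                          corruption = corruption_config(),
                          split_fracs = c(train = 0.8, val = 0.1, test = 0.1),
                          seed = 1L, smear_width = 5, n_quad = 721L,
                          geometry = waxd_geometry(), weighting = "gaussian") {
  labels <- canonical_order(labels)
  if (abs(sum(split_fracs) - 1) > 1e-8) abort("`split_fracs` must sum to 1.")
  n <- nrow(labels)
  clean <- simulate_curves(labels,
    grid = grid, smear_width = smear_width,
    n_quad = n_quad, geometry = geometry, weighting = weighting
  )
  curves <- clean
  masks <- matrix(TRUE, n, grid$n_bins)
  if (!is.null(corruption)) {
    for (i in seq_len(n)) {
      ci <- ichi_curve(clean[i, ], grid = grid)
      cfg_i <- corruption
      cfg_i$seed <- derive_seed(seed, i)
      out <- corrupt(ci, cfg_i)
      curves[i, ] <- out$intensity
      masks[i, ] <- out$valid_mask
    }
  }
  enc <- encode_labels(labels)
  split <- assign_split(n, split_fracs, seed = derive_seed(seed, 0L))
  structure(
    list(
      curves = curves, masks = masks, clean = clean,
      labels = enc, params = labels, split = split,
      grid = grid, seed = as.integer(seed),
      provenance = list(
        corruption = corruption, split_fracs = split_fracs,
        smear_width = smear_width, n_quad = n_quad,
        geometry = geometry, weighting = weighting
      )
    ),
    class = "fiber_dataset"
  )
}

# Deterministic shuffled split assignment with exact rounded sizes.
assign_split <- function(n, split_fracs, seed = 1L) {
  sizes <- floor(split_fracs * n)
  rem <- n - sum(sizes)
  if (rem > 0) {
    order_frac <- order(split_fracs * n - sizes, decreasing = TRUE)
    sizes[order_frac[seq_len(rem)]] <- sizes[order_frac[seq_len(rem)]] + 1L
  }
  lab <- rep(factor(c("train", "val", "test"), levels = c("train", "val", "test")),
    times = sizes
  )
  with_seed(seed, lab[sample.int(n)])
}

#' Reassign dataset splits
#'
#' Returns the same dataset with a fresh seeded train/val/test shuffle;
#' used by the repeated-training protocol.
#'
#' @param dataset a `fiber_dataset`.
#' @param seed integer seed.
#' @return the dataset with a new `split`.
#' @export
reshuffle_split <- function(dataset, seed) {
  stopifnot(inherits(dataset, "fiber_dataset"))
  dataset$split <- assign_split(
    nrow(dataset$curves), dataset$provenance$split_fracs,
    seed = seed
  )
  dataset
}

#' @export
print.fiber_dataset <- function(x, ...) {
  cat(sprintf(
    "<fiber_dataset> %d curves x %d bins (train/val/test = %d/%d/%d), seed %d\n",
    nrow(x$curves), ncol(x$curves),
    sum(x$split == "train"), sum(x$split == "val"), sum(x$split == "test"),
    x$seed
  ))
  invisible(x)
}

# [intensity; mask] feature matrix fed to every regressor.
dataset_features <- function(dataset, rows = NULL) {
  rows <- rows %||% seq_len(nrow(dataset$curves))
  cbind(dataset$curves[rows, , drop = FALSE],
        dataset$masks[rows, , drop = FALSE] * 1)
}

dataset_rows <- function(dataset, split) {
  which(dataset$split == split)
}
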