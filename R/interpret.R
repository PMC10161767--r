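#' Gradient saliency of one model output
#'
#' First-order interpretation of the network: the output is linearized
#' around the presented input curve and the absolute input gradient ranks
#' the influence of each azimuth bin on the selected output. Exact for a
#' linear model; only differentiable (FCNN) models are supported.
#'
#' @param model an `fcnn_model`.
#' @param curve an [ichi_curve()] or a feature vector of length
#'   `model$input_len` (`[intensity; mask]`).
#' @param output_index output unit, 1..17 (see the label layout in
#'   [encode_labels()]).
#' @return a list with `saliency` (absolute gradient over the intensity
#'   bins), `saliency_mask` (absolute gradient over the mask channel),
#'   `gradient` (signed, full input length), `output_index` and
#'   `output_name`.
#' @export
saliency <- function(model, curve, output_index) {
  if (!inherits(model, "fcnn_model")) {
    abort("saliency requires a differentiable (FCNN) model.")
  }
  output_index <- as.integer(output_index)
  if (output_index < 1L || output_index > 17L) {
    abort("`output_index` must be in 1..17.")
  }
  x <- if (inherits(curve, "ichi_curve")) {
    drop(curves_to_features(curve, n_bins = model$n_bins))
  } else {
    as.double(curve)
  }
  if (length(x) != model$input_len) {
    abort("curve length does not match the model input length.")
  }
  g <- mlp_input_grad(model$net, x, output_index)
  nb <- model$n_bins
  list(
    saliency = abs(g[seq_len(nb)]),
    saliency_mask = abs(g[nb + seq_len(nb)]),
    gradient = g,
    output_index = output_index,
    output_name = LABEL_NAMES[output_index]
  )
}

#' Saliency map over all outputs for one curve
#'
#' @inheritParams saliency
#' @return matrix (17 x n_bins) of absolute intensity-channel gradients,
#'   rows named by output label.
#' @export
saliency_map <- function(model, curve) {
  rows <- lapply(seq_len(17L), function(k) saliency(model, curve, k)$saliency)
  out <- do.call(rbind, rows)
  rownames(out) <- LABEL_NAMES
  out
}

#' Fraction of saliency mass near detected peaks
#'
#' Quantifies how strongly the model relies on the diffraction peaks: the
#' share of total (intensity-channel) saliency that falls within
#' `half_window` degrees of a detected peak apex. A model attending
#' uniformly would score the fraction of bins covered by the windows; a
#' peak-focused model scores higher.
#'
#' @param sal saliency vector over intensity bins.
#' @param peaks peak tibble from [detect_peaks()].
#' @param grid the [chi_grid()].
#' @param half_window window half-width in degrees (default 10).
#' @return list with `mass_fraction`, `bin_fraction` (uniform baseline) and
#'   `concentration` (their ratio).
#' @export
peak_saliency_concentration <- function(sal, peaks, grid, half_window = 10) {
  if (!nrow(peaks)) {
    return(list(
      mass_fraction = NA_real_, bin_fraction = NA_real_,
      concentration = NA_real_
    ))
  }
  near <- rep(FALSE, grid$n_bins)
  for (loc in peaks$location) {
    near <- near | abs(circ_diff360(grid$chi_centers, loc)) <= half_window
  }
  tot <- sum(sal)
  mass <- if (tot > 0) sum(sal[near]) / tot else NA_real_
  binf <- mean(near)
  list(
    mass_fraction = mass, bin_fraction = binf,
    concentration = mass / binf
  )
}

#' Saliency sweep report
#'
#' Sweeps one orientation parameter over a set of values, simulates the
#' corresponding curves, and records the saliency row of a chosen output
#' aligned with each curve, plus the peak-concentration statistic. This is
#' the quantitative form of the qualitative saliency-versus-orientation
#' panels: peak shifts, relative-height changes and broadening of the
#' diffraction arcs move the model's attended regions with them.
#'
#' @param model an `fcnn_model`.
#' @param base_params parameter set the sweep starts from.
#' @param sweep_param name of the swept parameter column.
#' @param sweep_values numeric vector of values for it.
#' @param output_index output unit whose saliency is recorded.
#' @param grid,smear_width,n_quad,geometry forward-model settings.
#' @param corruption optional [corruption_config()] applied to each curve
#'   before presentation (as in corruption-trained usage); `NULL` presents
#'   clean curves.
#' @return a list with `sweep` (tibble: one row per sweep point with the
#'   concentration statistics) and matrices `curves` and `saliency`
#'   (one row per sweep point).
#' @export
saliency_report <- function(model, base_params, sweep_param, sweep_values,
                            output_index = 5L, grid = chi_grid(),
                            smear_width = 5, n_quad = 721L,
                            geometry = waxd_geometry(), corruption = NULL) {
  if (!sweep_param %in% PARAM_NAMES) {
    abort(sprintf("unknown parameter '%s'.", sweep_param))
  }
  base <- as_params_row(base_params)
  n <- length(sweep_values)
  curves <- matrix(0, n, grid$n_bins)
  sal <- matrix(0, n, grid$n_bins)
  stats <- vector("list", n)
  for (i in seq_len(n)) {
    p <- base
    p[[sweep_param]] <- sweep_values[i]
    p <- canonical_order(p)
    cu <- simulate_ichi(p,
      grid = grid, smear_width = smear_width,
      n_quad = n_quad, geometry = geometry
    )
    if (!is.null(corruption)) {
      cfg <- corruption
      cfg$seed <- derive_seed(corruption$seed, i)
      cu <- corrupt(cu, cfg)
    }
    s <- saliency(model, cu, output_index)
    curves[i, ] <- cu$intensity
    sal[i, ] <- s$saliency
    pk <- detect_peaks(cu)
    conc <- peak_saliency_concentration(s$saliency, pk, grid)
    stats[[i]] <- tibble::tibble(
      value = sweep_values[i],
      n_peaks = nrow(pk),
      mass_fraction = conc$mass_fraction,
      bin_fraction = conc$bin_fraction,
      concentration = conc$concentration
    )
  }
  list(
    sweep = dplyr::bind_rows(stats),
    curves = curves,
    saliency = sal,
    sweep_param = sweep_param,
    output_name = LABEL_NAMES[output_index]
  )
}
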