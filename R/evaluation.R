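#' Reconstruct a curve from (predicted) orientation parameters
#'
#' Thin wrapper over [simulate_ichi()] used by the reconstruction-based
#' evaluation protocol: the forward model is re-run with the predicted
#' parameters and the result compared with the observed curve.
#'
#' @inheritParams simulate_ichi
#' @return an [ichi_curve()].
#' @export
reconstruct <- function(params, grid = chi_grid(), smear_width = 5,
                        n_quad = 721L, geometry = waxd_geometry(),
                        weighting = "gaussian") {
  simulate_ichi(params,
    grid = grid, smear_width = smear_width, n_quad = n_quad,
    geometry = geometry, weighting = weighting
  )
}

#' Reconstruction RMSE between two curves
#'
#' Root-mean-square difference over the bins valid in both curves, after
#' each curve is normalized to unit maximum over those bins. Curves are
#' defined up to an intensity scale, so the comparison is scale-free.
#'
#' @param curve_a,curve_b [ichi_curve()]s on the same grid.
#' @return non-negative scalar; 0 iff the curves agree on the shared bins.
#' @export
rmse <- function(curve_a, curve_b) {
  stopifnot(inherits(curve_a, "ichi_curve"), inherits(curve_b, "ichi_curve"))
  if (curve_a$grid$n_bins != curve_b$grid$n_bins) {
    abort("curves must share one chi grid.")
  }
  ok <- curve_a$valid_mask & curve_b$valid_mask
  if (!any(ok)) abort("no overlapping valid bins.")
  a <- curve_a$intensity[ok]
  b <- curve_b$intensity[ok]
  ma <- max(a)
  mb <- max(b)
  if (ma <= 0 || mb <= 0) abort("a curve is zero on the shared bins.")
  sqrt(mean((a / ma - b / mb)^2))
}

#' Detect peaks on a circular intensity profile
#'
#' Circular local maxima with prominence at least `min_prominence`; at most
#' `max_peaks` peaks are kept (two fiber groups produce at most two pairs
#' of diffraction arcs), ranked by prominence and returned sorted by
#' location. Bins flagged invalid are excluded as apex candidates.
#'
#' @param curve an [ichi_curve()], expected unit-max normalized.
#' @param min_prominence minimum prominence in normalized units.
#' @param max_peaks maximum number of peaks kept.
#' @return tibble with columns `location` (degrees), `intensity`,
#'   `prominence`; zero rows if nothing qualifies.
#' @export
detect_peaks <- function(curve, min_prominence = 0.05, max_peaks = 4L) {
  stopifnot(inherits(curve, "ichi_curve"))
  v <- curve$intensity
  n <- length(v)
  nxt <- c(2:n, 1L)
  prv <- c(n, 1:(n - 1L))
  # strict rise on one side avoids double-counting flat-top plateaus
  cand <- which(v > v[prv] & v >= v[nxt] & curve$valid_mask)
  if (!length(cand)) {
    return(tibble::tibble(
      location = double(0), intensity = double(0), prominence = double(0)
    ))
  }
  prom <- vapply(cand, function(p) circular_prominence(v, p), double(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]
  prom <- prom[keep]
  if (!length(cand)) {
    return(tibble::tibble(
      location = double(0), intensity = double(0), prominence = double(0)
    ))
  }
  ord <- order(prom, decreasing = TRUE)
  sel <- head(ord, max_peaks)
  out <- tibble::tibble(
    location = curve$grid$chi_centers[cand[sel]],
    intensity = v[cand[sel]],
    prominence = prom[sel]
  )
  out[order(out$location), ]
}

# Topographic prominence of bin p on the circular profile v: walk both ways
# until a higher bin is met; prominence is the drop to the higher of the two
# path minima (global maxima use the global minimum).
circular_prominence <- function(v, p) {
  n <- length(v)
  walk <- function(dir) {
    lo <- v[p]
    i <- p
    for (step in seq_len(n - 1L)) {
      i <- (i - 1L + dir) %% n + 1L
      if (v[i] > v[p]) {
        return(lo)
      }
      if (v[i] < lo) lo <- v[i]
    }
    NA_real_ # no higher bin: global maximum
  }
  left <- walk(-1L)
  right <- walk(1L)
  if (is.na(left) || is.na(right)) {
    return(v[p] - min(v))
  }
  v[p] - max(left, right)
}

# Signed circular difference on the 360-degree azimuth circle.
circ_diff360 <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  d
}

#' Pooled Pearson correlation of matched peak locations and intensities
#'
#' Peaks of each reconstructed/reference curve pair are matched greedily by
#' nearest circular location within a matching window; matches are pooled
#' over all curves and the Pearson correlation is computed separately for
#' locations and intensities. Matched reconstructed locations are unwrapped
#' to the reference branch (reference + signed circular difference) so the
#' +/-180 seam does not break the correlation.
#'
#' @param pairs list; each element a list with elements `recon` and `ref`,
#'   both peak tibbles from [detect_peaks()].
#' @param window matching window in degrees (default 15).
#' @return list with `r_location`, `r_intensity`, `n_matches` and the
#'   pooled match tibble `matches`.
#' @export
peak_pearson <- function(pairs, window = 15) {
  match_one <- function(el) {
    rc <- el$recon
    rf <- el$ref
    if (!nrow(rc) || !nrow(rf)) {
      return(NULL)
    }
    cand <- expand.grid(i = seq_len(nrow(rc)), j = seq_len(nrow(rf)))
    cand$d <- abs(circ_diff360(rc$location[cand$i], rf$location[cand$j]))
    cand <- cand[cand$d <= window, , drop = FALSE]
    cand <- cand[order(cand$d), , drop = FALSE]
    used_i <- logical(nrow(rc))
    used_j <- logical(nrow(rf))
    rows <- list()
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]
      j <- cand$j[r]
      if (!used_i[i] && !used_j[j]) {
        used_i[i] <- TRUE
        used_j[j] <- TRUE
        rows[[length(rows) + 1L]] <- tibble::tibble(
          ref_location = rf$location[j],
          recon_location = rf$location[j] +
            circ_diff360(rc$location[i], rf$location[j]),
          ref_intensity = rf$intensity[j],
          recon_intensity = rc$intensity[i]
        )
      }
    }
    if (length(rows)) dplyr::bind_rows(rows) else NULL
  }
  matches <- dplyr::bind_rows(lapply(pairs, match_one))
  if (is.null(matches) || nrow(matches) < 2L) {
    abort("fewer than 2 matched peak pairs; cannot compute correlations.")
  }
  list(
    r_location = cor(matches$ref_location, matches$recon_location),
    r_intensity = cor(matches$ref_intensity, matches$recon_intensity),
    n_matches = nrow(matches),
    matches = matches
  )
}

#' Per-label R-squared and mean absolute error
#'
#' Compares predicted and ground-truth orientation parameters label by
#' label. The six tilt/mean angles are compared on their 180-degree circle
#' (residual = shortest circular difference; the R-squared total sum of
#' squares uses circular deviations about the circular mean of the truth).
#' The spreads, which the codec represents on the same circle, are compared
#' the same way; the quantity ratio is compared linearly.
#'
#' @param predicted,truth parameter tibbles of equal length (>= 2 rows).
#' @return tibble with columns `label`, `r2`, `mae`.
#' @export
label_metrics <- function(predicted, truth) {
  predicted <- validate_params(predicted)
  truth <- validate_params(truth)
  if (nrow(predicted) != nrow(truth) || nrow(truth) < 2L) {
    abort("`predicted` and `truth` must have equal length >= 2.")
  }
  one <- function(nm) {
    p <- predicted[[nm]]
    t <- truth[[nm]]
    if (nm %in% ANGLE_NAMES) {
      res <- angle_diff180(p, t)
      tc <- circular_mean180(t)
      dev <- angle_diff180(t, tc)
    } else {
      res <- p - t
      dev <- t - mean(t)
    }
    ss_tot <- sum(dev^2)
    if (ss_tot == 0) {
      abort(sprintf("zero-variance truth for label %s: R^2 undefined.", nm))
    }
    tibble::tibble(
      label = nm, r2 = 1 - sum(res^2) / ss_tot, mae = mean(abs(res))
    )
  }
  dplyr::bind_rows(lapply(PARAM_NAMES, one))
}

# Circular mean of period-180 angles via the doubled-angle resultant.
circular_mean180 <- function(theta) {
  th2 <- 2 * theta * DEG2RAD
  norm_angle180(atan2(mean(sin(th2)), mean(cos(th2))) / DEG2RAD / 2)
}

#' Reconstruction-based evaluation of a fitted model
#'
#' Implements the reconstruction protocol: predict orientation parameters
#' for each evaluation curve, regenerate the corresponding clean curve with
#' the forward model, and score the match between observed and
#' reconstructed curves (RMSE on shared valid bins; pooled Pearson
#' correlations of matched peak locations and intensities). With ground
#' truth available (phase 1), per-label R-squared/MAE are added.
#'
#' Phase 1 evaluates on the dataset's held-out test split as stored. Phase 2
#' emulates experimental curves with unseen gap layouts: the clean test
#' curves are re-corrupted with mask blocks drawn from a disjoint
#' block-length range.
#'
#' @param model fitted model ([train_fcnn()] / [train_baseline()]).
#' @param dataset the `fiber_dataset` the model was trained on.
#' @param phase `"phase1"` or `"phase2"`.
#' @param split which split to evaluate (default `"test"`).
#' @param min_prominence,window peak detection / matching settings.
#' @param phase2_block_len block-length range for the phase-2 mask layouts.
#' @param phase2_seed seed for the phase-2 re-corruption.
#' @return an `eval_report` object; see [glance.eval_report()].
#' @export
evaluate <- function(model, dataset, phase = c("phase1", "phase2"),
                     split = "test", min_prominence = 0.05, window = 15,
                     phase2_block_len = c(61L, 120L), phase2_seed = 271L) {
  phase <- match.arg(phase)
  stopifnot(inherits(dataset, "fiber_dataset"))
  rows <- dataset_rows(dataset, split)
  if (!length(rows)) abort(sprintf("split '%s' is empty.", split))
  prov <- dataset$provenance
  grid <- dataset$grid

  if (phase == "phase1") {
    inten <- dataset$curves[rows, , drop = FALSE]
    vmask <- dataset$masks[rows, , drop = FALSE]
  } else {
    # unseen gap layouts on the clean curves (+ the dataset's noise model)
    inten <- matrix(0, length(rows), grid$n_bins)
    vmask <- matrix(TRUE, length(rows), grid$n_bins)
    cfg <- prov$corruption %||% corruption_config()
    cfg$block_len_range <- as.integer(phase2_block_len)
    for (k in seq_along(rows)) {
      cfg$seed <- derive_seed(phase2_seed, k)
      cc <- corrupt(ichi_curve(dataset$clean[rows[k], ], grid = grid), cfg)
      inten[k, ] <- cc$intensity
      vmask[k, ] <- cc$valid_mask
    }
  }

  pred <- predict_orientation(model, inten, vmask)
  recon <- simulate_curves(pred,
    grid = grid, smear_width = prov$smear_width, n_quad = prov$n_quad,
    geometry = prov$geometry, weighting = prov$weighting
  )

  rmse_i <- rep(NA_real_, length(rows))
  pairs <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    obs <- ichi_curve(inten[k, ], grid = grid, valid_mask = vmask[k, ])
    rec <- ichi_curve(recon[k, ], grid = grid)
    # degenerate observations (all signal masked) or degenerate predicted
    # geometry cannot be scored; they are skipped and counted
    rmse_i[k] <- tryCatch(rmse(obs, rec), error = function(e) NA_real_)
    if (is.na(rmse_i[k])) next
    m_obs <- max(obs$intensity)
    obs_n <- ichi_curve(obs$intensity / max(m_obs, .Machine$double.eps),
      grid = grid, valid_mask = obs$valid_mask
    )
    pairs[[k]] <- list(
      recon = detect_peaks(rec, min_prominence = min_prominence),
      ref = detect_peaks(obs_n, min_prominence = min_prominence)
    )
  }
  n_skipped <- sum(is.na(rmse_i))
  rmse_ok <- rmse_i[!is.na(rmse_i)]
  pk <- peak_pearson(pairs[!vapply(pairs, is.null, logical(1))],
    window = window
  )

  labels_tbl <- NULL
  if (phase == "phase1") {
    labels_tbl <- label_metrics(pred, dataset$params[rows, , drop = FALSE])
  }
  structure(
    list(
      phase = phase,
      n_curves = length(rows),
      n_skipped = n_skipped,
      rmse_mean = mean(rmse_ok), rmse_sd = sd(rmse_ok),
      rmse_per_curve = rmse_i,
      pearson_location = pk$r_location,
      pearson_intensity = pk$r_intensity,
      n_peak_matches = pk$n_matches,
      label_metrics = labels_tbl,
      n_repetitions = 1L,
      predicted = pred
    ),
    class = "eval_report"
  )
}

#' Repeat the phase-1 protocol over several training runs
#'
#' Retrains the model `n_repetitions` times with fresh split shuffles and
#' initialization seeds (the usual way to average out split and
#' initialization randomness), evaluates each run, and aggregates metrics
#' as mean and standard deviation across repetitions.
#'
#' @param dataset a `fiber_dataset`.
#' @param trainer function `(dataset, seed) -> model`.
#' @param n_repetitions number of repetitions (>= 1).
#' @param seed master seed; repetition seeds are derived from it.
#' @param phase passed to [evaluate()].
#' @param ... further arguments to [evaluate()].
#' @return an `eval_report` aggregated over repetitions, with the per-rep
#'   reports in `$reps`.
#' @export
repeat_phase1 <- function(dataset, trainer, n_repetitions = 5L, seed = 1L,
                          phase = "phase1", ...) {
  stopifnot(n_repetitions >= 1L)
  reps <- vector("list", n_repetitions)
  for (r in seq_len(n_repetitions)) {
    ds <- reshuffle_split(dataset, seed = derive_seed(seed, 100L + r))
    model <- trainer(ds, derive_seed(seed, 200L + r))
    reps[[r]] <- evaluate(model, ds, phase = phase, ...)
  }
  agg <- function(field) vapply(reps, function(x) x[[field]], double(1))
  rmse_m <- agg("rmse_mean")
  ploc <- agg("pearson_location")
  pint <- agg("pearson_intensity")
  lm_tbl <- NULL
  if (!is.null(reps[[1]]$label_metrics)) {
    all_lm <- dplyr::bind_rows(
      lapply(seq_along(reps), function(r) {
        dplyr::mutate(reps[[r]]$label_metrics, rep = r)
      })
    )
    lm_tbl <- dplyr::summarise(
      dplyr::group_by(all_lm, .data$label),
      r2_sd = sd_or_zero(.data$r2), r2 = mean(.data$r2),
      mae_sd = sd_or_zero(.data$mae), mae = mean(.data$mae),
      .groups = "drop"
    )
    lm_tbl <- lm_tbl[, c("label", "r2", "r2_sd", "mae", "mae_sd")]
    lm_tbl <- lm_tbl[match(PARAM_NAMES, lm_tbl$label), ]
  }
  structure(
    list(
      phase = phase,
      n_curves = reps[[1]]$n_curves,
      rmse_mean = mean(rmse_m), rmse_sd = sd_or_zero(rmse_m),
      pearson_location = mean(ploc), pearson_location_sd = sd_or_zero(ploc),
      pearson_intensity = mean(pint), pearson_intensity_sd = sd_or_zero(pint),
      label_metrics = lm_tbl,
      n_repetitions = as.integer(n_repetitions),
      reps = reps
    ),
    class = "eval_report"
  )
}

sd_or_zero <- function(x) if (length(x) < 2L) 0 else sd(x)

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report %s> %d curves, %d repetition(s)\n", x$phase, x$n_curves,
    x$n_repetitions
  ))
  cat(sprintf(
    "  reconstruction RMSE %.4f (%.4f)\n", x$rmse_mean, x$rmse_sd %||% 0
  ))
  cat(sprintf(
    "  peak Pearson location/intensity %.4f / %.4f\n",
    x$pearson_location, x$pearson_intensity
  ))
  if (!is.null(x$label_metrics)) {
    print(x$label_metrics, n = nrow(x$label_metrics))
  }
  invisible(x)
}

#' One-row summary of an evaluation report
#'
#' @param x an `eval_report`.
#' @param ... unused.
#' @return a one-row tibble of the headline metrics.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    phase = x$phase,
    n_curves = x$n_curves,
    n_repetitions = x$n_repetitions,
    rmse_mean = x$rmse_mean,
    rmse_sd = x$rmse_sd %||% NA_real_,
    pearson_location = x$pearson_location,
    pearson_intensity = x$pearson_intensity
  )
}

#' Per-label metrics of an evaluation report
#'
#' @param x an `eval_report` with label metrics (phase 1).
#' @param ... unused.
#' @return tibble of per-label R-squared and MAE.
#' @export
tidy.eval_report <- function(x, ...) {
  if (is.null(x$label_metrics)) {
    abort("report has no label metrics (phase 2).")
  }
  x$label_metrics
}
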