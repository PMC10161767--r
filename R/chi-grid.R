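#' Uniform circular azimuth grid for I(chi) profiles
#'
#' The azimuthal intensity profile I(chi) of a diffraction ring is sampled on
#' a uniform circular grid over \[-180, 180) degrees; the last bin is adjacent
#' to the first. One degree per bin (`n_bins = 360`) matches common radial
#' integration practice.
#'
#' @param n_bins number of azimuth bins (default 360).
#' @return an object of class `chi_grid` with fields `n_bins`, `chi_centers`
#'   (bin-center azimuths in degrees) and `step` (bin width in degrees).
#' @examples
#' g <- chi_grid(360)
#' head(g$chi_centers)
#' @export
chi_grid <- function(n_bins = 360L) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 4L) {
    abort("`n_bins` must be an integer >= 4.")
  }
  step <- 360 / n_bins
  structure(
    list(
      n_bins = n_bins,
      chi_centers = -180 + (seq_len(n_bins) - 0.5) * step,
      step = step
    ),
    class = "chi_grid"
  )
}

#' @export
print.chi_grid <- function(x, ...) {
  cat(sprintf(
    "<chi_grid> %d bins over [-180, 180), %.4g deg/bin\n",
    x$n_bins, x$step
  ))
  invisible(x)
}

#' Azimuthal intensity curve I(chi)
#'
#' Container for a single azimuthal intensity profile: intensities on a
#' [chi_grid()] plus a validity mask marking observed bins. Missing regions
#' (detector module gaps, beamstop shadow) are `valid_mask = FALSE` bins whose
#' intensity is stored as 0.
#'
#' @param intensity numeric vector of non-negative intensities (arbitrary
#'   units), one per grid bin.
#' @param grid a [chi_grid()]; defaults to a grid matching `length(intensity)`.
#' @param valid_mask logical vector, `TRUE` for observed bins.
#' @param q_label optional text tag for the reflection, e.g. `"(110)"`.
#' @param degenerate logical flag set by the simulator when the diffraction
#'   geometry produced no intersections (all-zero curve).
#' @return an object of class `ichi_curve`.
#' @export
ichi_curve <- function(intensity, grid = chi_grid(length(intensity)),
                       valid_mask = rep(TRUE, length(intensity)),
                       q_label = "(110)", degenerate = FALSE) {
  intensity <- as.double(intensity)
  valid_mask <- as.logical(valid_mask)
  if (length(intensity) != grid$n_bins) {
    abort("`intensity` length must equal the number of grid bins.")
  }
  if (length(valid_mask) != grid$n_bins) {
    abort("`valid_mask` length must equal the number of grid bins.")
  }
  if (anyNA(valid_mask)) abort("`valid_mask` must not contain NA.")
  bad <- is.finite(intensity) & valid_mask & intensity < 0
  if (any(bad)) {
    abort(sprintf("negative intensity on %d valid bin(s).", sum(bad)))
  }
  structure(
    list(
      grid = grid,
      intensity = intensity,
      valid_mask = valid_mask,
      q_label = q_label,
      degenerate = isTRUE(degenerate)
    ),
    class = "ichi_curve"
  )
}

#' @export
print.ichi_curve <- function(x, ...) {
  cat(sprintf(
    "<ichi_curve %s> %d bins, %d masked, max intensity %.4g%s\n",
    x$q_label %||% "", x$grid$n_bins, sum(!x$valid_mask),
    max(x$intensity), if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Tidy an I(chi) curve into a tibble
#'
#' @param x an [ichi_curve()].
#' @param ... unused.
#' @return a tibble with columns `chi`, `intensity`, `valid`.
#' @importFrom generics tidy
#' @export
tidy.ichi_curve <- function(x, ...) {
  tibble::tibble(
    chi = x$grid$chi_centers,
    intensity = x$intensity,
    valid = x$valid_mask
  )
}

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_rug labs
#' @export
autoplot.ichi_curve <- function(object, ...) {
  df <- tidy(object)
  ggplot(df[df$valid, ], aes(x = .data$chi, y = .data$intensity)) +
    geom_line(colour = "steelblue") +
    geom_rug(
      data = df[!df$valid, ], aes(x = .data$chi), inherit.aes = FALSE,
      sides = "b", colour = "grey40", alpha = 0.6
    ) +
    labs(
      x = expression(chi ~ "(degrees)"), y = "intensity (a.u.)",
      title = paste("I(chi)", object$q_label %||% "")
    )
}

#' @importFrom ggplot2 .data
NULL
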