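#' Diffraction geometry constants for the (110) ring
#'
#' Fixes the Ewald-sphere construction used by the forward model. The beam
#' travels along the lab +z axis; the detector plane is x-y and the azimuth
#' chi is measured from +x, counter-clockwise. For a reflection with
#' d-spacing `d_spacing` at photon energy `energy_kev`, the Bragg angle
#' theta places the accessible part of the reciprocal shell |q| = Q on a
#' small circle at polar offset -sin(theta) from the detector plane.
#'
#' @param energy_kev photon energy in keV (default 10, typical microfocus
#'   WAXD setting).
#' @param det_distance_mm sample-to-detector distance in mm (default 262.3);
#'   used only by detector-frame integration, kept here so simulation and
#'   integration share one geometry object.
#' @param d_spacing lattice d-spacing of the reflection in Angstrom
#'   (default 4.60, alpha-chitin (110)).
#' @param pole_angle angle in degrees between the reflection's reciprocal
#'   vectors and the fiber axis (default 90: the (110) planes contain the
#'   chitin chain axis, so their poles are equatorial).
#' @return an object of class `waxd_geometry`.
#' @export
waxd_geometry <- function(energy_kev = 10, det_distance_mm = 262.3,
                          d_spacing = 4.60, pole_angle = 90) {
  stopifnot(energy_kev > 0, det_distance_mm > 0, d_spacing > 0)
  wavelength <- 12.398420 / energy_kev
  sin_theta <- wavelength / (2 * d_spacing)
  if (sin_theta >= 1) abort("reflection not reachable at this energy.")
  theta <- asin(sin_theta)
  structure(
    list(
      energy_kev = energy_kev,
      det_distance_mm = det_distance_mm,
      d_spacing = d_spacing,
      wavelength = wavelength,
      theta_deg = theta / DEG2RAD,
      sin_theta = sin_theta,
      cos_theta = cos(theta),
      tan_theta = tan(theta),
      pole_angle = pole_angle,
      cos_pole = cos(pole_angle * DEG2RAD)
    ),
    class = "waxd_geometry"
  )
}

#' @export
print.waxd_geometry <- function(x, ...) {
  cat(sprintf(
    "<waxd_geometry> %g keV, d = %g A, 2theta = %.3f deg, pole angle %g deg\n",
    x$energy_kev, x$d_spacing, 2 * x$theta_deg, x$pole_angle
  ))
  invisible(x)
}

#' Rotation matrix for the fiber-plane tilts
#'
#' The untilted fiber plane is the lab z = 0 plane. The plane is tilted by a
#' rotation about the lab x axis by `alpha`, followed by a rotation about
#' the lab y axis by `beta`. Tilt angles are periodic with period 180 and
#' are normalized into (-90, 90] before the matrix is built, so `alpha` and
#' `alpha + 180` produce the same configuration by construction.
#'
#' @param alpha,beta tilt angles in degrees.
#' @return a 3x3 proper rotation matrix (determinant +1).
#' @examples
#' rotation_from_tilts(0, 0) # identity
#' @export
rotation_from_tilts <- function(alpha, beta) {
  stopifnot(is.finite(alpha), is.finite(beta))
  a <- norm_angle180(alpha) * DEG2RAD
  b <- norm_angle180(beta) * DEG2RAD
  rx <- rbind(
    c(1, 0, 0),
    c(0, cos(a), -sin(a)),
    c(0, sin(a), cos(a))
  )
  ry <- rbind(
    c(cos(b), 0, sin(b)),
    c(0, 1, 0),
    c(-sin(b), 0, cos(b))
  )
  ry %*% rx
}

#' Fiber axes of one tilted, fanned fiber group
#'
#' A fiber group is a planar fan of unit fiber axes: in the untilted plane
#' the axes point at in-plane angles spread around the mean angle `gamma`
#' with total width `dgamma`, then the whole plane is tilted by
#' [rotation_from_tilts()]. Within-fan weighting is a truncated Gaussian
#' with sigma = dgamma/4 on the support
#' \[gamma - dgamma/2, gamma + dgamma/2\] (default; it gives the smooth
#' peak shapes seen in experimental profiles) or uniform over the same
#' support.
#'
#' @param alpha,beta,gamma,dgamma group angles in degrees; `dgamma >= 0`.
#' @param n_samples number of fan quadrature samples (>= 1).
#' @param weighting `"uniform"` or `"gaussian"`.
#' @return a list with `axes` (3 x n matrix of unit vectors), `weights`
#'   (summing to 1) and `fan_angles` (degrees).
#' @export
group_fiber_axes <- function(alpha, beta, gamma, dgamma, n_samples = 181L,
                             weighting = c("gaussian", "uniform")) {
  weighting <- match.arg(weighting)
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) {
    abort("`n_samples` must be >= 1.")
  }
  if (dgamma < 0) abort("`dgamma` must be >= 0.")
  gamma <- norm_angle180(gamma)
  if (dgamma == 0) {
    fan <- rep(gamma, n_samples)
    u <- rep(0, n_samples)
  } else {
    # midpoint rule over the fan support
    u <- (-0.5 + (seq_len(n_samples) - 0.5) / n_samples) * dgamma
    fan <- gamma + u
  }
  w <- switch(weighting,
    uniform = rep(1 / n_samples, n_samples),
    gaussian = {
      sigma <- max(dgamma / 4, .Machine$double.eps)
      wg <- exp(-u^2 / (2 * sigma^2))
      wg / sum(wg)
    }
  )
  rot <- rotation_from_tilts(alpha, beta)
  f0 <- rbind(cos(fan * DEG2RAD), sin(fan * DEG2RAD), 0)
  list(axes = rot %*% f0, weights = w, fan_angles = fan)
}

# Azimuths where each fiber's pole circle crosses the Ewald circle on the
# reflection shell. For a unit fiber axis f, the reciprocal vectors of the
# reflection lie on the cone q . f = Q cos(pole_angle); the Ewald condition
# restricts q on the shell to the circle q_z = -Q sin(theta). Writing
# q = Q (cos(theta) cos(chi), cos(theta) sin(chi), -sin(theta)) the crossing
# condition is fx cos(chi) + fy sin(chi) = (cos_pole + sin_theta * fz) /
# cos_theta, with zero, one or two solutions in chi.
ewald_intersections <- function(axes, weights, geometry) {
  fx <- axes[1, ]
  fy <- axes[2, ]
  fz <- axes[3, ]
  rhs <- (geometry$cos_pole + geometry$sin_theta * fz) / geometry$cos_theta
  rt <- sqrt(fx^2 + fy^2)
  ok <- rt > 0 & abs(rhs) <= rt
  if (!any(ok)) {
    return(list(chi = numeric(0), w = numeric(0)))
  }
  phi0 <- atan2(fy[ok], fx[ok]) / DEG2RAD
  half <- acos(pmin(pmax(rhs[ok] / rt[ok], -1), 1)) / DEG2RAD
  list(
    chi = c(phi0 + half, phi0 - half),
    w = rep(weights[ok], 2L)
  )
}

# Deposit weighted azimuth positions onto the circular grid, splitting each
# deposit linearly between its two nearest bins (center of mass exact).
deposit_mass <- function(chi, w, n_bins) {
  out <- numeric(n_bins)
  if (!length(chi)) {
    return(out)
  }
  step <- 360 / n_bins
  pos <- (chi + 180) / step - 0.5 # continuous 0-based bin coordinate
  j0 <- floor(pos)
  frac <- pos - j0
  idx <- c(j0 %% n_bins, (j0 + 1L) %% n_bins) + 1L
  wts <- c(w * (1 - frac), w * frac)
  acc <- rowsum(wts, group = idx)
  out[as.integer(rownames(acc))] <- acc[, 1L]
  out
}

# Discrete wrapped-Gaussian smearing kernel (unit sum) and its FFT; the
# smeared curve is the circular convolution of the deposited mass with it.
smear_kernel_fft <- function(n_bins, sigma) {
  step <- 360 / n_bins
  offs <- c(0:(n_bins %/% 2), -((n_bins - n_bins %/% 2 - 1):1)) * step
  kern <- exp(-offs^2 / (2 * sigma^2))
  stats::fft(kern / sum(kern))
}

smear_mass <- function(mass, kern_fft) {
  out <- Re(stats::fft(stats::fft(mass) * kern_fft, inverse = TRUE)) /
    length(mass)
  pmax(out, 0) # clip FFT round-off noise
}

# Unnormalized single-group deposit-mass vector by fan quadrature.
group_mass <- function(alpha, beta, gamma, dgamma, n_bins,
                       n_quad, geometry, weighting) {
  g <- group_fiber_axes(alpha, beta, gamma, dgamma,
    n_samples = n_quad, weighting = weighting
  )
  is_ <- ewald_intersections(g$axes, g$weights, geometry)
  deposit_mass(is_$chi, is_$w, n_bins)
}

# Fast inner simulation: takes a named numeric parameter vector (already
# validated/normalized) and a precomputed kernel FFT; returns intensities.
simulate_core <- function(pv, grid, kern_fft, n_quad, geometry, weighting) {
  m1 <- group_mass(
    pv[["alpha1"]], pv[["beta1"]], pv[["gamma1"]], pv[["dgamma1"]],
    grid$n_bins, n_quad, geometry, weighting
  )
  m2 <- group_mass(
    pv[["alpha2"]], pv[["beta2"]], pv[["gamma2"]], pv[["dgamma2"]],
    grid$n_bins, n_quad, geometry, weighting
  )
  curve <- smear_mass(pv[["lam_ratio"]] * m1 + m2, kern_fft)
  mx <- max(curve)
  if (mx == 0) {
    return(list(intensity = curve, degenerate = TRUE))
  }
  list(intensity = curve / mx, degenerate = FALSE)
}

#' Simulate the azimuthal intensity profile of two fiber groups
#'
#' Forward diffraction model: each fiber group contributes an azimuthal
#' intensity profile computed by quadrature over its fan of fiber axes; for
#' every axis the pole circle of the reflection is intersected with the
#' Ewald circle on the reflection shell and the intersection azimuths are
#' deposited onto the chi grid with a wrapped Gaussian kernel of width
#' `smear_width` (sigma, degrees). The combined curve is
#' `lam_ratio * group1 + group2`, normalized to unit maximum.
#'
#' @param params a single orientation-parameter set (see
#'   [orientation_params()]); angles are normalized into their 180-degree
#'   period internally.
#' @param grid a [chi_grid()].
#' @param smear_width wrapped-Gaussian smearing sigma in degrees (> 0).
#' @param n_quad number of fan quadrature samples per group (>= 8).
#' @param geometry a [waxd_geometry()].
#' @param weighting within-fan weighting, `"uniform"` (default) or
#'   `"gaussian"`.
#' @return an [ichi_curve()] with all bins valid; if the geometry yields no
#'   Ewald intersections a zero curve flagged `degenerate` is returned with
#'   a warning.
#' @examples
#' p <- orientation_params(0, 0, 30, 40, 0, 0, -30, 40, lam_ratio = 2)
#' curve <- simulate_ichi(p)
#' @export
simulate_ichi <- function(params, grid = chi_grid(), smear_width = 5,
                          n_quad = 721L, geometry = waxd_geometry(),
                          weighting = c("gaussian", "uniform")) {
  weighting <- match.arg(weighting)
  if (smear_width <= 0) abort("`smear_width` must be > 0.")
  if (n_quad < 8L) abort("`n_quad` must be >= 8.")
  p <- as_params_row(params)
  res <- simulate_core(
    unlist(p[1, ]), grid, smear_kernel_fft(grid$n_bins, smear_width),
    n_quad, geometry, weighting
  )
  if (res$degenerate) {
    warn("degenerate geometry: no Ewald intersections; returning zero curve.")
  }
  ichi_curve(res$intensity, grid = grid, degenerate = res$degenerate)
}

#' Simulate many parameter sets into an intensity matrix
#'
#' Row-wise driver over a parameter tibble, used for dataset generation and
#' curve reconstruction.
#'
#' @param params_tbl tibble of parameter rows ([orientation_params()] columns).
#' @inheritParams simulate_ichi
#' @return numeric matrix, one row per parameter set, `grid$n_bins` columns.
#' @export
simulate_curves <- function(params_tbl, grid = chi_grid(), smear_width = 5,
                            n_quad = 721L, geometry = waxd_geometry(),
                            weighting = "gaussian") {
  params_tbl <- validate_params(params_tbl)
  kern_fft <- smear_kernel_fft(grid$n_bins, smear_width)
  pm <- as.matrix(params_tbl)
  out <- matrix(0, nrow(pm), grid$n_bins)
  for (i in seq_len(nrow(pm))) {
    out[i, ] <- simulate_core(
      pm[i, ], grid, kern_fft, n_quad, geometry, weighting
    )$intensity
  }
  out
}

#' Monte-Carlo forward simulation (brute-force oracle)
#'
#' Same physical model as [simulate_ichi()], but the fan integral is
#' estimated by random sampling: fiber axes are drawn from the within-fan
#' distribution and their Ewald-intersection azimuths deposited with the
#' same wrapped-Gaussian kernel. Draws are split into batches and per-bin
#' Monte-Carlo standard errors are estimated from the batch spread (returned
#' as attribute `mc_se`, on the scale of the normalized curve).
#'
#' @inheritParams simulate_ichi
#' @param n_draws number of random fiber draws per group (>= 1000).
#' @param seed integer RNG seed.
#' @param n_batches batches used for the standard-error estimate.
#' @return an [ichi_curve()] with attribute `mc_se`.
#' @export
simulate_ichi_mc <- function(params, grid = chi_grid(), smear_width = 5,
                             n_draws = 100000L, seed = 1L,
                             geometry = waxd_geometry(),
                             weighting = c("gaussian", "uniform"),
                             n_batches = 20L) {
  weighting <- match.arg(weighting)
  if (n_draws < 1000L) abort("`n_draws` must be >= 1000.")
  p <- as_params_row(params)
  n_batches <- max(2L, as.integer(n_batches))
  per_batch <- ceiling(n_draws / n_batches)

  kern_fft <- smear_kernel_fft(grid$n_bins, smear_width)
  draw_group <- function(alpha, beta, gamma, dgamma, n) {
    gamma <- norm_angle180(gamma)
    if (dgamma == 0) {
      fan <- rep(gamma, n)
    } else if (weighting == "uniform") {
      fan <- runif(n, gamma - dgamma / 2, gamma + dgamma / 2)
    } else {
      sigma <- dgamma / 4
      fan <- numeric(0)
      while (length(fan) < n) {
        cand <- rnorm(2L * n, gamma, sigma)
        cand <- cand[abs(cand - gamma) <= dgamma / 2]
        fan <- c(fan, cand)
      }
      fan <- fan[seq_len(n)]
    }
    rot <- rotation_from_tilts(alpha, beta)
    axes <- rot %*% rbind(cos(fan * DEG2RAD), sin(fan * DEG2RAD), 0)
    is_ <- ewald_intersections(axes, rep(1 / n, n), geometry)
    deposit_mass(is_$chi, is_$w, grid$n_bins)
  }

  batches <- with_seed(seed, {
    lapply(seq_len(n_batches), function(b) {
      g1 <- draw_group(p$alpha1, p$beta1, p$gamma1, p$dgamma1, per_batch)
      g2 <- draw_group(p$alpha2, p$beta2, p$gamma2, p$dgamma2, per_batch)
      smear_mass(p$lam_ratio * g1 + g2, kern_fft)
    })
  })
  bm <- do.call(rbind, batches)
  combined <- colMeans(bm)
  se_raw <- apply(bm, 2, sd) / sqrt(n_batches)
  m <- max(combined)
  if (m == 0) {
    warn("degenerate geometry: no Ewald intersections; returning zero curve.")
    out <- ichi_curve(combined, grid = grid, degenerate = TRUE)
    attr(out, "mc_se") <- se_raw
    return(out)
  }
  imax <- which.max(combined)
  curve <- combined / m
  # conservative SE on the normalized scale: direct error plus the error
  # propagated through the unit-max normalization
  se_norm <- (se_raw + curve * se_raw[imax]) / m
  out <- ichi_curve(curve, grid = grid)
  attr(out, "mc_se") <- se_norm
  out
}
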