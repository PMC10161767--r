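#' Canonicalize the order of the two fiber groups
#'
#' The two fiber groups can be swapped without changing the simulated curve
#' (the quantity ratio inverts), so the regression target would be
#' ill-defined without a convention. The group with the larger mean in-plane
#' angle `gamma` is defined as group 1. Ties on `gamma` are broken by the
#' larger `dgamma`, then the larger `beta`. Swapping the groups inverts
#' `lam_ratio`. Idempotent; works row-wise on a parameter tibble.
#'
#' @param params parameter tibble (any number of rows) or a single set.
#' @return parameter tibble of the same size with `gamma1 >= gamma2`.
#' @examples
#' canonical_order(orientation_params(gamma1 = 10, gamma2 = 50, lam_ratio = 2))
#' @export
canonical_order <- function(params) {
  p <- validate_params(params)
  swap <- p$gamma2 > p$gamma1 |
    (p$gamma2 == p$gamma1 & p$dgamma2 > p$dgamma1) |
    (p$gamma2 == p$gamma1 & p$dgamma2 == p$dgamma1 & p$beta2 > p$beta1)
  if (any(swap)) {
    g1 <- c("alpha1", "beta1", "gamma1", "dgamma1")
    g2 <- c("alpha2", "beta2", "gamma2", "dgamma2")
    tmp <- p[swap, g1]
    p[swap, g1] <- p[swap, g2]
    p[swap, g2] <- tmp
    p$lam_ratio[swap] <- 1 / p$lam_ratio[swap]
  }
  p
}

is_canonical <- function(params) {
  p <- validate_params(params)
  p$gamma1 >= p$gamma2
}

#' Encode orientation parameters as a 17-value regression target
#'
#' Each of the eight angle labels is periodic with period 180; a direct
#' regression on the angle value would have a jump discontinuity at the
#' +/-90 boundary. The angle is therefore doubled (mapping the period onto
#' the full circle) and represented as a point on the unit circle,
#' `(x, y) = (cos 2*theta, sin 2*theta)`, so physically identical angles
#' such as -90 and +90 share one encoding. The quantity ratio is encoded as
#' `log(lam_ratio)` so reciprocal ratios are symmetric about zero.
#'
#' @param params canonically ordered parameter tibble (see
#'   [canonical_order()]); non-canonical input is an error.
#' @return numeric matrix, one row per parameter set, 17 named columns.
#' @examples
#' encode_labels(orientation_params(gamma1 = 45))
#' @export
encode_labels <- function(params) {
  p <- validate_params(params)
  if (!all(is_canonical(p))) {
    abort("params must be canonically ordered (gamma1 >= gamma2); see canonical_order().")
  }
  out <- matrix(0, nrow(p), 17L, dimnames = list(NULL, LABEL_NAMES))
  for (i in seq_along(ANGLE_NAMES)) {
    th2 <- 2 * p[[ANGLE_NAMES[i]]] * DEG2RAD
    out[, 2 * i - 1] <- cos(th2)
    out[, 2 * i] <- sin(th2)
  }
  out[, 17] <- log(p$lam_ratio)
  out
}

#' Decode a 17-value regression output into orientation parameters
#'
#' Inverse of [encode_labels()], tolerant to raw regressor outputs: each
#' angle is recovered as half the two-argument arctangent of its (x, y)
#' pair (the radius is ignored, so off-circle points are fine), mapped into
#' (-90, 90]; the spreads `dgamma` are mapped into [0, 180); the quantity
#' ratio is exponentiated. Canonical group order is re-applied, since
#' independent per-output noise can break it.
#'
#' @param labels numeric matrix (n x 17) or vector of length 17.
#' @return parameter tibble with n rows.
#' @export
decode_labels <- function(labels) {
  if (is.null(dim(labels))) labels <- matrix(labels, nrow = 1L)
  if (ncol(labels) != 17L) abort("`labels` must have 17 columns.")
  p <- tibble::as_tibble(matrix(0, nrow(labels), 9L,
    dimnames = list(NULL, PARAM_NAMES)
  ))
  for (i in seq_along(ANGLE_NAMES)) {
    x <- unname(labels[, 2 * i - 1])
    y <- unname(labels[, 2 * i])
    if (any(x == 0 & y == 0)) {
      abort(sprintf(
        "undefined angle: (x, y) = (0, 0) for label %s.", ANGLE_NAMES[i]
      ))
    }
    th <- norm_angle180(atan2(y, x) / DEG2RAD / 2)
    if (grepl("^dgamma", ANGLE_NAMES[i])) {
      th <- ifelse(th < 0, th + 180, th)
    }
    p[[ANGLE_NAMES[i]]] <- th
  }
  p$lam_ratio <- unname(exp(labels[, 17]))
  canonical_order(p)
}
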