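#' @importFrom rlang abort warn `%||%`
#' @importFrom stats rnorm runif rpois cor sd quantile
#' @importFrom utils head tail modifyList
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Normalize angles into the canonical 180-degree period
#'
#' All orientation angles of the fiber model are defined modulo 180 degrees:
#' a fiber axis is a line, not a vector, so an angle and its 180-degree
#' complement describe the same physical configuration. This maps any finite
#' angle into the canonical interval (-90, 90].
#'
#' @param theta numeric vector of angles in degrees.
#' @return numeric vector in (-90, 90].
#' @examples
#' norm_angle180(c(-90, 90, 180, 270))
#' @export
norm_angle180 <- function(theta) {
  stopifnot(is.numeric(theta))
  out <- theta - 180 * ceiling((theta - 90) / 180)
  # guard against ceiling() rounding at representable boundaries
  out[out <= -90] <- out[out <= -90] + 180
  out[out > 90] <- out[out > 90] - 180
  out
}

#' Circular difference of two angles on the 180-degree circle
#'
#' Returns the signed difference `a - b` wrapped into (-90, 90], i.e. the
#' shortest rotation between two fiber-angle values.
#'
#' @param a,b numeric vectors of angles in degrees.
#' @return numeric vector in (-90, 90].
#' @export
angle_diff180 <- function(a, b) {
  norm_angle180(a - b)
}

# Deterministic per-index sub-seed derivation; keeps results below 2^31.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 9973
  as.integer(s %% 2147483629L) + 1L
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
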