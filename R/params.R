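#' Orientation parameters for two fiber groups
#'
#' Builds a one-row-per-sample tibble of the nine physical orientation
#' labels: for each fiber group a plane tilt about the lab x axis (`alpha`),
#' a tilt about the lab y axis (`beta`), the mean in-plane fiber angle
#' (`gamma`) and the in-plane angular spread of the fan (`dgamma`), all in
#' degrees, plus the quantity ratio `lam_ratio` = lambda1/lambda2 of the two
#' groups. Tilt and mean angles are periodic with period 180 and are
#' normalized into (-90, 90]; spreads are clamped-checked to be >= 0.
#'
#' @param alpha1,beta1,gamma1,dgamma1 group-1 angles (degrees).
#' @param alpha2,beta2,gamma2,dgamma2 group-2 angles (degrees).
#' @param lam_ratio positive finite quantity ratio lambda1/lambda2.
#' @return a tibble with the nine parameter columns, angles normalized.
#' @examples
#' orientation_params(0, 0, 40, 30, 0, 0, -20, 60, lam_ratio = 1.5)
#' @export
orientation_params <- function(alpha1 = 0, beta1 = 0, gamma1 = 0, dgamma1 = 0,
                               alpha2 = 0, beta2 = 0, gamma2 = 0, dgamma2 = 0,
                               lam_ratio = 1) {
  p <- tibble::tibble(
    alpha1 = as.double(alpha1), beta1 = as.double(beta1),
    gamma1 = as.double(gamma1), dgamma1 = as.double(dgamma1),
    alpha2 = as.double(alpha2), beta2 = as.double(beta2),
    gamma2 = as.double(gamma2), dgamma2 = as.double(dgamma2),
    lam_ratio = as.double(lam_ratio)
  )
  validate_params(p)
}

# Normalize periodic angles and check domains on a params tibble.
validate_params <- function(p) {
  missing_cols <- setdiff(PARAM_NAMES, names(p))
  if (length(missing_cols)) {
    abort(paste0(
      "params must contain columns: ", paste(missing_cols, collapse = ", ")
    ))
  }
  p <- tibble::as_tibble(p)[PARAM_NAMES]
  if (!all(vapply(p, function(x) all(is.finite(x)), logical(1)))) {
    abort("all orientation parameters must be finite.")
  }
  for (nm in c("alpha1", "beta1", "gamma1", "alpha2", "beta2", "gamma2")) {
    p[[nm]] <- norm_angle180(p[[nm]])
  }
  if (any(p$dgamma1 < 0) || any(p$dgamma2 < 0)) {
    abort("`dgamma1` and `dgamma2` must be >= 0.")
  }
  if (any(p$dgamma1 > 180) || any(p$dgamma2 > 180)) {
    abort("`dgamma1` and `dgamma2` must be <= 180 degrees.")
  }
  if (any(p$lam_ratio <= 0)) {
    abort("`lam_ratio` must be > 0.")
  }
  p
}

# Coerce a single parameter set (1-row data frame, named list or named
# vector) to a validated 1-row tibble.
as_params_row <- function(params) {
  if (is.numeric(params) && !is.null(names(params))) {
    params <- tibble::as_tibble(as.list(params))
  } else if (is.list(params) && !is.data.frame(params)) {
    params <- tibble::as_tibble(params[PARAM_NAMES])
  }
  params <- validate_params(params)
  if (nrow(params) != 1L) {
    abort("expected a single parameter set (one row).")
  }
  params
}
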