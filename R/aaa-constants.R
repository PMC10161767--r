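# Package-wide constants: parameter layout of the nine orientation labels
# and the 17-value encoded target (defined here so every file can use them
# at load time).

DEG2RAD <- pi / 180

PARAM_NAMES <- c(
  "alpha1", "beta1", "gamma1", "dgamma1",
  "alpha2", "beta2", "gamma2", "dgamma2",
  "lam_ratio"
)

ANGLE_NAMES <- c(
  "alpha1", "beta1", "gamma1", "dgamma1",
  "alpha2", "beta2", "gamma2", "dgamma2"
)

LABEL_NAMES <- c(
  as.vector(vapply(ANGLE_NAMES, function(nm) paste0(nm, c("_x", "_y")),
    character(2)
  )),
  "log_lam_ratio"
)
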