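Package: fiborient
Title: Fiber Orientation Recovery from WAXD Azimuthal Intensity Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward simulation and machine-learning inversion of wide-angle
    X-ray diffraction (WAXD) azimuthal intensity profiles I(chi) for samples
    containing two groups of textured nanofibers, such as the chitin fiber
    networks of arthropod cuticle. Provides a diffraction-geometry forward
    model for the (110) reflection, a data-corruption pipeline (Poisson
    noise, circular blockwise masking, intensity scaling) that makes
    simulation-trained models robust to detector gaps, a periodic angle
    label codec, a fully connected neural-network regressor trained with
    mean-absolute-error loss and Adam plus classical baselines,
    reconstruction-based evaluation metrics, and gradient saliency maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    randomForest,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
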