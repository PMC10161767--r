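#' Write an I(chi) curve as delimited text
#'
#' Two tab-separated columns, `chi_deg` and `intensity`, one row per bin;
#' masked bins are written as `NaN`. The format round-trips through
#' [read_curve()].
#'
#' @param curve an [ichi_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "ichi_curve"))
  inten <- ifelse(curve$valid_mask, curve$intensity, NaN)
  df <- data.frame(
    chi_deg = curve$grid$chi_centers,
    intensity = inten
  )
  utils::write.table(
    format(df, digits = 12, trim = TRUE, scientific = FALSE),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read an I(chi) curve from delimited text
#'
#' Expects the two-column layout of [write_curve()] (whitespace or tab
#' separated, header optional). `NaN`/`NA` intensities become masked bins.
#' Malformed rows, non-uniform chi spacing and duplicate chi values are
#' rejected with line-numbered diagnostics.
#'
#' @param path input file path.
#' @return an [ichi_curve()].
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (!length(lines)) abort(sprintf("%s: empty file.", path))
  start <- 1L
  first <- strsplit(trimws(lines[1]), "[\t ,]+")[[1]]
  if (any(is.na(suppressWarnings(as.numeric(first))) &
            !first %in% c("NaN", "NA"))) {
    start <- 2L # header row
  }
  n <- length(lines) - start + 1L
  chi <- numeric(n)
  inten <- numeric(n)
  for (i in seq_len(n)) {
    ln <- trimws(lines[start + i - 1L])
    if (!nzchar(ln)) abort(sprintf("%s: line %d is empty.", path, start + i - 1L))
    parts <- strsplit(ln, "[\t ,]+")[[1]]
    if (length(parts) != 2L) {
      abort(sprintf(
        "%s: line %d has %d fields (expected 2).", path, start + i - 1L,
        length(parts)
      ))
    }
    vals <- suppressWarnings(as.numeric(parts))
    if (is.na(vals[1])) {
      abort(sprintf("%s: line %d has a non-numeric chi value.", path, start + i - 1L))
    }
    chi[i] <- vals[1]
    inten[i] <- vals[2]
  }
  if (anyDuplicated(chi)) {
    abort(sprintf(
      "%s: duplicate chi value at line %d.", path,
      start + anyDuplicated(chi) - 1L
    ))
  }
  steps <- diff(chi)
  if (length(steps) && (max(steps) - min(steps)) > 1e-6 * abs(mean(steps))) {
    abort(sprintf("%s: non-uniform chi grid.", path))
  }
  grid <- chi_grid(length(chi))
  if (max(abs(grid$chi_centers - chi)) > 1e-6) {
    abort(sprintf("%s: chi values are not bin centers over [-180, 180).", path))
  }
  mask <- is.finite(inten)
  inten[!mask] <- 0
  ichi_curve(inten, grid = grid, valid_mask = mask)
}

#' Save / load a dataset
#'
#' Datasets are runtime artifacts (matrices plus metadata) and are stored
#' as a single RDS file.
#'
#' @param dataset a `fiber_dataset`.
#' @param path file path.
#' @return `path` / the dataset.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "fiber_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ds <- readRDS(path)
  if (!inherits(ds, "fiber_dataset")) abort("not a fiber_dataset file.")
  ds
}

#' Save / load a fitted model
#'
#' @param model a fitted model.
#' @param path file path.
#' @return `path` / the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "fib_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  m <- readRDS(path)
  if (!inherits(m, "fib_model")) abort("not a model file.")
  m
}

#' Detector geometry for azimuthal integration
#'
#' @param beam_center c(x, y) beam-center position in pixels (1-based,
#'   x = column, y = row).
#' @param pixel_size_um detector pixel size in micrometres.
#' @param det_distance_mm sample-to-detector distance in mm.
#' @param energy_kev photon energy in keV.
#' @param radial_window c(min, max) radius window of the reflection ring in
#'   pixels.
#' @return an object of class `beam_geometry`.
#' @export
beam_geometry <- function(beam_center, pixel_size_um = 172,
                          det_distance_mm = 262.3, energy_kev = 10,
                          radial_window) {
  stopifnot(
    length(beam_center) == 2L, pixel_size_um > 0, det_distance_mm > 0,
    energy_kev > 0, length(radial_window) == 2L
  )
  if (radial_window[1] >= radial_window[2] || radial_window[1] < 0) {
    abort("`radial_window` must be an increasing non-negative interval.")
  }
  structure(
    list(
      beam_center = as.double(beam_center),
      pixel_size_um = pixel_size_um,
      det_distance_mm = det_distance_mm,
      energy_kev = energy_kev,
      radial_window = as.double(radial_window)
    ),
    class = "beam_geometry"
  )
}

#' Azimuthal (ring) integration of a detector frame
#'
#' Averages unmasked pixel intensities per azimuth bin within the radial
#' window of the reflection ring. The azimuth convention matches the
#' simulator: 0 degrees along +x (columns), counter-clockwise (+y up, i.e.
#' decreasing row index). Pixels below 0 or above `saturation` are masked
#' automatically; chi bins with no contributing pixel become masked bins.
#'
#' @param image numeric matrix (rows y, columns x).
#' @param geometry a [beam_geometry()].
#' @param mask_image optional logical matrix, TRUE = usable pixel.
#' @param grid output [chi_grid()].
#' @param saturation upper intensity threshold for automatic masking.
#' @return an [ichi_curve()].
#' @export
azimuthal_integrate <- function(image, geometry, mask_image = NULL,
                                grid = chi_grid(), saturation = 100000) {
  stopifnot(is.matrix(image), inherits(geometry, "beam_geometry"))
  if (is.null(mask_image)) mask_image <- matrix(TRUE, nrow(image), ncol(image))
  if (!all(dim(mask_image) == dim(image))) {
    abort("`mask_image` must match the image dimensions.")
  }
  mask <- mask_image & image >= 0 & image <= saturation
  xs <- matrix(seq_len(ncol(image)), nrow(image), ncol(image), byrow = TRUE) -
    geometry$beam_center[1]
  ys <- geometry$beam_center[2] -
    matrix(seq_len(nrow(image)), nrow(image), ncol(image)) # +y up
  r <- sqrt(xs^2 + ys^2)
  inring <- mask & r >= geometry$radial_window[1] &
    r <= geometry$radial_window[2]
  if (!any(inring)) abort("empty radial window: no usable pixels in the ring.")
  chi <- atan2(ys[inring], xs[inring]) / DEG2RAD
  bin <- floor((chi + 180) / grid$step) + 1L
  bin[bin > grid$n_bins] <- 1L
  vals <- image[inring]
  sums <- rowsum(vals, bin)
  counts <- rowsum(rep(1, length(vals)), bin)
  inten <- numeric(grid$n_bins)
  vm <- rep(FALSE, grid$n_bins)
  idx <- as.integer(rownames(sums))
  inten[idx] <- sums[, 1] / counts[, 1]
  vm[idx] <- TRUE
  inten[!vm] <- 0
  ichi_curve(inten, grid = grid, valid_mask = vm)
}

#' Read a 2D detector frame
#'
#' Reads a detector image into the numeric matrix expected by
#' [azimuthal_integrate()]. TIFF frames are read via the tiff package
#' (integer counts preserved); plain-text matrices (whitespace-delimited
#' rows) are read directly.
#'
#' @param path image path (`.tif`/`.tiff` or delimited text).
#' @return numeric matrix (rows y, columns x).
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("the tiff package is required to read TIFF frames.")
    }
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) img <- img[, , 1L] # first channel
    return(img)
  }
  as.matrix(utils::read.table(path))
}
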