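#' @useDynLib octava, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Physical geometry of an en face scan
#'
#' Couples the pixel grid of an en face OCTA image to its physical field of
#' view, so that millimetre-scale structures (the fovea, exclusion regions)
#' can be placed on the grid. Square pixels are assumed for native scans.
#'
#' @param height_px,width_px positive integers, grid size in pixels.
#' @param field_mm positive physical side length of the scan in millimetres
#'   (6 mm for the standard macular field this package targets).
#' @return An object of class `image_geometry` with fields `height_px`,
#'   `width_px` and `field_mm`.
#' @examples
#' g <- image_geometry(400, 400)
#' pixel_pitch(g)  # 0.015 mm per pixel
#' @export
image_geometry <- function(height_px, width_px, field_mm = 6.0) {
  height_px <- as.integer(height_px)
  width_px <- as.integer(width_px)
  stopifnot(length(height_px) == 1L, length(width_px) == 1L,
            height_px >= 1L, width_px >= 1L)
  if (!is.numeric(field_mm) || length(field_mm) != 1L || field_mm <= 0)
    stop("field_mm must be a positive real", call. = FALSE)
  structure(list(height_px = height_px, width_px = width_px,
                 field_mm = as.numeric(field_mm)),
            class = "image_geometry")
}

#' @rdname image_geometry
#' @param geometry an `image_geometry`.
#' @export
pixel_pitch <- function(geometry) {
  stopifnot(inherits(geometry, "image_geometry"))
  geometry$field_mm / geometry$width_px
}

#' @export
print.image_geometry <- function(x, ...) {
  cat(sprintf("<image_geometry> %d x %d px, %.3g mm field (%.5g mm/px)\n",
              x$height_px, x$width_px, x$field_mm, pixel_pitch(x)))
  invisible(x)
}

same_geometry <- function(a, b) {
  a$height_px == b$height_px && a$width_px == b$width_px &&
    isTRUE(all.equal(a$field_mm, b$field_mm))
}

check_geometry_match <- function(a, b, what = "objects") {
  if (!same_geometry(a, b))
    stop(sprintf("geometry mismatch between %s: %dx%d/%.3gmm vs %dx%d/%.3gmm",
                 what, a$height_px, a$width_px, a$field_mm,
                 b$height_px, b$width_px, b$field_mm), call. = FALSE)
  invisible(TRUE)
}

check_grid <- function(m, geometry, what) {
  if (!is.matrix(m) || nrow(m) != geometry$height_px ||
      ncol(m) != geometry$width_px)
    stop(sprintf("%s grid shape (%s) does not match geometry %dx%d",
                 what, paste(dim(m), collapse = "x"),
                 geometry$height_px, geometry$width_px), call. = FALSE)
  invisible(TRUE)
}

#' Grayscale en face OCTA image
#'
#' The raw network input: an 8-bit intensity grid whose values carry the
#' decorrelation (flow) signal, together with its physical geometry.
#'
#' @param pixels integer matrix of intensities in \[0, 255\], rows = image
#'   rows (origin top-left).
#' @param geometry an [image_geometry()]; defaults to a 6 mm field matching
#'   the pixel grid.
#' @param id subject-eye identifier string.
#' @return An `octa_image` object.
#' @export
octa_image <- function(pixels, geometry = NULL, id = "unknown") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (is.null(geometry)) geometry <- image_geometry(nrow(pixels), ncol(pixels))
  check_grid(pixels, geometry, "octa_image")
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L)
    stop("octa_image intensities must be integers in [0, 255]", call. = FALSE)
  structure(list(pixels = pixels, geometry = geometry, id = as.character(id)),
            class = "octa_image")
}

#' @export
print.octa_image <- function(x, ...) {
  cat(sprintf("<octa_image> id=%s, %d x %d px, mean intensity %.1f\n",
              x$id, x$geometry$height_px, x$geometry$width_px,
              mean(x$pixels)))
  invisible(x)
}

# label codes for sparse artery/vein vessel maps
AV_BACKGROUND <- 0L
AV_ARTERY <- 1L
AV_VEIN <- 2L

#' Sparse artery/vein vessel label map
#'
#' Per-pixel labels from manual grading of large vessels: every pixel is
#' exactly one of artery, vein or background. Background pixels are what the
#' kNN propagation step later assigns to arterial or venous territories.
#'
#' @param labels integer matrix over codes 0 (background), 1 (artery),
#'   2 (vein).
#' @param geometry an [image_geometry()] (defaulted from the grid if NULL).
#' @return An `av_map` object.
#' @export
av_map <- function(labels, geometry = NULL) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (is.null(geometry)) geometry <- image_geometry(nrow(labels), ncol(labels))
  check_grid(labels, geometry, "av_map")
  if (anyNA(labels) || !all(labels %in% c(AV_BACKGROUND, AV_ARTERY, AV_VEIN)))
    stop("av_map labels must be 0 (background), 1 (artery) or 2 (vein)",
         call. = FALSE)
  structure(list(labels = labels, geometry = geometry), class = "av_map")
}

#' @export
print.av_map <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf(
    "<av_map> %d x %d px: %d artery, %d vein, %d background pixels\n",
    x$geometry$height_px, x$geometry$width_px,
    sum(x$labels == AV_ARTERY), sum(x$labels == AV_VEIN),
    sum(x$labels == AV_BACKGROUND)))
  invisible(x)
}

#' Dense arterial-venous area (AVA) map
#'
#' A binary partition of the full field: 1 marks pixels in arterial
#' territory, 0 pixels in venous territory. There is no third state — every
#' pixel belongs to exactly one side. This is both the network target and
#' its thresholded output.
#'
#' @param labels binary (0/1) integer matrix.
#' @param geometry an [image_geometry()] (defaulted from the grid if NULL).
#' @return An `ava_map` object.
#' @export
ava_map <- function(labels, geometry = NULL) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (is.null(geometry)) geometry <- image_geometry(nrow(labels), ncol(labels))
  check_grid(labels, geometry, "ava_map")
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("ava_map labels must be binary: 1 = arterial area, 0 = venous area",
         call. = FALSE)
  structure(list(labels = labels, geometry = geometry), class = "ava_map")
}

#' @export
print.ava_map <- function(x, ...) {
  cat(sprintf("<ava_map> %d x %d px: %.1f%% arterial area\n",
              x$geometry$height_px, x$geometry$width_px,
              100 * mean(x$labels)))
  invisible(x)
}

#' Intensity-preserving OCTA-AV map
#'
#' The OCTA image split into an arterial and a venous channel by an AVA map:
#' each channel keeps the original 8-bit intensity on its side of the
#' partition and is zero elsewhere, so perfusion-intensity features can be
#' computed per territory without binarising the angiogram.
#'
#' @param arterial,venous integer matrices of intensities in \[0, 255\]; at
#'   every pixel at most one of the two is nonzero.
#' @param geometry an [image_geometry()] (defaulted from the grid if NULL).
#' @return An `octa_av_map` object.
#' @export
octa_av_map <- function(arterial, venous, geometry = NULL) {
  arterial <- as.matrix(arterial); venous <- as.matrix(venous)
  storage.mode(arterial) <- "integer"; storage.mode(venous) <- "integer"
  if (is.null(geometry))
    geometry <- image_geometry(nrow(arterial), ncol(arterial))
  check_grid(arterial, geometry, "octa_av_map arterial channel")
  check_grid(venous, geometry, "octa_av_map venous channel")
  rng <- range(arterial, venous)
  if (rng[1] < 0L || rng[2] > 255L)
    stop("octa_av_map intensities must be in [0, 255]", call. = FALSE)
  if (any(arterial > 0L & venous > 0L))
    stop("octa_av_map channels overlap: some pixels are nonzero in both",
         call. = FALSE)
  structure(list(arterial = arterial, venous = venous, geometry = geometry),
            class = "octa_av_map")
}

#' @export
print.octa_av_map <- function(x, ...) {
  cat(sprintf("<octa_av_map> %d x %d px\n",
              x$geometry$height_px, x$geometry$width_px))
  invisible(x)
}

#' Quantification exclusion mask
#'
#' Boolean grid marking which pixels participate in feature quantification
#' (`TRUE` = kept). The default analysis mask excludes the fovea disk, where
#' the avascular zone makes territory assignment artificial, and the vendor
#' layer-indicator overlay in the bottom-left corner.
#'
#' @param keep logical matrix.
#' @param geometry an [image_geometry()] (defaulted from the grid if NULL).
#' @return An `exclusion_mask` object.
#' @export
exclusion_mask <- function(keep, geometry = NULL) {
  keep <- as.matrix(keep)
  if (!is.logical(keep) || anyNA(keep))
    stop("exclusion mask must be a logical matrix without NA", call. = FALSE)
  if (is.null(geometry)) geometry <- image_geometry(nrow(keep), ncol(keep))
  check_grid(keep, geometry, "exclusion_mask")
  structure(list(keep = keep, geometry = geometry), class = "exclusion_mask")
}

#' @export
print.exclusion_mask <- function(x, ...) {
  cat(sprintf("<exclusion_mask> %d x %d px, %d excluded (%.2f%%)\n",
              x$geometry$height_px, x$geometry$width_px,
              sum(!x$keep), 100 * mean(!x$keep)))
  invisible(x)
}
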