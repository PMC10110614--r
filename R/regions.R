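# Exclusion geometry applied before quantification: the fovea disk (where
# territory assignment is artificial because the foveal avascular zone has
# no vessels) and the vendor layer-indicator overlay in the bottom-left
# corner. Exclusion is an analysis-time concept only; network training uses
# the full field.

#' Fovea exclusion mask
#'
#' Excludes a central disk of the given physical diameter. Commercial
#' scanners centre the macular scan on the fovea, so the disk is placed at
#' the image centre. A pixel is excluded when its centre lies strictly
#' within `diameter_mm / 2` of the image centre, which makes membership
#' deterministic and stable across resolutions.
#'
#' @param geometry an [image_geometry()].
#' @param diameter_mm disk diameter in millimetres (default 1 mm); must be
#'   smaller than the field.
#' @return An [exclusion_mask()] with `keep = FALSE` on the disk.
#' @export
fovea_mask <- function(geometry, diameter_mm = 1.0) {
  stopifnot(inherits(geometry, "image_geometry"))
  if (!is.numeric(diameter_mm) || length(diameter_mm) != 1L || diameter_mm < 0)
    stop("diameter_mm must be a nonnegative real", call. = FALSE)
  if (diameter_mm >= geometry$field_mm)
    stop(sprintf("fovea diameter (%g mm) must be smaller than the field (%g mm)",
                 diameter_mm, geometry$field_mm), call. = FALSE)
  h <- geometry$height_px; w <- geometry$width_px
  r_px <- (diameter_mm / 2) / pixel_pitch(geometry)
  # pixel centres at 0-based coordinates; image centre at ((h-1)/2, (w-1)/2)
  ci <- (h - 1) / 2; cj <- (w - 1) / 2
  di2 <- (seq_len(h) - 1 - ci)^2
  dj2 <- (seq_len(w) - 1 - cj)^2
  keep <- outer(di2, dj2, `+`) >= r_px^2  # strict '<' exclusion
  exclusion_mask(keep, geometry)
}

#' Layer-indicator exclusion mask
#'
#' Excludes the axis-aligned rectangle anchored at the bottom-left corner of
#' the image where the vendor export stamps its retinal-layer indicator.
#' The rectangle spans `floor(width_frac * width)` by
#' `floor(height_frac * height)` pixels (at least 1 each).
#'
#' @param geometry an [image_geometry()].
#' @param width_frac,height_frac rectangle extent as fractions of the image
#'   width and height, in (0, 1).
#' @return An [exclusion_mask()] with `keep = FALSE` on the rectangle.
#' @export
indicator_mask <- function(geometry, width_frac = 0.25, height_frac = 0.05) {
  stopifnot(inherits(geometry, "image_geometry"))
  for (f in c(width_frac, height_frac))
    if (!is.numeric(f) || length(f) != 1L || f <= 0 || f >= 1)
      stop("indicator fractions must lie strictly in (0, 1)", call. = FALSE)
  h <- geometry$height_px; w <- geometry$width_px
  rw <- max(1L, as.integer(floor(width_frac * w)))
  rh <- max(1L, as.integer(floor(height_frac * h)))
  keep <- matrix(TRUE, h, w)
  keep[(h - rh + 1L):h, 1L:rw] <- FALSE  # bottom rows, leftmost columns
  exclusion_mask(keep, geometry)
}

#' Combine exclusion masks
#'
#' A pixel is kept only if every mask keeps it (logical AND of `keep`
#' grids); the excluded set is the union of the inputs' excluded sets.
#'
#' @param ... [exclusion_mask()] objects (or a single list of them) over
#'   identical geometry.
#' @return The combined [exclusion_mask()].
#' @export
combine_masks <- function(...) {
  masks <- list(...)
  if (length(masks) == 1L && !inherits(masks[[1]], "exclusion_mask"))
    masks <- masks[[1]]
  if (length(masks) == 0L) stop("no masks supplied", call. = FALSE)
  for (m in masks) stopifnot(inherits(m, "exclusion_mask"))
  g <- masks[[1]]$geometry
  keep <- masks[[1]]$keep
  for (m in masks[-1]) {
    check_geometry_match(g, m$geometry, "masks")
    keep <- keep & m$keep
  }
  exclusion_mask(keep, g)
}

#' Default analysis mask
#'
#' The standard quantification mask: fovea disk plus bottom-left layer
#' indicator.
#'
#' @param geometry an [image_geometry()].
#' @param fovea_diameter_mm fovea disk diameter (mm).
#' @param indicator_width_frac,indicator_height_frac indicator rectangle
#'   fractions.
#' @return An [exclusion_mask()].
#' @export
analysis_mask <- function(geometry, fovea_diameter_mm = 1.0,
                          indicator_width_frac = 0.25,
                          indicator_height_frac = 0.05) {
  combine_masks(fovea_mask(geometry, fovea_diameter_mm),
                indicator_mask(geometry, indicator_width_frac,
                               indicator_height_frac))
}
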