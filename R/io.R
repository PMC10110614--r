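# Image and label-map readers/writers. All maps travel as lossless PNG (or
# 8-bit grayscale TIFF for the OCTA input); geometry is inferred from the
# pixel grid plus the stated physical field.

ext_of <- function(path) tolower(tools::file_ext(path))

read_raster <- function(path) {
  ext <- ext_of(path)
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (!is.null(info$bit.depth) && info$bit.depth > 8L)
      stop(sprintf("'%s': %d-bit image, expected 8-bit", path, info$bit.depth),
           call. = FALSE)
    img
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (!is.null(bits) && bits > 8L)
      stop(sprintf("'%s': %d-bit image, expected 8-bit", path, bits),
           call. = FALSE)
    img
  } else {
    stop(sprintf("'%s': unsupported image format '%s' (use PNG or TIFF)",
                 path, ext), call. = FALSE)
  }
}

to_u8 <- function(x) {
  x <- round(x * 255)
  storage.mode(x) <- "integer"
  attributes(x) <- list(dim = dim(x))  # drop reader metadata
  x
}

#' Read a grayscale OCTA image
#'
#' Reads an 8-bit single-channel PNG or TIFF en face OCTA export and attaches
#' its physical geometry.
#'
#' @param path path to an 8-bit grayscale PNG/TIFF file.
#' @param field_mm physical side length of the scan (default 6 mm).
#' @param id subject-eye identifier; defaults to the file name without
#'   extension.
#' @return An [octa_image()].
#' @export
read_octa <- function(path, field_mm = 6.0,
                      id = tools::file_path_sans_ext(basename(path))) {
  img <- read_raster(path)
  if (length(dim(img)) == 3L) {
    # tolerate gray+alpha or replicated-gray RGB; reject true colour
    ch <- dim(img)[3]
    rgb_equal <- ch >= 3L &&
      isTRUE(all.equal(img[, , 1], img[, , 2])) &&
      isTRUE(all.equal(img[, , 1], img[, , 3]))
    if (ch == 2L || (ch == 4L && rgb_equal)) {
      img <- img[, , 1]
    } else if (rgb_equal) {
      img <- img[, , 1]
    } else {
      stop(sprintf("'%s': colour image with %d channels, expected grayscale",
                   path, ch), call. = FALSE)
    }
  }
  px <- to_u8(as.matrix(img))
  octa_image(px, image_geometry(nrow(px), ncol(px), field_mm), id = id)
}

# palette for sparse AV maps (overridable in the readers/writers)
av_palette_default <- function() {
  list(artery = c(255L, 0L, 0L), vein = c(0L, 0L, 255L),
       background = c(0L, 0L, 0L))
}

#' Read and write sparse artery/vein label maps
#'
#' Sparse AV gradings are stored as RGB PNG with a fixed palette: artery red
#' (255,0,0), vein blue (0,0,255), background black. `read_av_map` decodes a
#' palette PNG and fails, naming the first offending pixel, on any colour
#' outside the palette; `write_av_map` is its inverse.
#'
#' @param path PNG path.
#' @param palette named list with `artery`, `vein`, `background` RGB triplets
#'   in 0..255.
#' @param field_mm physical side length (read direction only).
#' @return `read_av_map` returns an [av_map()]; `write_av_map` returns the
#'   path, invisibly.
#' @export
read_av_map <- function(path, field_mm = 6.0, palette = av_palette_default()) {
  img <- read_raster(path)
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop(sprintf("'%s': AV map must be an RGB PNG", path), call. = FALSE)
  r <- to_u8(img[, , 1]); g <- to_u8(img[, , 2]); b <- to_u8(img[, , 3])
  labels <- matrix(NA_integer_, nrow(r), ncol(r))
  match_col <- function(rgb) r == rgb[1] & g == rgb[2] & b == rgb[3]
  labels[match_col(palette$background)] <- AV_BACKGROUND
  labels[match_col(palette$artery)] <- AV_ARTERY
  labels[match_col(palette$vein)] <- AV_VEIN
  if (anyNA(labels)) {
    bad <- which(is.na(labels), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "'%s': pixel at row %d, col %d has colour (%d,%d,%d) outside the AV palette",
      path, bad[1], bad[2], r[bad[1], bad[2]], g[bad[1], bad[2]],
      b[bad[1], bad[2]]), call. = FALSE)
  }
  av_map(labels, image_geometry(nrow(labels), ncol(labels), field_mm))
}

write_rgb_png <- function(r, g, b, path) {
  arr <- array(0, dim = c(nrow(r), ncol(r), 3))
  arr[, , 1] <- r / 255; arr[, , 2] <- g / 255; arr[, , 3] <- b / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' @rdname read_av_map
#' @param av an [av_map()].
#' @export
write_av_map <- function(av, path, palette = av_palette_default()) {
  stopifnot(inherits(av, "av_map"))
  pick <- function(i) {
    m <- matrix(palette$background[i], nrow(av$labels), ncol(av$labels))
    m[av$labels == AV_ARTERY] <- palette$artery[i]
    m[av$labels == AV_VEIN] <- palette$vein[i]
    m
  }
  write_rgb_png(pick(1), pick(2), pick(3), path)
}

#' Read and write dense AVA maps
#'
#' Dense AVA maps are stored as single-channel PNG with 255 marking arterial
#' area and 0 venous area.
#'
#' @param path PNG path.
#' @param field_mm physical side length (read direction only).
#' @return `read_ava_map` returns an [ava_map()]; `write_ava_map` returns
#'   the path, invisibly.
#' @export
read_ava_map <- function(path, field_mm = 6.0) {
  img <- read_raster(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 2L) img <- img[, , 1]
    else stop(sprintf("'%s': AVA map must be single-channel", path),
              call. = FALSE)
  }
  px <- to_u8(as.matrix(img))
  if (!all(px %in% c(0L, 255L)))
    stop(sprintf("'%s': AVA map pixels must be 0 or 255", path),
         call. = FALSE)
  ava_map((px == 255L) * 1L,
          image_geometry(nrow(px), ncol(px), field_mm))
}

#' @rdname read_ava_map
#' @param ava an [ava_map()].
#' @export
write_ava_map <- function(ava, path) {
  stopifnot(inherits(ava, "ava_map"))
  png::writePNG(ava$labels * 1.0, path)  # 1 -> 255 on write
  invisible(path)
}

#' Render an AVA or OCTA-AV map as a red/blue RGB image
#'
#' Writes the conventional display rendering: arterial content in the red
#' channel, venous content in the blue channel, green zero. For a binary
#' [ava_map()] both channels are saturated (255); for an [octa_av_map()] the
#' channels carry the preserved OCTA intensities.
#'
#' @param map an [ava_map()] or [octa_av_map()].
#' @param path output PNG path.
#' @return The path, invisibly.
#' @export
write_ava_rgb <- function(map, path) {
  if (inherits(map, "ava_map")) {
    r <- map$labels * 255L
    b <- (1L - map$labels) * 255L
  } else if (inherits(map, "octa_av_map")) {
    r <- map$arterial
    b <- map$venous
  } else {
    stop("map must be an ava_map or octa_av_map", call. = FALSE)
  }
  write_rgb_png(r, matrix(0L, nrow(r), ncol(r)), b, path)
}

#' @rdname read_octa
#' @param octa an [octa_image()].
#' @export
write_octa <- function(octa, path) {
  stopifnot(inherits(octa, "octa_image"))
  ext <- ext_of(path)
  if (ext == "png") png::writePNG(octa$pixels / 255, path)
  else if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(octa$pixels / 255, path, bits.per.sample = 8L)
  else stop(sprintf("'%s': unsupported output format", path), call. = FALSE)
  invisible(path)
}
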