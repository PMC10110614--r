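# The seven whole-image biomarkers. Area features come from the AVA
# partition alone; perfusion intensity density (PID) features average the
# preserved OCTA intensities per territory, avoiding any binarisation
# threshold. All features are computed over the kept pixels of an exclusion
# mask (fovea + layer indicator by default).

#' Build an intensity-preserving OCTA-AV map
#'
#' Multiplies the OCTA image into the AVA partition: the arterial channel
#' keeps the OCTA intensity on arterial-territory pixels, the venous channel
#' on venous-territory pixels; pixels excluded by the mask are zero in both.
#'
#' @param octa an [octa_image()].
#' @param ava an [ava_map()] over the same geometry.
#' @param mask an [exclusion_mask()]; `NULL` keeps every pixel.
#' @return An [octa_av_map()].
#' @export
make_octa_av <- function(octa, ava, mask = NULL) {
  stopifnot(inherits(octa, "octa_image"), inherits(ava, "ava_map"))
  check_geometry_match(octa$geometry, ava$geometry, "octa_image and ava_map")
  keep <- if (is.null(mask)) matrix(TRUE, nrow(octa$pixels), ncol(octa$pixels))
          else { stopifnot(inherits(mask, "exclusion_mask"))
                 check_geometry_match(octa$geometry, mask$geometry,
                                      "octa_image and mask")
                 mask$keep }
  art <- octa$pixels * (ava$labels == 1L) * keep
  ven <- octa$pixels * (ava$labels == 0L) * keep
  octa_av_map(art, ven, octa$geometry)
}

#' Arterial/venous area features
#'
#' Over the kept pixels of the mask: `AA = 100 * A_A / A_T` and
#' `VA = 100 * A_V / A_T`, where `A_A`, `A_V` are the arterial and venous
#' pixel counts and `A_T` their sum, so `AA + VA = 100` identically.
#' `AVAR = A_A / A_V`.
#'
#' @param ava an [ava_map()].
#' @param mask an [exclusion_mask()] or `NULL` for the full field.
#' @return Named list with `AA`, `VA`, `AVAR` and the pixel counts `A_A`,
#'   `A_V`, `A_T`. `AVAR` is `NA` (flagged, not infinite) when no kept
#'   venous pixel exists.
#' @export
area_features <- function(ava, mask = NULL) {
  stopifnot(inherits(ava, "ava_map"))
  keep <- if (is.null(mask)) matrix(TRUE, nrow(ava$labels), ncol(ava$labels))
          else { stopifnot(inherits(mask, "exclusion_mask"))
                 check_geometry_match(ava$geometry, mask$geometry,
                                      "ava_map and mask")
                 mask$keep }
  a_a <- sum(ava$labels == 1L & keep)
  a_v <- sum(ava$labels == 0L & keep)
  a_t <- a_a + a_v
  if (a_t == 0L) stop("no kept pixels: cannot compute area features",
                      call. = FALSE)
  list(AA = 100 * a_a / a_t, VA = 100 * a_v / a_t,
       AVAR = if (a_v == 0L) NA_real_ else a_a / a_v,
       A_A = a_a, A_V = a_v, A_T = a_t)
}

#' Perfusion intensity density features
#'
#' Mean 8-bit OCTA intensity expressed as a percentage of full scale
#' (100/255 per intensity unit), over the kept total area (`T_PID`), the
#' kept arterial area (`A_PID`) and the kept venous area (`V_PID`);
#' `AV_PIDR = A_PID / V_PID`.
#'
#' @param oav an [octa_av_map()].
#' @param ava the [ava_map()] that generated it (defines the territories).
#' @param mask an [exclusion_mask()] or `NULL` for the full field.
#' @return Named list with `T_PID`, `A_PID`, `V_PID`, `AV_PIDR`. `AV_PIDR`
#'   is `NA` (flagged) when `V_PID` is zero.
#' @export
pid_features <- function(oav, ava, mask = NULL) {
  stopifnot(inherits(oav, "octa_av_map"), inherits(ava, "ava_map"))
  check_geometry_match(oav$geometry, ava$geometry, "octa_av_map and ava_map")
  keep <- if (is.null(mask)) matrix(TRUE, nrow(ava$labels), ncol(ava$labels))
          else { stopifnot(inherits(mask, "exclusion_mask"))
                 check_geometry_match(ava$geometry, mask$geometry,
                                      "ava_map and mask")
                 mask$keep }
  ka <- keep & ava$labels == 1L
  kv <- keep & ava$labels == 0L
  if (!any(ka) || !any(kv))
    stop("need at least one kept arterial and one kept venous pixel",
         call. = FALSE)
  inten <- oav$arterial + oav$venous
  scl <- 100 / 255
  a_pid <- scl * sum(inten[ka]) / sum(ka)
  v_pid <- scl * sum(inten[kv]) / sum(kv)
  t_pid <- scl * sum(inten[keep]) / sum(keep)
  list(T_PID = t_pid, A_PID = a_pid, V_PID = v_pid,
       AV_PIDR = if (v_pid == 0) NA_real_ else a_pid / v_pid)
}

#' All seven features for one image
#'
#' Convenience wrapper: builds the OCTA-AV map and returns the three area
#' features plus the four PID features as a one-row data frame.
#'
#' @param octa an [octa_image()].
#' @param ava an [ava_map()].
#' @param mask an [exclusion_mask()]; by default the standard analysis mask
#'   (fovea + layer indicator) for the image geometry.
#' @return A one-row `data.frame` with columns
#'   `id, AA, VA, AVAR, T_PID, A_PID, V_PID, AV_PIDR`.
#' @export
quantify_image <- function(octa, ava, mask = analysis_mask(octa$geometry)) {
  oav <- make_octa_av(octa, ava, mask)
  af <- area_features(ava, mask)
  pf <- pid_features(oav, ava, mask)
  data.frame(id = octa$id, AA = af$AA, VA = af$VA, AVAR = af$AVAR,
             T_PID = pf$T_PID, A_PID = pf$A_PID, V_PID = pf$V_PID,
             AV_PIDR = pf$AV_PIDR, stringsAsFactors = FALSE)
}

#' Batch feature quantification
#'
#' Computes the seven features for a list of image/AVA-map pairs. Per-item
#' failures are recorded (as an `NA` row plus a message in the `error`
#' attribute) and the batch continues.
#'
#' @param items list of `list(octa = , ava = )` pairs.
#' @param mask an [exclusion_mask()], `NULL` for full field, or the default
#'   `"analysis"` to build the standard mask per image geometry.
#' @param csv optional path; when given the table is written with
#'   [write_feature_csv()].
#' @return A `data.frame`, one row per item, in input order; failed items
#'   carry `NA` features and their messages sit in `attr(, "errors")`.
#' @export
quantify_batch <- function(items, mask = "analysis", csv = NULL) {
  if (length(items) == 0L) stop("empty batch", call. = FALSE)
  errors <- character()
  rows <- vector("list", length(items))
  for (i in seq_along(items)) {
    it <- items[[i]]
    m <- if (identical(mask, "analysis")) analysis_mask(it$octa$geometry)
         else mask
    rows[[i]] <- tryCatch(quantify_image(it$octa, it$ava, m), error = function(e) {
      errors[[length(errors) + 1L]] <<- sprintf("item %d (%s): %s", i,
                                                it$octa$id, conditionMessage(e))
      data.frame(id = it$octa$id, AA = NA_real_, VA = NA_real_,
                 AVAR = NA_real_, T_PID = NA_real_, A_PID = NA_real_,
                 V_PID = NA_real_, AV_PIDR = NA_real_,
                 stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "errors") <- errors
  if (!is.null(csv)) write_feature_csv(out, csv)
  out
}

#' Read and write feature tables
#'
#' CSV with header `id,AA,VA,AVAR,T_PID,A_PID,V_PID,AV_PIDR`; numeric
#' columns are written at 4 decimal places (features are percentages or
#' ratios of order 1, so 4 decimals is well beyond measurement precision).
#'
#' @param features a feature `data.frame` as returned by [quantify_batch()].
#' @param path CSV path.
#' @return `write_feature_csv` returns the path invisibly;
#'   `read_feature_csv` returns the table.
#' @export
write_feature_csv <- function(features, path) {
  out <- features
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) round(x, 4))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(id = "character"))
}
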