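# Dense AVA ground truth from sparse manual vessel gradings. Every graded
# vessel pixel keeps its own class; every background pixel is assigned to
# the arterial or venous territory by a kNN vote over the graded vessel
# pixels in pixel-coordinate space (Euclidean distance, distance-weighted
# by default). The dense map is the union of vessels with their territories.

#' kNN propagation settings
#'
#' @param k number of nearest graded vessel pixels consulted per background
#'   pixel. k = 5 is the working default: neighbourhood sizes between about
#'   4 and 25 give near-identical smooth territory maps, and small k keeps
#'   the computation cheap.
#' @param weighting `"distance"` for 1/d-weighted voting (default) or
#'   `"uniform"` for unweighted majority.
#' @param subsample_stride optional integer stride for thinning the graded
#'   pixel set on large images (1 = use all pixels, the default; required
#'   for exact oracle equality).
#' @return A `knn_config` object.
#' @export
knn_config <- function(k = 5L, weighting = c("distance", "uniform"),
                       subsample_stride = 1L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  weighting <- match.arg(weighting)
  subsample_stride <- as.integer(subsample_stride)
  if (is.na(subsample_stride) || subsample_stride < 1L)
    stop("subsample_stride must be a positive integer", call. = FALSE)
  structure(list(k = k, weighting = weighting,
                 subsample_stride = subsample_stride),
            class = "knn_config")
}

#' Propagate sparse artery/vein labels to a dense AVA map
#'
#' Classifies every background pixel of a sparse AV grading as arterial or
#' venous territory by a k-nearest-neighbour vote over the graded vessel
#' pixels: Euclidean distance between pixel coordinates, 1/d distance
#' weighting by default. Graded vessel pixels keep their own class, so the
#' result is the union of the vessels with their surrounding territories.
#' Ties are deterministic: equidistant k-th neighbours resolve to the
#' earlier row-major scan position, and an exactly balanced weighted vote
#' goes to the arterial class.
#'
#' @param av an [av_map()] containing at least one artery and one vein
#'   pixel.
#' @param cfg a [knn_config()].
#' @return The dense [ava_map()].
#' @export
classify_background <- function(av, cfg = knn_config()) {
  stopifnot(inherits(av, "av_map"), inherits(cfg, "knn_config"))
  lab <- av$labels
  if (!any(lab == AV_ARTERY) || !any(lab == AV_VEIN))
    stop("av_map must contain at least one artery and one vein pixel",
         call. = FALSE)
  # row-major scan order: row index varies last -> order by (row, col)
  idx <- which(lab != AV_BACKGROUND, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  if (cfg$subsample_stride > 1L) {
    sub <- seq(1L, nrow(idx), by = cfg$subsample_stride)
    # never thin a class out of existence
    cls <- lab[idx]
    if (length(unique(cls[sub])) < 2L) sub <- seq_len(nrow(idx))
    idx <- idx[sub, , drop = FALSE]
  }
  if (cfg$k > nrow(idx))
    stop(sprintf("k = %d exceeds the number of usable graded pixels (%d)",
                 cfg$k, nrow(idx)), call. = FALSE)
  labels_of <- lab[idx]
  bg <- which(lab == AV_BACKGROUND, arr.ind = TRUE)
  out <- lab
  if (nrow(bg) > 0L) {
    votes <- knn_vote(bg[, , drop = FALSE] * 1.0, idx * 1.0,
                      as.integer(labels_of), cfg$k,
                      cfg$weighting == "distance")
    out[bg] <- as.integer(votes)
  }
  ava_map((out == AV_ARTERY) * 1L, av$geometry)
}

#' Check a dense AVA map against its source grading
#'
#' Verifies that every graded artery pixel is arterial (1) and every graded
#' vein pixel venous (0) in the dense map — the union property of the
#' ground-truth construction.
#'
#' @param ava an [ava_map()].
#' @param av the source [av_map()].
#' @return A list with `ok` (logical), `n_violations`, and `violations`, a
#'   matrix of offending (row, col, expected) triplets.
#' @export
validate_partition <- function(ava, av) {
  stopifnot(inherits(ava, "ava_map"), inherits(av, "av_map"))
  check_geometry_match(ava$geometry, av$geometry, "ava_map and av_map")
  bad_a <- which(av$labels == AV_ARTERY & ava$labels != 1L, arr.ind = TRUE)
  bad_v <- which(av$labels == AV_VEIN & ava$labels != 0L, arr.ind = TRUE)
  viol <- rbind(
    if (nrow(bad_a)) cbind(bad_a, expected = 1L),
    if (nrow(bad_v)) cbind(bad_v, expected = 0L))
  if (is.null(viol)) viol <- matrix(integer(), 0, 3,
                                    dimnames = list(NULL, c("row", "col", "expected")))
  list(ok = nrow(viol) == 0L, n_violations = nrow(viol), violations = viol)
}
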