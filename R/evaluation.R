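# Segmentation quality metrics over binary AVA maps, reported as
# percentages: per-class IoU (Jaccard), mean IoU, Dice (F1) and pixel
# accuracy, plus cross-validation aggregation. Metrics are computed over
# all pixels — no exclusion mask — consistent with the training targets.

binary_of <- function(x, cls) {
  if (inherits(x, "ava_map")) x <- x$labels
  if (cls == "arterial") x == 1L else x == 0L
}

check_pair <- function(pred, gt) {
  stopifnot(inherits(pred, "ava_map"), inherits(gt, "ava_map"))
  check_geometry_match(pred$geometry, gt$geometry, "pred and gt")
}

#' Pixel accuracy
#'
#' Percentage of pixels on which prediction and ground truth agree.
#'
#' @param pred,gt [ava_map()] objects over the same geometry.
#' @return Percent in \[0, 100\].
#' @export
pixel_accuracy <- function(pred, gt) {
  check_pair(pred, gt)
  100 * mean(pred$labels == gt$labels)
}

#' Per-class intersection-over-union
#'
#' `100 * |pred n gt| / |pred u gt|` for the chosen class mask. When the
#' class is absent from both maps the union is empty and the IoU is defined
#' as 100 (perfect agreement on absence).
#'
#' @param pred,gt [ava_map()] objects over the same geometry.
#' @param cls `"arterial"` or `"venous"`.
#' @return Percent in \[0, 100\].
#' @export
class_iou <- function(pred, gt, cls = c("arterial", "venous")) {
  check_pair(pred, gt)
  cls <- match.arg(cls)
  p <- binary_of(pred, cls); g <- binary_of(gt, cls)
  u <- sum(p | g)
  if (u == 0L) return(100)
  100 * sum(p & g) / u
}

#' Mean IoU over the two classes
#'
#' Unweighted mean of the arterial and venous class IoUs.
#'
#' @inheritParams pixel_accuracy
#' @return Percent in \[0, 100\].
#' @export
mean_iou <- function(pred, gt) {
  (class_iou(pred, gt, "arterial") + class_iou(pred, gt, "venous")) / 2
}

#' Dice (F1) coefficient
#'
#' Per class, `100 * 2|pred n gt| / (|pred| + |gt|)` (100 when both masks
#' are empty); `dice_coef` averages the two classes. For hard masks the
#' identity `Dice = 2 IoU / (1 + IoU)` holds per class.
#'
#' @inheritParams class_iou
#' @return Percent in \[0, 100\].
#' @export
class_dice <- function(pred, gt, cls = c("arterial", "venous")) {
  check_pair(pred, gt)
  cls <- match.arg(cls)
  p <- binary_of(pred, cls); g <- binary_of(gt, cls)
  denom <- sum(p) + sum(g)
  if (denom == 0L) return(100)
  100 * 2 * sum(p & g) / denom
}

#' @rdname class_dice
#' @export
dice_coef <- function(pred, gt) {
  (class_dice(pred, gt, "arterial") + class_dice(pred, gt, "venous")) / 2
}

#' Metrics report for a set of predictions
#'
#' @param preds,gts lists of [ava_map()] objects, pairwise comparable.
#' @param aggregation `"per_image_mean"` (default: compute each metric per
#'   image, then average) or `"pooled"` (accumulate pixel counts over the
#'   whole set, then compute the metrics once).
#' @return A `metrics_report` list with `iou_arterial`, `iou_venous`,
#'   `mean_iou`, `dice`, `accuracy` (all percent), `n_images`,
#'   `aggregation`.
#' @export
metrics_report <- function(preds, gts,
                           aggregation = c("per_image_mean", "pooled")) {
  aggregation <- match.arg(aggregation)
  stopifnot(length(preds) == length(gts), length(preds) >= 1L)
  if (aggregation == "per_image_mean") {
    per <- mapply(function(p, g) c(
      ia = class_iou(p, g, "arterial"), iv = class_iou(p, g, "venous"),
      d = dice_coef(p, g), acc = pixel_accuracy(p, g)),
      preds, gts)
    m <- rowMeans(per)
    rep <- list(iou_arterial = m[["ia"]], iou_venous = m[["iv"]],
                mean_iou = (m[["ia"]] + m[["iv"]]) / 2, dice = m[["d"]],
                accuracy = m[["acc"]])
  } else {
    acc <- c(ia_i = 0, ia_u = 0, iv_i = 0, iv_u = 0, d_num = 0, d_den = 0,
             ok = 0, n = 0)
    for (i in seq_along(preds)) {
      check_pair(preds[[i]], gts[[i]])
      p <- preds[[i]]$labels; g <- gts[[i]]$labels
      pa <- p == 1L; ga <- g == 1L
      acc["ia_i"] <- acc["ia_i"] + sum(pa & ga)
      acc["ia_u"] <- acc["ia_u"] + sum(pa | ga)
      acc["iv_i"] <- acc["iv_i"] + sum(!pa & !ga)
      acc["iv_u"] <- acc["iv_u"] + sum(!pa | !ga)
      acc["d_num"] <- acc["d_num"] + 2 * sum(pa & ga) + 2 * sum(!pa & !ga)
      acc["d_den"] <- acc["d_den"] + sum(pa) + sum(ga) + sum(!pa) + sum(!ga)
      acc["ok"] <- acc["ok"] + sum(p == g)
      acc["n"] <- acc["n"] + length(p)
    }
    ia <- 100 * acc[["ia_i"]] / max(acc[["ia_u"]], 1)
    iv <- 100 * acc[["iv_i"]] / max(acc[["iv_u"]], 1)
    rep <- list(iou_arterial = ia, iou_venous = iv, mean_iou = (ia + iv) / 2,
                dice = 100 * acc[["d_num"]] / acc[["d_den"]],
                accuracy = 100 * acc[["ok"]] / acc[["n"]])
  }
  rep$n_images <- length(preds)
  rep$aggregation <- aggregation
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n=%d (%s)\n  IoU arterial %.2f%%, venous %.2f%%, mean %.2f%%\n  Dice %.2f%%, accuracy %.2f%%\n",
    x$n_images, x$aggregation, x$iou_arterial, x$iou_venous, x$mean_iou,
    x$dice, x$accuracy))
  invisible(x)
}

#' Cross-validation summary
#'
#' Unweighted mean and sample standard deviation of each metric over folds.
#'
#' @param per_fold list of `metrics_report` objects, one per fold (>= 2).
#' @return A `data.frame` with one row per metric: `mean` and `sd`.
#' @export
cross_validation_report <- function(per_fold) {
  if (length(per_fold) < 2L)
    stop("need at least 2 folds for a mean/sd summary", call. = FALSE)
  metrics <- c("iou_arterial", "iou_venous", "mean_iou", "dice", "accuracy")
  vals <- sapply(metrics, function(m)
    vapply(per_fold, function(f) f[[m]], numeric(1)))
  data.frame(metric = metrics,
             mean = colMeans(vals),
             sd = apply(vals, 2, stats::sd),
             row.names = NULL, stringsAsFactors = FALSE)
}
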