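# AVA-Net: a U-Net-style encoder-decoder for arterial/venous territory
# segmentation of en face OCTA images. Each of the five encoder blocks runs
# two plain 3x3 CBR (conv - batch norm - ReLU) units, then four parallel
# dilated 3x3 CBR branches (rates 2-5) whose outputs are concatenated with
# the plain-conv output (the skip tap) before 2x2 max pooling. Each of the
# five decoder blocks runs two CBR units, 2x nearest-neighbour upsampling,
# and concatenation with the matching skip. Two CBR units and a final 1x1
# convolution with a sigmoid produce a per-pixel arterial probability.

#' Network architecture settings
#'
#' @param base_filters filters in the first encoder level; deeper levels
#'   double it (32 by default, giving 32..512).
#' @param levels number of encoder/decoder levels (5; the architecture is
#'   defined at this depth).
#' @param filters_per_level optional explicit 5-vector of filter counts,
#'   overriding the doubling rule.
#' @param dilation_rates dilation rates of the parallel encoder branches
#'   (strictly increasing; default 2:5).
#' @return A `network_config` object.
#' @export
network_config <- function(base_filters = 32L, levels = 5L,
                           filters_per_level = NULL,
                           dilation_rates = 2:5) {
  levels <- as.integer(levels)
  if (levels != 5L)
    stop("the architecture is defined with 5 encoder/decoder levels",
         call. = FALSE)
  base_filters <- as.integer(base_filters)
  if (is.na(base_filters) || base_filters < 1L)
    stop("base_filters must be a positive integer", call. = FALSE)
  if (is.null(filters_per_level))
    filters_per_level <- base_filters * 2L^(0:(levels - 1L))
  filters_per_level <- as.integer(filters_per_level)
  stopifnot(length(filters_per_level) == levels, all(filters_per_level >= 1L))
  dilation_rates <- as.integer(dilation_rates)
  if (length(dilation_rates) < 1L || any(diff(dilation_rates) <= 0))
    stop("dilation_rates must be strictly increasing", call. = FALSE)
  structure(list(base_filters = base_filters, levels = levels,
                 filters_per_level = filters_per_level,
                 dilation_rates = dilation_rates,
                 input_channels = 1L, output_channels = 1L),
            class = "network_config")
}

#' Training settings
#'
#' Defaults follow the published regime: Adam with learning rate 1e-4,
#' beta1 0.9, beta2 0.999, epsilon 1e-7; mini-batches of 28 with an epoch
#' defined as 3 training batches; up to 5000 epochs with early stopping on
#' the validation score.
#'
#' @param learning_rate,beta1,beta2,epsilon Adam hyper-parameters.
#' @param batch_size images per mini-batch (capped at the dataset size).
#' @param batches_per_epoch batches constituting one epoch.
#' @param max_epochs training ceiling.
#' @param early_stop_patience epochs without improvement before stopping.
#' @param stop_at_train_iou optional target mean train IoU (fraction in
#'   (0,1]) at which training halts early, for bounded-budget fitting.
#' @param stop_at_train_loss_frac optional fraction of the first epoch's
#'   training loss at which training halts early (e.g. 0.5 stops once the
#'   loss has halved).
#' @param seed RNG seed for initialisation, shuffling and augmentation.
#' @param augmentation an [augment_config()] or `NULL` to disable.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-7, batch_size = 28L,
                         batches_per_epoch = 3L, max_epochs = 5000L,
                         early_stop_patience = 500L,
                         stop_at_train_iou = NULL,
                         stop_at_train_loss_frac = NULL, seed = 0L,
                         augmentation = NULL) {
  stopifnot(learning_rate > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            epsilon > 0, batch_size >= 1, batches_per_epoch >= 1,
            max_epochs >= 1)
  early_stop_patience <- as.integer(early_stop_patience)
  if (early_stop_patience >= max_epochs && max_epochs > 1L)
    stop("early_stop_patience must be smaller than max_epochs", call. = FALSE)
  if (!is.null(stop_at_train_iou))
    stopifnot(stop_at_train_iou > 0, stop_at_train_iou <= 1)
  if (!is.null(stop_at_train_loss_frac))
    stopifnot(stop_at_train_loss_frac > 0, stop_at_train_loss_frac < 1)
  if (!is.null(augmentation)) stopifnot(inherits(augmentation, "augment_config"))
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 batches_per_epoch = as.integer(batches_per_epoch),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = early_stop_patience,
                 stop_at_train_iou = stop_at_train_iou,
                 stop_at_train_loss_frac = stop_at_train_loss_frac,
                 seed = as.integer(seed), augmentation = augmentation),
            class = "train_config")
}

#' Soft intersection-over-union (Jaccard) loss
#'
#' `1 - sum(g*s) / sum(g + s - g*s)` for a binary ground truth `g` and a
#' predicted probability map `s`: the soft binary Jaccard loss that the
#' network optimises directly. A smoothing epsilon of 1e-6 stabilises the
#' denominator; when both maps are entirely empty the loss is defined as 0
#' (perfect agreement on absence).
#'
#' @param g binary ground-truth matrix/array (values 0/1).
#' @param s predicted probability matrix/array of the same shape, in
#'   \[0, 1\].
#' @return Scalar loss in \[0, 1\].
#' @export
iou_loss <- function(g, s) {
  if (!identical(dim(g) %||% length(g), dim(s) %||% length(s)))
    stop("g and s must have identical shape", call. = FALSE)
  if (any(g != 0 & g != 1)) stop("g must be binary", call. = FALSE)
  if (any(s < 0 | s > 1)) stop("s must lie in [0, 1]", call. = FALSE)
  I <- sum(g * s)
  U <- sum(g + s - g * s)
  if (U == 0) return(0)
  1 - I / (U + 1e-6)
}

#' Number of trainable parameters of an architecture
#'
#' Conv weights and biases plus batch-norm scale/shift, as a pure function
#' of the configuration.
#'
#' @param cfg a [network_config()].
#' @return Integer parameter count.
#' @export
avanet_param_count <- function(cfg = network_config()) {
  plan <- avanet_layer_plan(cfg)
  sum(vapply(plan, function(sp) {
    k <- sp$k %||% 3L
    n <- k * k * sp$cin * sp$cout + sp$cout          # w + b
    if (sp$bn %||% TRUE) n <- n + 2L * sp$cout       # gamma + beta
    n
  }, 0))
}

#' Pad an image to the pooling grid
#'
#' Five pooling stages require spatial dimensions divisible by 2^5 = 32.
#' Pads by edge reflection, splitting the padding evenly (extra pixel at
#' bottom/right), and returns a crop record that inverts the padding
#' exactly.
#'
#' @param x a matrix or [octa_image()].
#' @param multiple required divisor (32 for the 5-level network).
#' @return List with `padded` (same type as the input) and `crop`
#'   (`top`, `left`, `height`, `width`).
#' @export
pad_to_grid <- function(x, multiple = 32L) {
  m <- if (inherits(x, "octa_image")) x$pixels else x
  stopifnot(is.matrix(m))
  multiple <- as.integer(multiple)
  h <- nrow(m); w <- ncol(m)
  ht <- as.integer(ceiling(h / multiple) * multiple)
  wt <- as.integer(ceiling(w / multiple) * multiple)
  pt <- (ht - h) %/% 2L; pl <- (wt - w) %/% 2L
  ri <- reflect_index(seq_len(ht) - pt, h)
  ci <- reflect_index(seq_len(wt) - pl, w)
  padded <- m[ri, ci, drop = FALSE]
  crop <- list(top = pt, left = pl, height = h, width = w)
  if (inherits(x, "octa_image"))
    padded <- octa_image(padded, image_geometry(ht, wt, x$geometry$field_mm *
                                                  ht / h), id = x$id)
  list(padded = padded, crop = crop)
}

# fold an out-of-range index back into 1..n by repeated edge reflection
# (mirror about the half-pixel boundary, so 0 -> 1, -1 -> 2, n+1 -> n, ...)
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n
  j <- ((i - 1L) %% p + p) %% p  # 0-based, period 2n
  ifelse(j < n, j + 1L, p - j)
}

#' @rdname pad_to_grid
#' @param m a padded matrix.
#' @param crop a crop record from `pad_to_grid`.
#' @export
crop_from_grid <- function(m, crop) {
  m[crop$top + seq_len(crop$height), crop$left + seq_len(crop$width),
    drop = FALSE]
}

#' Augmentation settings
#'
#' On-the-fly training augmentation: random horizontal/vertical flips,
#' rotation, zoom, shift, shear and brightness shift. Each numeric control
#' is a half-width `a` giving a symmetric sampling range `[-a, a]` about
#' the identity, so an all-zero configuration (flips off) is exactly the
#' identity.
#'
#' @param flip_h,flip_v enable random flips (each applied with
#'   probability 1/2).
#' @param rotation_deg rotation half-range in degrees.
#' @param zoom_frac zoom half-range as a fraction (scale in `1 +- a`).
#' @param shift_frac translation half-range as a fraction of the image
#'   side.
#' @param shear_deg shear half-range in degrees.
#' @param brightness_delta additive intensity shift half-range (8-bit
#'   units); applied to the image only, never the label.
#' @return An `augment_config` object.
#' @export
augment_config <- function(flip_h = TRUE, flip_v = TRUE, rotation_deg = 15,
                           zoom_frac = 0.1, shift_frac = 0.05,
                           shear_deg = 5, brightness_delta = 20) {
  for (v in list(rotation_deg, zoom_frac, shift_frac, shear_deg,
                 brightness_delta))
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stop("augmentation half-ranges must be nonnegative scalars",
           call. = FALSE)
  structure(list(flip_h = isTRUE(flip_h), flip_v = isTRUE(flip_v),
                 rotation_deg = rotation_deg, zoom_frac = zoom_frac,
                 shift_frac = shift_frac, shear_deg = shear_deg,
                 brightness_delta = brightness_delta),
            class = "augment_config")
}

# deterministic geometric core: flips, then an affine resample (rotation,
# shear, zoom, shift) by nearest neighbour around the image centre. An
# identity transform returns the input pixels bit-for-bit.
affine_transform <- function(m, flip_h = FALSE, flip_v = FALSE,
                             angle_deg = 0, zoom = 1, shift_px = c(0, 0),
                             shear_deg = 0, fill = 0) {
  if (flip_h) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  if (flip_v) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (angle_deg == 0 && zoom == 1 && shear_deg == 0 && all(shift_px == 0))
    return(m)
  h <- nrow(m); w <- ncol(m)
  th <- angle_deg * pi / 180; sh <- tan(shear_deg * pi / 180)
  # forward map: rotate %*% shear %*% zoom, plus shift; sample by inverse
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) %*%
    matrix(c(1, 0, sh, 1), 2, 2) * zoom
  Ai <- solve(A)
  ci <- (h + 1) / 2; cj <- (w + 1) / 2
  tg <- expand.grid(i = seq_len(h), j = seq_len(w))
  rel <- rbind(tg$i - ci - shift_px[1], tg$j - cj - shift_px[2])
  src <- Ai %*% rel
  si <- round(src[1, ] + ci); sj <- round(src[2, ] + cj)
  ok <- si >= 1 & si <= h & sj >= 1 & sj <= w
  out <- matrix(fill, h, w)
  out[cbind(tg$i[ok], tg$j[ok])] <- m[cbind(si[ok], sj[ok])]
  out
}

#' Augment an image/label pair
#'
#' Draws one random transform from the configuration (consuming the current
#' RNG state, so a fixed seed replays exactly) and applies the geometric
#' part identically to image and label. Labels stay binary by nearest-
#' neighbour resampling plus explicit re-binarisation; the brightness shift
#' touches the image only, clipped to \[0, 255\].
#'
#' @param image intensity matrix (8-bit values).
#' @param label binary matrix of the same shape.
#' @param cfg an [augment_config()].
#' @return List with `image` and `label`.
#' @export
augment_pair <- function(image, label, cfg = augment_config()) {
  stopifnot(inherits(cfg, "augment_config"), all(dim(image) == dim(label)))
  r <- function(a) if (a == 0) 0 else stats::runif(1, -a, a)
  fh <- cfg$flip_h && stats::runif(1) < 0.5
  fv <- cfg$flip_v && stats::runif(1) < 0.5
  ang <- r(cfg$rotation_deg)
  zm <- 1 + r(cfg$zoom_frac)
  shift <- c(r(cfg$shift_frac) * nrow(image), r(cfg$shift_frac) * ncol(image))
  shr <- r(cfg$shear_deg)
  br <- r(cfg$brightness_delta)
  img <- affine_transform(image, fh, fv, ang, zm, shift, shr, fill = 0)
  lab <- affine_transform(label, fh, fv, ang, zm, shift, shr, fill = 0)
  lab <- (lab >= 0.5) * 1L
  if (br != 0) {
    was_int <- is.integer(img)
    img <- pmin(pmax(round(img + br), 0), 255)
    if (was_int) storage.mode(img) <- "integer"
  }
  list(image = img, label = lab)
}

#' Eye-grouped 5-fold split
#'
#' Shuffles the eye identifiers (seeded) and deals them into `n_folds`
#' folds whose sizes differ by at most one, so every eye sits in exactly
#' one validation fold and each fold trains on the remaining ~80%.
#'
#' @param eye_ids character vector of unique eye identifiers (>= n_folds).
#' @param seed shuffle seed.
#' @param n_folds number of folds (default 5).
#' @return Named integer vector mapping eye id to fold index 1..n_folds.
#' @export
make_folds <- function(eye_ids, seed = 0L, n_folds = 5L) {
  eye_ids <- as.character(eye_ids)
  if (anyDuplicated(eye_ids)) stop("eye_ids must be unique", call. = FALSE)
  n <- length(eye_ids)
  if (n < n_folds)
    stop(sprintf("need at least %d eyes for %d folds", n_folds, n_folds),
         call. = FALSE)
  with_seed(seed, {
    ord <- sample.int(n)
  })
  sizes <- rep(n %/% n_folds, n_folds)
  extra <- n %% n_folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold <- rep(seq_len(n_folds), times = sizes)
  stats::setNames(fold[order(ord)], eye_ids)
}

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

check_grid_divisible <- function(h, w, multiple) {
  if (h %% multiple != 0L || w %% multiple != 0L)
    stop(sprintf(
      "input %dx%d not divisible by %d (5 pooling stages); use pad_to_grid()",
      h, w, multiple), call. = FALSE)
}

#' Fit AVA-Net to OCTA image / AVA map pairs
#'
#' Trains the segmentation network with Adam on the soft IoU loss. Images
#' are scaled to \[0, 1\]; spatial dimensions must be divisible by 32 (use
#' [pad_to_grid()]). Per-epoch history records the training loss and hard
#' mean IoU (threshold 0.5, unweighted two-class mean); with a validation
#' set, validation loss/IoU drive early stopping, otherwise training IoU
#' does.
#'
#' @param x list of [octa_image()] (or plain intensity matrices).
#' @param y list of [ava_map()] (or plain binary matrices), parallel to `x`.
#' @param net a [network_config()].
#' @param train a [train_config()].
#' @param validation optional `list(x = , y = )` held-out set.
#' @param verbose print a progress line every `verbose` epochs (0 = quiet).
#' @return An object of class `avanet_fit` with elements `params`,
#'   `net_config`, `train_config`, `history` (data frame), `epochs_run`,
#'   and `stopped` (one of `"max_epochs"`, `"patience"`, `"target_iou"`,
#'   `"target_loss"`).
#' @seealso [predict.avanet_fit()], [plot.avanet_fit()]
#' @export
avanet_train <- function(x, y, net = network_config(), train = train_config(),
                         validation = NULL, verbose = 0L) {
  stopifnot(inherits(net, "network_config"), inherits(train, "train_config"))
  as_input <- function(o) {
    m <- if (inherits(o, "octa_image")) o$pixels else o
    a <- array(m / 255, dim = c(dim(m), 1L))
    a
  }
  as_target <- function(o) {
    m <- if (inherits(o, "ava_map")) o$labels else o
    array(as.numeric(m), dim = c(dim(m), 1L))
  }
  if (length(x) == 0L) stop("empty training set", call. = FALSE)
  stopifnot(length(x) == length(y))
  xb_all <- lapply(x, as_input)
  yb_all <- lapply(y, as_target)
  dims <- dim(xb_all[[1]])
  mult <- 2L^net$levels
  check_grid_divisible(dims[1], dims[2], mult)
  for (a in c(xb_all, yb_all))
    if (!all(dim(a)[1:2] == dims[1:2]))
      stop("all training images must share one spatial size", call. = FALSE)
  vx <- NULL; vy <- NULL
  if (!is.null(validation)) {
    vx <- lapply(validation$x, as_input)
    vy <- lapply(validation$y, as_target)
  }
  n <- length(xb_all)
  bs <- min(train$batch_size, n)
  hist_rows <- vector("list", train$max_epochs)
  stopped <- "max_epochs"
  with_seed(train$seed, {
    pe <- avanet_init_params(net)
    opt <- adam_state_init()
    t_adam <- 0L
    best <- -Inf; best_wait <- 0L
    for (epoch in seq_len(train$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_iou <- 0; nb_done <- 0L
      for (bi in seq_len(train$batches_per_epoch)) {
        pos <- (((bi - 1L) * bs + seq_len(bs) - 1L) %% n) + 1L
        take <- ord[pos]
        xb <- xb_all[take]; yb <- yb_all[take]
        if (!is.null(train$augmentation)) {
          for (k in seq_along(take)) {
            ag <- augment_pair(xb[[k]][, , 1] * 255, yb[[k]][, , 1],
                               train$augmentation)
            xb[[k]] <- array(ag$image / 255, dim = dims)
            yb[[k]] <- array(as.numeric(ag$label), dim = dims)
          }
        }
        cache <- new.env(parent = emptyenv())
        probs <- avanet_forward_pass(pe, net, xb, train = TRUE, cache = cache)
        ls <- iou_loss_batch(yb, probs)
        if (!is.finite(ls$loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d",
                       epoch), call. = FALSE)
        grads <- avanet_backward_pass(pe, net, cache, ls$dprob)
        t_adam <- t_adam + 1L
        adam_step(pe, grads, opt, train$learning_rate, train$beta1,
                  train$beta2, train$epsilon, t_adam)
        ep_loss <- ep_loss + ls$loss
        ep_iou <- ep_iou + batch_hard_miou(yb, probs)
        nb_done <- nb_done + 1L
      }
      ep_loss <- ep_loss / nb_done; ep_iou <- ep_iou / nb_done
      val_loss <- NA_real_; val_iou <- NA_real_
      if (!is.null(vx)) {
        vp <- avanet_forward_pass(pe, net, vx, train = FALSE)
        val_loss <- iou_loss_batch(vy, vp)$loss
        val_iou <- batch_hard_miou(vy, vp)
      }
      hist_rows[[epoch]] <- data.frame(
        epoch = epoch, train_loss = ep_loss, train_iou = ep_iou,
        val_loss = val_loss, val_iou = val_iou)
      if (verbose > 0L && epoch %% verbose == 0L)
        message(sprintf("epoch %4d  loss %.4f  train mIoU %.3f%s", epoch,
                        ep_loss, ep_iou,
                        if (!is.na(val_iou)) sprintf("  val mIoU %.3f", val_iou)
                        else ""))
      score <- if (!is.null(vx)) val_iou else ep_iou
      if (score > best + 1e-6) { best <- score; best_wait <- 0L }
      else best_wait <- best_wait + 1L
      if (!is.null(train$stop_at_train_iou) &&
          ep_iou >= train$stop_at_train_iou) { stopped <- "target_iou"; break }
      if (!is.null(train$stop_at_train_loss_frac) &&
          ep_loss <= train$stop_at_train_loss_frac *
            hist_rows[[1]]$train_loss) { stopped <- "target_loss"; break }
      if (best_wait >= train$early_stop_patience) { stopped <- "patience"; break }
    }
  })
  history <- do.call(rbind, hist_rows[!vapply(hist_rows, is.null, TRUE)])
  structure(list(params = params_to_list(pe), net_config = net,
                 train_config = train, history = history,
                 epochs_run = nrow(history), stopped = stopped,
                 input_dim = dims[1:2], call = match.call()),
            class = "avanet_fit")
}

# hard mean IoU (two-class, threshold 0.5) of a batch of probability maps
batch_hard_miou <- function(yb, probs) {
  v <- mapply(function(g, s) {
    p <- (s >= 0.5) * 1
    g <- g[, , 1]; p <- p[, , 1]
    iou1 <- {
      u <- sum(p == 1 | g == 1); if (u == 0) 1 else sum(p == 1 & g == 1) / u
    }
    iou0 <- {
      u <- sum(p == 0 | g == 0); if (u == 0) 1 else sum(p == 0 & g == 0) / u
    }
    (iou0 + iou1) / 2
  }, yb, probs)
  mean(v)
}

#' Predict an AVA map from an OCTA image
#'
#' Pads the image to the pooling grid by reflection, runs the network in
#' inference mode (batch-norm running statistics), crops back, and
#' thresholds the arterial probability at 0.5.
#'
#' @param object an `avanet_fit`.
#' @param octa an [octa_image()] (or intensity matrix).
#' @param type `"ava"` for the binary [ava_map()] (default), `"prob"` for
#'   the cropped probability matrix.
#' @param ... unused.
#' @return An [ava_map()] with the input geometry, or a probability matrix.
#' @export
predict.avanet_fit <- function(object, octa, type = c("ava", "prob"), ...) {
  type <- match.arg(type)
  m <- if (inherits(octa, "octa_image")) octa$pixels else octa
  geom <- if (inherits(octa, "octa_image")) octa$geometry
          else image_geometry(nrow(m), ncol(m))
  mult <- 2L^object$net_config$levels
  pg <- pad_to_grid(m, mult)
  xb <- list(array(pg$padded / 255, dim = c(dim(pg$padded), 1L)))
  pe <- params_from_list(object$params)
  prob <- avanet_forward_pass(pe, object$net_config, xb, train = FALSE)[[1]]
  prob <- crop_from_grid(prob[, , 1], pg$crop)
  if (type == "prob") return(prob)
  ava_map((prob >= 0.5) * 1L, geom)
}

#' @export
print.avanet_fit <- function(x, ...) {
  cfg <- x$net_config
  last <- x$history[nrow(x$history), ]
  cat(sprintf("AVA-Net fit: %d levels, filters %s, dilation rates %s\n",
              cfg$levels, paste(cfg$filters_per_level, collapse = "/"),
              paste(cfg$dilation_rates, collapse = ",")))
  cat(sprintf("  %s trainable parameters; input grid %dx%d\n",
              format(avanet_param_count(cfg), big.mark = ","),
              x$input_dim[1], x$input_dim[2]))
  cat(sprintf("  %d epochs (%s); final train loss %.4f, train mIoU %.3f\n",
              x$epochs_run, x$stopped, last$train_loss, last$train_iou))
  if (!is.na(last$val_iou))
    cat(sprintf("  final val loss %.4f, val mIoU %.3f\n", last$val_loss,
                last$val_iou))
  invisible(x)
}

#' @export
summary.avanet_fit <- function(object, ...) {
  h <- object$history
  out <- list(
    net_config = object$net_config,
    train_config = object$train_config,
    n_parameters = avanet_param_count(object$net_config),
    epochs_run = object$epochs_run,
    stopped = object$stopped,
    best_train_iou = max(h$train_iou),
    final_train_loss = h$train_loss[nrow(h)],
    best_val_iou = if (all(is.na(h$val_iou))) NA_real_
                   else max(h$val_iou, na.rm = TRUE))
  class(out) <- "summary.avanet_fit"
  out
}

#' @export
print.summary.avanet_fit <- function(x, ...) {
  cat(sprintf(
    "AVA-Net: %s parameters, %d epochs (%s)\n  best train mIoU %.3f, final train loss %.4f\n",
    format(x$n_parameters, big.mark = ","), x$epochs_run, x$stopped,
    x$best_train_iou, x$final_train_loss))
  if (!is.na(x$best_val_iou))
    cat(sprintf("  best val mIoU %.3f\n", x$best_val_iou))
  invisible(x)
}

#' Training-history plot
#'
#' Loss and hard mean IoU per epoch (validation curves dashed when
#' present).
#'
#' @param x an `avanet_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.avanet_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "IoU loss", main = "loss", ...)
  if (!all(is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::plot(h$epoch, h$train_iou, type = "l", xlab = "epoch",
                 ylab = "mean IoU", ylim = c(0, 1), main = "hard mean IoU",
                 ...)
  if (!all(is.na(h$val_iou)))
    graphics::lines(h$epoch, h$val_iou, lty = 2)
  invisible(x)
}
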