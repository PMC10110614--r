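test_that("soft IoU loss matches hand-computed values", {
  expect_equal(iou_loss(c(1, 0), c(1, 0)), 0, tolerance = 1e-6)
  expect_equal(iou_loss(c(1, 0), c(0, 1)), 1, tolerance = 1e-6)
  # g = [1,0], s = [.5,.5]: I = .5, U = 1.5 -> 1 - 1/3
  expect_equal(iou_loss(c(1, 0), c(0.5, 0.5)), 2 / 3, tolerance = 1e-5)
  # empty-set convention
  expect_equal(iou_loss(matrix(0, 3, 3), matrix(0, 3, 3)), 0)
  expect_error(iou_loss(c(1, 0), c(0.5)), "shape")
  expect_error(iou_loss(c(2, 0), c(0.5, 0.5)), "binary")
})

test_that("loss decreases monotonically toward the ground truth", {
  set.seed(31)
  g <- matrix(as.numeric(stats::runif(64) < 0.5), 8, 8)
  wrong <- 1 - g
  losses <- vapply(seq(0, 1, by = 0.1), function(a)
    iou_loss(g, (1 - a) * wrong + a * g), numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_true(all(losses >= 0 & losses <= 1))
})

test_that("one minus the loss equals the hard overlap score", {
  set.seed(32)
  for (rep in 1:20) {
    g <- matrix(as.numeric(stats::runif(49) < 0.5), 7, 7)
    s <- matrix(as.numeric(stats::runif(49) < 0.5), 7, 7)
    hard <- class_iou(ava_map(s), ava_map(g), "arterial") / 100
    expect_equal(1 - iou_loss(g, s), hard, tolerance = 1e-5)
  }
})

test_that("grid padding reflects and inverts exactly", {
  set.seed(33)
  m <- matrix(sample(0:255, 400 * 400, TRUE), 400, 400)
  pg <- pad_to_grid(m, 32)
  expect_equal(dim(pg$padded), c(416, 416))
  expect_identical(crop_from_grid(pg$padded, pg$crop), m)
  # already on the grid: unchanged
  m2 <- matrix(1:(96 * 96), 96, 96)
  pg2 <- pad_to_grid(m2, 32)
  expect_identical(pg2$padded, m2)
  # symmetric reflection about the image edge: first padded row inside the
  # border mirrors the first image row
  expect_identical(pg$padded[8, ], pg$padded[9, ])
})

test_that("augmentation replays under a fixed seed and respects identity", {
  set.seed(34)
  img <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  lab <- matrix(as.integer(stats::runif(64 * 64) < 0.5), 64, 64)
  ident <- augment_config(flip_h = FALSE, flip_v = FALSE, rotation_deg = 0,
                          zoom_frac = 0, shift_frac = 0, shear_deg = 0,
                          brightness_delta = 0)
  out <- augment_pair(img, lab, ident)
  expect_identical(out$image, img)
  expect_identical(out$label, lab)

  cfg <- augment_config()
  set.seed(99); a1 <- augment_pair(img, lab, cfg)
  set.seed(99); a2 <- augment_pair(img, lab, cfg)
  expect_identical(a1, a2)
  expect_true(all(a1$label %in% c(0L, 1L)))
  expect_true(all(a1$image >= 0 & a1$image <= 255))
})

test_that("flips are involutions of the geometric core", {
  set.seed(35)
  m <- matrix(stats::rnorm(100), 10, 10)
  f <- octava:::affine_transform(m, flip_h = TRUE)
  expect_identical(octava:::affine_transform(f, flip_h = TRUE), m)
  g <- octava:::affine_transform(m, flip_v = TRUE)
  expect_identical(octava:::affine_transform(g, flip_v = TRUE), m)
})

test_that("eye-grouped folds are balanced, exhaustive and reproducible", {
  f10 <- make_folds(paste0("eye", 1:10), seed = 1)
  expect_equal(unname(table(f10)), rep(2L, 5), ignore_attr = TRUE)
  f104 <- make_folds(paste0("eye", 1:104), seed = 2)
  expect_equal(sort(unname(table(f104)), decreasing = TRUE),
               c(21L, 21L, 21L, 21L, 20L), ignore_attr = TRUE)
  expect_setequal(names(f104), paste0("eye", 1:104))
  expect_identical(make_folds(paste0("eye", 1:104), seed = 2), f104)
  expect_false(identical(make_folds(paste0("eye", 1:104), seed = 3), f104))
  expect_error(make_folds(paste0("eye", 1:4)), "at least 5")
})

test_that("parameter count is a pure function of the configuration", {
  cfg <- network_config(base_filters = 4)
  n1 <- avanet_param_count(cfg)
  expect_identical(n1, avanet_param_count(network_config(base_filters = 4)))
  # two builds from one seed carry identical weights
  p1 <- octava:::with_seed(5, octava:::params_to_list(
    octava:::avanet_init_params(cfg)))
  p2 <- octava:::with_seed(5, octava:::params_to_list(
    octava:::avanet_init_params(cfg)))
  expect_identical(p1, p2)
  expect_equal(sum(vapply(p1, function(l)
    length(l$w) + length(l$b) + length(l$gamma) + length(l$beta), 0)), n1)
})

test_that("an untrained network maps a grid image to probabilities", {
  cfg <- network_config(base_filters = 2)
  pe <- octava:::with_seed(6, octava:::avanet_init_params(cfg))
  x <- list(array(stats::runif(64 * 64), c(64, 64, 1)))
  pr <- octava:::avanet_forward_pass(pe, cfg, x, train = FALSE)[[1]]
  expect_equal(dim(pr), c(64, 64, 1))
  expect_true(all(pr > 0 & pr < 1))
  # indivisible sizes are refused upfront by the training interface
  expect_error(
    avanet_train(list(matrix(0L, 50, 50)), list(matrix(0L, 50, 50)),
                 net = cfg, train = train_config(max_epochs = 1,
                                                 early_stop_patience = 1)),
    "divisible")
})

test_that("backpropagated gradients match finite differences", {
  cfg <- network_config(base_filters = 2)
  pe <- octava:::with_seed(7, octava:::avanet_init_params(cfg))
  set.seed(7)
  xb <- list(array(stats::runif(32 * 32), c(32, 32, 1)),
             array(stats::runif(32 * 32), c(32, 32, 1)))
  yb <- list(array(as.numeric(stats::runif(32 * 32) < 0.5), c(32, 32, 1)),
             array(as.numeric(stats::runif(32 * 32) < 0.5), c(32, 32, 1)))
  loss_at <- function() {
    pr <- octava:::avanet_forward_pass(pe, cfg, xb, train = TRUE,
                                       cache = new.env())
    octava:::iou_loss_batch(yb, pr)$loss
  }
  cache <- new.env()
  pr <- octava:::avanet_forward_pass(pe, cfg, xb, train = TRUE, cache = cache)
  ls <- octava:::iou_loss_batch(yb, pr)
  grads <- octava:::avanet_backward_pass(pe, cfg, cache, ls$dprob)
  eps <- 1e-6
  # spot-check one weight in an early, a dilated, and a decoder layer;
  # batch-norm statistics are recomputed in the perturbed passes, so the
  # analytic gradient must account for them (it does)
  for (nm in c("enc1_c1", "enc2_d3", "dec5_c2", "out")) {
    p <- pe[[nm]]
    i <- 2L; j <- 1L
    orig <- p$w[i, j]
    p$w[i, j] <- orig + eps; pe[[nm]] <- p; up <- loss_at()
    p$w[i, j] <- orig - eps; pe[[nm]] <- p; dn <- loss_at()
    p$w[i, j] <- orig; pe[[nm]] <- p
    expect_equal(grads[[nm]]$w[i, j], (up - dn) / (2 * eps),
                 tolerance = 1e-3)
  }
})

test_that("a short fit reduces the loss and stays reproducible", {
  fix <- overfit_fixture(size = 64, seeds = 3:4)
  tr <- train_config(batch_size = 2, batches_per_epoch = 1, max_epochs = 8,
                     early_stop_patience = 7, seed = 1)
  fit1 <- avanet_train(fix$x, fix$y, net = network_config(base_filters = 2),
                       train = tr)
  expect_equal(fit1$epochs_run, 8)
  expect_lt(fit1$history$train_loss[8], fit1$history$train_loss[1])
  fit2 <- avanet_train(fix$x, fix$y, net = network_config(base_filters = 2),
                       train = tr)
  expect_identical(fit1$history, fit2$history)
  # prediction has the input geometry and is binary
  pr <- predict(fit1, fix$x[[1]])
  expect_s3_class(pr, "ava_map")
  expect_equal(dim(pr$labels), c(64, 64))
  probs <- predict(fit1, fix$x[[1]], type = "prob")
  expect_true(all(probs > 0 & probs < 1))
  expect_output(print(fit1), "AVA-Net fit")
  expect_output(print(summary(fit1)), "parameters")
})

test_that("the training loss halves within 200 standard epochs", {
  # standard epoch definition: 3 mini-batches per epoch; training stops as
  # soon as the halving target is reached
  fix <- overfit_fixture(size = 96, seeds = 1:2)
  fit <- avanet_train(
    fix$x, fix$y, net = network_config(base_filters = 8),
    train = train_config(batch_size = 2, batches_per_epoch = 3,
                         max_epochs = 200, early_stop_patience = 199,
                         stop_at_train_loss_frac = 0.5, seed = 0))
  expect_lte(min(fit$history$train_loss),
             0.5 * fit$history$train_loss[1])
  expect_lte(fit$epochs_run, 200)
})

test_that("convolution layers are translation-equivariant in the interior", {
  # the network is built from convolutions with no spatial biases: a shifted
  # input yields a shifted response wherever the receptive field stays off
  # the zero-padded border (exact for each conv unit; whole-model covariance
  # is limited only by that padding)
  set.seed(8)
  x <- array(stats::rnorm(40 * 40 * 2), c(40, 40, 2))
  w <- matrix(stats::rnorm(9 * 2 * 3, sd = 0.2), 9 * 2, 3)
  b <- stats::rnorm(3)
  sh <- 7L
  xs <- x
  xs[(sh + 1):40, , ] <- x[1:(40 - sh), , ]
  for (d in c(1L, 2L, 5L)) {
    y <- octava:::conv2d_fw(x, w, b, 3L, d)
    ys <- octava:::conv2d_fw(xs, w, b, 3L, d)
    rf <- 1L + d  # half receptive field of a dilated 3x3 kernel
    rows <- (rf + 1):(40 - sh - rf)
    expect_equal(ys[rows + sh, (rf + 1):(40 - rf), ],
                 y[rows, (rf + 1):(40 - rf), ], tolerance = 1e-12)
  }
})
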