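# Internal network engine. Feature maps are (H, W, C) numeric arrays,
# mini-batches are lists of such arrays. Convolutions run through the
# compiled im2col+GEMM kernels; batch normalisation, activations, Adam and
# the layer graph live here. Parameters and backward caches are held in
# environments so layer passes can update them in place.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# weight layout must match the C++ kernels: row = c*k*k + kj*k + ki
conv_layer_init <- function(cin, cout, k = 3L, d = 1L, bn = TRUE) {
  std <- sqrt(2 / (k * k * cin))
  l <- list(w = matrix(stats::rnorm(k * k * cin * cout, sd = std),
                       k * k * cin, cout),
            b = rep(0, cout), k = as.integer(k), d = as.integer(d),
            cin = as.integer(cin), cout = as.integer(cout))
  if (bn) {
    l$gamma <- rep(1, cout); l$beta <- rep(0, cout)
    l$rmean <- rep(0, cout); l$rvar <- rep(1, cout)
  }
  l
}

# layer plan: names in creation order define RNG consumption, so two builds
# from the same seed produce identical parameters
avanet_layer_plan <- function(cfg) {
  nf <- cfg$filters_per_level
  dr <- cfg$dilation_rates
  nb <- 1L + length(dr)  # plain conv + dilated branches feeding each concat
  plan <- list()
  cin <- cfg$input_channels
  for (i in seq_len(cfg$levels)) {
    plan[[paste0("enc", i, "_c1")]] <- list(cin = cin, cout = nf[i], d = 1L)
    plan[[paste0("enc", i, "_c2")]] <- list(cin = nf[i], cout = nf[i], d = 1L)
    for (r in dr)
      plan[[paste0("enc", i, "_d", r)]] <-
        list(cin = nf[i], cout = nf[i], d = as.integer(r))
    cin <- nb * nf[i]
  }
  for (j in seq_len(cfg$levels)) {
    lvl <- cfg$levels + 1L - j
    plan[[paste0("dec", j, "_c1")]] <- list(cin = cin, cout = nf[lvl], d = 1L)
    plan[[paste0("dec", j, "_c2")]] <- list(cin = nf[lvl], cout = nf[lvl],
                                            d = 1L)
    cin <- (1L + nb) * nf[lvl]  # upsampled block output + skip concat
  }
  plan[["head_c1"]] <- list(cin = cin, cout = cfg$base_filters, d = 1L)
  plan[["head_c2"]] <- list(cin = cfg$base_filters, cout = cfg$base_filters,
                            d = 1L)
  plan[["out"]] <- list(cin = cfg$base_filters, cout = 1L, d = 1L, k = 1L,
                        bn = FALSE)
  plan
}

avanet_init_params <- function(cfg) {
  plan <- avanet_layer_plan(cfg)
  pe <- new.env(parent = emptyenv())
  for (nm in names(plan)) {
    sp <- plan[[nm]]
    pe[[nm]] <- conv_layer_init(sp$cin, sp$cout, k = sp$k %||% 3L,
                                d = sp$d, bn = sp$bn %||% TRUE)
  }
  attr(pe, "layer_names") <- names(plan)
  pe
}

# per-channel affine on an (H, W, C) array, looping channels (C is small)
chan_scale_shift <- function(a, scale, shift) {
  d <- dim(a)
  m <- matrix(a, d[1] * d[2], d[3])
  for (c in seq_len(d[3])) m[, c] <- m[, c] * scale[c] + shift[c]
  dim(m) <- d
  m
}

cbr_fw <- function(name, xb, pe, cache = NULL, train = FALSE) {
  p <- pe[[name]]
  yb <- lapply(xb, function(x) conv2d_fw(x, p$w, p$b, p$k, p$d))
  if (!is.null(p$gamma)) {
    C <- p$cout
    if (train) {
      n <- 0; s1 <- numeric(C); s2 <- numeric(C)
      for (y in yb) {
        m <- matrix(y, ncol = C)
        s1 <- s1 + colSums(m); s2 <- s2 + colSums(m * m); n <- n + nrow(m)
      }
      mu <- s1 / n
      va <- pmax(s2 / n - mu^2, 0)
      p$rmean <- BN_MOMENTUM * p$rmean + (1 - BN_MOMENTUM) * mu
      p$rvar <- BN_MOMENTUM * p$rvar +
        (1 - BN_MOMENTUM) * va * n / max(n - 1, 1)
      pe[[name]] <- p
    } else {
      mu <- p$rmean; va <- p$rvar; n <- NULL
    }
    istd <- 1 / sqrt(va + BN_EPS)
    xhat <- lapply(yb, function(y) chan_scale_shift(y, istd, -mu * istd))
    zb <- lapply(xhat, function(h) chan_scale_shift(h, p$gamma, p$beta))
  } else {
    xhat <- NULL; istd <- NULL; n <- NULL
    zb <- yb
  }
  mask <- lapply(zb, function(z) z > 0)
  ab <- mapply(function(z, m) z * m, zb, mask, SIMPLIFY = FALSE)
  if (!is.null(cache))
    cache[[name]] <- list(x = xb, xhat = xhat, istd = istd, n = n,
                          mask = mask)
  ab
}

cbr_bw <- function(name, da_b, pe, cache, grads) {
  p <- pe[[name]]
  cc <- cache[[name]]
  dz_b <- mapply(function(da, m) da * m, da_b, cc$mask, SIMPLIFY = FALSE)
  if (!is.null(p$gamma)) {
    C <- p$cout; n <- cc$n
    dgamma <- numeric(C); dbeta <- numeric(C)
    for (b in seq_along(dz_b)) {
      dz <- matrix(dz_b[[b]], ncol = C)
      xh <- matrix(cc$xhat[[b]], ncol = C)
      dgamma <- dgamma + colSums(dz * xh)
      dbeta <- dbeta + colSums(dz)
    }
    # d/dy of BN: (gamma/sd) * (dz - mean(dz) - xhat * mean(dz * xhat))
    sc <- p$gamma * cc$istd
    dy_b <- vector("list", length(dz_b))
    for (b in seq_along(dz_b)) {
      d <- dim(dz_b[[b]])
      dz <- matrix(dz_b[[b]], ncol = C)
      xh <- matrix(cc$xhat[[b]], ncol = C)
      for (c in seq_len(C))
        dz[, c] <- sc[c] * (dz[, c] - dbeta[c] / n - xh[, c] * dgamma[c] / n)
      dim(dz) <- d
      dy_b[[b]] <- dz
    }
  } else {
    dgamma <- NULL; dbeta <- NULL
    dy_b <- dz_b
  }
  dw <- 0; db <- 0
  dx_b <- vector("list", length(dy_b))
  for (b in seq_along(dy_b)) {
    r <- conv2d_bw(cc$x[[b]], p$w, dy_b[[b]], p$k, p$d)
    dw <- dw + r$dw; db <- db + r$db
    dx_b[[b]] <- r$dx
  }
  g <- list(w = dw, b = as.numeric(db))
  if (!is.null(dgamma)) { g$gamma <- dgamma; g$beta <- dbeta }
  grads[[name]] <- g
  dx_b
}

concat_batch <- function(parts) {
  B <- length(parts[[1]])
  lapply(seq_len(B), function(b) {
    as <- lapply(parts, `[[`, b)
    hw <- dim(as[[1]])[1:2]
    array(unlist(as, use.names = FALSE),
          dim = c(hw, sum(vapply(as, function(a) dim(a)[3], 0))))
  })
}

split_batch <- function(hb, sizes) {
  off <- c(0L, cumsum(sizes))
  lapply(seq_along(sizes), function(k)
    lapply(hb, function(a)
      a[, , (off[k] + 1L):(off[k] + sizes[k]), drop = FALSE]))
}

add_batch <- function(a, b) mapply(`+`, a, b, SIMPLIFY = FALSE)

# forward pass; xb is a list of (H, W, 1) arrays with H, W divisible by
# 2^levels. Returns a list of probability arrays; with a cache environment
# (train mode) every intermediate needed by avanet_backward_pass is stored.
avanet_forward_pass <- function(pe, cfg, xb, train = FALSE, cache = NULL) {
  dr <- cfg$dilation_rates
  skips <- vector("list", cfg$levels)
  h <- xb
  for (i in seq_len(cfg$levels)) {
    h <- cbr_fw(paste0("enc", i, "_c1"), h, pe, cache, train)
    c2 <- cbr_fw(paste0("enc", i, "_c2"), h, pe, cache, train)
    branches <- list(c2)
    for (r in dr)
      branches[[length(branches) + 1L]] <-
        cbr_fw(paste0("enc", i, "_d", r), c2, pe, cache, train)
    cat_i <- concat_batch(branches)
    skips[[i]] <- cat_i
    pl <- lapply(cat_i, maxpool2_fw)
    h <- lapply(pl, `[[`, "y")
    if (!is.null(cache)) {
      cache[[paste0("pool", i, "_amax")]] <- lapply(pl, `[[`, "argmax")
      cache[[paste0("pool", i, "_dim")]] <- dim(cat_i[[1]])
    }
  }
  for (j in seq_len(cfg$levels)) {
    lvl <- cfg$levels + 1L - j
    h <- cbr_fw(paste0("dec", j, "_c1"), h, pe, cache, train)
    h <- cbr_fw(paste0("dec", j, "_c2"), h, pe, cache, train)
    h <- lapply(h, upsample2_fw)
    h <- concat_batch(list(h, skips[[lvl]]))
  }
  h <- cbr_fw("head_c1", h, pe, cache, train)
  h <- cbr_fw("head_c2", h, pe, cache, train)
  p <- pe[["out"]]
  logits <- lapply(h, function(x) conv2d_fw(x, p$w, p$b, 1L, 1L))
  if (!is.null(cache)) cache[["out_x"]] <- h
  probs <- lapply(logits, function(l) 1 / (1 + exp(-l)))
  if (!is.null(cache)) cache[["probs"]] <- probs
  probs
}

# backward pass from dL/dprob; fills a grads environment keyed by layer
avanet_backward_pass <- function(pe, cfg, cache, dprob_b) {
  grads <- new.env(parent = emptyenv())
  nb <- 1L + length(cfg$dilation_rates)
  # sigmoid
  dlogit_b <- mapply(function(dp, s) dp * s * (1 - s), dprob_b,
                     cache[["probs"]], SIMPLIFY = FALSE)
  p_out <- pe[["out"]]
  dw <- 0; db <- 0
  dh <- vector("list", length(dlogit_b))
  for (b in seq_along(dlogit_b)) {
    r <- conv2d_bw(cache[["out_x"]][[b]], p_out$w, dlogit_b[[b]], 1L, 1L)
    dw <- dw + r$dw; db <- db + r$db
    dh[[b]] <- r$dx
  }
  grads[["out"]] <- list(w = dw, b = as.numeric(db))
  dh <- cbr_bw("head_c2", dh, pe, cache, grads)
  dh <- cbr_bw("head_c1", dh, pe, cache, grads)
  dskips <- vector("list", cfg$levels)
  for (j in rev(seq_len(cfg$levels))) {
    lvl <- cfg$levels + 1L - j
    nf <- cfg$filters_per_level[lvl]
    sp <- split_batch(dh, c(nf, nb * nf))
    dskips[[lvl]] <- sp[[2]]
    d_c2 <- lapply(sp[[1]], upsample2_bw)
    d_c2 <- cbr_bw(paste0("dec", j, "_c2"), d_c2, pe, cache, grads)
    dh <- cbr_bw(paste0("dec", j, "_c1"), d_c2, pe, cache, grads)
  }
  for (i in rev(seq_len(cfg$levels))) {
    dims <- cache[[paste0("pool", i, "_dim")]]
    amax <- cache[[paste0("pool", i, "_amax")]]
    d_cat <- mapply(function(g, a) maxpool2_bw(g, a, dims[1], dims[2]),
                    dh, amax, SIMPLIFY = FALSE)
    d_cat <- add_batch(d_cat, dskips[[i]])
    nf <- cfg$filters_per_level[i]
    sp <- split_batch(d_cat, rep(nf, nb))
    d_c2 <- sp[[1]]
    for (k in seq_along(cfg$dilation_rates)) {
      r <- cfg$dilation_rates[k]
      d_c2 <- add_batch(d_c2, cbr_bw(paste0("enc", i, "_d", r), sp[[k + 1L]],
                                     pe, cache, grads))
    }
    dh <- cbr_bw(paste0("enc", i, "_c2"), d_c2, pe, cache, grads)
    dh <- cbr_bw(paste0("enc", i, "_c1"), dh, pe, cache, grads)
  }
  grads
}

# batch-pooled soft IoU loss and its gradient wrt the probability maps
iou_loss_batch <- function(gb, sb, eps = 1e-6) {
  I <- 0; U <- 0
  for (b in seq_along(gb)) {
    g <- gb[[b]]; s <- sb[[b]]
    I <- I + sum(g * s)
    U <- U + sum(g + s - g * s)
  }
  if (U == 0) return(list(loss = 0, dprob = lapply(sb, function(s) s * 0)))
  Ue <- U + eps
  dprob <- mapply(function(g, s) -(g * Ue - I * (1 - g)) / Ue^2, gb, sb,
                  SIMPLIFY = FALSE)
  list(loss = 1 - I / Ue, dprob = dprob)
}

adam_state_init <- function() new.env(parent = emptyenv())

adam_step <- function(pe, grads, opt, lr, beta1, beta2, eps, t) {
  for (nm in ls(grads)) {
    g <- grads[[nm]]
    p <- pe[[nm]]
    st <- opt[[nm]]
    if (is.null(st)) st <- list()
    for (f in names(g)) {
      gv <- g[[f]]
      if (is.null(st[[f]])) st[[f]] <- list(m = gv * 0, v = gv * 0)
      st[[f]]$m <- beta1 * st[[f]]$m + (1 - beta1) * gv
      st[[f]]$v <- beta2 * st[[f]]$v + (1 - beta2) * gv^2
      mhat <- st[[f]]$m / (1 - beta1^t)
      vhat <- st[[f]]$v / (1 - beta2^t)
      p[[f]] <- p[[f]] - lr * mhat / (sqrt(vhat) + eps)
    }
    opt[[nm]] <- st
    pe[[nm]] <- p
  }
  invisible(NULL)
}

params_to_list <- function(pe) {
  nms <- attr(pe, "layer_names")
  stats::setNames(lapply(nms, function(nm) pe[[nm]]), nms)
}

params_from_list <- function(pl) {
  pe <- new.env(parent = emptyenv())
  for (nm in names(pl)) pe[[nm]] <- pl[[nm]]
  attr(pe, "layer_names") <- names(pl)
  pe
}
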