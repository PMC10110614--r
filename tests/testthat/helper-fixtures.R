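# Shared fixtures and independent oracles, built in code at test time.

# random sparse AV map with at least one artery and one vein pixel
random_av_map <- function(h = 16, w = 16, n_art = 6, n_vein = 6) {
  lab <- matrix(0L, h, w)
  pick <- sample(h * w, n_art + n_vein)
  lab[pick[seq_len(n_art)]] <- 1L
  lab[pick[n_art + seq_len(n_vein)]] <- 2L
  av_map(lab)
}

# random dense binary AVA map
random_ava_map <- function(h = 16, w = 16, p_art = 0.5) {
  ava_map(matrix(as.integer(stats::runif(h * w) < p_art), h, w))
}

# random OCTA intensity image
random_octa <- function(h = 16, w = 16, id = "t") {
  octa_image(matrix(sample(0:255, h * w, replace = TRUE), h, w), id = id)
}

# exhaustive kNN oracle, independent of the compiled implementation:
# all pairwise distances, neighbour order (distance, row-major scan index),
# 1/d or uniform vote, weighted ties to artery
knn_oracle <- function(av, k, weighted = TRUE) {
  lab <- av$labels
  idx <- which(lab != 0L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  cls <- lab[idx]
  out <- lab
  bg <- which(lab == 0L, arr.ind = TRUE)
  for (q in seq_len(nrow(bg))) {
    d2 <- (idx[, 1] - bg[q, 1])^2 + (idx[, 2] - bg[q, 2])^2
    o <- order(d2, seq_along(d2))[seq_len(k)]
    wts <- if (weighted) 1 / sqrt(d2[o]) else rep(1, k)
    wa <- sum(wts[cls[o] == 1L]); wv <- sum(wts[cls[o] == 2L])
    out[bg[q, 1], bg[q, 2]] <- if (wa >= wv) 1L else 2L
  }
  ava_map((out == 1L) * 1L, av$geometry)
}

# two small scenes plus kNN ground truths, used by the network tests
overfit_fixture <- function(size = 96, seeds = 1:2) {
  scenes <- lapply(seeds, function(s)
    simulate_scene(scene_config(size = size, seed = s)))
  list(x = lapply(scenes, `[[`, "octa"),
       y = lapply(scenes, function(s)
         classify_background(s$av, knn_config(k = 5))))
}
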