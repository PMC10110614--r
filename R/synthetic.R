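# Synthetic OCTA scenes with known artery/vein ground truth. The generator
# encodes the grading heuristics used for manual AV maps: arterial and
# venous trees alternate across the field (each vein drains the beds
# perfused by its neighbouring arteries), same-type vessels never cross
# (each tree is confined to its own territory band), all vessels avoid the
# foveal avascular zone, arteries carry a capillary-free flanking band, and
# the signal is degraded by multiplicative speckle. The reference AVA map
# comes from the generator's own territory assignment, independent of the
# kNN propagation module, so it can serve as that module's oracle.

#' Scene generator settings
#'
#' @param size image side in pixels (square grid).
#' @param field_mm physical side length (6 mm scan by default).
#' @param n_trunks even number of vessel trees, alternating artery/vein
#'   across the field.
#' @param branch_depth recursion depth of side branches per tree.
#' @param territory_share fraction of the field assigned to arterial
#'   territory (arterial bands are widened relative to venous bands).
#' @param vessel_intensity 8-bit intensity range of vessel pixels.
#' @param capillary_intensity 8-bit intensity range of the capillary
#'   background (use `c(0, 0)` for a capillary-free scene).
#' @param faz_diameter_mm diameter of the central avascular zone.
#' @param capillary_free_halfwidth_px half-width of the reduced-density
#'   band flanking arteries.
#' @param speckle_sigma standard deviation of the clipped multiplicative
#'   Gaussian speckle (0 disables it).
#' @param seed RNG seed; a fixed seed reproduces the scene bit for bit.
#' @return A `scene_config` object.
#' @export
scene_config <- function(size = 400L, field_mm = 6.0, n_trunks = 6L,
                         branch_depth = 4L, territory_share = 0.5,
                         vessel_intensity = c(180, 255),
                         capillary_intensity = c(60, 130),
                         faz_diameter_mm = 0.6,
                         capillary_free_halfwidth_px = 6L,
                         speckle_sigma = 0.15, seed = 1L) {
  size <- as.integer(size); n_trunks <- as.integer(n_trunks)
  if (n_trunks < 2L || n_trunks %% 2L != 0L)
    stop("n_trunks must be an even integer >= 2", call. = FALSE)
  if (territory_share <= 0 || territory_share >= 1)
    stop("territory_share must lie in (0, 1)", call. = FALSE)
  if (faz_diameter_mm < 0 || faz_diameter_mm >= field_mm)
    stop("faz_diameter_mm must lie in [0, field_mm)", call. = FALSE)
  stopifnot(size >= 32L, length(vessel_intensity) == 2L,
            length(capillary_intensity) == 2L, speckle_sigma >= 0)
  structure(list(size = size, field_mm = field_mm, n_trunks = n_trunks,
                 branch_depth = as.integer(branch_depth),
                 territory_share = territory_share,
                 vessel_intensity = vessel_intensity,
                 capillary_intensity = capillary_intensity,
                 faz_diameter_mm = faz_diameter_mm,
                 capillary_free_halfwidth_px =
                   as.integer(capillary_free_halfwidth_px),
                 speckle_sigma = speckle_sigma, seed = as.integer(seed)),
            class = "scene_config")
}

# midpoint-displaced polyline from (r0,c0) to (r1,c1), jitter shrinking
# with segment length
midpoint_polyline <- function(r0, c0, r1, c1, jitter, depth = 4L) {
  pts <- matrix(c(r0, c0, r1, c1), ncol = 2, byrow = TRUE)
  for (d in seq_len(depth)) {
    n <- nrow(pts)
    mid <- (pts[-n, , drop = FALSE] + pts[-1, , drop = FALSE]) / 2
    mid <- mid + matrix(stats::rnorm(2 * (n - 1), 0, jitter / d), ncol = 2)
    out <- matrix(0, 2 * n - 1, 2)
    out[seq(1, 2 * n - 1, by = 2), ] <- pts
    out[seq(2, 2 * n - 2, by = 2), ] <- mid
    pts <- out
  }
  pts
}

# stamp a polyline with a given radius onto a logical canvas; points are
# clamped to the column window and pushed sideways out of the FAZ disk
stamp_polyline <- function(canvas, pts, radius, cwin, faz, avoid_side) {
  h <- nrow(canvas); w <- ncol(canvas)
  # densify
  seg <- cbind(pts[-nrow(pts), , drop = FALSE], pts[-1, , drop = FALSE])
  dens <- lapply(seq_len(nrow(seg)), function(i) {
    n <- max(2L, ceiling(max(abs(seg[i, 3] - seg[i, 1]),
                             abs(seg[i, 4] - seg[i, 2])) * 2))
    cbind(seq(seg[i, 1], seg[i, 3], length.out = n),
          seq(seg[i, 2], seg[i, 4], length.out = n))
  })
  p <- do.call(rbind, dens)
  # keep inside the territory band
  p[, 2] <- pmin(pmax(p[, 2], cwin[1]), cwin[2])
  # push out of the avascular zone, sideways within the band
  if (faz$r > 0) {
    d2 <- (p[, 1] - faz$ci)^2 + (p[, 2] - faz$cj)^2
    inside <- d2 < (faz$r + radius)^2
    if (any(inside)) {
      dr <- abs(p[inside, 1] - faz$ci)
      lat <- sqrt(pmax((faz$r + radius)^2 - dr^2, 0))
      p[inside, 2] <- faz$cj + avoid_side * lat
      p[inside, 2] <- pmin(pmax(p[inside, 2], cwin[1]), cwin[2])
    }
  }
  ij <- unique(round(p))
  off <- expand.grid(di = -ceiling(radius):ceiling(radius),
                     dj = -ceiling(radius):ceiling(radius))
  off <- off[off$di^2 + off$dj^2 <= radius^2, , drop = FALSE]
  ii <- outer(ij[, 1], off$di, `+`)
  jj <- outer(ij[, 2], off$dj, `+`)
  ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
  canvas[cbind(ii[ok], jj[ok])] <- TRUE
  canvas
}

# binary dilation by r via r iterations of a 3x3 structuring element
dilate_mask <- function(m, r) {
  for (k in seq_len(r)) {
    sh <- m
    sh[-1, ] <- sh[-1, ] | m[-nrow(m), ]
    sh[-nrow(m), ] <- sh[-nrow(m), ] | m[-1, ]
    m2 <- sh
    m2[, -1] <- m2[, -1] | sh[, -ncol(sh)]
    m2[, -ncol(m2)] <- m2[, -ncol(m2)] | sh[, -1]
    m <- m2
  }
  m
}

#' Simulate an OCTA scene with known ground truth
#'
#' Generates an 8-bit en face OCTA-like image together with its sparse
#' artery/vein vessel grading and the reference dense territory partition.
#' Territories are alternating vertical bands whose arterial widths are
#' scaled by `territory_share`; each band holds one midpoint-displaced
#' branching tree entering from the top border, so same-type trees never
#' cross. All vessels route around the central avascular zone, capillaries
#' fill the remaining tissue except that zone and a thinned band flanking
#' arteries, and the final image carries clipped multiplicative Gaussian
#' speckle.
#'
#' @param cfg a [scene_config()].
#' @return List with `octa` ([octa_image()]), `av` ([av_map()]; sparse
#'   vessel labels), and `ava_ref` ([ava_map()]; the generative territory
#'   partition).
#' @export
simulate_scene <- function(cfg = scene_config()) {
  stopifnot(inherits(cfg, "scene_config"))
  with_seed(cfg$seed, simulate_scene_impl(cfg))
}

simulate_scene_impl <- function(cfg) {
  h <- cfg$size; w <- cfg$size
  geom <- image_geometry(h, w, cfg$field_mm)
  n2 <- cfg$n_trunks %/% 2L
  wa <- cfg$territory_share * w / n2       # arterial band width
  wv <- (1 - cfg$territory_share) * w / n2 # venous band width
  widths <- rep(c(wa, wv), n2)
  bounds <- c(0, cumsum(widths))           # length n_trunks + 1
  cls <- rep(c(AV_ARTERY, AV_VEIN), n2)    # band classes, alternating
  # reference partition by column
  col_band <- findInterval(seq_len(w) - 0.5, bounds, rightmost.closed = TRUE)
  col_band <- pmin(pmax(col_band, 1L), cfg$n_trunks)
  ava_ref <- matrix(rep((cls[col_band] == AV_ARTERY) * 1L, each = h), h, w)

  faz <- list(ci = (h + 1) / 2, cj = (w + 1) / 2,
              r = (cfg$faz_diameter_mm / 2) / pixel_pitch(geom))
  art <- matrix(FALSE, h, w); ven <- matrix(FALSE, h, w)
  for (b in seq_len(cfg$n_trunks)) {
    c0 <- bounds[b]; c1 <- bounds[b + 1]
    margin <- 2
    cwin <- c(c0 + margin, c1 - margin)
    if (cwin[2] <= cwin[1]) cwin <- c(mean(c(c0, c1)), mean(c(c0, c1)))
    cc <- mean(cwin)
    avoid_side <- if (cc >= faz$cj) 1 else -1
    canvas <- matrix(FALSE, h, w)
    # trunk: top border to bottom, wiggling inside the band
    trunk <- midpoint_polyline(1, cc + stats::runif(1, -1, 1) * (cwin[2] - cwin[1]) / 6,
                               h, cc + stats::runif(1, -1, 1) * (cwin[2] - cwin[1]) / 6,
                               jitter = (cwin[2] - cwin[1]) / 5)
    canvas <- stamp_polyline(canvas, trunk, 1.8, cwin, faz, avoid_side)
    # side branches off the parent, recursively finer; directions are
    # laterally biased so each tree perfuses its full band width. Branch
    # spawn spacing is physical (one branch per ~0.25 mm of parent
    # vessel); with branch length scaling with band width this keeps
    # pixel density comparable between wide and narrow territories and
    # coverage resolution-independent.
    spacing_px <- 0.25 / pixel_pitch(geom)
    grow <- function(base_pts, depth, radius) {
      if (depth < 1L) return(invisible(NULL))
      seg_len <- sum(sqrt(rowSums((base_pts[-1, , drop = FALSE] -
                                     base_pts[-nrow(base_pts), ,
                                              drop = FALSE])^2)))
      n_br <- as.integer(round(seg_len / spacing_px))
      if (n_br < 1L) return(invisible(NULL))
      at <- sort(sample(seq(2L, nrow(base_pts) - 1L),
                        min(n_br, nrow(base_pts) - 2L)))
      side <- if (stats::runif(1) < 0.5) 1 else -1
      for (a in at) {
        p0 <- base_pts[a, ]
        side <- -side  # alternate left/right of the parent
        reach <- if (side > 0) cwin[2] - p0[2] else p0[2] - cwin[1]
        len <- stats::runif(1, 0.75, 1.05) * max(reach, 2)
        p1 <- c(p0[1] + stats::runif(1, -0.6, 0.6) * len,
                p0[2] + side * len)
        p1[1] <- min(max(p1[1], 1), h)
        br <- midpoint_polyline(p0[1], p0[2], p1[1], p1[2],
                                jitter = len / 7, depth = 4L)
        canvas <<- stamp_polyline(canvas, br, radius, cwin, faz, avoid_side)
        grow(br, depth - 1L, max(radius * 0.65, 0.5))
      }
    }
    grow(trunk, cfg$branch_depth, 1.2)
    if (cls[b] == AV_ARTERY) art <- art | canvas else ven <- ven | canvas
  }
  # the avascular zone is devoid of vessels: routing pushes trees around
  # it, and any residue from band clamping at its rim is erased
  di2v <- (seq_len(h) - faz$ci)^2
  dj2v <- (seq_len(w) - faz$cj)^2
  in_faz_disk <- outer(di2v, dj2v, `+`) < faz$r^2
  art[in_faz_disk] <- FALSE
  ven[in_faz_disk] <- FALSE
  # same-type trees are band-confined; at shared boundaries give arteries
  # priority so no pixel carries both labels
  ven <- ven & !art
  labels <- matrix(AV_BACKGROUND, h, w)
  labels[art] <- AV_ARTERY
  labels[ven] <- AV_VEIN

  # intensity composition
  vessel <- matrix(0, h, w)
  nv <- sum(art | ven)
  vessel[art | ven] <- stats::runif(nv, cfg$vessel_intensity[1],
                                    cfg$vessel_intensity[2])
  di2 <- (seq_len(h) - faz$ci)^2
  dj2 <- (seq_len(w) - faz$cj)^2
  in_faz <- outer(di2, dj2, `+`) < faz$r^2
  cap <- matrix(0, h, w)
  if (cfg$capillary_intensity[2] > 0) {
    tissue <- !(art | ven) & !in_faz
    cap_free <- dilate_mask(art, cfg$capillary_free_halfwidth_px) &
      !(art | ven)
    dens <- matrix(stats::runif(h * w), h, w)
    fill <- tissue & ((!cap_free & dens < 0.85) | (cap_free & dens < 0.30))
    cap[fill] <- stats::runif(sum(fill), cfg$capillary_intensity[1],
                              cfg$capillary_intensity[2])
    cap[cap_free & fill] <- cap[cap_free & fill] * 0.6
  }
  img <- pmax(vessel, cap)
  if (cfg$speckle_sigma > 0) {
    sp <- 1 + stats::rnorm(h * w, 0, cfg$speckle_sigma)
    sp <- pmin(pmax(sp, 0), 2)
    img <- img * matrix(sp, h, w)
  }
  img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), h, w)
  list(octa = octa_image(img, geom, id = sprintf("scene_seed%d", cfg$seed)),
       av = av_map(labels, geom),
       ava_ref = ava_map(ava_ref, geom))
}

#' Cohort simulator settings
#'
#' Study-condition defaults mirror the clinical cohort the package's
#' statistics target: three groups (healthy control, diabetic without
#' retinopathy, mild retinopathy), each eye one observation. Group effects
#' are multiplicative on the per-eye arterial intensity, venous intensity
#' and arterial territory share (1 = no effect).
#'
#' @param n_per_group named integer vector of eyes per group.
#' @param effects named list (one entry per group) of
#'   `c(art = , ven = , share = )` multipliers.
#' @param share_mean mean arterial territory share of a healthy eye
#'   (0.526, i.e. mean arterial area 52.6%).
#' @param intensity_mean_art,intensity_mean_ven mean per-eye 8-bit mean
#'   intensity of arterial and venous territory (ratio 0.944, the healthy
#'   arterial-venous perfusion-intensity-density ratio).
#' @param intensity_cv between-eye coefficient of variation of the
#'   territory intensities.
#' @param share_sd between-eye standard deviation of the territory share.
#' @param aa_noise_sd measurement noise (percentage points) on the
#'   arterial-area estimate, emulating segmentation/quantisation error.
#' @param seed cohort seed.
#' @param render render full scenes through the image pipeline instead of
#'   sampling features from the scene model's statistical abstraction.
#' @param render_size scene side in pixels when `render = TRUE`.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_per_group = c(control = 20L, NoDR = 20L,
                                          mildDR = 20L),
                          effects = list(
                            control = c(art = 1, ven = 1, share = 1),
                            NoDR = c(art = 1, ven = 1, share = 1),
                            mildDR = c(art = 1, ven = 1, share = 1)),
                          share_mean = 0.526,
                          intensity_mean_art = 0.944 * 92,
                          intensity_mean_ven = 92,
                          intensity_cv = 0.07, share_sd = 0.03,
                          aa_noise_sd = 0.5, seed = 1L,
                          render = FALSE, render_size = 160L) {
  n_per_group <- vapply(n_per_group, as.integer, 0L)
  if (any(n_per_group < 2L))
    stop("need at least 2 eyes per group", call. = FALSE)
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group))))
    stop("n_per_group must be named by group", call. = FALSE)
  if (!all(names(n_per_group) %in% names(effects)))
    stop("every group needs an entry in effects", call. = FALSE)
  for (e in effects)
    if (any(e <= 0)) stop("effects must be positive multipliers",
                          call. = FALSE)
  structure(list(n_per_group = n_per_group, effects = effects,
                 share_mean = share_mean,
                 intensity_mean_art = intensity_mean_art,
                 intensity_mean_ven = intensity_mean_ven,
                 intensity_cv = intensity_cv, share_sd = share_sd,
                 aa_noise_sd = aa_noise_sd, seed = as.integer(seed),
                 render = isTRUE(render),
                 render_size = as.integer(render_size)),
            class = "cohort_config")
}

#' Simulate a cohort feature table
#'
#' Draws per-eye latent parameters (arterial territory share, arterial and
#' venous territory intensities) with the configured group effects and
#' returns the seven-feature table in the same schema as
#' [quantify_batch()], plus a `group` column. By default features are
#' computed directly from the latents via the same formulas the image
#' pipeline applies (share to area percentages; mean territory intensity
#' to perfusion intensity density, with the total as the area-weighted
#' mixture); with `render = TRUE` each eye is rendered as a full scene and
#' pushed through kNN propagation, masking and quantification.
#'
#' @param cfg a [cohort_config()].
#' @return A `data.frame` with columns
#'   `id, group, AA, VA, AVAR, T_PID, A_PID, V_PID, AV_PIDR`.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(cfg$seed, {
    rows <- list()
    for (g in names(cfg$n_per_group)) {
      ef <- cfg$effects[[g]]
      for (i in seq_len(cfg$n_per_group[[g]])) {
        share <- stats::rnorm(1, cfg$share_mean * ef[["share"]], cfg$share_sd)
        share <- min(max(share, 0.3), 0.7)
        i_a <- stats::rnorm(1, 1, cfg$intensity_cv) *
          cfg$intensity_mean_art * ef[["art"]]
        i_v <- stats::rnorm(1, 1, cfg$intensity_cv) *
          cfg$intensity_mean_ven * ef[["ven"]]
        i_a <- min(max(i_a, 1), 255); i_v <- min(max(i_v, 1), 255)
        id <- sprintf("%s_eye%02d", g, i)
        if (cfg$render) {
          row <- render_eye(cfg, id, share, i_a, i_v)
        } else {
          aa <- 100 * share + stats::rnorm(1, 0, cfg$aa_noise_sd)
          aa <- min(max(aa, 1), 99)
          a_pid <- (100 / 255) * i_a
          v_pid <- (100 / 255) * i_v
          row <- data.frame(
            id = id, AA = aa, VA = 100 - aa, AVAR = aa / (100 - aa),
            T_PID = (aa * a_pid + (100 - aa) * v_pid) / 100,
            A_PID = a_pid, V_PID = v_pid, AV_PIDR = a_pid / v_pid,
            stringsAsFactors = FALSE)
        }
        row$group <- g
        rows[[length(rows) + 1L]] <- row
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[, c("id", "group", "AA", "VA", "AVAR", "T_PID", "A_PID", "V_PID",
            "AV_PIDR")]
  })
}

# full-pipeline rendering of one eye: scene -> kNN AVA map -> masked
# quantification; territory intensities rescaled to the eye's latents
render_eye <- function(cfg, id, share, i_a, i_v) {
  sc <- scene_config(size = cfg$render_size, territory_share = share,
                     seed = stats::runif(1, 0, .Machine$integer.max))
  scene <- simulate_scene_impl(sc)
  px <- scene$octa$pixels * 1.0
  ref <- scene$ava_ref$labels
  m_a <- mean(px[ref == 1L]); m_v <- mean(px[ref == 0L])
  px[ref == 1L] <- px[ref == 1L] * (i_a / max(m_a, 1))
  px[ref == 0L] <- px[ref == 0L] * (i_v / max(m_v, 1))
  octa <- octa_image(matrix(as.integer(pmin(pmax(round(px), 0), 255)),
                            nrow(px), ncol(px)),
                     scene$octa$geometry, id = id)
  ava <- classify_background(scene$av, knn_config(k = 5L))
  quantify_image(octa, ava, analysis_mask(octa$geometry))
}
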