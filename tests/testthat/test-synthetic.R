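test_that("scenes are reproducible and structurally valid", {
  cfg <- scene_config(size = 96, seed = 5)
  s1 <- simulate_scene(cfg)
  s2 <- simulate_scene(cfg)
  expect_identical(s1$octa$pixels, s2$octa$pixels)
  expect_identical(s1$av$labels, s2$av$labels)
  expect_identical(s1$ava_ref$labels, s2$ava_ref$labels)
  # different seed, different scene
  expect_false(identical(simulate_scene(scene_config(size = 96,
                                                     seed = 6))$octa$pixels,
                         s1$octa$pixels))
  # both vessel classes present, dense reference partition
  expect_true(all(c(1L, 2L) %in% s1$av$labels))
  expect_true(all(s1$ava_ref$labels %in% c(0L, 1L)))
})

test_that("a noiseless capillary-free scene is dark off the vessels", {
  s <- simulate_scene(scene_config(size = 96, speckle_sigma = 0,
                                   capillary_intensity = c(0, 0), seed = 2))
  off_vessel <- s$av$labels == 0L
  expect_true(all(s$octa$pixels[off_vessel] == 0L))
  expect_true(all(s$octa$pixels[!off_vessel] > 0L))
})

test_that("vessels avoid the avascular zone and capillaries vanish there", {
  cfg <- scene_config(size = 128, speckle_sigma = 0, seed = 3)
  s <- simulate_scene(cfg)
  n <- 128; ci <- (n + 1) / 2
  r <- (cfg$faz_diameter_mm / 2) / (cfg$field_mm / n)
  d2 <- outer((1:n - ci)^2, (1:n - ci)^2, `+`)
  inner <- d2 < (r * 0.8)^2  # clear interior, away from the rim
  expect_true(all(s$av$labels[inner] == 0L))
  expect_true(all(s$octa$pixels[inner] == 0L))
})

test_that("two symmetric trunks split the field in half", {
  s <- simulate_scene(scene_config(size = 128, n_trunks = 2, seed = 3))
  af <- area_features(s$ava_ref)
  expect_equal(af$AA, 50, tolerance = 1)
  expect_equal(af$VA, 50, tolerance = 1)
})

test_that("the reference partition tracks the territory share", {
  for (s in c(0.4, 0.6)) {
    scn <- simulate_scene(scene_config(size = 160, territory_share = s,
                                       seed = 4))
    expect_equal(area_features(scn$ava_ref)$AA, 100 * s, tolerance = 1.5)
  }
})

test_that("kNN propagation recovers the generative territories", {
  scn <- simulate_scene(scene_config(size = 192, territory_share = 0.6,
                                     seed = 9))
  ava <- classify_background(scn$av, knn_config(k = 5))
  expect_gte(mean(ava$labels == scn$ava_ref$labels), 0.9)
  aa <- area_features(ava, analysis_mask(ava$geometry))$AA
  expect_lt(abs(aa - 60), 3)
})

test_that("raising vessel intensity raises total perfusion intensity", {
  t_pid <- vapply(c(150, 200, 250), function(vi) {
    s <- simulate_scene(scene_config(size = 96, speckle_sigma = 0,
                                     vessel_intensity = c(vi, vi), seed = 11))
    quantify_image(s$octa, s$ava_ref, mask = NULL)$T_PID
  }, numeric(1))
  expect_true(all(diff(t_pid) > 0))
})

test_that("scene configs validate their invariants", {
  expect_error(scene_config(n_trunks = 3), "even")
  expect_error(scene_config(territory_share = 1.2), "territory_share")
  expect_error(scene_config(faz_diameter_mm = 7), "faz_diameter_mm")
})

test_that("cohorts carry group structure with the configured effects", {
  tab <- simulate_cohort(cohort_config(seed = 2))
  expect_equal(nrow(tab), 60)
  expect_equal(unname(table(tab$group)[c("control", "NoDR", "mildDR")]),
               rep(20L, 3), ignore_attr = TRUE)
  expect_equal(tab$AA + tab$VA, rep(100, 60), tolerance = 1e-9)
  expect_equal(tab$AV_PIDR, tab$A_PID / tab$V_PID, tolerance = 1e-9)
  # mixture identity holds row-wise
  expect_equal(tab$T_PID, (tab$AA * tab$A_PID + tab$VA * tab$V_PID) / 100,
               tolerance = 1e-9)
  # reproducible
  expect_identical(simulate_cohort(cohort_config(seed = 2)), tab)
  expect_error(cohort_config(n_per_group = c(control = 1L, NoDR = 5L,
                                             mildDR = 5L)), "at least 2")
})

test_that("an arterial perfusion deficit is detected by the pipeline", {
  eff <- list(control = c(art = 1, ven = 1, share = 1),
              NoDR = c(art = 1, ven = 1, share = 1),
              mildDR = c(art = 0.92, ven = 1, share = 1))
  hits <- 0
  for (s in 1:20) {
    tab <- simulate_cohort(cohort_config(effects = eff, seed = s))
    expect_lt(mean(tab$A_PID[tab$group == "mildDR"]),
              mean(tab$A_PID[tab$group == "control"]) + 3)
    res <- compare_groups(tab, "A_PID")
    hit <- res$p[res$group1 == "control" & res$group2 == "mildDR"] < 0.05
    hits <- hits + hit
  }
  expect_gte(hits, 16)
})

test_that("rendered cohorts agree with the parametric abstraction", {
  eff1 <- list(g1 = c(art = 1, ven = 1, share = 1))
  cfgp <- cohort_config(n_per_group = c(g1 = 8L), effects = eff1, seed = 5)
  cfgr <- cohort_config(n_per_group = c(g1 = 8L), effects = eff1, seed = 5,
                        render = TRUE, render_size = 128L)
  par_tab <- simulate_cohort(cfgp)
  ren_tab <- simulate_cohort(cfgr)
  expect_equal(names(ren_tab), names(par_tab))
  # the rendered pipeline reproduces the latent means to within the
  # abstraction error of the scene model
  expect_lt(abs(mean(ren_tab$AA) - mean(par_tab$AA)), 5)
  expect_lt(abs(mean(ren_tab$AV_PIDR) - mean(par_tab$AV_PIDR)), 0.15)
})
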