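test_that("the OCTA-AV map splits intensity by territory and mask", {
  px <- matrix(0L, 6, 6); px[2, 2] <- 200L; px[3, 3] <- 90L; px[5, 5] <- 40L
  octa <- octa_image(px, id = "s")
  lab <- matrix(0L, 6, 6); lab[2, 2] <- 1L
  ava <- ava_map(lab)
  keep <- matrix(TRUE, 6, 6); keep[5, 5] <- FALSE
  mask <- exclusion_mask(keep)
  oav <- make_octa_av(octa, ava, mask)
  expect_equal(oav$arterial[2, 2], 200L)
  expect_equal(oav$venous[2, 2], 0L)
  expect_equal(oav$venous[3, 3], 90L)
  # excluded pixel is zero in both channels
  expect_equal(oav$arterial[5, 5] + oav$venous[5, 5], 0L)
  # channel sum reproduces the masked image everywhere
  expect_identical(oav$arterial + oav$venous, px * keep)
  # geometry mismatch refused
  expect_error(make_octa_av(octa, random_ava_map(5, 5)), "geometry mismatch")
})

test_that("area features follow the pixel-count definitions", {
  # hand-counted: 63 arterial kept, 27 venous kept, 10 excluded
  lab <- matrix(0L, 10, 10)
  lab[1:70] <- 1L                      # 70 arterial, 30 venous
  keep <- matrix(TRUE, 10, 10)
  keep[1:7] <- FALSE                   # drops 7 arterial
  keep[98:100] <- FALSE                # drops 3 venous
  af <- area_features(ava_map(lab), exclusion_mask(keep))
  expect_equal(af$A_A, 63); expect_equal(af$A_V, 27)
  expect_equal(af$AA, 70)
  expect_equal(af$VA, 30)
  expect_equal(af$AVAR, 63 / 27)

  # equal split
  lab <- matrix(c(1L, 0L), 10, 10)
  af <- area_features(ava_map(lab))
  expect_equal(af$AA, 50); expect_equal(af$VA, 50); expect_equal(af$AVAR, 1)
})

test_that("arterial and venous percentages always sum to 100", {
  set.seed(21)
  for (rep in 1:25) {
    ava <- random_ava_map(12, 12, p_art = stats::runif(1, 0.1, 0.9))
    keep <- matrix(stats::runif(144) > 0.2, 12, 12)
    af <- area_features(ava, exclusion_mask(keep))
    expect_equal(af$AA + af$VA, 100)
    expect_equal(af$AA, 100 - af$VA)
  }
})

test_that("degenerate denominators are flagged, not infinite", {
  ava <- ava_map(matrix(1L, 4, 4))    # no venous pixels
  af <- area_features(ava)
  expect_true(is.na(af$AVAR))
  expect_error(area_features(ava, exclusion_mask(matrix(FALSE, 4, 4))),
               "no kept pixels")
  octa <- random_octa(4, 4)
  expect_error(pid_features(make_octa_av(octa, ava), ava),
               "arterial and one kept venous")
})

test_that("perfusion intensity densities scale mean intensity to percent", {
  # uniform 255 -> all PIDs 100; uniform 51 -> all PIDs 20
  for (v in c(255L, 51L)) {
    px <- matrix(v, 8, 8)
    ava <- ava_map(matrix(c(1L, 0L), 8, 8))
    octa <- octa_image(px)
    pf <- pid_features(make_octa_av(octa, ava), ava)
    expect_equal(pf$T_PID, 100 * v / 255)
    expect_equal(pf$A_PID, 100 * v / 255)
    expect_equal(pf$V_PID, 100 * v / 255)
    expect_equal(pf$AV_PIDR, 1)
  }

  # 2x2 grid: arterial {100, 200}, venous {50, 150}
  px <- matrix(c(100L, 50L, 200L, 150L), 2, 2)
  ava <- ava_map(matrix(c(1L, 0L, 1L, 0L), 2, 2))
  pf <- pid_features(make_octa_av(octa_image(px), ava), ava)
  expect_equal(pf$A_PID, 100 / 255 * 150, tolerance = 1e-12)  # 58.8235
  expect_equal(pf$V_PID, 100 / 255 * 100, tolerance = 1e-12)  # 39.2157
  expect_equal(pf$T_PID, 100 / 255 * 125, tolerance = 1e-12)  # 49.0196
  expect_equal(pf$AV_PIDR, 1.5)
})

test_that("total PID is the area-weighted mixture of the class PIDs", {
  set.seed(22)
  for (rep in 1:25) {
    octa <- random_octa(14, 14)
    ava <- random_ava_map(14, 14)
    keep <- matrix(stats::runif(196) > 0.25, 14, 14)
    if (!any(ava$labels == 1L & keep) || !any(ava$labels == 0L & keep)) next
    mask <- exclusion_mask(keep)
    af <- area_features(ava, mask)
    pf <- pid_features(make_octa_av(octa, ava, mask), ava, mask)
    lhs <- af$A_T * pf$T_PID
    rhs <- af$A_A * pf$A_PID + af$A_V * pf$V_PID
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("features are invariant to quarter-turn rotations", {
  set.seed(23)
  octa <- random_octa(12, 12)
  ava <- random_ava_map(12, 12)
  rot <- function(m) t(m[nrow(m):1, ])
  f0 <- quantify_image(octa, ava, mask = NULL)
  m_octa <- octa$pixels; m_ava <- ava$labels
  for (turn in 1:3) {
    m_octa <- rot(m_octa); m_ava <- rot(m_ava)
    f <- quantify_image(octa_image(m_octa, id = "t"), ava_map(m_ava),
                        mask = NULL)
    expect_equal(unlist(f[-1]), unlist(f0[-1]), tolerance = 1e-12)
  }
})

test_that("an all-true mask reproduces unmasked values", {
  set.seed(24)
  octa <- random_octa(10, 10)
  ava <- random_ava_map(10, 10)
  f_null <- quantify_image(octa, ava, mask = NULL)
  f_true <- quantify_image(octa, ava,
                           mask = exclusion_mask(matrix(TRUE, 10, 10)))
  expect_equal(f_null, f_true)
})

test_that("batch quantification preserves order and survives failures", {
  set.seed(25)
  items <- lapply(1:4, function(i)
    list(octa = random_octa(20, 20, id = paste0("img", i)),
         ava = random_ava_map(20, 20)))
  # an item whose mask keeps nothing arterial fails but the batch continues
  items[[3]]$ava <- ava_map(matrix(0L, 20, 20))
  tab <- quantify_batch(items, mask = NULL)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$id, paste0("img", 1:4))
  expect_true(is.na(tab$A_PID[3]))
  expect_length(attr(tab, "errors"), 1)

  # single item equals the single-image path
  one <- quantify_batch(items[1], mask = NULL)
  expect_equal(one[1, ], quantify_image(items[[1]]$octa, items[[1]]$ava,
                                        mask = NULL), ignore_attr = TRUE)
})

test_that("feature tables round-trip through CSV at written precision", {
  set.seed(26)
  items <- lapply(1:3, function(i)
    list(octa = random_octa(20, 20, id = paste0("e", i)),
         ava = random_ava_map(20, 20)))
  tab <- quantify_batch(items, mask = NULL)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(tab, path)
  expect_equal(readLines(path, n = 1),
               "id,AA,VA,AVAR,T_PID,A_PID,V_PID,AV_PIDR")
  back <- read_feature_csv(path)
  for (col in names(tab)[-1])
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-4)
})
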