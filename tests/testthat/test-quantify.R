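test_that("mask area scales with the pixel footprint", {
  m <- matrix(0L, 20, 20); m[1:10, 1:10] <- 1L
  expect_equal(mask_area(m, c(2, 2)), 400)
  expect_equal(mask_area(matrix(0L, 5, 5), c(2, 2)), 0)
  expect_equal(mask_area(m, c(2.083, 2.083)), 433.9, tolerance = 0.05 / 433.9)
  expect_equal(mask_area(m, c(1, 2)), 200)   # anisotropic pixels
})

test_that("Simpson volumes sum areas times effective spacing", {
  expect_equal(simpson_volume(c(1000, 1200, 800), 6), 18)
  expect_equal(simpson_volume(c(1000, 1200, 800), 6, gap_fraction = 0.2), 21.6)
  expect_equal(simpson_volume(numeric(0), 6), 0)
  expect_error(simpson_volume(c(100, -1), 6), class = "cardioseg_range_error")
})

test_that("Simpson volumes are additive and gap handling is multiplicative", {
  set.seed(51)
  a <- runif(5, 0, 2000); b <- runif(7, 0, 2000)
  expect_equal(simpson_volume(c(a, b), 6), simpson_volume(a, 6) + simpson_volume(b, 6))
  expect_equal(simpson_volume(a, 6, 0.2), 1.2 * simpson_volume(a, 6, 0))
})

test_that("ejection fraction follows (EDV - ESV) * 100 / EDV", {
  expect_identical(ejection_fraction(150, 75), 50)
  expect_identical(ejection_fraction(123.4, 123.4), 0)
  expect_error(ejection_fraction(0, 10), class = "cardioseg_range_error")
  expect_warning(ef <- ejection_fraction(100, 120), "exceeds")
  expect_equal(ef, -20)
})

test_that("doubling all areas doubles volumes and preserves EF", {
  a_ed <- c(1000, 1200, 800); a_es <- c(500, 700, 300)
  v1 <- simpson_volume(a_ed, 6); v2 <- simpson_volume(2 * a_ed, 6)
  expect_equal(v2, 2 * v1)
  expect_equal(ejection_fraction(simpson_volume(2 * a_ed, 6), simpson_volume(2 * a_es, 6)),
               ejection_fraction(v1, simpson_volume(a_es, 6)))
})

test_that("BSA indexing divides by the body surface area", {
  expect_equal(index_to_bsa(296, 2), 148)
  expect_equal(index_to_bsa(77.7, 1), 77.7)
  expect_error(index_to_bsa(100, 0), class = "cardioseg_range_error")
})

test_that("identical ED and ES masks give zero ejection fraction", {
  ph <- generate_phantom(small_config())
  masks <- list()
  for (s in 0:4) {
    m <- ph$truth$lv$masks[[s + 1]][[1]]
    masks[[frame_key(s, 0)]] <- m
    masks[[frame_key(s, 4)]] <- m
  }
  seg <- fake_segmentation(masks, 0, 4, c(0, 4))
  vf <- quantify_study(seg, ph$study)
  expect_equal(vf$ef_percent, 0)
})

test_that("a basal mismatch of more than one slice is rejected", {
  ph <- generate_phantom(small_config())
  masks <- list()
  for (s in 0:4) masks[[frame_key(s, 0)]] <- ph$truth$lv$masks[[s + 1]][[1]]
  for (s in 2:4) masks[[frame_key(s, 4)]] <- ph$truth$lv$masks[[s + 1]][[5]]
  seg <- fake_segmentation(masks, 0, 4, c(0, 4))
  expect_error(quantify_study(seg, ph$study), class = "cardioseg_quantify_error")
  # a one-slice offset is tolerated by default but not with the strict flag
  masks[[frame_key(1, 4)]] <- ph$truth$lv$masks[[2]][[5]]
  seg <- fake_segmentation(masks, 0, 4, c(0, 4))
  expect_s3_class(quantify_study(seg, ph$study), "ventricle_function")
  expect_error(quantify_study(seg, ph$study, allow_basal_offset = FALSE),
               class = "cardioseg_quantify_error")
})

test_that("quantifying ground-truth masks reproduces the truth volumes exactly", {
  ph <- generate_phantom(small_config())
  masks <- list()
  for (s in 0:4) {
    masks[[frame_key(s, 0)]] <- ph$truth$lv$masks[[s + 1]][[1]]
    masks[[frame_key(s, 4)]] <- ph$truth$lv$masks[[s + 1]][[5]]
  }
  seg <- fake_segmentation(masks, 0, 4, c(0, 4))
  vf <- quantify_study(seg, ph$study)
  expect_equal(vf$edv_ml, ph$truth$lv$edv_ml)
  expect_equal(vf$esv_ml, ph$truth$lv$esv_ml)
  expect_equal(vf$ef_percent, ph$truth$lv$ef_percent)
  vfb <- quantify_study(seg, ph$study, bsa_m2 = 2)
  expect_equal(vfb$edv_index_ml_m2, vf$edv_ml / 2)
})
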