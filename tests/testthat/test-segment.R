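test_that("a noiseless phantom frame is recovered from one click", {
  ph <- generate_phantom(small_config())
  img <- ph$study$frames[[3]][[1]]
  res <- segment_frame(img, seed_point(48, 70, 2, 0))
  expect_gte(mask_dice(res$mask, ph$truth$lv$masks[[3]][[1]]), 0.98)
  expect_true(res$threshold_gray > 80 && res$threshold_gray < 200)
  expect_equal(polygon_area(res$contour), sum(res$mask))
})

test_that("segmentation is a pure function of its inputs", {
  ph <- generate_phantom(small_config(noise_sd = 10))
  img <- ph$study$frames[[3]][[1]]
  r1 <- segment_frame(img, seed_point(48, 70, 2, 0))
  r2 <- segment_frame(img, seed_point(48, 70, 2, 0))
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$contour$vertices, r2$contour$vertices)
  s1 <- segment_study(ph$study, seed_point(48, 70, 2, 0), ed_phase = 0, es_phase = 4)
  s2 <- segment_study(ph$study, seed_point(48, 70, 2, 0), ed_phase = 0, es_phase = 4)
  expect_identical(lapply(s1$results, `[[`, "mask"),
                   lapply(s2$results, `[[`, "mask"))
})

test_that("a background click is rejected with the seed coordinates", {
  ph <- generate_phantom(small_config())
  img <- ph$study$frames[[3]][[1]]
  err <- expect_error(segment_frame(img, seed_point(5, 5, 2, 0)),
                      class = "cardioseg_seed_error")
  expect_match(conditionMessage(err), "row=5, col=5")
})

test_that("restricting the slice range yields exactly the ED and ES frames", {
  ph <- generate_phantom(small_config())
  seg <- segment_study(ph$study, seed_point(48, 70, 2, 0),
                       slice_range = c(2L, 2L), ed_phase = 0, es_phase = 4)
  expect_setequal(names(seg$results), c("s002_p000", "s002_p004"))
})

test_that("an apical slice with no end-systolic cavity is recorded, not fatal", {
  ph <- generate_phantom(small_config(es_apex_dropout = 1L))
  expect_equal(ph$truth$lv$areas_px[5, 5], 0)        # slice 4 empty at ES
  expect_gt(ph$truth$lv$areas_px[5, 1], 0)           # but present at ED
  seg <- segment_study(ph$study, seed_point(48, 70, 2, 0),
                       ed_phase = 0, es_phase = 4)
  expect_true("s004_p004" %in% names(seg$failed))
  expect_false("s004_p004" %in% names(seg$results))
  expect_true("s004_p000" %in% names(seg$results))
})

test_that("a larger true cavity yields a strictly larger segmented mask", {
  px <- sapply(c(12, 15, 17), function(r) {
    ph <- generate_phantom(small_config(lv_radius_ed_px = r,
                                        lv_radius_es_px = r - 6))
    res <- segment_frame(ph$study$frames[[1]][[1]], seed_point(48, 70, 0, 0))
    sum(res$mask)
  })
  expect_true(all(diff(px) > 0))
})

test_that("automatic phase selection finds end-diastole and end-systole", {
  ph <- generate_phantom(small_config())
  sel <- select_phases(ph$study, seed_point(48, 70, 2, 0))
  expect_equal(sel$ed_phase, 0L)
  expect_equal(sel$es_phase, 4L)
  expect_equal(which.max(sel$areas_px) - 1L, 0L)
})

test_that("ED and ES phases must differ", {
  ph <- generate_phantom(small_config())
  expect_error(segment_study(ph$study, seed_point(48, 70, 2, 0),
                             ed_phase = 0, es_phase = 0),
               class = "cardioseg_config_error")
})
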