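test_that("the phantom is reproducible from its seed", {
  a <- generate_phantom(small_config(noise_sd = 10, rng_seed = 7))
  b <- generate_phantom(small_config(noise_sd = 10, rng_seed = 7))
  expect_identical(a$study$frames, b$study$frames)
  c <- generate_phantom(small_config(noise_sd = 10, rng_seed = 8))
  expect_false(identical(a$study$frames, c$study$frames))
  # generation must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_phantom(small_config(noise_sd = 5)))
  expect_identical(rnorm(1), before)
})

test_that("truth volumes are consistent with truth masks by construction", {
  ph <- generate_phantom(small_config())
  px_area <- prod(ph$truth$config$pixel_spacing_mm)
  edv <- simpson_volume(ph$truth$lv$areas_px[, 1] * px_area, 6)
  expect_identical(edv, ph$truth$lv$edv_ml)
  counts <- vapply(1:5, function(s) sum(ph$truth$lv$masks[[s]][[1]]), numeric(1))
  expect_equal(counts, ph$truth$lv$areas_px[, 1])
})

test_that("per-phase truth area peaks at ED and bottoms out near ES", {
  ph <- generate_phantom(small_config())
  for (v in c("lv", "rv")) {
    total <- colSums(ph$truth[[v]]$areas_px)
    expect_equal(which.max(total), 1L)                       # ED = phase 0
    expect_equal(which.min(total), ph$truth$es_phase + 1L)   # ES = mid-cycle
  }
})

test_that("uniform contraction yields the analytic ejection fraction", {
  ph <- generate_phantom(phantom_config(
    n_slices = 4L, n_phases = 8L, image_size = c(96L, 128L),
    lv_center = c(48L, 64L), lv_radius_ed_px = 20, lv_radius_es_px = 14,
    apical_taper = rep(1, 4), rv_enabled = FALSE, noise_sd = 0))
  # area ratio (14/20)^2 = 0.49 -> EF = 51%, up to rasterization
  expect_equal(ph$truth$lv$ef_percent, 51, tolerance = 1 / 51)
})

test_that("equal ED and ES areas give zero truth EF", {
  a <- matrix(400, 3, 5)
  px <- 4
  edv <- simpson_volume(a[, 1] * px, 6)
  expect_equal(ejection_fraction(edv, edv), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(phantom_config(lv_radius_es_px = 20, lv_radius_ed_px = 17),
               class = "cardioseg_config_error")
  expect_error(phantom_config(image_size = c(40L, 40L), lv_center = c(20L, 20L)),
               class = "cardioseg_config_error")   # cavity exceeds bounds
  expect_error(phantom_config(intensities = c(blood = 80, myocardium = 80,
                                              background = 30)),
               class = "cardioseg_config_error")
  expect_error(phantom_config(apical_taper = c(1, 0.5)),
               class = "cardioseg_config_error")   # wrong length
})

test_that("perturbations are reproducible and a zero-amplitude field is the identity", {
  ph <- generate_phantom(small_config())
  same <- perturb_study(ph$study, "bias_field", list(amplitude = 0))
  expect_identical(same$frames, ph$study$frames)
  shaded <- perturb_study(ph$study, "bias_field", list(amplitude = 0.3))
  expect_false(identical(shaded$frames, ph$study$frames))
  n1 <- perturb_study(ph$study, "extra_noise", list(sd = 5), rng_seed = 3)
  n2 <- perturb_study(ph$study, "extra_noise", list(sd = 5), rng_seed = 3)
  expect_identical(n1$frames, n2$frames)
})

test_that("segmentation quality degrades monotonically under gross noise", {
  ph <- generate_phantom(small_config())
  truth <- ph$truth$lv$masks[[3]][[1]]
  dice_at <- function(sd) {
    st <- if (sd == 0) ph$study
          else perturb_study(ph$study, "extra_noise", list(sd = sd), rng_seed = 5)
    res <- tryCatch(segment_frame(st$frames[[3]][[1]], seed_point(48, 70, 2, 0)),
                    cardioseg_error = function(e) NULL)
    if (is.null(res)) 0 else mask_dice(res$mask, truth)
  }
  d <- c(dice_at(0), dice_at(40), dice_at(200))
  expect_true(d[1] >= d[2] && d[2] >= d[3])
  expect_gt(d[1], 0.98)
})
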