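# Small phantoms used across tests: 5 slices x 8 phases on a 96 x 128
# matrix keep unit tests fast while preserving the default anatomy.

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_slices = 5L, n_phases = 8L, image_size = c(96L, 128L),
         lv_center = c(48L, 70L),
         apical_taper = seq(1, 0.6, length.out = 5),
         noise_sd = 0),
    list(...))
  do.call(phantom_config, args)
}

# LV-only tiny study spanning the full 0..255 range (lossless disk round trip).
fullrange_config <- function(...) {
  args <- utils::modifyList(
    list(n_slices = 2L, n_phases = 3L, image_size = c(64L, 64L),
         lv_center = c(32L, 36L), rv_enabled = FALSE,
         apical_taper = c(1, 0.8), noise_sd = 0,
         intensities = c(blood = 255, myocardium = 80, background = 0),
         pixel_spacing_mm = c(2, 2)),
    list(...))
  do.call(phantom_config, args)
}

# Dice scores of a study segmentation against per-frame truth masks.
study_dice <- function(seg, truth_masks) {
  vapply(names(seg$results), function(k) {
    s <- as.integer(substr(k, 2, 4))
    p <- as.integer(substr(k, 7, 9))
    mask_dice(seg$results[[k]]$mask, truth_masks[[s + 1]][[p + 1]])
  }, numeric(1))
}

# Minimal study_segmentation wrapping externally supplied masks (used to
# quantify ground-truth masks or hand-built scenarios).
fake_segmentation <- function(masks_by_key, ed_phase, es_phase, slice_range) {
  structure(list(
    results = lapply(masks_by_key, function(m)
      structure(list(mask = m), class = "segmentation_result")),
    failed = list(), ed_phase = as.integer(ed_phase),
    es_phase = as.integer(es_phase),
    slice_range = as.integer(slice_range)
  ), class = "study_segmentation")
}

frame_key <- function(s, p) sprintf("s%03d_p%03d", s, p)
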