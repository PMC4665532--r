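#' Cavity cross-sectional area of a mask
#'
#' @param mask integer 0/1 matrix.
#' @param pixel_spacing_mm numeric length-2 (row, col) spacing in mm;
#'   anisotropic spacing is respected.
#' @return area in mm^2 (object pixel count times pixel area).
#' @export
mask_area <- function(mask, pixel_spacing_mm) {
  check_mask(mask)
  if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0))
    cardioseg_error("pixel_spacing_mm must be two positive numbers",
                    class = "cardioseg_config_error")
  sum(mask == 1L) * pixel_spacing_mm[1] * pixel_spacing_mm[2]
}

#' Simpson's-method volume from per-slice areas
#'
#' Sums the endocardial cross-sectional areas over all slices and multiplies
#' by the effective inter-slice spacing, `thickness * (1 + gap_fraction)`.
#' The inter-slice gap (typically 20% of slice thickness) is not recorded in
#' image headers and defaults to 0.
#'
#' @param areas_mm2 numeric vector of per-slice areas in mm^2.
#' @param slice_thickness_mm slice thickness in mm.
#' @param gap_fraction inter-slice gap as a fraction of thickness, in [0, 1).
#' @return volume in mL.
#' @export
simpson_volume <- function(areas_mm2, slice_thickness_mm, gap_fraction = 0) {
  if (length(areas_mm2) && any(areas_mm2 < 0))
    cardioseg_error("areas must be non-negative", class = "cardioseg_range_error")
  if (slice_thickness_mm <= 0)
    cardioseg_error("slice thickness must be positive", class = "cardioseg_config_error")
  if (gap_fraction < 0 || gap_fraction >= 1)
    cardioseg_error("gap_fraction must be in [0, 1)", class = "cardioseg_config_error")
  spacing <- slice_thickness_mm * (1 + gap_fraction)
  sum(areas_mm2) * spacing / 1000
}

#' Ejection fraction
#'
#' `EF = (EDV - ESV) * 100 / EDV`, in percent.  If `esv_ml > edv_ml` the
#' negative EF is returned as computed, with a warning.
#'
#' @param edv_ml end-diastolic volume, mL (must be > 0).
#' @param esv_ml end-systolic volume, mL (>= 0).
#' @return ejection fraction in percent.
#' @export
ejection_fraction <- function(edv_ml, esv_ml) {
  if (edv_ml <= 0)
    cardioseg_error("EDV must be positive to compute an ejection fraction",
                    class = "cardioseg_range_error")
  if (esv_ml < 0)
    cardioseg_error("ESV must be non-negative", class = "cardioseg_range_error")
  if (esv_ml > edv_ml)
    warning("ESV exceeds EDV; reporting the negative ejection fraction as computed")
  (edv_ml - esv_ml) * 100 / edv_ml
}

#' Body-surface-area indexed volume
#'
#' @param volume_ml volume in mL.
#' @param bsa_m2 body surface area in m^2 (must be > 0).
#' @return indexed volume in mL/m^2.
#' @export
index_to_bsa <- function(volume_ml, bsa_m2) {
  if (bsa_m2 <= 0)
    cardioseg_error("BSA must be positive", class = "cardioseg_range_error")
  volume_ml / bsa_m2
}

#' Ventricular function from a study segmentation
#'
#' Converts the per-frame masks of a [segment_study()] result into per-slice
#' areas at end-diastole and end-systole, Simpson's-method EDV and ESV,
#' ejection fraction, and (when `bsa_m2` is given) BSA-indexed volumes.
#' Slices whose segmentation failed contribute no area, mirroring the
#' clinical practice of contouring only slices that show intracavitary
#' blood pool.  The most basal contoured slice may differ between ED and ES
#' by at most one position (through-plane motion); with
#' `allow_basal_offset = FALSE` the basal slices must match exactly.
#'
#' @param segmentation a `study_segmentation` from [segment_study()].
#' @param study the [cine_study()] that was segmented.
#' @param gap_fraction inter-slice gap override; defaults to the study's.
#' @param bsa_m2 optional body surface area in m^2 for indexed volumes.
#' @param allow_basal_offset logical (default TRUE).
#' @return a `ventricle_function`: list with `areas_ed`, `areas_es` (mm^2,
#'   base to apex over the segmented slice range), `edv_ml`, `esv_ml`,
#'   `ef_percent`, `edv_index_ml_m2`, `esv_index_ml_m2` (NA without BSA),
#'   `slice_spacing_mm`.
#' @export
quantify_study <- function(segmentation, study, gap_fraction = study$gap_fraction,
                           bsa_m2 = NULL, allow_basal_offset = TRUE) {
  stopifnot(inherits(segmentation, "study_segmentation"),
            inherits(study, "cine_study"))
  slices <- segmentation$slice_range[1]:segmentation$slice_range[2]
  phase_areas <- function(phase) {
    vapply(slices, function(s) {
      res <- segmentation$results[[frame_key(s, phase)]]
      if (is.null(res)) 0 else mask_area(res$mask, study$pixel_spacing_mm)
    }, numeric(1))
  }
  areas_ed <- phase_areas(segmentation$ed_phase)
  areas_es <- phase_areas(segmentation$es_phase)
  if (all(areas_ed == 0) || all(areas_es == 0))
    cardioseg_error("no segmented ED or ES frames to quantify",
                    class = "cardioseg_quantify_error")

  basal_ed <- slices[which(areas_ed > 0)[1]]
  basal_es <- slices[which(areas_es > 0)[1]]
  max_off <- if (allow_basal_offset) 1L else 0L
  if (abs(basal_ed - basal_es) > max_off)
    cardioseg_error(
      sprintf("most basal contoured slice differs between ED (%d) and ES (%d) by more than %d",
              basal_ed, basal_es, max_off),
      class = "cardioseg_quantify_error")

  spacing <- study$slice_thickness_mm * (1 + gap_fraction)
  edv <- simpson_volume(areas_ed, study$slice_thickness_mm, gap_fraction)
  esv <- simpson_volume(areas_es, study$slice_thickness_mm, gap_fraction)
  structure(list(
    areas_ed = areas_ed, areas_es = areas_es,
    edv_ml = edv, esv_ml = esv,
    ef_percent = ejection_fraction(edv, esv),
    edv_index_ml_m2 = if (is.null(bsa_m2)) NA_real_ else index_to_bsa(edv, bsa_m2),
    esv_index_ml_m2 = if (is.null(bsa_m2)) NA_real_ else index_to_bsa(esv, bsa_m2),
    slice_spacing_mm = spacing
  ), class = "ventricle_function")
}

#' @export
print.ventricle_function <- function(x, ...) {
  cat(sprintf("ventricle_function (slice spacing %.2f mm):\n", x$slice_spacing_mm))
  cat(sprintf("  EDV %.1f mL   ESV %.1f mL   EF %.1f%%\n",
              x$edv_ml, x$esv_ml, x$ef_percent))
  if (!is.na(x$edv_index_ml_m2))
    cat(sprintf("  EDV index %.1f mL/m^2   ESV index %.1f mL/m^2\n",
                x$edv_index_ml_m2, x$esv_index_ml_m2))
  invisible(x)
}
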