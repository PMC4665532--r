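#' Segment one cine frame from a single seed point
#'
#' Runs the full five-step pipeline on a frame:
#'
#' 1. *Edge detection* -- gradient magnitude of the gray-scale image
#'    ([detect_edges()]).
#' 2. *Iterative thresholding of the edge image* -- the kernel around the
#'    seed yields threshold `k_e`; pixels with magnitude at most `k_e`
#'    (flat, non-edge regions) become the object of binary image 1, so edge
#'    ridges are background barriers.
#' 3. *Iterative thresholding of the gray-scale image* -- threshold `k_g`
#'    from the same kernel; bright pixels (`>= k_g`, the blood pool) are the
#'    object of binary image 2.
#' 4. *Background overlap* -- OR of the two backgrounds
#'    ([overlap_backgrounds()]): the blood pool fenced by edge barriers.
#' 5. *Region growing* from the kernel's object pixels
#'    ([region_grow()]), then hole filling ([fill_holes()]) so papillary
#'    muscles and trabeculae count as cavity.
#'
#' Because a 3x3 gradient operator responds on both sides of an intensity
#' step, the barrier of step 2 includes the ridge pixels on the *cavity*
#' side of the endocardial border.  The gradient ridge straddles the true
#' border, so with `boundary_reclaim = TRUE` (default) ridge pixels at blood
#' intensity (object in binary image 2, background in binary image 1) that
#' are 8-adjacent to the grown region are reassigned to the cavity, in at
#' most `reclaim_passes` sweeps.  Sealed leak channels remain sealed: the
#' reclaim only enters edge-classified pixels and never grows past them.
#'
#' The pipeline is fully deterministic: identical inputs give bit-identical
#' outputs.
#'
#' @param img integer matrix 0--255.
#' @param seed [seed_point()] inside the blood pool.
#' @param spec [kernel_spec()].
#' @param edge_operator `"sobel"` (default) or `"prewitt"`.
#' @param edge_kernel_source image from which the kernel statistics for
#'   binary image 1 are drawn: `"edge"` (default) or `"gray"`.
#' @param gray_polarity polarity of binary image 2 (default `"object_above"`,
#'   matching bright-blood cine contrast).
#' @param boundary_reclaim logical; re-include blood-intensity gradient-ridge
#'   pixels adjacent to the grown region (default TRUE).
#' @param reclaim_passes maximum reclaim sweeps (default 2).
#' @return a `segmentation_result`: list with `mask`, `contour`,
#'   `threshold_edge`, `threshold_gray`, `seed_used`.
#' @export
segment_frame <- function(img, seed, spec = kernel_spec(),
                          edge_operator = c("sobel", "prewitt"),
                          edge_kernel_source = c("edge", "gray"),
                          gray_polarity = c("object_above", "object_below"),
                          boundary_reclaim = TRUE, reclaim_passes = 2L) {
  check_gray_image(img)
  edge_operator <- match.arg(edge_operator)
  edge_kernel_source <- match.arg(edge_kernel_source)
  gray_polarity <- match.arg(gray_polarity)

  edge <- detect_edges(img, edge_operator)
  k_e <- isodata_threshold(if (edge_kernel_source == "edge") edge else img, seed, spec)
  bin1 <- binarize(edge, k_e, "object_below")
  k_g <- isodata_threshold(img, seed, spec)
  bin2 <- binarize(img, k_g, gray_polarity)
  bin3 <- overlap_backgrounds(bin1, bin2)
  grown <- region_grow(bin3, seed, spec)
  # region_grow returns every component reachable from the kernel window;
  # the ventricular mask is the one holding (or nearest to) the click
  mask <- fill_holes(seed_component(grown, seed))

  if (isTRUE(boundary_reclaim)) {
    nr <- nrow(mask); nc <- ncol(mask)
    reclaimable <- bin2 == 1L & bin1 == 0L          # blood-bright edge ridge
    for (pass in seq_len(reclaim_passes)) {
      m <- matrix(FALSE, nr + 2L, nc + 2L)
      m[2:(nr + 1L), 2:(nc + 1L)] <- mask == 1L
      nb <- m[1:nr, 2:(nc + 1L)] | m[3:(nr + 2L), 2:(nc + 1L)] |
            m[2:(nr + 1L), 1:nc] | m[2:(nr + 1L), 3:(nc + 2L)] |
            m[1:nr, 1:nc] | m[1:nr, 3:(nc + 2L)] |
            m[3:(nr + 2L), 1:nc] | m[3:(nr + 2L), 3:(nc + 2L)]
      add <- reclaimable & nb & mask == 0L
      if (!any(add)) break
      mask[add] <- 1L
    }
    mask <- fill_holes(mask)
  }

  # A ventricular blood pool is interior to the thorax; a region that runs
  # into the image border is the flooded background of a misplaced click.
  if (any(mask[1L, ] == 1L) || any(mask[nrow(mask), ] == 1L) ||
      any(mask[, 1L] == 1L) || any(mask[, ncol(mask)] == 1L))
    cardioseg_error(
      sprintf(paste0("segmented region reaches the image border; seed ",
                     "(row=%d, col=%d) does not appear to lie on a ",
                     "ventricular blood pool"), seed$row, seed$col),
      class = "cardioseg_seed_error")

  contour <- extract_contour(mask, seed$slice_index, seed$phase_index)
  structure(list(mask = mask, contour = contour,
                 threshold_edge = k_e, threshold_gray = k_g,
                 seed_used = seed),
            class = "segmentation_result")
}

frame_key <- function(slice_index, phase_index) {
  sprintf("s%03d_p%03d", slice_index, phase_index)
}

#' Segment a cine study from one click
#'
#' Segments the seeded end-diastolic frame first, then propagates outward:
#' each neighbouring slice (toward base and toward apex, within
#' `slice_range`) is seeded with the rounded centroid of the nearest
#' already-segmented mask of the same phase, and the end-systolic frame of
#' every slice is seeded with the centroid of that slice's end-diastolic
#' mask.  Frames whose segmentation fails (e.g. no blood pool under the
#' kernel at an apical end-systolic slice) are recorded as missing with the
#' error message; only failure on the initial seed frame is fatal.
#'
#' @param study [cine_study()].
#' @param seed [seed_point()] in a midventricular end-diastolic frame; its
#'   `slice_index`/`phase_index` locate the starting frame.
#' @param spec [kernel_spec()].
#' @param edge_operator passed to [segment_frame()].
#' @param slice_range 0-based inclusive `(first, last)` slice indices to
#'   segment (default: all slices).
#' @param ed_phase,es_phase 0-based phase indices of end-diastole and
#'   end-systole; `ed_phase` defaults to the seed's phase.
#' @param ... further options passed to [segment_frame()].
#' @return a `study_segmentation`: list with `results` (named list of
#'   `segmentation_result`, keys `s<slice>_p<phase>`), `failed` (named list
#'   of error messages), `ed_phase`, `es_phase`, `slice_range`.
#' @export
segment_study <- function(study, seed, spec = kernel_spec(),
                          edge_operator = "sobel",
                          slice_range = c(0L, study$n_slices - 1L),
                          ed_phase = seed$phase_index, es_phase, ...) {
  stopifnot(inherits(study, "cine_study"))
  slice_range <- as.integer(slice_range)
  if (length(slice_range) != 2L || slice_range[1] < 0L ||
      slice_range[2] >= study$n_slices || slice_range[1] > slice_range[2])
    cardioseg_error("invalid slice_range", class = "cardioseg_config_error")
  if (seed$slice_index < slice_range[1] || seed$slice_index > slice_range[2])
    cardioseg_error("seed slice outside slice_range", class = "cardioseg_config_error")
  ed_phase <- as.integer(ed_phase); es_phase <- as.integer(es_phase)
  if (ed_phase == es_phase)
    cardioseg_error("ed_phase and es_phase must differ", class = "cardioseg_config_error")

  results <- list()
  failed <- list()
  seg_one <- function(slice, phase, row, col) {
    sp <- seed_point(row, col, slice, phase)
    segment_frame(get_frame(study, slice, phase), sp, spec,
                  edge_operator = edge_operator, ...)
  }

  # Seed frame (fatal on failure).
  first <- seg_one(seed$slice_index, ed_phase, seed$row, seed$col)
  results[[frame_key(seed$slice_index, ed_phase)]] <- first

  # Outward along slices at ED, chaining centroids.
  for (dir in c(-1L, 1L)) {
    prev <- first
    s <- seed$slice_index + dir
    while (!is.null(prev) && s >= slice_range[1] && s <= slice_range[2]) {
      ctr <- mask_centroid(prev$mask)
      res <- tryCatch(seg_one(s, ed_phase, ctr["row"], ctr["col"]),
                      cardioseg_error = function(e) e)
      if (inherits(res, "error")) {
        failed[[frame_key(s, ed_phase)]] <- conditionMessage(res)
        prev <- NULL            # chain broken: no centroid to continue from
      } else {
        results[[frame_key(s, ed_phase)]] <- res
        prev <- res
      }
      s <- s + dir
    }
  }

  # ES frame of every slice, seeded from that slice's ED centroid.
  for (key in names(results)) {
    res <- results[[key]]
    s <- res$seed_used$slice_index
    ctr <- mask_centroid(res$mask)
    es <- tryCatch(seg_one(s, es_phase, ctr["row"], ctr["col"]),
                   cardioseg_error = function(e) e)
    if (inherits(es, "error")) {
      failed[[frame_key(s, es_phase)]] <- conditionMessage(es)
    } else {
      results[[frame_key(s, es_phase)]] <- es
    }
  }

  structure(list(results = results, failed = failed,
                 ed_phase = ed_phase, es_phase = es_phase,
                 slice_range = slice_range),
            class = "study_segmentation")
}

#' Automatic end-diastole / end-systole phase selection
#'
#' Segments the seed slice at every cardiac phase (chaining seed centroids
#' from phase to phase) and returns the phases of maximal and minimal
#' cross-sectional cavity area, the computable counterpart of picking the
#' visually largest and smallest midventricular cavity.
#'
#' @inheritParams segment_study
#' @return list with `ed_phase`, `es_phase`, and `areas_px` (per-phase
#'   object pixel counts, `NA` where segmentation failed).
#' @export
select_phases <- function(study, seed, spec = kernel_spec(),
                          edge_operator = "sobel", ...) {
  stopifnot(inherits(study, "cine_study"))
  areas <- rep(NA_real_, study$n_phases)
  row <- seed$row; col <- seed$col
  for (p in seq_len(study$n_phases) - 1L) {
    sp <- seed_point(row, col, seed$slice_index, p)
    res <- tryCatch(
      segment_frame(get_frame(study, seed$slice_index, p), sp, spec,
                    edge_operator = edge_operator, ...),
      cardioseg_error = function(e) NULL)
    if (!is.null(res)) {
      areas[p + 1L] <- sum(res$mask)
      ctr <- mask_centroid(res$mask)
      row <- ctr["row"]; col <- ctr["col"]
    }
  }
  if (all(is.na(areas)))
    cardioseg_error(
      sprintf("segmentation from seed (row=%d, col=%d) failed at every phase of slice %d",
              seed$row, seed$col, seed$slice_index),
      class = "cardioseg_seed_error")
  list(ed_phase = which.max(areas) - 1L,
       es_phase = which.min(areas) - 1L,
       areas_px = areas)
}
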