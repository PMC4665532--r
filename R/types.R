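#' Seed point
#'
#' A single user click identifying the ventricular blood pool, given as
#' 0-based pixel indices (row increases downward) plus the grid position of
#' the frame it refers to.
#'
#' @param row,col 0-based pixel indices.
#' @param slice_index,phase_index 0-based grid indices of the frame.
#' @return an object of class `seed_point`.
#' @export
seed_point <- function(row, col, slice_index = 0L, phase_index = 0L) {
  row <- as.integer(row); col <- as.integer(col)
  slice_index <- as.integer(slice_index); phase_index <- as.integer(phase_index)
  if (anyNA(c(row, col, slice_index, phase_index)) || row < 0L || col < 0L ||
      slice_index < 0L || phase_index < 0L)
    cardioseg_error("seed indices must be non-negative integers",
                    class = "cardioseg_seed_error")
  structure(list(row = row, col = col,
                 slice_index = slice_index, phase_index = phase_index),
            class = "seed_point")
}

#' Kernel specification for iterative thresholding
#'
#' The square kernel centred on the seed click from which the isodata
#' threshold statistics are computed, together with the initial threshold and
#' an iteration cap.
#'
#' @param size odd kernel side length in pixels (default 9, the value used
#'   throughout the original study).
#' @param k0 initial threshold, integer in 0--255 (default 128); the converged
#'   threshold is insensitive to it for bimodal kernel samples.
#' @param max_iter iteration cap before a non-convergence error (default 100).
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(size = 9L, k0 = 128L, max_iter = 100L) {
  size <- as.integer(size); k0 <- as.integer(k0); max_iter <- as.integer(max_iter)
  if (is.na(size) || size < 3L || size %% 2L == 0L)
    cardioseg_error("kernel size must be an odd integer >= 3",
                    class = "cardioseg_config_error")
  if (is.na(k0) || k0 < 0L || k0 > 255L)
    cardioseg_error("k0 must be in 0..255", class = "cardioseg_config_error")
  if (is.na(max_iter) || max_iter < 1L)
    cardioseg_error("max_iter must be >= 1", class = "cardioseg_config_error")
  structure(list(size = size, k0 = k0, max_iter = max_iter),
            class = "kernel_spec")
}

#' Cine study container
#'
#' Assembles per-frame gray images into the slice-by-phase grid of a
#' short-axis cine study together with its geometry.  `frames` is a list of
#' `n_slices` elements (base to apex), each a list of `n_phases` integer
#' matrices sharing one dimension.
#'
#' @param frames nested list `frames[[slice]][[phase]]` of 0--255 matrices.
#' @param pixel_spacing_mm numeric length-2, (row, col) spacing in mm.
#' @param slice_thickness_mm slice thickness in mm.
#' @param gap_fraction inter-slice gap as a fraction of slice thickness
#'   (default 0; the acquisition's undocumented gap, typically 0.2, must be
#'   supplied by the user because it is absent from image headers).
#' @return an object of class `cine_study`.
#' @export
cine_study <- function(frames, pixel_spacing_mm, slice_thickness_mm,
                       gap_fraction = 0) {
  if (!length(frames) || !length(frames[[1]]))
    abort_dim("frames must be a non-empty slice x phase grid")
  n_slices <- length(frames)
  n_phases <- length(frames[[1]])
  d <- dim(frames[[1]][[1]])
  for (s in seq_len(n_slices)) {
    if (length(frames[[s]]) != n_phases)
      cardioseg_error(sprintf("slice %d has %d phases, expected %d",
                              s - 1L, length(frames[[s]]), n_phases),
                      class = "cardioseg_grid_error")
    for (p in seq_len(n_phases)) {
      f <- frames[[s]][[p]]
      if (is.null(f))
        cardioseg_error(sprintf("missing frame at slice %d, phase %d", s - 1L, p - 1L),
                        class = "cardioseg_grid_error")
      check_gray_image(f, sprintf("frame (%d,%d)", s - 1L, p - 1L))
      if (!all(dim(f) == d))
        abort_dim(sprintf("frame (%d,%d) dimensions differ from the first frame",
                          s - 1L, p - 1L))
    }
  }
  pixel_spacing_mm <- as.numeric(pixel_spacing_mm)
  if (length(pixel_spacing_mm) != 2L || any(pixel_spacing_mm <= 0))
    cardioseg_error("pixel_spacing_mm must be two positive numbers",
                    class = "cardioseg_config_error")
  if (slice_thickness_mm <= 0)
    cardioseg_error("slice_thickness_mm must be positive",
                    class = "cardioseg_config_error")
  if (gap_fraction < 0 || gap_fraction >= 1)
    cardioseg_error("gap_fraction must be in [0, 1)",
                    class = "cardioseg_config_error")
  structure(list(frames = frames,
                 pixel_spacing_mm = pixel_spacing_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 gap_fraction = gap_fraction,
                 n_slices = n_slices, n_phases = n_phases,
                 n_rows = d[1], n_cols = d[2]),
            class = "cine_study")
}

#' @export
print.cine_study <- function(x, ...) {
  cat(sprintf(paste0("cine_study: %d slices (base->apex) x %d phases, ",
                     "%d x %d px\n  pixel spacing %.3f x %.3f mm, slice ",
                     "thickness %.1f mm, gap fraction %.2f\n"),
              x$n_slices, x$n_phases, x$n_rows, x$n_cols,
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              x$slice_thickness_mm, x$gap_fraction))
  invisible(x)
}

# Frame accessor with 0-based grid indices.
get_frame <- function(study, slice_index, phase_index) {
  study$frames[[slice_index + 1L]][[phase_index + 1L]]
}

# Effective inter-slice spacing in mm (thickness plus gap).
slice_spacing_mm <- function(study) {
  study$slice_thickness_mm * (1 + study$gap_fraction)
}
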