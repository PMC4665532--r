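# Study, mask, contour and report I/O.
#
# The on-disk study format ("image_dir" dialect) is a directory of 8-bit
# gray PNG (or TIFF) frames, one per (slice, phase), plus a YAML sidecar
# `study.yaml` with the geometry and the filename pattern.  Masks are 8-bit
# single-channel PNGs (0 = background, 255 = object).

default_pattern <- "slice%03d_phase%03d.png"

read_frame_file <- function(path) {
  if (!file.exists(path))
    cardioseg_error(sprintf("missing frame file '%s' (incomplete grid)", path),
                    class = "cardioseg_grid_error")
  px <- tryCatch({
    if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
      if (!requireNamespace("tiff", quietly = TRUE))
        cardioseg_error("the 'tiff' package is required to read TIFF frames",
                        class = "cardioseg_io_error")
      tiff::readTIFF(path)
    } else {
      png::readPNG(path)
    }
  }, error = function(e)
    cardioseg_error(sprintf("cannot read '%s': %s", path, conditionMessage(e)),
                    class = "cardioseg_io_error"))
  if (length(dim(px)) == 3L) px <- px[, , 1L]   # drop colour channels
  px
}

#' Load a cine study from disk
#'
#' Reads a short-axis cine study from a directory of 2-D gray-scale frames
#' plus a YAML sidecar `study.yaml` declaring `n_slices`, `n_phases`,
#' `pixel_spacing_mm`, `slice_thickness_mm`, `gap_fraction` and the frame
#' filename `pattern` (a `sprintf` template taking slice then phase, both
#' 0-based).  Frames are organized base-to-apex by slice, then by phase, and
#' intensities are min--max normalized *per study* to 0--255 (rounding half
#' up), so one threshold is comparable across slices.  Loading is
#' deterministic: the same directory always yields the same grid.
#'
#' @param path study directory.
#' @param dialect `"image_dir"` (PNG/TIFF + sidecar).  `"dicom"` is not
#'   supported by this package and raises an error.
#' @return a [cine_study()].
#' @export
load_cine_series <- function(path, dialect = c("image_dir", "dicom")) {
  dialect <- match.arg(dialect)
  if (dialect == "dicom")
    cardioseg_error(paste0("the DICOM dialect is not supported; convert the ",
                           "series to an image directory with a YAML sidecar"),
                    class = "cardioseg_io_error")
  if (!dir.exists(path))
    cardioseg_error(sprintf("study directory '%s' does not exist", path),
                    class = "cardioseg_io_error")
  sidecar <- file.path(path, "study.yaml")
  if (!file.exists(sidecar))
    cardioseg_error(sprintf("missing sidecar '%s'", sidecar),
                    class = "cardioseg_io_error")
  meta <- yaml::read_yaml(sidecar)
  for (nm in c("n_slices", "n_phases", "pixel_spacing_mm", "slice_thickness_mm"))
    if (is.null(meta[[nm]]))
      cardioseg_error(sprintf("sidecar lacks required field '%s'", nm),
                      class = "cardioseg_io_error")
  pattern <- if (is.null(meta$pattern)) default_pattern else meta$pattern
  gapf <- if (is.null(meta$gap_fraction)) 0 else meta$gap_fraction

  n_slices <- as.integer(meta$n_slices)
  n_phases <- as.integer(meta$n_phases)
  frames <- vector("list", n_slices)
  d <- NULL
  for (s in seq_len(n_slices)) {
    frames[[s]] <- vector("list", n_phases)
    for (p in seq_len(n_phases)) {
      px <- read_frame_file(file.path(path, sprintf(pattern, s - 1L, p - 1L)))
      if (is.null(d)) d <- dim(px)
      if (!all(dim(px) == d))
        abort_dim(sprintf("frame (%d,%d) has dimensions %dx%d, expected %dx%d",
                          s - 1L, p - 1L, nrow(px), ncol(px), d[1], d[2]))
      frames[[s]][[p]] <- px * 255
    }
  }

  # Per-study min-max normalization to the integer range 0..255.
  rng <- range(unlist(lapply(frames, function(sl) lapply(sl, range))))
  for (s in seq_len(n_slices)) for (p in seq_len(n_phases)) {
    f <- frames[[s]][[p]]
    f <- if (rng[2] > rng[1])
      round_half_up((f - rng[1]) / (rng[2] - rng[1]) * 255)
    else matrix(0, d[1], d[2])
    storage.mode(f) <- "integer"
    frames[[s]][[p]] <- f
  }
  cine_study(frames, as.numeric(unlist(meta$pixel_spacing_mm)),
             meta$slice_thickness_mm, gapf)
}

#' Write a cine study (and optional ground truth) to disk
#'
#' Writes the image-directory dialect read back by [load_cine_series()]:
#' one 8-bit gray PNG per frame plus `study.yaml`.  When `truth` is given,
#' ground-truth masks go to `truth/` (one PNG per frame and ventricle) and
#' the truth volumes to `truth/truth.json`.
#'
#' @param study a [cine_study()].
#' @param path output directory (created if needed).
#' @param truth optional `phantom_truth` from [generate_phantom()].
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path, truth = NULL) {
  stopifnot(inherits(study, "cine_study"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_len(study$n_slices)) for (p in seq_len(study$n_phases)) {
    png::writePNG(study$frames[[s]][[p]] / 255,
                  file.path(path, sprintf(default_pattern, s - 1L, p - 1L)))
  }
  yaml::write_yaml(list(
    n_slices = study$n_slices, n_phases = study$n_phases,
    pixel_spacing_mm = study$pixel_spacing_mm,
    slice_thickness_mm = study$slice_thickness_mm,
    gap_fraction = study$gap_fraction,
    pattern = default_pattern
  ), file.path(path, "study.yaml"))

  if (!is.null(truth)) {
    tdir <- file.path(path, "truth")
    dir.create(tdir, showWarnings = FALSE)
    for (v in c("lv", "rv")) {
      if (is.null(truth[[v]])) next
      for (s in seq_len(study$n_slices)) for (p in seq_len(study$n_phases))
        write_mask(truth[[v]]$masks[[s]][[p]],
                   file.path(tdir, sprintf("%s_%s", v,
                                           sprintf(default_pattern, s - 1L, p - 1L))))
    }
    vol <- function(v) if (is.null(truth[[v]])) NULL else
      list(edv_ml = truth[[v]]$edv_ml, esv_ml = truth[[v]]$esv_ml,
           ef_percent = truth[[v]]$ef_percent)
    write_report_json(list(ed_phase = truth$ed_phase, es_phase = truth$es_phase,
                           lv = vol("lv"), rv = vol("rv")),
                      file.path(tdir, "truth.json"))
  }
  invisible(path)
}

#' Write / read a binary mask as an 8-bit PNG
#'
#' Lossless round trip: `read_mask(write_mask(m, f))` equals `m` pixelwise.
#' Object pixels are stored as 255, background as 0.
#'
#' @param mask integer 0/1 matrix.
#' @param path output file.
#' @return `write_mask` returns `path` invisibly; `read_mask` returns the
#'   0/1 integer matrix.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  ok <- tryCatch({ png::writePNG(mask * 1.0, path); TRUE },
                 error = function(e) FALSE)
  if (!ok)
    cardioseg_error(sprintf("cannot write mask to '%s'", path),
                    class = "cardioseg_io_error")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  px <- read_frame_file(path)
  out <- px >= 0.5
  mode(out) <- "integer"
  out
}

#' Write contour polygons to CSV
#'
#' One row per vertex with header
#' `slice_index,phase_index,vertex_index,row,col`, grouped by
#' `(slice_index, phase_index)` in ascending order.  An empty contour list
#' writes a header-only file.
#'
#' @param contours list of `contour_polygon`s (see [extract_contour()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(contours, path) {
  rows <- lapply(contours, function(ct) {
    data.frame(slice_index = ct$slice_index, phase_index = ct$phase_index,
               vertex_index = seq_len(nrow(ct$vertices)) - 1L,
               row = ct$vertices[, "row"], col = ct$vertices[, "col"])
  })
  df <- if (length(rows)) do.call(rbind, rows)
  else data.frame(slice_index = integer(), phase_index = integer(),
                  vertex_index = integer(), row = numeric(), col = numeric())
  df <- df[order(df$slice_index, df$phase_index), ]
  atomic_write(path, function(tmp)
    utils::write.table(df, tmp, sep = ",", row.names = FALSE, quote = FALSE))
}

#' Write a machine-readable JSON report
#'
#' Reports are written atomically (temp file + rename) with stable
#' formatting, so repeated runs on identical inputs are byte-identical.
#'
#' @param x a list (or classed list) to serialize.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  strip <- function(v) {
    if (is.list(v)) { v <- lapply(unclass(v), strip) }
    v
  }
  atomic_write(path, function(tmp)
    jsonlite::write_json(strip(x), tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null"))
}
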