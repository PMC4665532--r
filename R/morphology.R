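#' Overlap the backgrounds of two binary images
#'
#' Pixelwise OR of the two backgrounds; equivalently the object of the
#' result is the AND of the two objects.  Used to seal discontinuities in
#' the thresholded gray-scale image with the edge barriers of binary image 1.
#'
#' @param bin1,bin2 integer 0/1 matrices of equal dimensions.
#' @return integer 0/1 matrix ("binary image 3").
#' @export
overlap_backgrounds <- function(bin1, bin2) {
  check_mask(bin1, "bin1"); check_mask(bin2, "bin2")
  if (!all(dim(bin1) == dim(bin2)))
    abort_dim("binary images must share dimensions")
  out <- (bin1 == 1L) & (bin2 == 1L)
  mode(out) <- "integer"
  out
}

# Vectorized frontier flood fill over a logical membership matrix.
# `start` are linear indices (already members); 8- or 4-connectivity.
flood_fill <- function(member, start, connectivity = 8L) {
  nr <- nrow(member); nc <- ncol(member)
  dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
  dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  nnb <- if (connectivity == 8L) 8L else 4L
  visited <- matrix(FALSE, nr, nc)
  visited[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    r0 <- (frontier - 1L) %% nr + 1L
    c0 <- (frontier - 1L) %/% nr + 1L
    nxt <- integer(0)
    for (k in seq_len(nnb)) {
      rr <- r0 + dr[k]; cc <- c0 + dc[k]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      idx <- (cc[ok] - 1L) * nr + rr[ok]
      idx <- idx[member[idx] & !visited[idx]]
      if (length(idx)) {
        visited[idx] <- TRUE
        nxt <- c(nxt, idx)
      }
    }
    frontier <- nxt
  }
  visited
}

#' Seeded region growing
#'
#' All object pixels of `bin3` inside the square kernel window centred on
#' the seed are taken as initial seed points; the region then grows to every
#' object pixel reachable through 8-connected neighbours (breadth-first
#' flood fill).  The result is a subset of the object of `bin3` and is empty
#' only when the kernel window contains no object pixel, which raises a
#' seed-off-object error.
#'
#' @param bin3 integer 0/1 matrix (the background-overlapped binary image).
#' @param seed [seed_point()].
#' @param spec [kernel_spec()] (only `size` is used).
#' @return integer 0/1 matrix, one 8-connected component.
#' @export
region_grow <- function(bin3, seed, spec = kernel_spec()) {
  check_mask(bin3, "bin3")
  nr <- nrow(bin3); nc <- ncol(bin3)
  win <- kernel_window(nr, nc, seed, spec$size)
  obj <- bin3 == 1L
  inwin <- matrix(FALSE, nr, nc)
  inwin[win$rows, win$cols] <- TRUE
  start <- which(obj & inwin)
  if (!length(start)) abort_seed(seed$row, seed$col, seed$slice_index, seed$phase_index)
  grown <- flood_fill(obj, start, connectivity = 8L)
  mode(grown) <- "integer"
  grown
}

#' Fill enclosed background holes in a binary mask
#'
#' Background components not 4-connected to the image border become object;
#' border-connected background is untouched.  This re-includes papillary
#' muscles and trabeculae -- dark structures enclosed by the blood pool --
#' which by convention count as part of the ventricular cavity.
#'
#' @param mask integer 0/1 matrix.
#' @return integer 0/1 matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  check_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- mask == 0L
  border <- unique(c(which(bg[, 1L]),                      # first column
                     (nc - 1L) * nr + which(bg[, nc]),     # last column
                     (which(bg[1L, ]) - 1L) * nr + 1L,     # first row
                     (which(bg[nr, ]) - 1L) * nr + nr))    # last row
  if (!length(border)) return(matrix(1L, nr, nc))
  reach <- flood_fill(bg, border, connectivity = 4L)
  out <- !reach
  mode(out) <- "integer"
  out
}

# Number of 8-connected object components (internal; used by extract_contour).
count_components <- function(mask) {
  obj <- mask == 1L
  remaining <- which(obj)
  n <- 0L
  while (length(remaining)) {
    n <- n + 1L
    comp <- flood_fill(obj, remaining[1L], connectivity = 8L)
    remaining <- remaining[!comp[remaining]]
  }
  n
}

# Restrict a mask to the single 8-connected component containing the seed
# pixel (or, when the seed itself is background, the component of the object
# pixel nearest to the seed; ties broken by linear index for determinism).
seed_component <- function(mask, seed) {
  obj <- mask == 1L
  nr <- nrow(mask)
  sidx <- seed$col * nr + seed$row + 1L
  if (!obj[sidx]) {
    idx <- which(obj)
    r <- (idx - 1L) %% nr
    c <- (idx - 1L) %/% nr
    d2 <- (r - seed$row)^2 + (c - seed$col)^2
    sidx <- idx[which.min(d2)]
  }
  comp <- flood_fill(obj, sidx, connectivity = 8L)
  mode(comp) <- "integer"
  comp
}

# Mask centroid as a 0-based (row, col) pair, rounded half up.  For
# non-convex masks (the right ventricular crescent) the centroid can fall
# outside the object; it is then snapped to the nearest object pixel so
# chained seeds always lie on the structure they were derived from.
mask_centroid <- function(mask) {
  idx <- which(mask == 1L)
  if (!length(idx)) return(NULL)
  nr <- nrow(mask)
  r <- (idx - 1L) %% nr       # 0-based
  c <- (idx - 1L) %/% nr
  ctr <- c(round_half_up(mean(r)), round_half_up(mean(c)))
  if (!mask[ctr[2] * nr + ctr[1] + 1L]) {
    d2 <- (r - ctr[1])^2 + (c - ctr[2])^2
    ctr <- c(r[which.min(d2)], c[which.min(d2)])
  }
  c(row = as.integer(ctr[1]), col = as.integer(ctr[2]))
}
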