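#' Extract the boundary polygon of a single-component mask
#'
#' Traces the outer boundary of the object at the 0.5-level between object
#' and background: each object pixel `(r, c)` (0-based centre coordinates)
#' contributes its unit square `[r-0.5, r+0.5] x [c-0.5, c+0.5]`, and the
#' polygon is the boundary of their union.  Vertices are sub-pixel `(row,
#' col)` positions in traversal order; the shoelace area of the polygon
#' equals the object pixel count (after interior holes are closed).  At
#' pixels touching only diagonally the polygon passes through the shared
#' corner twice (a weakly simple pinch point).
#'
#' @param mask integer 0/1 matrix with exactly one 8-connected component.
#' @param slice_index,phase_index 0-based grid indices recorded on the polygon.
#' @return a `contour_polygon`: list with `vertices` (n x 2 matrix of row,
#'   col), `slice_index`, `phase_index`.
#' @export
extract_contour <- function(mask, slice_index = 0L, phase_index = 0L) {
  check_mask(mask)
  if (!any(mask == 1L))
    cardioseg_error("cannot extract a contour from an empty mask",
                    class = "cardioseg_contour_error")
  if (count_components(mask) != 1L)
    cardioseg_error("mask has more than one 8-connected object component",
                    class = "cardioseg_contour_error")

  filled <- fill_holes(mask)        # trace the outer boundary only
  nr <- nrow(filled); nc <- ncol(filled)
  obj <- filled == 1L
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- obj
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  bg_up    <- !pad[1:nr, 2:(nc + 1L)]       & core
  bg_down  <- !pad[3:(nr + 2L), 2:(nc + 1L)] & core
  bg_left  <- !pad[2:(nr + 1L), 1:nc]       & core
  bg_right <- !pad[2:(nr + 1L), 3:(nc + 2L)] & core

  # Directed boundary edges in doubled 0-based corner coordinates (odd
  # integers), oriented clockwise on screen so the object lies inside.
  edges_for <- function(sel, v_from, v_to) {
    idx <- which(sel)
    r <- (idx - 1L) %% nr       # 0-based pixel row
    c <- (idx - 1L) %/% nr
    list(from = cbind(2L * r + v_from[1L], 2L * c + v_from[2L]),
         to   = cbind(2L * r + v_to[1L],   2L * c + v_to[2L]))
  }
  e <- list(
    edges_for(bg_up,    c(-1L, -1L), c(-1L,  1L)),  # top edge, heading +col
    edges_for(bg_right, c(-1L,  1L), c( 1L,  1L)),  # right edge, heading +row
    edges_for(bg_down,  c( 1L,  1L), c( 1L, -1L)),  # bottom edge, heading -col
    edges_for(bg_left,  c( 1L, -1L), c(-1L, -1L))   # left edge, heading -row
  )
  from <- do.call(rbind, lapply(e, `[[`, "from"))
  to   <- do.call(rbind, lapply(e, `[[`, "to"))

  key <- function(v) (v[, 1L] + 1L) * (2L * (nc + 2L)) + v[, 2L] + 1L
  from_key <- key(from)
  out_by_vertex <- split(seq_along(from_key), from_key)

  used <- logical(length(from_key))
  start_edge <- order(from[, 1L], from[, 2L])[1L]
  verts <- matrix(NA_integer_, nrow = length(from_key) + 1L, ncol = 2L)
  nv <- 0L
  cur <- start_edge
  start_vertex <- from[start_edge, ]
  repeat {
    used[cur] <- TRUE
    nv <- nv + 1L
    verts[nv, ] <- from[cur, ]
    v <- to[cur, ]
    if (v[1L] == start_vertex[1L] && v[2L] == start_vertex[2L]) break
    cand <- out_by_vertex[[as.character((v[1L] + 1L) * (2L * (nc + 2L)) + v[2L] + 1L)]]
    cand <- cand[!used[cand]]
    if (!length(cand))
      cardioseg_error("contour tracing reached a dead end", # defensive; unreachable
                      class = "cardioseg_contour_error")
    if (length(cand) == 1L) {
      cur <- cand
    } else {
      # Pinch point (diagonal contact): prefer the sharpest left turn so the
      # traversal stays on the same outer loop.
      din <- to[cur, ] - from[cur, ]
      cross <- vapply(cand, function(i) {
        dout <- to[i, ] - from[i, ]
        din[1L] * dout[2L] - din[2L] * dout[1L]
      }, numeric(1))
      cur <- cand[which.max(cross)]
    }
  }
  verts <- verts[seq_len(nv), , drop = FALSE] / 2   # back to pixel units

  # Merge collinear runs (consecutive edges with the same direction).
  if (nrow(verts) > 2L) {
    d <- diff(rbind(verts, verts[1L, , drop = FALSE]))
    prev <- rbind(d[nrow(d), , drop = FALSE], d[-nrow(d), , drop = FALSE])
    keep <- !(d[, 1L] == prev[, 1L] & d[, 2L] == prev[, 2L])
    verts <- verts[keep, , drop = FALSE]
  }
  colnames(verts) <- c("row", "col")
  structure(list(vertices = verts,
                 slice_index = as.integer(slice_index),
                 phase_index = as.integer(phase_index)),
            class = "contour_polygon")
}

#' Shoelace area of a closed polygon
#'
#' @param vertices n x 2 matrix of (row, col) vertices in traversal order
#'   (closure implicit), or a `contour_polygon`.
#' @return enclosed area in squared pixel units.
#' @export
polygon_area <- function(vertices) {
  if (inherits(vertices, "contour_polygon")) vertices <- vertices$vertices
  x <- vertices[, 1L]; y <- vertices[, 2L]
  n <- length(x)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}
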