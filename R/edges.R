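#' Gradient-magnitude edge detection
#'
#' Computes the per-pixel gradient magnitude `sqrt(Gx^2 + Gy^2)` with a 3x3
#' Sobel or Prewitt operator (reflective border handling) and min--max
#' renormalizes the result to integers 0--255.  Edges -- discontinuities in
#' gray level such as the endocardial border -- appear as bright ridges; a
#' constant image maps to all zeros.
#'
#' @param img integer matrix, values 0--255.
#' @param operator `"sobel"` (default) or `"prewitt"`.
#' @return integer matrix 0--255 of edge magnitudes, same dimensions.
#' @export
detect_edges <- function(img, operator = c("sobel", "prewitt")) {
  check_gray_image(img)
  operator <- match.arg(operator)
  w <- if (operator == "sobel") 2 else 1
  nr <- nrow(img); nc <- ncol(img)

  # Reflective padding by one pixel (edge row/col mirrored).
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- img
  p[1L, ] <- p[2L, ]; p[nr + 2L, ] <- p[nr + 1L, ]
  p[, 1L] <- p[, 2L]; p[, nc + 2L] <- p[, nc + 1L]

  sub <- function(dr, dc) p[(1L + dr):(nr + dr), (1L + dc):(nc + dc)]
  # dr/dc offsets: 0 = up/left neighbour, 1 = centre, 2 = down/right.
  gx <- (sub(0, 2) + w * sub(1, 2) + sub(2, 2)) -
        (sub(0, 0) + w * sub(1, 0) + sub(2, 0))
  gy <- (sub(2, 0) + w * sub(2, 1) + sub(2, 2)) -
        (sub(0, 0) + w * sub(0, 1) + sub(0, 2))
  mag <- sqrt(gx^2 + gy^2)

  mx <- max(mag); mn <- min(mag)
  if (mx == mn) return(matrix(0L, nr, nc))
  out <- round_half_up((mag - mn) / (mx - mn) * 255)
  storage.mode(out) <- "integer"
  out
}
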