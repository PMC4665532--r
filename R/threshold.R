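#' Kernel-seeded iterative (isodata) threshold
#'
#' Computes the isodata threshold from the pixels of a square kernel centred
#' on the seed click (clipped at image borders).  Starting from `spec$k0`,
#' each iteration splits the kernel pixels into a class below the current
#' threshold (`value < k`) and a class at or above it (`value >= k`), and
#' updates
#'
#'   `k1 = round((mean_below + mean_above) / 2)`.
#'
#' If one class is empty the update degenerates to the rounded mean of all
#' kernel pixels (the limit of the formula as the classes merge) and the
#' iteration continues from there.  Iteration stops at the fixpoint
#' `k1 == k`; the result is deterministic, independent of pixel order, and
#' for well-separated bimodal samples independent of `k0`.
#'
#' @param img integer matrix 0--255 (gray-scale or edge-magnitude image).
#' @param seed [seed_point()] giving the kernel centre.
#' @param spec [kernel_spec()].
#' @return integer threshold in 0--255.
#' @export
isodata_threshold <- function(img, seed, spec = kernel_spec()) {
  check_gray_image(img)
  win <- kernel_window(nrow(img), ncol(img), seed, spec$size)
  px <- as.numeric(img[win$rows, win$cols])
  k <- as.numeric(spec$k0)
  prev <- NA_real_
  for (i in seq_len(spec$max_iter)) {
    below <- px[px < k]
    above <- px[px >= k]
    k1 <- if (!length(below) || !length(above)) round_half_up(mean(px))
          else round_half_up((mean(below) + mean(above)) / 2)
    if (k1 == k) return(as.integer(k))
    prev <- k
    k <- k1
  }
  cardioseg_error(
    sprintf("isodata threshold did not converge in %d iterations (last thresholds %d, %d)",
            spec$max_iter, as.integer(prev), as.integer(k)),
    class = "cardioseg_convergence_error"
  )
}

#' Threshold an image into a binary mask
#'
#' `object_above` marks pixels with `value >= threshold` as object (bright
#' blood pool against darker myocardium); `object_below` marks pixels with
#' `value <= threshold` as object, so that background is *strictly above*
#' the threshold -- the convention needed for edge suppression, where a
#' converged threshold of 0 on a flat region must keep that region as
#' object.
#'
#' @param img integer matrix 0--255.
#' @param threshold integer in 0--255.
#' @param polarity `"object_above"` or `"object_below"`.
#' @return integer 0/1 matrix of the same dimensions.
#' @export
binarize <- function(img, threshold, polarity = c("object_above", "object_below")) {
  check_gray_image(img)
  polarity <- match.arg(polarity)
  if (threshold < 0 || threshold > 255)
    cardioseg_error("threshold must be in 0..255", class = "cardioseg_range_error")
  out <- if (polarity == "object_above") img >= threshold else img <= threshold
  mode(out) <- "integer"
  out
}
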