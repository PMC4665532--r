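# Shared internal helpers: rounding, conditions, RNG scoping, image checks.

# Round half away from zero on the non-negative reals (all image quantities
# here are >= 0).  base::round() rounds half to even, which would make the
# integer threshold fixpoint depend on parity.
round_half_up <- function(x) floor(x + 0.5)

cardioseg_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "cardioseg_error")))
}

abort_seed <- function(row, col, slice = NA, phase = NA) {
  loc <- sprintf("seed (row=%d, col=%d)", row, col)
  if (!is.na(slice)) loc <- sprintf("%s at slice %d, phase %d", loc, slice, phase)
  cardioseg_error(
    sprintf("kernel window around %s contains no object pixel", loc),
    class = "cardioseg_seed_error", row = row, col = col
  )
}

abort_dim <- function(msg) cardioseg_error(msg, class = "cardioseg_dim_error")

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards so package internals never perturb user simulations.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Validate a gray image: integer-valued matrix in 0..255, at least 3x3.
check_gray_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    abort_dim(sprintf("%s must be a numeric matrix", arg))
  if (nrow(img) < 3L || ncol(img) < 3L)
    abort_dim(sprintf("%s must be at least 3x3", arg))
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    cardioseg_error(sprintf("%s must have values in 0..255", arg),
                    class = "cardioseg_range_error")
  invisible(img)
}

check_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.numeric(mask))
    abort_dim(sprintf("%s must be a numeric matrix", arg))
  if (anyNA(mask) || !all(mask %in% c(0, 1)))
    cardioseg_error(sprintf("%s must be a binary 0/1 matrix", arg),
                    class = "cardioseg_range_error")
  invisible(mask)
}

# Clipped kernel window around a 0-based seed; returns 1-based row/col ranges.
kernel_window <- function(nr, nc, seed, size) {
  h <- (size - 1L) %/% 2L
  r <- seed$row + 1L
  c <- seed$col + 1L
  if (r < 1L || r > nr || c < 1L || c > nc)
    cardioseg_error("seed point lies outside the image",
                    class = "cardioseg_seed_error")
  list(rows = max(1L, r - h):min(nr, r + h),
       cols = max(1L, c - h):min(nc, c + h))
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b binary 0/1 matrices of equal dimensions.
#' @return `2|A∩B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#' @export
mask_dice <- function(a, b) {
  check_mask(a, "a"); check_mask(b, "b")
  if (!all(dim(a) == dim(b))) abort_dim("masks must share dimensions")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a == 1 & b == 1) / (sa + sb)
}

# Atomic text/JSON write: write to a temp file in the same directory, rename.
atomic_write <- function(path, writer) {
  tmp <- file.path(dirname(path), paste0(".tmp-", basename(path)))
  writer(tmp)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    cardioseg_error(sprintf("cannot write '%s'", path), class = "cardioseg_io_error")
  }
  invisible(path)
}
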