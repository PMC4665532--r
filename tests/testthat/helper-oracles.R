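# Independent oracles used to check the pipeline primitives.  These are
# deliberately written as naive scalar loops, sharing no code with the
# vectorized implementations they verify.

# Direct 3x3 convolution gradient magnitude with edge-replicating reflection,
# min-max renormalized to 0..255 (round half up).
oracle_edges <- function(img, operator = "sobel") {
  w <- if (operator == "sobel") 2 else 1
  kx <- matrix(c(-1, 0, 1, -w, 0, w, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  nr <- nrow(img); nc <- ncol(img)
  at <- function(r, c) img[min(max(r, 1), nr), min(max(c, 1), nc)]
  mag <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    gx <- 0; gy <- 0
    for (i in -1:1) for (j in -1:1) {
      v <- at(r + i, c + j)
      gx <- gx + kx[i + 2, j + 2] * v
      gy <- gy + ky[i + 2, j + 2] * v
    }
    mag[r, c] <- sqrt(gx^2 + gy^2)
  }
  mn <- min(mag); mx <- max(mag)
  if (mx == mn) return(matrix(0L, nr, nc))
  out <- floor((mag - mn) / (mx - mn) * 255 + 0.5)
  storage.mode(out) <- "integer"
  out
}

# All integer fixpoints of the isodata update map on a pixel sample.
oracle_isodata_fixpoints <- function(px) {
  Filter(function(t) {
    below <- px[px < t]; above <- px[px >= t]
    k1 <- if (!length(below) || !length(above)) floor(mean(px) + 0.5)
          else floor((mean(below) + mean(above)) / 2 + 0.5)
    k1 == t
  }, 0:255)
}

# Scalar queue breadth-first flood fill from a set of start indices.
oracle_bfs <- function(member, starts, connectivity = 8) {
  nr <- nrow(member); nc <- ncol(member)
  offs <- if (connectivity == 8)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  visited <- matrix(FALSE, nr, nc)
  queue <- integer(sum(member) + length(starts))
  queue[seq_along(starts)] <- starts
  head <- 1L; tail <- length(starts)
  for (s in starts) visited[s] <- TRUE
  while (head <= tail) {
    idx <- queue[head]; head <- head + 1L
    r <- (idx - 1) %% nr + 1; c <- (idx - 1) %/% nr + 1
    for (o in offs) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
        j <- (cc - 1) * nr + rr
        if (member[j] && !visited[j]) {
          visited[j] <- TRUE
          tail <- tail + 1L
          queue[tail] <- j
        }
      }
    }
  }
  visited
}

# Hole filling oracle: complement of the border-seeded 4-connected
# background flood.
oracle_fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- mask == 0
  border <- unique(c(which(bg[, 1]), (nc - 1) * nr + which(bg[, nc]),
                     (which(bg[1, ]) - 1) * nr + 1,
                     (which(bg[nr, ]) - 1) * nr + nr))
  if (!length(border)) return(matrix(1L, nr, nc))
  out <- !oracle_bfs(bg, border, connectivity = 4)
  mode(out) <- "integer"
  out
}
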