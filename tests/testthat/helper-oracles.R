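# Independent reference implementations used as oracles. These stay
# deliberately naive (loops, BFS, exhaustive enumeration) so they share no
# code path with the package internals they check.

# 8-connected component labeling by BFS flood fill on a logical matrix.
oracle_label <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!bin[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(i, j), 1L)
    lab[i, j] <- nxt
    while (nrow(queue)) {
      p <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1L] + di; jj <- p[2L] + dj
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc &&
            bin[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nxt
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  lab
}

# Per-pixel loop implementing the cover-colour formulas: mean of each
# channel over window pixels whose luma is below the cutoff.
oracle_cover_color <- function(image, xr, yr, s, cutoff) {
  w <- img_width(image); h <- img_height(image)
  x0 <- floor(xr); y0 <- floor(yr)
  acc <- c(0, 0, 0); n <- 0L
  for (x in x0:(x0 + s - 1L)) for (y in y0:(y0 + s - 1L)) {
    if (x < 0 || x >= w || y < 0 || y >= h) next
    px <- as.numeric(image[y + 1L, x + 1L, ])
    if (0.299 * px[1] + 0.587 * px[2] + 0.114 * px[3] < cutoff) {
      acc <- acc + px; n <- n + 1L
    }
  }
  list(R = acc[1] / n, G = acc[2] / n, B = acc[3] / n, N = n)
}

# Exhaustive optimal one-to-one assignment: maximum number of (pred, truth)
# pairs with IoU >= thr, by recursion over predictions. Feasible for <= 5x5.
oracle_max_matches <- function(iou, thr) {
  np <- nrow(iou); nt <- ncol(iou)
  rec <- function(i, used) {
    if (i > np) return(0L)
    best <- rec(i + 1L, used)
    for (t in seq_len(nt)) {
      if (!used[t] && iou[i, t] >= thr) {
        u <- used; u[t] <- TRUE
        best <- max(best, 1L + rec(i + 1L, u))
      }
    }
    best
  }
  rec(1L, logical(nt))
}

iou_matrix <- function(pred, truth) {
  np <- nrow(pred); nt <- nrow(truth)
  m <- matrix(0, np, nt)
  for (i in seq_len(np)) for (j in seq_len(nt)) {
    ix <- max(0, min(pred$x2[i], truth$x2[j]) - max(pred$x1[i], truth$x1[j]))
    iy <- max(0, min(pred$y2[i], truth$y2[j]) - max(pred$y1[i], truth$y1[j]))
    inter <- ix * iy
    a1 <- (pred$x2[i] - pred$x1[i]) * (pred$y2[i] - pred$y1[i])
    a2 <- (truth$x2[j] - truth$x1[j]) * (truth$y2[j] - truth$y1[j])
    m[i, j] <- inter / (a1 + a2 - inter)
  }
  m
}

# A small standard test plate shared by several files.
small_plate <- function(n = 8, seed = 42, width = 220, height = 220, ...) {
  generate_plate(plate_spec(width, height, n_colonies = n, seed = seed, ...))
}

# Draw a flat-top disc of the given peak gray onto a background matrix.
draw_disc <- function(gray, cx, cy, r, peak) {
  for (x in max(0, floor(cx - r)):min(ncol(gray) - 1, ceiling(cx + r)))
    for (y in max(0, floor(cy - r)):min(nrow(gray) - 1, ceiling(cy + r)))
      if ((x - cx)^2 + (y - cy)^2 <= r^2) gray[y + 1, x + 1] <- peak
  gray
}

# Concatenate raster arrays side by side / stacked, for tiling checks.
abind_cols <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  out <- array(0L, dim = c(dim(a)[1], dim(a)[2] + dim(b)[2], 3L))
  out[, seq_len(dim(a)[2]), ] <- a
  out[, dim(a)[2] + seq_len(dim(b)[2]), ] <- b
  out
}
abind_rows <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  out <- array(0L, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2], 3L))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}
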