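#' Lossless right-angle image rotation
#'
#' Rotates by 90, 180 or 270 degrees using axis transposition and flips, so
#' the pixel multiset is preserved exactly. The 90-degree rotation maps
#' pixel `(x, y)` of a `w x h` image to `(y, w - 1 - x)` in the `h x w`
#' result (the single bright pixel at the origin lands at `(0, w - 1)`);
#' 270 degrees is its inverse.
#'
#' @param image a [plate_image()].
#' @param theta rotation angle, one of 90, 180, 270.
#' @return the rotated [plate_image()]; dimensions `(h, w)` become `(w, h)`
#'   for 90/270.
#' @export
rotate_image <- function(image, theta) {
  stopifnot(inherits(image, "plate_image"))
  if (!theta %in% c(90, 180, 270))
    stop("unsupported rotation angle: ", theta, " (use 90, 180 or 270)", call. = FALSE)
  a <- unclass(image)
  rot1 <- function(m, theta) {
    switch(as.character(theta),
           "90"  = t(m)[rev(seq_len(ncol(m))), , drop = FALSE],
           "180" = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE],
           "270" = t(m)[, rev(seq_len(nrow(m))), drop = FALSE])
  }
  ch <- lapply(1:3, function(i) rot1(a[, , i], theta))
  out <- array(0L, dim = c(dim(ch[[1]]), 3L))
  for (i in 1:3) out[, , i] <- ch[[i]]
  structure(out, class = "plate_image")
}

#' Rotate a bounding box with its image
#'
#' Applies the center-anchored right-angle rotation
#' `xR = cos(theta) (xo - w/2) + sin(theta) (yo - h/2) + W/2`,
#' `yR = -sin(theta) (xo - w/2) + cos(theta) (yo - h/2) + H/2`
#' to all four box corners and returns their axis-aligned bounding box in
#' the rotated image, where `(W, H)` is `(h, w)` for 90/270 and `(w, h)`
#' for 180. The sign convention is the one that maps the image center to
#' the rotated-image center and agrees pixel-for-pixel with
#' [rotate_image()].
#'
#' @param box one-or-more-row [box_set()] (all rows are rotated).
#' @param theta rotation angle, one of 90, 180, 270.
#' @param w,h width and height of the source image.
#' @return the rotated [box_set()], valid in the `W x H` rotated image.
#' @export
rotate_box <- function(box, theta, w, h) {
  box <- check_boxes(box)
  if (!theta %in% c(90, 180, 270))
    stop("unsupported rotation angle: ", theta, " (use 90, 180 or 270)", call. = FALSE)
  th <- theta * pi / 180
  co <- round(cos(th)); si <- round(sin(th))
  if (theta == 180) { W <- w; H <- h } else { W <- h; H <- w }
  tx <- function(x, y)  co * (x - w / 2) + si * (y - h / 2) + W / 2
  ty <- function(x, y) -si * (x - w / 2) + co * (y - h / 2) + H / 2
  xs <- cbind(tx(box$x1, box$y1), tx(box$x2, box$y1), tx(box$x1, box$y2), tx(box$x2, box$y2))
  ys <- cbind(ty(box$x1, box$y1), ty(box$x2, box$y1), ty(box$x1, box$y2), ty(box$x2, box$y2))
  box_set(box$class_id,
          apply(xs, 1L, min), apply(ys, 1L, min),
          apply(xs, 1L, max), apply(ys, 1L, max))
}

# internal: clip boxes to a half-open window [wx1, wx2) x [wy1, wy2),
# translate into window-local coordinates, and keep boxes retaining at
# least `min_kept_fraction` of their original area.
clip_boxes <- function(boxes, wx1, wy1, wx2, wy2, min_kept_fraction) {
  if (!nrow(boxes)) return(boxes)
  cx1 <- pmax(boxes$x1, wx1); cy1 <- pmax(boxes$y1, wy1)
  cx2 <- pmin(boxes$x2, wx2); cy2 <- pmin(boxes$y2, wy2)
  kept_area <- pmax(cx2 - cx1, 0) * pmax(cy2 - cy1, 0)
  orig_area <- (boxes$x2 - boxes$x1) * (boxes$y2 - boxes$y1)
  keep <- kept_area >= min_kept_fraction * orig_area & kept_area > 0
  box_set(boxes$class_id[keep],
          cx1[keep] - wx1, cy1[keep] - wy1, cx2[keep] - wx1, cy2[keep] - wy1)
}

#' Cut a plate image into four equal quadrants
#'
#' Divides the image into its four `floor(w/2) x floor(h/2)` quadrants in
#' reading order (top-left, top-right, bottom-left, bottom-right). Odd
#' dimensions are padded by one replicated edge row/column first so the
#' quadrants tile the (padded) image exactly. Each annotation box is
#' clipped to every quadrant it intersects, translated to quadrant-local
#' coordinates, and kept only if the clipped area is at least
#' `min_kept_fraction` of the original box area — slivers left at a cut
#' line would make unlearnable labels.
#'
#' @param image a [plate_image()].
#' @param annotations a [box_set()].
#' @param min_kept_fraction minimum retained area fraction for a clipped
#'   box to survive (default 0.3).
#' @return list of four elements named `tl`, `tr`, `bl`, `br`, each a list
#'   with `image` and `annotations`.
#' @export
quarter_cut <- function(image, annotations, min_kept_fraction = 0.3) {
  stopifnot(inherits(image, "plate_image"))
  annotations <- check_boxes(annotations)
  a <- unclass(image)
  if (nrow(a) %% 2L == 1L) a <- a[c(seq_len(nrow(a)), nrow(a)), , , drop = FALSE]
  if (ncol(a) %% 2L == 1L) a <- a[, c(seq_len(ncol(a)), ncol(a)), , drop = FALSE]
  h2 <- nrow(a) %/% 2L; w2 <- ncol(a) %/% 2L
  quad <- function(rows, cols, wx1, wy1) {
    img <- structure(a[rows, cols, , drop = FALSE], class = "plate_image")
    list(image = img,
         annotations = clip_boxes(annotations, wx1, wy1, wx1 + w2, wy1 + h2,
                                  min_kept_fraction))
  }
  list(tl = quad(seq_len(h2), seq_len(w2), 0, 0),
       tr = quad(seq_len(h2), w2 + seq_len(w2), w2, 0),
       bl = quad(h2 + seq_len(h2), seq_len(w2), 0, h2),
       br = quad(h2 + seq_len(h2), w2 + seq_len(w2), w2, h2))
}

#' Relative colony-size scaling under image division
#'
#' Cutting an image into `D` equal parts (`D` a perfect square) leaves a
#' colony's absolute pixel length unchanged while the image width shrinks
#' by `sqrt(D)`, so the colony's linear size relative to the image grows by
#' `sqrt(D)` and its relative area by `D`. (The relation is sometimes
#' quoted with a single factor `D` against the linear ratio; the geometry —
#' and the worked 4-part case, where relative size doubles — give
#' `sqrt(D)` for lengths, so both factors are returned.)
#'
#' @param D number of division parts; a perfect square >= 4.
#' @return named numeric vector `c(linear = sqrt(D), area = D)`.
#' @examples
#' relative_scale(4)   # linear 2, area 4
#' @export
relative_scale <- function(D) {
  stopifnot(length(D) == 1L, D >= 4)
  s <- sqrt(D)
  if (s != floor(s)) stop("D must be a perfect square (4, 9, 16, ...)", call. = FALSE)
  c(linear = s, area = as.numeric(D))
}
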