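#' @title Plate images and the toolkit's coordinate convention
#'
#' @description
#' A `plate_image` is an 8-bit, 3-channel raster stored as an integer array
#' with dimensions `(height, width, 3)` and values in `0:255`. One
#' coordinate convention is used throughout the package:
#'
#' * pixels are addressed by `(x, y)` with `x` running rightward along
#'   columns and `y` downward along rows, both 0-based, so pixel `(x, y)`
#'   lives at `arr[y + 1, x + 1, ]`;
#' * bounding boxes are half-open, `[x1, x2) x [y1, y2)`, so a box's pixel
#'   width is `x2 - x1` and `x2` may equal the image width.
#'
#' @param data integer or numeric array of dimension `c(height, width, 3)`
#'   (values are rounded and clamped to `0:255`), or a `height x width`
#'   matrix which is replicated onto three identical channels.
#' @name plate_image
NULL

#' Create a plate image from pixel data
#'
#' @rdname plate_image
#' @return An object of class `plate_image`: an integer array
#'   `c(height, width, 3)` in `0:255`.
#' @examples
#' img <- plate_image(matrix(12L, 40, 60))
#' img_width(img)   # 60
#' img_height(img)  # 40
#' @export
plate_image <- function(data) {
  if (is.matrix(data)) data <- array(rep(data, 3L), dim = c(dim(data), 3L))
  if (!is.array(data) || length(dim(data)) != 3L || dim(data)[3L] != 3L)
    stop("`data` must be a (height, width, 3) array or a matrix", call. = FALSE)
  storage.mode(data) <- "double"
  data <- pmin(pmax(round(data), 0), 255)
  storage.mode(data) <- "integer"
  structure(data, class = "plate_image")
}

#' @rdname plate_image
#' @param x a `plate_image`.
#' @export
img_width <- function(x) dim(x)[2L]

#' @rdname plate_image
#' @export
img_height <- function(x) dim(x)[1L]

#' @export
print.plate_image <- function(x, ...) {
  cat(sprintf("<plate_image %d x %d px (width x height), 3 channels, gray range [%d, %d]>\n",
              img_width(x), img_height(x), min(x), max(x)))
  invisible(x)
}

#' Convert a plate image to a grayscale matrix
#'
#' Uses the standard luma weights 0.299 R + 0.587 G + 0.114 B.
#'
#' @param image a `plate_image`.
#' @return a `height x width` numeric matrix of gray values in `[0, 255]`.
#' @export
img_gray <- function(image) {
  stopifnot(inherits(image, "plate_image"))
  0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
}

#' Read and write plate images as PNG
#'
#' Thin wrappers around [png::readPNG()] / [png::writePNG()] that apply the
#' package's `(height, width, 3)` 8-bit representation. Grayscale and RGBA
#' PNGs are promoted/truncated to 3 channels on read.
#'
#' @param path file path.
#' @param image a `plate_image`.
#' @return `read_plate_png()` returns a `plate_image`; `write_plate_png()`
#'   returns `path` invisibly.
#' @export
read_plate_png <- function(path) {
  a <- png::readPNG(path)
  if (is.matrix(a)) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3L] >= 4L) a <- a[, , 1:3, drop = FALSE]
  plate_image(a * 255)
}

#' @rdname read_plate_png
#' @export
write_plate_png <- function(image, path) {
  stopifnot(inherits(image, "plate_image"))
  a <- unclass(image)
  storage.mode(a) <- "double"
  png::writePNG(a / 255, path)
  invisible(path)
}

# Run `expr` under a temporary RNG seed without touching the caller's
# RNG state. Seeds derived from user seeds are kept below 2^31 - 1.
local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed %% 2147483647), expr)
}

#' Box annotation tables
#'
#' Bounding boxes travel as plain data frames with columns `class_id`,
#' `x1`, `y1`, `x2`, `y2` in the package's 0-based, half-open pixel
#' convention (see [plate_image]).
#'
#' @param class_id integer class labels (recycled).
#' @param x1,y1,x2,y2 box corner coordinates, `x1 < x2`, `y1 < y2`.
#' @return a data frame of class annotations.
#' @examples
#' box_set(0, 10, 20, 30, 60)  # width 20, height 40
#' @export
box_set <- function(class_id = integer(), x1 = numeric(), y1 = numeric(),
                    x2 = numeric(), y2 = numeric()) {
  b <- data.frame(class_id = as.integer(class_id), x1 = as.numeric(x1),
                  y1 = as.numeric(y1), x2 = as.numeric(x2), y2 = as.numeric(y2))
  if (nrow(b) && (any(b$x1 >= b$x2) | any(b$y1 >= b$y2)))
    stop("boxes must satisfy x1 < x2 and y1 < y2", call. = FALSE)
  b
}

# internal: validate an externally supplied box table
check_boxes <- function(boxes) {
  need <- c("class_id", "x1", "y1", "x2", "y2")
  if (!is.data.frame(boxes) || !all(need %in% names(boxes)))
    stop("`boxes` must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  boxes[, need, drop = FALSE]
}

# internal: box centers as an n x 2 matrix of (x, y)
box_centers <- function(boxes) {
  cbind((boxes$x1 + boxes$x2) / 2, (boxes$y1 + boxes$y2) / 2)
}
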