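#' Read YOLO-darknet label files
#'
#' Each line is `class cx cy w h` with center and size normalized to image
#' dimensions. Conversion to pixel boxes uses `x1 = (cx - w/2) * image_width`
#' and so on, in the package's 0-based half-open convention.
#'
#' @param path label file path (may be empty or missing: both give zero
#'   boxes, matching darknet's treatment of images without objects).
#' @param image_width,image_height dimensions of the owning image in pixels.
#' @return a [box_set()].
#' @export
read_yolo_labels <- function(path, image_width, image_height) {
  if (!file.exists(path)) return(box_set())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(box_set())
  parsed <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 5L)
      stop(sprintf("malformed label line %d in %s: expected 5 fields, got %d",
                   i, path, length(parts)), call. = FALSE)
    v <- suppressWarnings(as.numeric(parts))
    if (anyNA(v))
      stop(sprintf("malformed label line %d in %s: non-numeric field", i, path),
           call. = FALSE)
    if (any(v[2:5] < 0) || any(v[2:5] > 1))
      stop(sprintf("out-of-range value on label line %d in %s: normalized fields must be in [0, 1]",
                   i, path), call. = FALSE)
    v
  })
  m <- do.call(rbind, parsed)
  box_set(m[, 1],
          (m[, 2] - m[, 4] / 2) * image_width,
          (m[, 3] - m[, 5] / 2) * image_height,
          (m[, 2] + m[, 4] / 2) * image_width,
          (m[, 3] + m[, 5] / 2) * image_height)
}

#' @rdname read_yolo_labels
#' @param boxes a [box_set()] to write.
#' @return `write_yolo_labels()` returns `path` invisibly. Values are
#'   written with 6 decimals, so a write/read round trip reproduces pixel
#'   coordinates to well under 0.5 px at any realistic image size.
#' @export
write_yolo_labels <- function(boxes, path, image_width, image_height) {
  boxes <- check_boxes(boxes)
  lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                   boxes$class_id,
                   (boxes$x1 + boxes$x2) / 2 / image_width,
                   (boxes$y1 + boxes$y2) / 2 / image_height,
                   (boxes$x2 - boxes$x1) / image_width,
                   (boxes$y2 - boxes$y1) / image_height)
  writeLines(lines, path)
  invisible(path)
}

# internal: one dataset item
dataset_item <- function(annotations, width, height, provenance,
                         image = NULL, image_path = NULL) {
  structure(list(annotations = annotations, width = width, height = height,
                 provenance = provenance, image = image, image_path = image_path),
            class = "dataset_item")
}

#' Build the augmented few-shot training pool
#'
#' Reproduces the few-shot dataset-construction pipeline: per source image,
#' the original plus `variants_per_source - 1` random-cover variants at
#' increasing iteration counts k = 1, 2, ...; each pool image cut into its
#' four quadrants; each quadrant kept unrotated plus rotated by 90, 180 and
#' 270 degrees. The pool therefore always holds
#' `length(sources) * variants_per_source * 4 * 4` items (5 sources at 12
#' variants give the canonical 960). Annotations are propagated through
#' every stage (cover-pruning, clipping, rotation).
#'
#' Every item's raster is computed, but kept in memory or written to disk
#' only on request; annotations, dimensions and provenance are always
#' retained, which is what dataset bookkeeping and splitting need.
#'
#' @param sources list of sources, each a list with `image`
#'   ([plate_image()]) and `annotations` ([box_set()]).
#' @param variants_per_source images per source including the original
#'   (>= 1); the canonical pipeline uses 12.
#' @param rcta_config an [rcta_config()]; each source/variant pair gets a
#'   seed derived deterministically from `rcta_config$seed`.
#' @param min_kept_fraction passed to [quarter_cut()].
#' @param out_dir if non-NULL, write each item's PNG and YOLO label file
#'   here (flat, stem `src<i>_v<k>_<quadrant>_r<theta>`).
#' @param keep_images if TRUE, store each item's [plate_image()] in the
#'   item (only sensible for small sources).
#' @return list of `dataset_item` objects, each with `annotations`,
#'   `width`, `height`, `provenance` (`source_id`, `rcta_variant_index`
#'   with 0 = original, `quadrant`, `rotation`) and optionally `image` /
#'   `image_path`.
#' @export
build_augmented_pool <- function(sources, variants_per_source,
                                 rcta_config = rcta_config(),
                                 min_kept_fraction = 0.3,
                                 out_dir = NULL, keep_images = FALSE) {
  stopifnot(variants_per_source >= 1, length(sources) >= 1)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  pool <- list()
  for (si in seq_along(sources)) {
    src <- sources[[si]]
    stopifnot(inherits(src$image, "plate_image"))
    src_ann <- check_boxes(src$annotations)
    for (vi in seq_len(variants_per_source) - 1L) {
      if (vi == 0L) {
        vimg <- src$image; vann <- src_ann
      } else {
        cfg <- rcta_config
        cfg$seed <- as.integer((rcta_config$seed + 1009L * si + vi) %% 2147483647)
        res <- withCallingHandlers(
          rcta_augment(src$image, src_ann, cfg, k = vi),
          warning = function(w) {
            # fewer eligible regions than k: the variant falls back to
            # covering all of them, which is still a valid pool image
            invokeRestart("muffleWarning")
          })
        vimg <- res$image; vann <- res$annotations
      }
      quads <- quarter_cut(vimg, vann, min_kept_fraction)
      for (qn in names(quads)) {
        q <- quads[[qn]]
        qw <- img_width(q$image); qh <- img_height(q$image)
        for (theta in c(0, 90, 180, 270)) {
          if (theta == 0) {
            itimg <- q$image; itann <- q$annotations; iw <- qw; ih <- qh
          } else {
            itimg <- rotate_image(q$image, theta)
            itann <- rotate_box(q$annotations, theta, qw, qh)
            iw <- img_width(itimg); ih <- img_height(itimg)
          }
          path <- NULL
          if (!is.null(out_dir)) {
            stem <- sprintf("src%d_v%d_%s_r%d", si, vi, qn, theta)
            path <- file.path(out_dir, paste0(stem, ".png"))
            write_plate_png(itimg, path)
            write_yolo_labels(itann, file.path(out_dir, paste0(stem, ".txt")), iw, ih)
          }
          pool[[length(pool) + 1L]] <- dataset_item(
            itann, iw, ih,
            provenance = list(source_id = si, rcta_variant_index = vi,
                              quadrant = qn, rotation = theta),
            image = if (keep_images) itimg else NULL,
            image_path = path)
        }
      }
    }
  }
  pool
}

#' Split a dataset pool into training and validation sets
#'
#' Seeded uniform shuffle; the first `round(train_fraction * n)` items form
#' the training set. At the canonical pool size this is exactly 864 of 960.
#'
#' @param pool list of dataset items (any list).
#' @param train_fraction fraction of items for training, in (0, 1).
#' @param seed RNG seed; the split is deterministic given `(pool, seed)`.
#' @return object of class `split_result`: list with `train`, `validation`,
#'   `train_fraction`, `seed`.
#' @export
split_dataset <- function(pool, train_fraction = 0.9, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- length(pool)
  if (n == 0L) stop("cannot split an empty pool", call. = FALSE)
  perm <- local_seed(seed, sample.int(n))
  n_train <- round(train_fraction * n)
  structure(list(train = pool[perm[seq_len(n_train)]],
                 validation = pool[perm[setdiff(seq_len(n), seq_len(n_train))]],
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result: %d train / %d validation (fraction %.2f, seed %d)>\n",
              length(x$train), length(x$validation), x$train_fraction, x$seed))
  invisible(x)
}

#' Export a split in darknet layout
#'
#' Writes `images/` and `labels/` (one label file per image, same stem),
#' `train.txt` and `valid.txt` path lists, and a single-class `colony.names`
#' file. Items must carry pixel data (`keep_images = TRUE` at pool build)
#' or an existing `image_path` to copy from.
#'
#' @param split a [split_dataset()] result.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a manifest list with the written file paths and
#'   per-split counts.
#' @export
export_darknet <- function(split, out_dir) {
  stopifnot(inherits(split, "split_result"))
  img_dir <- file.path(out_dir, "images")
  lab_dir <- file.path(out_dir, "labels")
  for (d in c(out_dir, img_dir, lab_dir))
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE))
      stop("cannot create directory ", d, call. = FALSE)
  write_items <- function(items) {
    vapply(items, function(it) {
      p <- it$provenance
      stem <- sprintf("src%d_v%d_%s_r%d", p$source_id, p$rcta_variant_index,
                      p$quadrant, p$rotation)
      img_path <- file.path(img_dir, paste0(stem, ".png"))
      if (!is.null(it$image)) write_plate_png(it$image, img_path)
      else if (!is.null(it$image_path) && file.exists(it$image_path))
        file.copy(it$image_path, img_path, overwrite = TRUE)
      else stop("dataset item ", stem, " carries no pixel data to export",
                call. = FALSE)
      write_yolo_labels(it$annotations, file.path(lab_dir, paste0(stem, ".txt")),
                        it$width, it$height)
      img_path
    }, character(1))
  }
  train_paths <- write_items(split$train)
  valid_paths <- write_items(split$validation)
  writeLines(train_paths, file.path(out_dir, "train.txt"))
  writeLines(valid_paths, file.path(out_dir, "valid.txt"))
  writeLines("colony", file.path(out_dir, "colony.names"))
  invisible(list(train_list = file.path(out_dir, "train.txt"),
                 valid_list = file.path(out_dir, "valid.txt"),
                 names_file = file.path(out_dir, "colony.names"),
                 n_train = length(train_paths), n_validation = length(valid_paths),
                 images = c(train_paths, valid_paths)))
}
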