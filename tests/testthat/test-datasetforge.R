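test_that("YOLO label conversion matches the format definition", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  b <- box_set(0L, 100, 100, 200, 200)
  write_yolo_labels(b, tmp, 1000, 1000)
  expect_equal(readLines(tmp), "0 0.150000 0.150000 0.100000 0.100000")
  back <- read_yolo_labels(tmp, 1000, 1000)
  expect_equal(back, b)
})

test_that("empty and malformed label files are handled explicitly", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), tmp)
  expect_equal(nrow(read_yolo_labels(tmp, 100, 100)), 0L)
  writeLines(c("0 0.5 0.5 0.1 0.1", "0 0.5 0.5 0.1"), tmp)
  expect_error(read_yolo_labels(tmp, 100, 100), "line 2")
  writeLines("0 1.5 0.5 0.1 0.1", tmp)
  expect_error(read_yolo_labels(tmp, 100, 100), "out-of-range")
  writeLines("0 a 0.5 0.1 0.1", tmp)
  expect_error(read_yolo_labels(tmp, 100, 100), "non-numeric")
})

test_that("label round trip is bounded by normalization quantization", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  W <- 2560; H <- 2590
  boxes <- withr::with_seed(4, {
    x1 <- runif(1000, 0, W - 40); y1 <- runif(1000, 0, H - 40)
    box_set(0L, x1, y1, x1 + runif(1000, 5, 40), y1 + runif(1000, 5, 40))
  })
  write_yolo_labels(boxes, tmp, W, H)
  back <- read_yolo_labels(tmp, W, H)
  err <- max(abs(as.matrix(back[, -1]) - as.matrix(boxes[, -1])))
  expect_lte(err, 0.5)
})

test_that("pool size obeys the sources x variants x 16 law", {
  p1 <- small_plate(n = 6, seed = 1, width = 200, height = 200,
                    radius_range = c(5L, 9L))
  p2 <- small_plate(n = 5, seed = 2, width = 200, height = 200,
                    radius_range = c(5L, 9L))
  sources <- list(list(image = p1$image, annotations = p1$boxes),
                  list(image = p2$image, annotations = p2$boxes))
  pool <- build_augmented_pool(sources, 3, rcta_config(seed = 7))
  expect_length(pool, 2 * 3 * 16)
  # provenance uniquely identifies items
  keys <- vapply(pool, function(it)
    paste(it$provenance$source_id, it$provenance$rcta_variant_index,
          it$provenance$quadrant, it$provenance$rotation), character(1))
  expect_false(anyDuplicated(keys) > 0)
  # every annotation lies within its item's bounds
  for (it in pool) {
    a <- it$annotations
    if (nrow(a))
      expect_true(all(a$x1 >= 0 & a$y1 >= 0 & a$x2 <= it$width & a$y2 <= it$height))
  }
  # a single unaugmented source yields 16 annotation-complete items
  pool1 <- build_augmented_pool(sources[1], 1, rcta_config(seed = 7))
  expect_length(pool1, 16)
  expect_true(all(vapply(pool1, function(it)
    it$provenance$rcta_variant_index == 0, logical(1))))
})

test_that("rcta variants prune annotations monotonically across the schedule", {
  p <- small_plate(n = 10, seed = 3, width = 300, height = 300)
  pool <- build_augmented_pool(list(list(image = p$image, annotations = p$boxes)),
                               4, rcta_config(seed = 11))
  # total annotations per variant (summed over the 4 unrotated quadrants)
  totals <- vapply(0:3, function(v) {
    sum(vapply(pool, function(it)
      if (it$provenance$rcta_variant_index == v && it$provenance$rotation == 0)
        nrow(it$annotations) else 0L, integer(1)))
  }, integer(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("split sizes are deterministic and the split is a partition", {
  pool <- as.list(seq_len(960))
  s <- split_dataset(pool, 0.9, seed = 5)
  expect_length(s$train, 864)
  expect_length(s$validation, 96)
  expect_setequal(c(unlist(s$train), unlist(s$validation)), seq_len(960))

  s2 <- split_dataset(pool, 0.9, seed = 5)
  expect_identical(unlist(s$train), unlist(s2$train))
  s3 <- split_dataset(as.list(1:10), 0.9, seed = 1)
  expect_length(s3$train, 9)
  expect_error(split_dataset(list(), 0.9, 1), "empty")

  for (s4_seed in 1:20) {
    n <- 17
    s4 <- split_dataset(as.list(seq_len(n)), 0.7, seed = s4_seed)
    expect_length(s4$train, round(0.7 * n))
    expect_setequal(c(unlist(s4$train), unlist(s4$validation)), seq_len(n))
  }
})

test_that("darknet export writes a complete, idempotent layout", {
  p <- small_plate(n = 5, seed = 6, width = 160, height = 160,
                   radius_range = c(5L, 8L))
  pool <- build_augmented_pool(list(list(image = p$image, annotations = p$boxes)),
                               2, rcta_config(seed = 3), keep_images = TRUE)
  s <- split_dataset(pool, 0.9, seed = 2)
  out <- withr::local_tempdir()
  man <- export_darknet(s, out)
  expect_length(list.files(file.path(out, "images")), 32)
  expect_length(list.files(file.path(out, "labels")), 32)
  expect_length(readLines(file.path(out, "train.txt")), length(s$train))
  expect_length(readLines(file.path(out, "valid.txt")), length(s$validation))
  expect_equal(readLines(file.path(out, "colony.names")), "colony")
  # re-export reproduces the same manifest
  man2 <- export_darknet(s, out)
  expect_identical(man[c("n_train", "n_validation", "images")],
                   man2[c("n_train", "n_validation", "images")])
  # labels round-trip against the items
  it <- s$train[[1]]
  stem <- sprintf("src%d_v%d_%s_r%d", it$provenance$source_id,
                  it$provenance$rcta_variant_index, it$provenance$quadrant,
                  it$provenance$rotation)
  back <- read_yolo_labels(file.path(out, "labels", paste0(stem, ".txt")),
                           it$width, it$height)
  expect_equal(nrow(back), nrow(it$annotations))
})
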