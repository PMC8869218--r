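test_that("segmentation matches the flood-fill oracle on rendered scenes", {
  # nothing above threshold
  flat <- plate_image(matrix(10L, 50, 50))
  expect_equal(nrow(find_target_regions(flat, 40)), 0L)

  # one disc
  g <- draw_disc(matrix(12, 80, 80), cx = 40, cy = 38, r = 20, peak = 120)
  img <- plate_image(g)
  reg <- find_target_regions(img, 40)
  expect_equal(nrow(reg), 1L)
  expect_lt(sqrt((reg$xr - 40)^2 + (reg$yr - 38)^2), 2)
  lab <- oracle_label(g > 40)
  expect_equal(reg$area, sum(lab == 1))

  # two separate discs vs two fused discs
  g2 <- draw_disc(draw_disc(matrix(12, 100, 100), 25, 25, 10, 120), 70, 70, 10, 120)
  expect_equal(nrow(find_target_regions(plate_image(g2), 40)), 2L)
  g3 <- draw_disc(draw_disc(matrix(12, 100, 100), 40, 50, 10, 120), 55, 50, 10, 120)
  expect_equal(nrow(find_target_regions(plate_image(g3), 40)), 1L)
})

test_that("8-connectivity: diagonal pixel chains form one component", {
  g <- matrix(0, 30, 30)
  for (k in 0:8) g[5 + k, 5 + k] <- 200   # diagonal line
  reg <- find_target_regions(plate_image(g), 40)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$area, 9)
  expect_equal(max(oracle_label(g > 40)), 1L)
})

test_that("component labeling agrees with the BFS oracle on random rasters", {
  for (s in 1:5) {
    bin <- withr::with_seed(s, matrix(runif(40 * 35) < 0.35, 35, 40))
    g <- matrix(0, 35, 40); g[bin] <- 150
    reg <- find_target_regions(plate_image(g), 40)
    expect_equal(nrow(reg), max(oracle_label(bin)))
    expect_equal(sum(reg$area), sum(bin))
  }
})

test_that("enclosing circles contain every component pixel", {
  p <- small_plate(n = 6, seed = 21)
  g <- img_gray(p$image)
  reg <- find_target_regions(p$image, 40)
  lab <- oracle_label(g > 40)
  for (i in seq_len(nrow(reg))) {
    # the oracle component under this region's center
    comp <- lab[round(reg$yr[i]) + 1, round(reg$xr[i]) + 1]
    if (comp == 0) next
    px <- arrayInd(which(lab == comp), dim(lab))
    d <- sqrt((px[, 2] - 1 - reg$xr[i])^2 + (px[, 1] - 1 - reg$yr[i])^2)
    expect_lte(max(d), reg$radius[i] + 1e-6)
  }
})

test_that("region filtering applies strict area bounds and the central margin", {
  cfg <- rcta_config()
  regions <- data.frame(
    xr = c(500, 500, 500, 500, 5, 500, 950),
    yr = c(500, 500, 500, 500, 5, 95, 500),
    radius = rep(10, 7),
    area = c(60, 61, 3499, 3500, 500, 500, 500))
  kept <- filter_regions(regions, cfg, 1000, 1000)
  # strict bounds: 60 and 3500 excluded; border centers excluded
  expect_equal(kept$area, c(61, 3499))
  # margin boundary is half-open: center exactly at 0.1*w is kept
  edge <- data.frame(xr = c(100, 99.999, 900, 899.999), yr = rep(500, 4),
                     radius = 5, area = 500)
  expect_equal(nrow(filter_regions(edge, cfg, 1000, 1000)), 2L)
})

test_that("cover colour equals the per-pixel oracle, including clipped windows", {
  p <- small_plate(n = 5, seed = 33, width = 120, height = 100,
                   radius_range = c(5L, 10L))
  cfg <- rcta_config()
  cases <- withr::with_seed(8, data.frame(
    xr = c(runif(40, 0, 119), 0, 110, 115, 0),
    yr = c(runif(40, 0, 99), 0, 90, 0, 95)))
  for (i in seq_len(nrow(cases))) {
    reg <- list(xr = cases$xr[i], yr = cases$yr[i])
    got <- compute_cover_color(p$image, reg, cfg)
    ref <- oracle_cover_color(p$image, reg$xr, reg$yr, cfg$window_size,
                              cfg$background_cutoff)
    expect_equal(got$N, ref$N)
    if (ref$N > 0) {
      expect_equal(got$Rmean, ref$R)
      expect_equal(got$Gmean, ref$G)
      expect_equal(got$Bmean, ref$B)
      expect_false(got$fallback)
    } else {
      expect_true(got$fallback)
    }
  }
})

test_that("cover colour on a constant background window is exact with N = s^2", {
  img <- plate_image(matrix(10L, 60, 60))
  got <- compute_cover_color(img, list(xr = 10, yr = 10), rcta_config())
  expect_equal(c(got$Rmean, got$Gmean, got$Bmean), c(10, 10, 10))
  expect_equal(got$N, 400L)
})

test_that("windows with no background fall back to the global mean, and error when none exists", {
  g <- matrix(10, 80, 80)
  g <- draw_disc(g, 40, 40, 30, 120)
  img <- plate_image(g)
  got <- compute_cover_color(img, list(xr = 40, yr = 40), rcta_config())
  expect_true(got$fallback)
  expect_equal(got$N, 0L)
  expect_equal(got$Rmean, mean(img[, , 1][img_gray(img) < 20]))

  bright <- plate_image(matrix(200L, 30, 30))
  expect_error(compute_cover_color(bright, list(xr = 5, yr = 5), rcta_config()),
               "no background")
})

test_that("covering changes exactly the disc pixels, to one colour", {
  p <- small_plate(n = 3, seed = 11)
  reg <- find_target_regions(p$image, 40)[1, ]
  col <- compute_cover_color(p$image, reg, rcta_config())
  out <- cover_target(p$image, reg, col)
  diff <- which(unclass(out) != unclass(p$image), arr.ind = TRUE)
  # every changed pixel is inside the disc; all carry the cover colour
  d <- sqrt((diff[, 2] - 1 - reg$xr)^2 + (diff[, 1] - 1 - reg$yr)^2)
  expect_true(all(d <= reg$radius))
  vals <- round(c(col$Rmean, col$Gmean, col$Bmean))
  for (ch in 1:3) {
    chg <- diff[diff[, 3] == ch, , drop = FALSE]
    expect_true(all(out[cbind(chg[, 1], chg[, 2], ch)] == vals[ch]))
  }
  # disc-interior pixel count matches the rasterized disc
  w <- img_width(p$image); h <- img_height(p$image)
  mask <- outer((seq_len(h) - 1 - reg$yr)^2, (seq_len(w) - 1 - reg$xr)^2, `+`) <= reg$radius^2
  changed_any <- unique(diff[, 1:2, drop = FALSE])
  expect_lte(nrow(changed_any), sum(mask))

  # degenerate radius: at most the center pixel changes
  tiny <- reg; tiny$radius <- 0
  out0 <- cover_target(p$image, tiny, col)
  expect_lte(sum(unclass(out0) != unclass(p$image)) / 3, 1)
})

test_that("a covered target disappears on re-segmentation", {
  p <- small_plate(n = 5, seed = 17, overlap_fraction = 0)
  cfg <- rcta_config(seed = 2)
  before <- find_target_regions(p$image, cfg$seg_threshold)
  res <- rcta_augment(p$image, p$boxes, cfg, k = 2)
  after <- find_target_regions(res$image, cfg$seg_threshold)
  expect_equal(nrow(after), nrow(before) - 2L)
})

test_that("rcta_augment honours k, removes only boxes inside covered discs", {
  p <- small_plate(n = 10, seed = 5, width = 300, height = 300)
  cfg <- rcta_config(seed = 9)

  # k = 0 is the identity
  res0 <- rcta_augment(p$image, p$boxes, cfg, k = 0)
  expect_identical(unclass(res0$image), unclass(p$image))
  expect_equal(res0$annotations, p$boxes)

  res <- rcta_augment(p$image, p$boxes, cfg, k = 3)
  expect_equal(nrow(res$covered), 3L)
  # removed boxes are exactly those with centers in a covered disc
  ctr <- cbind((p$boxes$x1 + p$boxes$x2) / 2, (p$boxes$y1 + p$boxes$y2) / 2)
  inside <- rep(FALSE, nrow(p$boxes))
  for (i in seq_len(nrow(res$covered)))
    inside <- inside | ((ctr[, 1] - res$covered$xr[i])^2 +
                          (ctr[, 2] - res$covered$yr[i])^2 <= res$covered$radius[i]^2)
  expect_equal(res$annotations, p$boxes[!inside, ], ignore_attr = TRUE)
  expect_equal(nrow(p$boxes), nrow(res$annotations) + sum(inside))

  # locality: pixels outside covered discs are bit-identical
  w <- img_width(p$image); h <- img_height(p$image)
  covered_mask <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(res$covered))) {
    m <- outer((seq_len(h) - 1 - res$covered$yr[i])^2,
               (seq_len(w) - 1 - res$covered$xr[i])^2, `+`) <= res$covered$radius[i]^2
    covered_mask <- covered_mask | m
  }
  for (ch in 1:3)
    expect_identical(unclass(res$image)[, , ch][!covered_mask],
                     unclass(p$image)[, , ch][!covered_mask])
})

test_that("requesting more covers than eligible regions warns and caps", {
  p <- small_plate(n = 4, seed = 3)
  cfg <- rcta_config(seed = 1)
  expect_warning(res <- rcta_augment(p$image, p$boxes, cfg, k = 500),
                 "eligible")
  n_el <- nrow(filter_regions(find_target_regions(p$image, cfg$seg_threshold),
                              cfg, img_width(p$image), img_height(p$image)))
  expect_equal(nrow(res$covered), n_el)
})

test_that("monotone erasure: covers at k1 are a prefix of covers at k2", {
  p <- small_plate(n = 12, seed = 6, width = 350, height = 350)
  cfg <- rcta_config(seed = 4)
  res_all <- lapply(0:5, function(k) rcta_augment(p$image, p$boxes, cfg, k = k))
  for (j in 2:6) {
    # res_all[[j]] holds j - 1 covers; the previous result is its prefix
    expect_equal(res_all[[j - 1]]$covered,
                 res_all[[j]]$covered[seq_len(j - 2), ],
                 ignore_attr = TRUE)
    expect_lte(nrow(res_all[[j]]$annotations), nrow(res_all[[j - 1]]$annotations))
  }
})

test_that("rcta_augment is deterministic given config seed and k", {
  p <- small_plate(n = 9, seed = 8)
  cfg <- rcta_config(seed = 77)
  r1 <- rcta_augment(p$image, p$boxes, cfg, k = 4)
  r2 <- rcta_augment(p$image, p$boxes, cfg, k = 4)
  expect_identical(unclass(r1$image), unclass(r2$image))
  expect_equal(r1$covered, r2$covered)
})
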