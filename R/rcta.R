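#' Configuration for random target coverage
#'
#' Parameters of the annotation-preserving augmentation that erases randomly
#' chosen colonies by overwriting them with the local background colour.
#'
#' @param seg_threshold gray value tau for candidate segmentation; pixels
#'   with luma above tau are foreground. The default 40 sits well above the
#'   near-black background band (gray < 20) and below colony peaks.
#' @param area_range `(a_min, a_max)` pixel-area band; only candidate
#'   regions with `a_min < area < a_max` (strict, matching the open-interval
#'   reading of the effective range) are eligible. Default `(60, 3500)`.
#' @param margin_fraction border fraction excluded from coverage per side
#'   (default 0.10): a region is eligible only if its center lies in the
#'   central rectangle.
#' @param window_size side `s` of the background sampling window anchored at
#'   the region center and extending to its bottom-right (default 20 px).
#' @param background_cutoff gray value below which pixels count as
#'   background when estimating the cover colour (default 20).
#' @param seed RNG seed for target selection.
#' @return an object of class `rcta_config`.
#' @export
rcta_config <- function(seg_threshold = 40, area_range = c(60, 3500),
                        margin_fraction = 0.10, window_size = 20L,
                        background_cutoff = 20, seed = 1L) {
  stopifnot(seg_threshold > 0, seg_threshold < 255,
            length(area_range) == 2L, area_range[1] >= 0,
            area_range[1] < area_range[2],
            margin_fraction >= 0, margin_fraction < 0.5,
            window_size >= 1, background_cutoff > 0, background_cutoff <= 255)
  structure(list(seg_threshold = seg_threshold, area_range = area_range,
                 margin_fraction = margin_fraction,
                 window_size = as.integer(window_size),
                 background_cutoff = background_cutoff,
                 seed = as.integer(seed)),
            class = "rcta_config")
}

#' @export
print.rcta_config <- function(x, ...) {
  cat(sprintf("<rcta_config tau=%g, area (%g, %g), margin %.2f, window %d, cutoff %g, seed %d>\n",
              x$seg_threshold, x$area_range[1], x$area_range[2],
              x$margin_fraction, x$window_size, x$background_cutoff, x$seed))
  invisible(x)
}

# internal: 8-connected component labeling. EBImage::bwlabel is
# 4-connected; diagonal-only adjacencies between its labels are merged
# with a union-find pass over the (small) label graph.
label_components <- function(bin) {
  lab <- EBImage::bwlabel(bin)
  if (methods::is(lab, "Image")) lab <- EBImage::imageData(lab)
  dim(lab) <- dim(bin)
  n <- as.integer(max(lab))
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]    # NW-SE diagonal neighbours
  c2 <- lab[-1, -nc]; d <- lab[-nr, -1]   # SW-NE diagonal neighbours
  s1 <- a > 0L & b > 0L & a != b
  s2 <- c2 > 0L & d > 0L & c2 != d
  pairs <- unique(rbind(cbind(a[s1], b[s1]), cbind(c2[s2], d[s2])))
  if (nrow(pairs)) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(n), find, integer(1))
    dense <- match(root, sort(unique(root)))
    pos <- lab > 0L
    lab[pos] <- dense[lab[pos]]
  }
  lab
}

# internal: minimum enclosing circle of an n x 2 point set, computed on the
# convex hull with the deterministic incremental algorithm. Returns
# list(center = c(x, y), radius).
min_enclosing_circle <- function(xy) {
  xy <- unique(xy)
  n <- nrow(xy)
  if (n == 1L) return(list(center = as.numeric(xy[1L, ]), radius = 0))
  if (n > 3L) {
    hull <- grDevices::chull(xy[, 1], xy[, 2])
    xy <- xy[hull, , drop = FALSE]
    n <- nrow(xy)
    # hull points arrive in angular order, the worst case for the
    # incremental algorithm; a fixed coprime stride scatters them
    if (n > 8L) {
      gcd <- function(a, b) { while (b) { t <- a %% b; a <- b; b <- t }; a }
      stride <- max(7919L %% n, 1L)
      while (stride > 1L && gcd(stride, n) != 1L) stride <- stride - 1L
      xy <- xy[((seq_len(n) - 1L) * stride) %% n + 1L, , drop = FALSE]
    }
  }
  eps <- 1e-9
  from2 <- function(p, q) list(center = (p + q) / 2, radius = sqrt(sum((p - q)^2)) / 2)
  from3 <- function(p, q, r) {
    d <- 2 * (p[1] * (q[2] - r[2]) + q[1] * (r[2] - p[2]) + r[1] * (p[2] - q[2]))
    if (abs(d) < 1e-12) return(NULL)
    ux <- (sum(p^2) * (q[2] - r[2]) + sum(q^2) * (r[2] - p[2]) + sum(r^2) * (p[2] - q[2])) / d
    uy <- (sum(p^2) * (r[1] - q[1]) + sum(q^2) * (p[1] - r[1]) + sum(r^2) * (q[1] - p[1])) / d
    ctr <- c(ux, uy)
    list(center = ctr, radius = sqrt(sum((p - ctr)^2)))
  }
  holds <- function(circ, p) sqrt(sum((p - circ$center)^2)) <= circ$radius + eps
  circ <- from2(xy[1L, ], xy[2L, ])
  for (i in seq_len(n)[-(1:2)]) {
    p <- xy[i, ]
    if (holds(circ, p)) next
    circ <- from2(xy[1L, ], p)
    for (j in 2:(i - 1L)) {
      q <- xy[j, ]
      if (holds(circ, q)) next
      circ <- from2(p, q)
      for (k in seq_len(j - 1L)) {
        s <- xy[k, ]
        if (!holds(circ, s)) {
          cc <- from3(p, q, s)
          if (!is.null(cc)) circ <- cc
        }
      }
    }
  }
  circ
}

#' Segment candidate colony regions
#'
#' Converts the image to grayscale with the standard luma weights,
#' binarizes at `tau` (pixel > tau is foreground), labels 8-connected
#' foreground components, and returns one region per component with the
#' minimum enclosing circle of its pixels and its pixel area.
#'
#' @param image a [plate_image()].
#' @param tau segmentation gray threshold.
#' @return a data frame of class `target_regions` with columns `xr`, `yr`
#'   (enclosing-circle center, 0-based pixel coordinates), `radius`
#'   (enclosing-circle radius, floored at 0.5 px so single-pixel components
#'   have positive radius) and `area` (component pixel count). Zero rows
#'   when nothing exceeds `tau`.
#' @export
find_target_regions <- function(image, tau) {
  stopifnot(inherits(image, "plate_image"), tau > 0, tau < 255)
  bin <- img_gray(image) > tau
  storage.mode(bin) <- "integer"
  lab <- label_components(bin)
  n <- max(lab)
  out <- data.frame(xr = numeric(n), yr = numeric(n),
                    radius = numeric(n), area = numeric(n))
  if (n > 0L) {
    idx <- which(lab > 0L)
    rc <- arrayInd(idx, dim(lab))
    labs <- lab[idx]
    # pixel centers in (x, y): x = col - 1, y = row - 1
    xs <- split(rc[, 2L] - 1, labs)
    ys <- split(rc[, 1L] - 1, labs)
    for (i in seq_len(n)) {
      mec <- min_enclosing_circle(cbind(xs[[i]], ys[[i]]))
      out$xr[i] <- mec$center[1]; out$yr[i] <- mec$center[2]
      # tiny inflation keeps support pixels strictly inside the circle, so
      # rasterizing the disc is guaranteed to cover the whole component
      out$radius[i] <- max(mec$radius + 1e-6, 0.5)
      out$area[i] <- length(xs[[i]])
    }
  }
  class(out) <- c("target_regions", "data.frame")
  out
}

#' Filter candidate regions to the eligible set
#'
#' Keeps regions whose pixel area lies strictly inside the effective band
#' and whose center lies in the central rectangle that excludes a border
#' margin, preserving order.
#'
#' @param regions a `target_regions` data frame from [find_target_regions()].
#' @param config an [rcta_config()].
#' @param width,height dimensions of the image the regions came from.
#' @return the filtered `target_regions` data frame.
#' @export
filter_regions <- function(regions, config, width, height) {
  stopifnot(inherits(config, "rcta_config"))
  a <- config$area_range; m <- config$margin_fraction
  keep <- regions$area > a[1] & regions$area < a[2] &
    regions$xr >= m * width & regions$xr < (1 - m) * width &
    regions$yr >= m * height & regions$yr < (1 - m) * height
  regions[keep, , drop = FALSE]
}

#' Estimate the cover colour for a target region
#'
#' Over the `s x s` window anchored at the region center and extending to
#' its bottom-right, `[xr, xr + s) x [yr, yr + s)` clipped to the image,
#' selects the pixels whose grayscale value is below `background_cutoff`
#' and returns the per-channel mean over those pixels. Colony pixels inside
#' the window are excluded by the cutoff mask. If no window pixel
#' qualifies, falls back to the mean over all background pixels of the
#' whole image and flags it.
#'
#' @param image a [plate_image()].
#' @param region one-row `target_regions` data frame (or a list with `xr`,
#'   `yr`).
#' @param config an [rcta_config()].
#' @return an object of class `cover_color`: list with `Rmean`, `Gmean`,
#'   `Bmean`, `N` (number of qualifying window pixels) and `fallback`
#'   (TRUE when the global background mean was used).
#' @export
compute_cover_color <- function(image, region, config) {
  stopifnot(inherits(image, "plate_image"), inherits(config, "rcta_config"))
  cover_color_impl(image, region$xr[1], region$yr[1], config)
}

# internal: cover-colour computation on the raw array (subsetting a classed
# array drops the class, so `image` may be a plate_image or a plain array).
# `fallback_color` short-circuits the whole-image background scan when the
# caller has already computed it.
cover_color_impl <- function(image, xr, yr, config, fallback_color = NULL) {
  h <- dim(image)[1L]; w <- dim(image)[2L]
  s <- config$window_size
  x0 <- floor(xr); y0 <- floor(yr)
  if (x0 > w - 1 || y0 > h - 1 || x0 + s - 1 < 0 || y0 + s - 1 < 0)
    stop("window lies outside the image", call. = FALSE)
  xs <- max(0, x0):min(w - 1, x0 + s - 1)
  ys <- max(0, y0):min(h - 1, y0 + s - 1)
  win <- image[ys + 1, xs + 1, , drop = FALSE]
  win_gray <- 0.299 * win[, , 1L] + 0.587 * win[, , 2L] + 0.114 * win[, , 3L]
  win_mask <- win_gray < config$background_cutoff
  fallback <- FALSE
  if (any(win_mask)) {
    means <- vapply(1:3, function(ch) mean(win[, , ch][win_mask]), numeric(1))
    n_sel <- sum(win_mask)
  } else if (!is.null(fallback_color)) {
    means <- fallback_color
    n_sel <- 0L
    fallback <- TRUE
  } else {
    gray <- 0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
    glob <- gray < config$background_cutoff
    if (!any(glob))
      stop("no background found: no pixel below the background cutoff", call. = FALSE)
    means <- vapply(1:3, function(ch) mean(image[, , ch][glob]), numeric(1))
    n_sel <- 0L
    fallback <- TRUE
  }
  structure(list(Rmean = means[1L], Gmean = means[2L], Bmean = means[3L],
                 N = as.integer(n_sel), fallback = fallback),
            class = "cover_color")
}

#' @export
print.cover_color <- function(x, ...) {
  cat(sprintf("<cover_color (%.2f, %.2f, %.2f), N=%d%s>\n",
              x$Rmean, x$Gmean, x$Bmean, x$N,
              if (x$fallback) ", global fallback" else ""))
  invisible(x)
}

#' Cover one target with a constant-colour disc
#'
#' Sets every pixel within `radius` of `(xr, yr)` to the cover colour
#' (rounded to 8-bit); all other pixels are returned bit-identical.
#'
#' @param image a [plate_image()].
#' @param region one-row `target_regions` data frame (uses `xr`, `yr`,
#'   `radius`).
#' @param color a [compute_cover_color()] result (or list with `Rmean`,
#'   `Gmean`, `Bmean`).
#' @return a new [plate_image()].
#' @export
cover_target <- function(image, region, color) {
  stopifnot(inherits(image, "plate_image"))
  out <- unclass(image)
  w <- dim(out)[2L]; h <- dim(out)[1L]
  cx <- region$xr[1]; cy <- region$yr[1]; r <- region$radius[1]
  xs <- max(0, floor(cx - r)):min(w - 1, ceiling(cx + r))
  ys <- max(0, floor(cy - r)):min(h - 1, ceiling(cy + r))
  if (!length(xs) || !length(ys)) return(image)
  inside <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= r^2
  vals <- as.integer(pmin(pmax(round(c(color$Rmean, color$Gmean, color$Bmean)), 0), 255))
  for (ch in 1:3) {
    sub <- out[ys + 1, xs + 1, ch, drop = FALSE]
    sub[inside] <- vals[ch]
    out[ys + 1, xs + 1, ch] <- sub
  }
  structure(out, class = "plate_image")
}

#' Random target coverage augmentation
#'
#' Segments the image once, filters to the eligible region set, draws a
#' seeded uniform permutation of it, and covers the first
#' `min(k, n_eligible)` regions in permutation order. Each cover's colour
#' is computed on the image as already modified by the earlier covers, one
#' target at a time. Annotation boxes whose center lies inside a covered
#' disc are removed; all others are passed through untouched. Because
#' selection is a prefix of one fixed permutation, the covered set at
#' iteration `k1 <= k2` (same seed) is a prefix of the set at `k2`.
#'
#' @param image a [plate_image()].
#' @param annotations a [box_set()] of the image's colony boxes.
#' @param config an [rcta_config()]; `config$seed` drives target selection.
#' @param k number of cover operations requested (capped at the number of
#'   eligible regions, with a warning when fewer are available).
#' @return list of class `rcta_result`: `image` (augmented
#'   [plate_image()]), `annotations` (surviving boxes), `covered`
#'   (`target_regions` rows actually covered, in cover order), `colors`
#'   (list of the [compute_cover_color()] results used).
#' @export
rcta_augment <- function(image, annotations, config = rcta_config(), k = 1L) {
  stopifnot(inherits(image, "plate_image"), k >= 0)
  annotations <- check_boxes(annotations)
  regions <- find_target_regions(image, config$seg_threshold)
  eligible <- filter_regions(regions, config, img_width(image), img_height(image))
  n_el <- nrow(eligible)
  if (k > n_el)
    warning(sprintf("requested %d covers but only %d eligible regions; covering %d",
                    as.integer(k), n_el, n_el), call. = FALSE)
  n_cover <- min(as.integer(k), n_el)
  perm <- if (n_el) local_seed(config$seed, sample.int(n_el)) else integer(0)
  take <- perm[seq_len(n_cover)]
  a <- unclass(image)
  w <- dim(a)[2L]; h <- dim(a)[1L]
  colors <- vector("list", n_cover)
  # global fallback colour (used when a window holds no background pixel) is
  # computed at most once per call, on the image as of its first use
  fb <- NULL
  for (i in seq_len(n_cover)) {
    reg <- eligible[take[i], , drop = FALSE]
    col <- cover_color_impl(a, reg$xr, reg$yr, config, fallback_color = fb)
    if (col$fallback && is.null(fb)) fb <- c(col$Rmean, col$Gmean, col$Bmean)
    colors[[i]] <- col
    cx <- reg$xr; cy <- reg$yr; r <- reg$radius
    xs <- max(0, floor(cx - r)):min(w - 1, ceiling(cx + r))
    ys <- max(0, floor(cy - r)):min(h - 1, ceiling(cy + r))
    inside <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= r^2
    vals <- as.integer(pmin(pmax(round(c(col$Rmean, col$Gmean, col$Bmean)), 0), 255))
    for (ch in 1:3) {
      sub <- a[ys + 1, xs + 1, ch, drop = FALSE]
      sub[inside] <- vals[ch]
      a[ys + 1, xs + 1, ch] <- sub
    }
  }
  out <- structure(a, class = "plate_image")
  covered <- eligible[take, , drop = FALSE]
  if (nrow(annotations) && n_cover) {
    ctr <- box_centers(annotations)
    hit <- rep(FALSE, nrow(annotations))
    for (i in seq_len(n_cover)) {
      hit <- hit | ((ctr[, 1] - covered$xr[i])^2 + (ctr[, 2] - covered$yr[i])^2
                    <= covered$radius[i]^2)
    }
    annotations <- annotations[!hit, , drop = FALSE]
  }
  structure(list(image = out, annotations = annotations,
                 covered = covered, colors = colors),
            class = "rcta_result")
}

#' @export
print.rcta_result <- function(x, ...) {
  cat(sprintf("<rcta_result: %d targets covered, %d annotation boxes remain>\n",
              nrow(x$covered), nrow(x$annotations)))
  invisible(x)
}
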