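#' Specify a synthetic colony plate
#'
#' Describes the imaging regime of low-cost colony photography in a dark
#' enclosure: a near-black background (channel values kept strictly below
#' the gray-20 background ceiling used throughout the package), low-contrast
#' bright colonies rendered as radially shaded discs, optional
#' overlapping/adherent colony pairs, and an optional bright dish rim near
#' the border. A spec plus its seed fully determines both the colony layout
#' and the rendered raster.
#'
#' @param width,height image size in pixels.
#' @param n_colonies number of colonies to place.
#' @param radius_range integer `(min, max)` colony disc radius in pixels.
#'   The default keeps rendered bright-pixel areas inside the (60, 3500)
#'   px^2 band treated as the effective colony size range.
#' @param background_level mean background gray value (default 12; must be
#'   below 18 so the background stays under the gray-20 ceiling).
#' @param background_noise standard deviation of the background gray noise.
#' @param colony_intensity_range `(min, max)` colony peak gray value.
#' @param overlap_fraction fraction of colonies placed adjacent/overlapping
#'   another colony (in `[0, 1]`); realised as overlapping pairs.
#' @param rim logical; draw a bright dish rim ring near the border.
#' @param rim_brightness gray value of the rim ring.
#' @param seed RNG seed; layout and raster are deterministic given the spec.
#' @return an object of class `plate_spec`.
#' @seealso [sample_layout()], [render_plate()]
#' @export
plate_spec <- function(width, height, n_colonies,
                       radius_range = c(6L, 32L),
                       background_level = 12,
                       background_noise = 3,
                       colony_intensity_range = c(90, 160),
                       overlap_fraction = 0.15,
                       rim = FALSE,
                       rim_brightness = 200,
                       seed = 1L) {
  stopifnot(width > 0, height > 0, n_colonies >= 0,
            length(radius_range) == 2L, radius_range[1] <= radius_range[2],
            radius_range[1] >= 1,
            overlap_fraction >= 0, overlap_fraction <= 1,
            background_noise >= 0,
            length(colony_intensity_range) == 2L,
            colony_intensity_range[1] <= colony_intensity_range[2])
  if (background_level >= colony_intensity_range[1])
    stop("colonies must be brighter than the background", call. = FALSE)
  if (background_level >= 18)
    stop("`background_level` must stay below 18 so background channels remain < 20",
         call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_colonies = as.integer(n_colonies),
                 radius_range = as.integer(radius_range),
                 background_level = background_level,
                 background_noise = background_noise,
                 colony_intensity_range = colony_intensity_range,
                 overlap_fraction = overlap_fraction,
                 rim = isTRUE(rim), rim_brightness = rim_brightness,
                 seed = as.integer(seed)),
            class = "plate_spec")
}

#' @export
print.plate_spec <- function(x, ...) {
  cat(sprintf("<plate_spec %dx%d px, %d colonies (r %d-%d px), overlap %.2f, rim %s, seed %d>\n",
              x$width, x$height, x$n_colonies, x$radius_range[1], x$radius_range[2],
              x$overlap_fraction, if (x$rim) "on" else "off", x$seed))
  invisible(x)
}

# internal: dish placement limits. Centers must keep the whole disc inside
# the image and, when a rim is drawn, inside the rim ring.
placement_bounds <- function(spec, r) {
  lim <- list(xmin = r, xmax = spec$width - r, ymin = r, ymax = spec$height - r)
  if (spec$rim) {
    rim_r <- 0.98 * min(spec$width, spec$height) / 2
    lim$center <- c(spec$width / 2, spec$height / 2)
    lim$max_dist <- rim_r - 3 - r   # stay clear of the 4-px ring
  }
  lim
}

placement_ok <- function(spec, cx, cy, r) {
  if (cx < r || cx > spec$width - r || cy < r || cy > spec$height - r) return(FALSE)
  if (spec$rim) {
    rim_r <- 0.98 * min(spec$width, spec$height) / 2
    d <- sqrt((cx - spec$width / 2)^2 + (cy - spec$height / 2)^2)
    if (d + r > rim_r - 3) return(FALSE)
  }
  TRUE
}

#' Sample a colony layout
#'
#' Places `n_colonies` colony discs inside the dish. A fraction
#' `overlap_fraction` of colonies is laid down as adherent pairs whose
#' center distance is 55-90% of the radius sum; all remaining colonies are
#' kept at least 3 px of clearance from every other disc, so the set of
#' colonies with an overlapping neighbour is exactly the paired ones.
#'
#' @param spec a [plate_spec()].
#' @param max_tries placement attempts per colony before declaring the
#'   layout infeasible.
#' @return an object of class `plate_layout`: a list with `boxes` (ground
#'   truth [box_set()], one tight box per colony disc), `centers` (n x 2
#'   matrix of x, y) and `radii` (integer vector).
#' @export
sample_layout <- function(spec, max_tries = 2000L) {
  stopifnot(inherits(spec, "plate_spec"))
  n <- spec$n_colonies
  out <- local_seed(spec$seed, {
    centers <- matrix(numeric(0), 0L, 2L)
    radii <- integer(0)
    if (n > 0L) {
      n_pairs <- min(round(spec$overlap_fraction * n / 2), n %/% 2L)
      clear <- function(cx, cy, r) {
        !nrow(centers) ||
          all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >= radii + r + 3)
      }
      rvals <- spec$radius_range[1]:spec$radius_range[2]
      draw_r <- function() rvals[sample.int(length(rvals), 1L)]
      place_single <- function(r, near = NULL, near_r = NULL) {
        for (i in seq_len(max_tries)) {
          if (is.null(near)) {
            cx <- round(stats::runif(1, r, spec$width - r))
            cy <- round(stats::runif(1, r, spec$height - r))
          } else {
            d <- stats::runif(1, 0.55, 0.90) * (r + near_r)
            a <- stats::runif(1, 0, 2 * pi)
            cx <- round(near[1] + d * cos(a))
            cy <- round(near[2] + d * sin(a))
          }
          ok_clear <- if (is.null(near)) clear(cx, cy, r) else {
            # the partner may (must) overlap `near` but nothing else
            others <- nrow(centers) > 1L
            d_all <- if (nrow(centers)) sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) else numeric(0)
            keep <- d_all; keep[length(keep)] <- Inf  # partner is last placed
            all(keep >= radii + r + 3)
          }
          if (placement_ok(spec, cx, cy, r) && ok_clear) return(c(cx, cy))
        }
        stop("layout infeasible: could not place colony after ", max_tries,
             " attempts; reduce n_colonies or radii", call. = FALSE)
      }
      for (p in seq_len(n_pairs)) {
        r1 <- draw_r(); c1 <- place_single(r1)
        centers <- rbind(centers, c1); radii <- c(radii, r1)
        r2 <- draw_r(); c2 <- place_single(r2, near = c1, near_r = r1)
        centers <- rbind(centers, c2); radii <- c(radii, r2)
      }
      for (s in seq_len(n - 2L * n_pairs)) {
        r <- draw_r(); cc <- place_single(r)
        centers <- rbind(centers, cc); radii <- c(radii, r)
      }
    }
    list(centers = centers, radii = radii)
  })
  boxes <- if (n > 0L)
    box_set(0L, out$centers[, 1] - out$radii, out$centers[, 2] - out$radii,
            out$centers[, 1] + out$radii, out$centers[, 2] + out$radii)
  else box_set()
  structure(list(boxes = boxes, centers = out$centers, radii = out$radii),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout: %d colonies>\n", length(x$radii)))
  invisible(x)
}

#' Render a plate image from a layout
#'
#' Background gray values are drawn from a clamped normal noise model kept
#' strictly below 18 so that, after the +/-2 per-channel jitter, every
#' background channel stays below the gray-20 ceiling. Colonies are radially
#' shaded discs: flat at their peak brightness out to 80% of the radius,
#' then a cosine falloff to background level at the radius, giving the soft
#' low-contrast edges typical of colonies photographed without contrast
#' enhancement. The three channels are the gray raster plus independent
#' integer jitter in `[-2, 2]`, so per-channel statistics are
#' distinguishable while the image stays grayscale-like.
#'
#' @param spec a [plate_spec()].
#' @param layout a `plate_layout` from [sample_layout()]; defaults to
#'   sampling one from `spec`.
#' @return a [plate_image()]. Deterministic given `(spec, layout)`.
#' @export
render_plate <- function(spec, layout = sample_layout(spec)) {
  stopifnot(inherits(spec, "plate_spec"), inherits(layout, "plate_layout"))
  w <- spec$width; h <- spec$height
  render_seed <- (spec$seed + 499979) %% 2147483647
  local_seed(render_seed, {
    gray <- matrix(stats::rnorm(h * w, spec$background_level, spec$background_noise), h, w)
    gray <- pmin(pmax(gray, 0), 17)
    n <- length(layout$radii)
    peaks <- if (n) stats::runif(n, spec$colony_intensity_range[1],
                                 spec$colony_intensity_range[2]) else numeric(0)
    for (i in seq_len(n)) {
      cx <- layout$centers[i, 1]; cy <- layout$centers[i, 2]; r <- layout$radii[i]
      xs <- max(0L, floor(cx - r)):min(w - 1L, ceiling(cx + r))
      ys <- max(0L, floor(cy - r)):min(h - 1L, ceiling(cy + r))
      d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
      s <- ifelse(d <= 0.8 * r, 1,
                  ifelse(d <= r, (1 + cos(pi * (d - 0.8 * r) / (0.2 * r))) / 2, 0))
      val <- spec$background_level + (peaks[i] - spec$background_level) * s
      sub <- gray[ys + 1L, xs + 1L, drop = FALSE]
      gray[ys + 1L, xs + 1L] <- pmax(sub, val)
    }
    if (spec$rim) {
      rim_r <- 0.98 * min(w, h) / 2
      d <- sqrt(outer((seq_len(h) - 1 - h / 2)^2, (seq_len(w) - 1 - w / 2)^2, `+`))
      gray[abs(d - rim_r) <= 2] <- spec$rim_brightness
    }
    jit <- array(sample(-2:2, h * w * 3L, replace = TRUE), dim = c(h, w, 3L))
    plate_image(array(rep(gray, 3L), dim = c(h, w, 3L)) + jit)
  })
}

#' Generate a synthetic plate with ground truth in one call
#'
#' @param spec a [plate_spec()].
#' @return list with `image` ([plate_image()]), `layout` (`plate_layout`)
#'   and `boxes` (the ground-truth [box_set()]).
#' @examples
#' p <- generate_plate(plate_spec(200, 200, n_colonies = 6, seed = 42))
#' nrow(p$boxes)
#' @export
generate_plate <- function(spec) {
  layout <- sample_layout(spec)
  list(image = render_plate(spec, layout), layout = layout, boxes = layout$boxes)
}
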