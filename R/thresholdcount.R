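#' Simple threshold-segmentation colony counter
#'
#' The classical baseline: grayscale conversion, binarization at `tau`
#' (pixel > tau is a valid target), and one detection per 8-connected
#' foreground component — its bounding box, centroid and pixel area. No
#' filtering of any kind, so every noise speck above the threshold counts,
#' which is exactly the failure mode that motivates the comprehensive
#' variant.
#'
#' @param image a [plate_image()].
#' @param tau gray threshold in (0, 255); plate photographs have too little
#'   colony/background contrast for an automatic threshold to be reliable,
#'   so it must be chosen by the user.
#' @return a data frame of class `detections` with columns `class_id`,
#'   `x1`, `y1`, `x2`, `y2` (half-open component bounding box), `cx`, `cy`
#'   (pixel centroid) and `area` (component pixel count).
#' @export
simple_threshold_count <- function(image, tau) {
  stopifnot(inherits(image, "plate_image"), tau > 0, tau < 255)
  bin <- img_gray(image) > tau
  storage.mode(bin) <- "integer"
  lab <- label_components(bin)
  n <- max(lab)
  out <- data.frame(class_id = integer(n), x1 = numeric(n), y1 = numeric(n),
                    x2 = numeric(n), y2 = numeric(n),
                    cx = numeric(n), cy = numeric(n), area = numeric(n))
  if (n > 0L) {
    idx <- which(lab > 0L)
    rc <- arrayInd(idx, dim(lab))
    labs <- lab[idx]
    xs <- split(rc[, 2L] - 1, labs)   # 0-based x per component
    ys <- split(rc[, 1L] - 1, labs)
    for (i in seq_len(n)) {
      out$x1[i] <- min(xs[[i]]); out$x2[i] <- max(xs[[i]]) + 1
      out$y1[i] <- min(ys[[i]]); out$y2[i] <- max(ys[[i]]) + 1
      out$cx[i] <- mean(xs[[i]]); out$cy[i] <- mean(ys[[i]])
      out$area[i] <- length(xs[[i]])
    }
  }
  class(out) <- c("detections", "data.frame")
  out
}

#' Comprehensive (area-filtered) threshold colony counter
#'
#' [simple_threshold_count()] followed by the size-selection step: only
#' components with `min_area < area < max_area` (strict bounds, the same
#' open-interval convention used for the augmentation's effective range)
#' are kept. This removes small noise specks but still merges adherent
#' colony pairs into one component — and drops them entirely once the fused
#' area exceeds `max_area`.
#'
#' @inheritParams simple_threshold_count
#' @param min_area,max_area pixel-area band, `0 <= min_area < max_area`
#'   (`max_area` may be `Inf`).
#' @return a `detections` data frame, a subset of the simple counter's rows.
#' @export
comprehensive_threshold_count <- function(image, tau, min_area = 60, max_area = 3500) {
  stopifnot(min_area >= 0, min_area < max_area)
  det <- simple_threshold_count(image, tau)
  det[det$area > min_area & det$area < max_area, , drop = FALSE]
}
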