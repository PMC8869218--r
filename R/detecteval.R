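#' Match detections against ground truth
#'
#' One-to-one matching of predicted detections to ground-truth boxes,
#' producing the confusion counts used by the counting metrics. Two rules:
#'
#' * `"iou-greedy"` (default): all candidate pairs with intersection-over-
#'   union at least `iou_threshold` are sorted by IoU descending (ties
#'   broken by prediction then truth index) and accepted greedily, each
#'   prediction and truth at most once.
#' * `"center-in-box"`: predictions, in order, match the first unmatched
#'   truth box containing their centroid — for centroid-only counters.
#'
#' `TN` is fixed at 0: background is not an enumerable negative class in
#' colony counting, so true negatives are conventionally undefined and
#' dropped from the accuracy formula.
#'
#' @param predicted a `detections` data frame (needs `x1, y1, x2, y2`, and
#'   `cx, cy` for the center rule; centroids default to box centers).
#' @param truth a [box_set()] of ground-truth boxes.
#' @param rule matching rule, `"iou-greedy"` or `"center-in-box"`.
#' @param iou_threshold minimum IoU for a greedy match (default 0.5).
#' @return object of class `confusion_counts`: list with integers `TP`,
#'   `FP`, `FN`, `TN` (= 0).
#' @export
match_detections <- function(predicted, truth,
                             rule = c("iou-greedy", "center-in-box"),
                             iou_threshold = 0.5) {
  rule <- match.arg(rule)
  truth <- check_boxes(truth)
  np <- nrow(predicted); nt <- nrow(truth)
  tp <- 0L
  if (np > 0L && nt > 0L) {
    if (rule == "iou-greedy") {
      iou <- matrix(0, np, nt)
      for (i in seq_len(np)) {
        ix1 <- pmax(predicted$x1[i], truth$x1); iy1 <- pmax(predicted$y1[i], truth$y1)
        ix2 <- pmin(predicted$x2[i], truth$x2); iy2 <- pmin(predicted$y2[i], truth$y2)
        inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
        a1 <- (predicted$x2[i] - predicted$x1[i]) * (predicted$y2[i] - predicted$y1[i])
        a2 <- (truth$x2 - truth$x1) * (truth$y2 - truth$y1)
        iou[i, ] <- inter / (a1 + a2 - inter)
      }
      cand <- which(iou >= iou_threshold, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(-iou[cand], cand[, 1L], cand[, 2L])
        cand <- cand[ord, , drop = FALSE]
        p_used <- logical(np); t_used <- logical(nt)
        for (r in seq_len(nrow(cand))) {
          pi <- cand[r, 1L]; ti <- cand[r, 2L]
          if (!p_used[pi] && !t_used[ti]) {
            p_used[pi] <- t_used[ti] <- TRUE
            tp <- tp + 1L
          }
        }
      }
    } else {
      cx <- if ("cx" %in% names(predicted)) predicted$cx else (predicted$x1 + predicted$x2) / 2
      cy <- if ("cy" %in% names(predicted)) predicted$cy else (predicted$y1 + predicted$y2) / 2
      t_used <- logical(nt)
      for (i in seq_len(np)) {
        hit <- which(!t_used & cx[i] >= truth$x1 & cx[i] < truth$x2 &
                       cy[i] >= truth$y1 & cy[i] < truth$y2)
        if (length(hit)) { t_used[hit[1L]] <- TRUE; tp <- tp + 1L }
      }
    }
  }
  confusion_counts(TP = tp, FP = np - tp, FN = nt - tp)
}

#' Confusion counts for colony counting
#'
#' @param TP,FP,FN non-negative counts of matched detections, spurious
#'   detections and missed colonies. `TN` is fixed at 0 by convention.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  structure(list(TP = as.integer(TP), FP = as.integer(FP),
                 FN = as.integer(FN), TN = 0L),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts TP=%d FP=%d FN=%d TN=%d>\n", x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Counting metrics from confusion counts
#'
#' With `TN = 0` the counting metrics are
#' `ACC = TP / (TP + FP + FN)` (average accuracy),
#' `TPR = TP / (TP + FN)` (true positive rate, recall) and
#' `FNR = FN / (TP + FN)` (false negative rate), so `TPR + FNR = 1`
#' exactly, and `ACC <= TPR` with equality only when `FP = 0`.
#'
#' @param counts a [confusion_counts()] (a plain list with `TP`, `FP`,
#'   `FN`, `TN` also works).
#' @return object of class `metric_set`: list with `ACC`, `TPR`, `FNR`.
#' @examples
#' m <- compute_metrics(confusion_counts(TP = 3327, FP = 279, FN = 1571))
#' round(100 * m$ACC, 1)  # 64.3
#' @export
compute_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  tn <- if (is.null(counts$TN)) 0 else counts$TN
  if (tp + fn == 0)
    stop("undefined metrics: TP + FN = 0 (no positive targets)", call. = FALSE)
  structure(list(ACC = (tn + tp) / (tn + tp + fn + fp),
                 TPR = tp / (tp + fn),
                 FNR = fn / (tp + fn)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("ACC %.1f%%  TPR %.1f%%  FNR %.1f%%\n",
              100 * x$ACC, 100 * x$TPR, 100 * x$FNR))
  invisible(x)
}

#' Per-colony size statistics from annotation boxes
#'
#' From each detection box, width `x2 - x1`, height `y2 - y1` and area
#' `width * height`, plus a histogram of areas over half-open bins
#' `[edge_i, edge_{i+1})`. Areas falling outside the given edges are
#' reported separately as `n_below` / `n_above` rather than clamped; when
#' the edges cover the data the histogram counts sum to the box count.
#'
#' @param boxes a [box_set()].
#' @param bin_edges ascending numeric vector of area bin edges.
#' @return object of class `size_stats`: list with `widths`, `heights`,
#'   `areas`, `histogram` (named integer vector, one entry per bin),
#'   `bin_edges`, `n_below`, `n_above`.
#' @export
colony_size_stats <- function(boxes, bin_edges) {
  boxes <- check_boxes(boxes)
  stopifnot(length(bin_edges) >= 2L, !is.unsorted(bin_edges, strictly = TRUE))
  widths <- boxes$x2 - boxes$x1
  heights <- boxes$y2 - boxes$y1
  areas <- widths * heights
  nb <- length(bin_edges) - 1L
  counts <- integer(nb)
  if (length(areas)) {
    bin <- findInterval(areas, bin_edges)       # 0 below, nb + 1 at/above last edge
    inb <- bin >= 1L & bin <= nb
    tab <- tabulate(bin[inb], nbins = nb)
    counts <- as.integer(tab)
  }
  names(counts) <- sprintf("[%g,%g)", bin_edges[-length(bin_edges)], bin_edges[-1L])
  structure(list(widths = widths, heights = heights, areas = areas,
                 histogram = counts, bin_edges = bin_edges,
                 n_below = if (length(areas)) sum(areas < bin_edges[1L]) else 0L,
                 n_above = if (length(areas)) sum(areas >= bin_edges[length(bin_edges)]) else 0L),
            class = "size_stats")
}

#' @export
print.size_stats <- function(x, ...) {
  cat(sprintf("<size_stats: %d boxes, mean area %.1f px^2>\n",
              length(x$areas), if (length(x$areas)) mean(x$areas) else NA_real_))
  print(x$histogram)
  invisible(x)
}
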