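#' Classical reference plant detector
#'
#' A colour-based detector for synthetic bed scenes that fills the same
#' contract as a learned detector: it returns a confidence-ranked box
#' table and nothing downstream depends on how the boxes were produced.
#' The image is first normalised per channel by its 99th percentile,
#' which cancels multiplicative LED colour casts; a green-foliage mask is
#' then thresholded (green dominating red and blue after normalisation),
#' connected components are labelled, and each sufficiently large
#' component yields a tight box with confidence
#' `min(1, area / reference_area)`. Near-black frames (mean luminance
#' below `dark_cap`) return no detections.
#'
#' @param image Numeric `h x w x 3` array in `[0, 1]`.
#' @param min_area_px Minimum component area in pixels; smaller blobs are
#'   treated as noise.
#' @param reference_area Component area at which confidence saturates
#'   at 1.
#' @param dark_cap Mean-luminance threshold below which the frame is
#'   considered a dark (lights-off) frame.
#' @return A box table (see [boxes()]) sorted by decreasing confidence;
#'   zero rows when nothing is detected.
#' @export
reference_detect <- function(image, min_area_px = 120,
                             reference_area = 350, dark_cap = 0.05) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("reference_detect requires a 3-channel RGB raster", call. = FALSE)
  if (mean(image) < dark_cap) return(empty_boxes())
  h <- dim(image)[1]; w <- dim(image)[2]
  norm <- image
  for (ch in 1:3) {
    q <- stats::quantile(image[, , ch], 0.99, names = FALSE)
    norm[, , ch] <- image[, , ch] / max(q, 1e-6)
  }
  g <- norm[, , 2]
  mask <- (g > 1.15 * norm[, , 1]) & (g > 1.15 * norm[, , 3]) & (g > 0.2)
  if (!any(mask)) return(empty_boxes())
  # close small gaps (noise holes, thin leaf tips) before labelling
  mask <- EBImage::closing(mask * 1, EBImage::makeBrush(5, "disc"))
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab == 0) return(empty_boxes())
  idx <- which(lab > 0)
  comp <- lab[idx]
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  area <- tabulate(comp, nlab)
  keep <- which(area >= min_area_px)
  if (length(keep) == 0) return(empty_boxes())
  x1 <- tapply(cols, comp, min)[keep] - 1
  x2 <- tapply(cols, comp, max)[keep]
  y1 <- tapply(rows, comp, min)[keep] - 1
  y2 <- tapply(rows, comp, max)[keep]
  b <- boxes(x1, y1, x2, y2, conf = pmin(1, area[keep] / reference_area))
  b <- b[order(-b$conf), , drop = FALSE]
  rownames(b) <- NULL
  b
}

#' Match predicted boxes against ground truth
#'
#' Greedy one-to-one matching: predictions are visited in order of
#' decreasing confidence and each is assigned to the unmatched truth box
#' with the highest IoU, provided that IoU reaches `iou_thresh`. Each
#' truth box is matched at most once. Precision is defined as 1 when
#' there are no predictions (needed for confidence-threshold sweeps).
#'
#' @param preds,truths Box tables (see [boxes()]).
#' @param iou_thresh IoU threshold in `(0, 1]`.
#' @return An object of class `match_result` with counts `tp`, `fp`,
#'   `fn`, a `pairs` data.frame (`pred_idx`, `truth_idx`, `iou`) and
#'   `precision`, `recall`, `f1`.
#' @export
match_boxes <- function(preds, truths, iou_thresh = 0.5) {
  stopifnot(iou_thresh > 0, iou_thresh <= 1)
  np <- nrow(preds); nt <- nrow(truths)
  ord <- if (np > 0) order(-preds$conf) else integer(0)
  used <- rep(FALSE, nt)
  pairs <- list()
  if (np > 0 && nt > 0) {
    m <- iou_matrix(preds, truths)
    for (i in ord) {
      cand <- which(!used & m[i, ] >= iou_thresh)
      if (length(cand) == 0) next
      j <- cand[which.max(m[i, cand])]
      used[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(pred_idx = i, truth_idx = j,
                                                iou = m[i, j])
    }
  }
  pairs <- if (length(pairs) > 0) do.call(rbind, pairs) else
    data.frame(pred_idx = integer(0), truth_idx = integer(0),
               iou = numeric(0))
  tp <- nrow(pairs)
  detection_summary(tp = tp, fp = np - tp, fn = nt - tp, pairs = pairs)
}

#' Precision, recall and F1 from detection counts
#'
#' @param tp,fp,fn True-positive, false-positive and false-negative
#'   counts.
#' @param pairs Optional matched-pair table (as in [match_boxes()]).
#' @return A `match_result` object.
#' @examples
#' s <- detection_summary(tp = 352, fp = 0, fn = 1)
#' s$precision  # 1
#' s$recall     # 352/353
#' @export
detection_summary <- function(tp, fp, fn, pairs = NULL) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(tp = tp, fp = fp, fn = fn, pairs = pairs,
                 precision = precision, recall = recall, f1 = f1),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Detection match: TP=%d FP=%d FN=%d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' F1-confidence curve and optimal threshold
#'
#' Sweeps candidate confidence thresholds over the observed prediction
#' confidences (plus 0); at each threshold only predictions with
#' confidence at or above it are kept, matching is re-run per image, and
#' the aggregated F1 is recorded. The returned optimum is the threshold
#' maximising F1, with ties broken in favour of the highest threshold
#' (so the weakest acceptable detections are cut).
#'
#' @param preds List of box tables, one per image.
#' @param truths List of box tables, one per image (same length).
#' @param iou_thresh IoU threshold for matching.
#' @return A list with `curve` (`data.frame` of `threshold`, `f1`,
#'   `precision`, `recall`) and `best_threshold`.
#' @export
f1_confidence_curve <- function(preds, truths, iou_thresh = 0.5) {
  stopifnot(length(preds) == length(truths))
  all_conf <- unlist(lapply(preds, function(b) b$conf))
  if (length(all_conf) == 0)
    stop("at least one prediction is required", call. = FALSE)
  if (sum(vapply(truths, nrow, integer(1))) == 0)
    stop("F1 is undefined without any ground-truth boxes", call. = FALSE)
  thr <- sort(unique(c(0, all_conf)))
  rows <- lapply(thr, function(t) {
    tp <- fp <- fn <- 0
    for (i in seq_along(preds)) {
      keep <- preds[[i]][preds[[i]]$conf >= t, , drop = FALSE]
      m <- match_boxes(keep, truths[[i]], iou_thresh)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    s <- detection_summary(tp, fp, fn)
    data.frame(threshold = t, f1 = s$f1, precision = s$precision,
               recall = s$recall)
  })
  curve <- do.call(rbind, rows)
  best <- max(curve$threshold[curve$f1 >= max(curve$f1) - 1e-12])
  list(curve = curve, best_threshold = best)
}

#' Average precision and mAP
#'
#' All-point interpolated precision-recall integration, the standard
#' single-class detection metric: predictions are pooled across images,
#' sorted by decreasing confidence, greedily matched within their image,
#' and AP is the sum over recall steps of the interpolated precision
#' (the maximum precision at any recall at least as large).
#' `mAP@0.5:0.95` averages AP over IoU thresholds 0.50 to 0.95 in steps
#' of 0.05.
#'
#' @param preds,truths Lists of per-image box tables.
#' @param iou_thresholds Numeric vector of IoU thresholds; AP is computed
#'   at each and averaged into `map`.
#' @return A list with `ap` (named by threshold) and `map` (their mean).
#' @export
average_precision <- function(preds, truths,
                              iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  stopifnot(length(preds) == length(truths))
  n_truth <- sum(vapply(truths, nrow, integer(1)))
  ap <- vapply(iou_thresholds, function(t) {
    ap_single(preds, truths, t, n_truth)
  }, numeric(1))
  names(ap) <- sprintf("%.2f", iou_thresholds)
  list(ap = ap, map = mean(ap))
}

ap_single <- function(preds, truths, iou_thresh, n_truth) {
  if (n_truth == 0) return(NA_real_)
  flat <- list()
  for (i in seq_along(preds)) {
    b <- preds[[i]]
    if (nrow(b) > 0)
      flat[[length(flat) + 1L]] <- cbind(b, image = i,
                                         idx = seq_len(nrow(b)))
  }
  if (length(flat) == 0) return(0)
  flat <- do.call(rbind, flat)
  flat <- flat[order(-flat$conf), , drop = FALSE]
  used <- lapply(truths, function(t) rep(FALSE, nrow(t)))
  is_tp <- logical(nrow(flat))
  for (k in seq_len(nrow(flat))) {
    i <- flat$image[k]
    tt <- truths[[i]]
    if (nrow(tt) == 0) next
    ious <- iou(flat[k, , drop = FALSE], tt)
    cand <- which(!used[[i]] & ious >= iou_thresh)
    if (length(cand) == 0) next
    j <- cand[which.max(ious[cand])]
    used[[i]][j] <- TRUE
    is_tp[k] <- TRUE
  }
  tp_cum <- cumsum(is_tp)
  fp_cum <- cumsum(!is_tp)
  recall <- tp_cum / n_truth
  precision <- tp_cum / (tp_cum + fp_cum)
  # all-point interpolation: running max of precision from the right
  p_interp <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * p_interp)
}

#' Replay detector built from ground truth
#'
#' Returns a detector function that, given a scene index, replays the
#' ground-truth boxes of a corpus with confidence 1. Used to isolate the
#' downstream pipeline from detection error and to demonstrate that any
#' detector honouring the box contract can be plugged in.
#'
#' @param corpus A `scene_corpus` from [make_corpus()].
#' @return A function `f(scene_id)` returning a box table.
#' @export
replay_detector <- function(corpus) {
  force(corpus)
  function(scene_id) {
    b <- corpus$truth[[scene_id]]$boxes
    rownames(b) <- NULL
    b
  }
}

#' Read or write detections as CSV
#'
#' The on-disk exchange format for plugging in an external detector:
#' columns `scene_id, x1, y1, x2, y2, conf`.
#'
#' @param path CSV path.
#' @param dets A `data.frame` with the columns above.
#' @return `read_detections` returns a named list of box tables keyed by
#'   `scene_id`; `write_detections` returns `path` invisibly.
#' @export
read_detections <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("scene_id", "x1", "y1", "x2", "y2", "conf") %in% names(d)))
  split_ids <- split(d, d$scene_id)
  lapply(split_ids, function(s)
    boxes(s$x1, s$y1, s$x2, s$y2, s$conf))
}

#' @rdname read_detections
#' @export
write_detections <- function(dets, path) {
  utils::write.csv(dets, path, row.names = FALSE)
  invisible(path)
}
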