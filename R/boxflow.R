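#' Confidence filtering of detections
#'
#' Keeps only boxes whose confidence lies strictly above the threshold
#' ("above this value"), preserving the original relative order. Applied
#' before nested-box removal in the default pipeline; the two steps do
#' not commute in general.
#'
#' @param b Box table.
#' @param threshold Confidence threshold in `[0, 1]`; the pipeline
#'   default is 0.706, chosen from the F1-confidence curve.
#' @return The filtered box table.
#' @export
filter_confidence <- function(b, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  out <- b[b$conf > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nested-box removal
#'
#' When one detection lies (almost) entirely inside another, the smaller
#' box is removed: box A is dropped iff some kept box B with
#' `area(B) >= area(A)` contains A once B is expanded by `tolerance_px`
#' on all four sides. Boxes are processed largest-area first (ties broken
#' by higher confidence), so the survivor of any nested cluster is its
#' largest member; the operation is idempotent and its output is pairwise
#' non-nested at the given tolerance.
#'
#' The default 10-pixel tolerance is expressed at the native resolution
#' of the frames being processed; configurations that rescale frames must
#' set it explicitly.
#'
#' @param b Box table.
#' @param tolerance_px Non-negative slack in pixels.
#' @return Box table with nested boxes removed, in original relative
#'   order.
#' @export
remove_nested <- function(b, tolerance_px = 10) {
  stopifnot(tolerance_px >= 0)
  n <- nrow(b)
  if (n <= 1) return(b)
  area <- box_area(b)
  conf <- if ("conf" %in% names(b)) b$conf else rep(1, n)
  ord <- order(-area, -conf)
  kept <- integer(0)
  removed <- logical(n)
  t <- tolerance_px
  for (i in ord) {
    nested <- FALSE
    for (j in kept) {
      if (area[j] >= area[i] &&
          b$x1[i] >= b$x1[j] - t && b$y1[i] >= b$y1[j] - t &&
          b$x2[i] <= b$x2[j] + t && b$y2[i] <= b$y2[j] + t) {
        nested <- TRUE
        break
      }
    }
    if (nested) removed[i] <- TRUE else kept <- c(kept, i)
  }
  out <- b[!removed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact-count gate
#'
#' Frames are only admitted when the detector returned exactly the
#' expected number of plants; otherwise the frame is skipped (reason
#' `"wrong_count"`) so that box-to-pot label pairing can never be
#' misaligned. The per-stage box counts are recorded so skip accounting
#' across preprocessing variants can be tabulated later.
#'
#' @param b Box table after preprocessing.
#' @param expected Expected number of plants (>= 1).
#' @param counts Optional named integer vector of box counts observed at
#'   earlier pipeline stages (e.g. `c(raw = 10, thresholded = 9)`),
#'   carried into the returned record.
#' @return A list with `boxes`, `skip_reason` (`"none"` or
#'   `"wrong_count"`) and `counts`.
#' @export
enforce_count <- function(b, expected = 8, counts = NULL) {
  stopifnot(expected >= 1)
  counts <- c(counts, c(final = nrow(b)))
  if (nrow(b) == expected) {
    list(boxes = b, skip_reason = "none", counts = counts)
  } else {
    list(boxes = empty_boxes(), skip_reason = "wrong_count",
         counts = counts)
  }
}

#' Order detected plants into a stable reading order
#'
#' Assigns each box its pot label by clustering the vertical box centers
#' `cy` into `n_rows` rows with one-dimensional K-means (deterministic
#' quantile initialisation), ordering rows top to bottom by mean `cy`,
#' and sorting boxes within each row left to right by `cx`. Ties on `cx`
#' are broken by `cy`, then by input position. The result is invariant to
#' permutations of the input and deterministic for a fixed seed.
#'
#' @param b Box table with at least `n_rows` rows.
#' @param n_rows Number of plant rows (default 3: top, middle, bottom).
#' @param seed Integer seed (K-means is deterministically initialised;
#'   the seed guards the underlying optimiser).
#' @return An object of class `ordered_layout`: a list with `boxes` (in
#'   final label order), `row_of` (row index per box, 1 = top),
#'   `input_index` (position of each ordered box in the input) and
#'   `skip_reason` (`"none"` or `"degenerate_rows"`).
#' @export
order_instances <- function(b, n_rows = 3, seed = 1L) {
  if (nrow(b) < n_rows)
    return(structure(list(boxes = empty_boxes(), row_of = integer(0),
                          input_index = integer(0),
                          skip_reason = "degenerate_rows"),
                     class = "ordered_layout"))
  ctr <- box_centers(b)
  cy <- ctr$cy
  if (n_rows == 1L) {
    cl <- rep(1L, nrow(b))
  } else {
    init <- stats::quantile(cy, probs = (2 * seq_len(n_rows) - 1) /
                              (2 * n_rows), names = FALSE)
    if (anyDuplicated(init)) init <- seq(min(cy), max(cy),
                                         length.out = n_rows)
    if (anyDuplicated(init))
      return(structure(list(boxes = empty_boxes(), row_of = integer(0),
                            input_index = integer(0),
                            skip_reason = "degenerate_rows"),
                       class = "ordered_layout"))
    km <- with_seed(seed, suppressWarnings(
      stats::kmeans(cy, centers = matrix(init, ncol = 1))))
    cl <- km$cluster
    if (length(unique(cl)) < n_rows)
      return(structure(list(boxes = empty_boxes(), row_of = integer(0),
                            input_index = integer(0),
                            skip_reason = "degenerate_rows"),
                       class = "ordered_layout"))
  }
  # relabel clusters by ascending mean cy (row 1 = top)
  mean_cy <- tapply(cy, cl, mean)
  row_rank <- rank(mean_cy, ties.method = "first")
  row_of_input <- row_rank[as.character(cl)]
  ord <- order(row_of_input, ctr$cx, cy, seq_len(nrow(b)))
  out <- b[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(boxes = out, row_of = as.integer(row_of_input[ord]),
                 input_index = ord, skip_reason = "none"),
            class = "ordered_layout")
}

#' @export
print.ordered_layout <- function(x, ...) {
  if (x$skip_reason != "none") {
    cat("Ordered layout: skipped (", x$skip_reason, ")\n", sep = "")
  } else {
    cat("Ordered layout:", nrow(x$boxes), "boxes in",
        length(unique(x$row_of)), "rows\n")
  }
  invisible(x)
}

#' Full box post-processing chain
#'
#' The default preprocessing applied to raw detections before cropping:
#' confidence filtering (strictly above `conf_threshold`), nested-box
#' removal, the exact-count gate and row ordering, in that order.
#'
#' @param b Raw box table from a detector.
#' @param conf_threshold Confidence threshold.
#' @param tolerance_px Nested-box tolerance.
#' @param expected Expected plant count.
#' @param n_rows Number of rows for ordering.
#' @param seed Seed forwarded to [order_instances()].
#' @return An `ordered_layout` (possibly skipped) whose `counts` element
#'   records the box count after each stage (`raw`, `thresholded`,
#'   `denested`, `final`).
#' @export
postprocess_boxes <- function(b, conf_threshold = 0.706, tolerance_px = 10,
                              expected = 8, n_rows = 3, seed = 1L) {
  counts <- c(raw = nrow(b))
  b <- filter_confidence(b, conf_threshold)
  counts <- c(counts, thresholded = nrow(b))
  b <- remove_nested(b, tolerance_px)
  counts <- c(counts, denested = nrow(b))
  gate <- enforce_count(b, expected, counts = counts)
  if (gate$skip_reason != "none") {
    lay <- structure(list(boxes = empty_boxes(), row_of = integer(0),
                          input_index = integer(0),
                          skip_reason = gate$skip_reason),
                     class = "ordered_layout")
    lay$counts <- gate$counts
    return(lay)
  }
  lay <- order_instances(gate$boxes, n_rows = n_rows, seed = seed)
  lay$counts <- gate$counts
  lay
}
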