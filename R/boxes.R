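#' Construct a table of bounding boxes
#'
#' Boxes are the currency passed between the detector, the post-processing
#' steps and the cropper. They are stored as a plain `data.frame` with one
#' row per box and columns `x1, y1, x2, y2, conf`. Coordinates are
#' continuous pixels with the origin at the top-left corner and the y axis
#' pointing down; `(x1, y1)` is the top-left corner, `(x2, y2)` the
#' bottom-right, so `x1 < x2` and `y1 < y2`. Crop extraction uses the
#' half-open integer convention `[floor(x1), ceiling(x2))` (and likewise in
#' y), which maps exactly onto 1-based pixel columns
#' `floor(x1) + 1 .. ceiling(x2)`.
#'
#' @param x1,y1,x2,y2 Numeric vectors of box corners (recycled to a common
#'   length).
#' @param conf Detection confidence in `[0, 1]`; defaults to 1.
#' @return A `data.frame` with columns `x1, y1, x2, y2, conf`.
#' @examples
#' boxes(c(0, 10), c(0, 10), c(5, 20), c(5, 20), conf = c(0.9, 0.8))
#' @export
boxes <- function(x1, y1, x2, y2, conf = 1) {
  b <- data.frame(x1 = as.numeric(x1), y1 = as.numeric(y1),
                  x2 = as.numeric(x2), y2 = as.numeric(y2),
                  conf = as.numeric(conf))
  validate_boxes(b)
  b
}

#' @keywords internal
validate_boxes <- function(b) {
  stopifnot(is.data.frame(b))
  need <- c("x1", "y1", "x2", "y2")
  if (!all(need %in% names(b)))
    stop("box table must have columns x1, y1, x2, y2", call. = FALSE)
  if (nrow(b) > 0 && any(b$x1 >= b$x2 | b$y1 >= b$y2))
    stop("degenerate box: require x1 < x2 and y1 < y2", call. = FALSE)
  invisible(b)
}

empty_boxes <- function() {
  data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
             y2 = numeric(0), conf = numeric(0))
}

box_area <- function(b) {
  (b$x2 - b$x1) * (b$y2 - b$y1)
}

#' Box centers
#'
#' Center coordinates of each box, `cx = (x1 + x2) / 2`,
#' `cy = (y1 + y2) / 2`. The vertical center `cy` drives row clustering
#' and the horizontal center `cx` the left-to-right ordering within a row.
#'
#' @param b A box table (see [boxes()]).
#' @return A `data.frame` with columns `cx`, `cy`.
#' @export
box_centers <- function(b) {
  data.frame(cx = (b$x1 + b$x2) / 2, cy = (b$y1 + b$y2) / 2)
}

#' Intersection over union of two boxes
#'
#' The standard overlap ratio used to match detections against ground
#' truth: area of the intersection rectangle divided by the area of the
#' union. Returns 0 for disjoint boxes and 1 only for identical boxes.
#'
#' @param a,b Single-row box tables, or lists/vectors with named elements
#'   `x1, y1, x2, y2`.
#' @return A number in `[0, 1]`.
#' @examples
#' a <- boxes(0, 0, 2, 2)
#' b <- boxes(1, 0, 3, 2)
#' iou(a, b)  # 2 / 6
#' @export
iou <- function(a, b) {
  ix <- pmin(a$x2, b$x2) - pmax(a$x1, b$x1)
  iy <- pmin(a$y2, b$y2) - pmax(a$y1, b$y1)
  inter <- pmax(ix, 0) * pmax(iy, 0)
  u <- box_area(a) + box_area(b) - inter
  ifelse(u > 0, inter / u, 0)
}

#' Pairwise IoU matrix
#'
#' @param a,b Box tables with `nrow(a)` and `nrow(b)` rows.
#' @return A `nrow(a)` x `nrow(b)` matrix of IoU values.
#' @export
iou_matrix <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  m <- matrix(0, na, nb)
  if (na == 0L || nb == 0L) return(m)
  for (i in seq_len(na)) {
    m[i, ] <- iou(a[i, , drop = FALSE], b)
  }
  m
}
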