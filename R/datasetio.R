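#' Frame-level exclusion rules
#'
#' Applies the frame exclusion taxonomy used when assembling the training
#' corpus. Excluded are: frames with multiple seedlings in one pot
#' (inseparable individuals), dark frames (mean luminance below
#' `dark_cap`, tested photometrically so untagged dark frames are caught
#' too), frames where a plant extends more than half outside the field
#' of view or hides its shoot apex, and frames with fewer than the
#' expected number of plants (failed germination). Frames whose plants
#' merely lost leaves are *kept* -- leaf loss is handled by the effective
#' pair count, not by exclusion.
#'
#' @param corpus A `scene_corpus` from [make_corpus()].
#' @param expected Expected number of plants per frame.
#' @param dark_cap Mean-luminance exclusion threshold.
#' @param out_margin Fraction of a truth box that may lie outside the
#'   frame before the frame is excluded (default 0.5).
#' @return A list with `kept` (integer scene ids), `log` (a `data.frame`
#'   of `scene_id`, `reason` for every excluded frame).
#' @export
exclude_frames <- function(corpus, expected = 8, dark_cap = 0.05,
                           out_margin = 0.5) {
  n <- nrow(corpus$scenes)
  wh <- if (!is.null(corpus$image_wh)) corpus$image_wh else c(820, 616)
  reasons <- character(n)
  for (i in seq_len(n)) {
    tr <- corpus$truth[[i]]
    anom <- tr$anomaly
    reason <- ""
    if (corpus$scenes$mean_luminance[i] < dark_cap) {
      reason <- "dark_frame"
    } else if (anom == "multi_seedling") {
      reason <- "multi_seedling"
    } else if (nrow(tr$boxes) > 0 &&
               any(outside_fraction(tr$boxes, wh) > out_margin |
                   !tr$visible)) {
      reason <- "out_of_frame"
    } else if (nrow(tr$boxes) < expected) {
      reason <- "empty_pot"
    }
    reasons[i] <- reason
  }
  log <- data.frame(scene_id = corpus$scenes$scene_id[reasons != ""],
                    reason = reasons[reasons != ""])
  list(kept = corpus$scenes$scene_id[reasons == ""], log = log)
}

# fraction of each box's area lying outside the frame; frame dims are
# taken from the rendered image size recorded at corpus build time
outside_fraction <- function(b, image_wh = c(820, 616)) {
  w <- image_wh[1]; h <- image_wh[2]
  full <- box_area(b)
  ix <- pmax(0, pmin(b$x2, w) - pmax(b$x1, 0))
  iy <- pmax(0, pmin(b$y2, h) - pmax(b$y1, 0))
  1 - (ix * iy) / full
}

#' Crop ordered instances out of a frame
#'
#' Extracts one crop per box of an ordered layout, in label order, using
#' the half-open integer pixel convention
#' `[floor(x1), ceiling(x2)) x [floor(y1), ceiling(y2))`. Boxes reaching
#' outside the image are clipped to the frame with a warning. Crops are
#' optionally resized to a square side for model input.
#'
#' @param image Numeric `h x w x 3` array.
#' @param layout An `ordered_layout` (must not be skipped), or a plain
#'   box table.
#' @param side `NULL` to keep native crop sizes, or an integer square
#'   side to resize each crop to (bilinear).
#' @return A list of numeric crop arrays.
#' @export
crop_instances <- function(image, layout, side = 128) {
  b <- if (inherits(layout, "ordered_layout")) {
    if (layout$skip_reason != "none")
      stop("cannot crop a skipped layout", call. = FALSE)
    layout$boxes
  } else layout
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- vector("list", nrow(b))
  for (i in seq_len(nrow(b))) {
    c1 <- floor(b$x1[i]) + 1L; c2 <- ceiling(b$x2[i])
    r1 <- floor(b$y1[i]) + 1L; r2 <- ceiling(b$y2[i])
    if (c1 < 1L || r1 < 1L || c2 > w || r2 > h) {
      warning("box ", i, " extends outside the image; clipped to frame")
      c1 <- max(1L, c1); r1 <- max(1L, r1)
      c2 <- min(w, c2); r2 <- min(h, r2)
    }
    crop <- image[r1:r2, c1:c2, , drop = FALSE]
    if (!is.null(side))
      crop <- EBImage::resize(crop, w = side, h = side)
    out[[i]] <- crop
  }
  out
}

#' Build a cropped-instance dataset from a corpus
#'
#' Runs the full dataset-construction pipeline over a synthetic corpus:
#' frame exclusion, detection (or ground-truth replay), box
#' post-processing, cropping, and pairing of each crop with its
#' ground-truth effective leaf-pair label by reading order. Crops can be
#' written to disk as PNGs (with a manifest CSV) or kept in memory.
#'
#' @param corpus A `scene_corpus`.
#' @param detector `"replay"` to replay ground-truth boxes, or a function
#'   `f(image)` returning a box table.
#' @param out_dir Directory for crop PNGs and `manifest.csv`, or `NULL`
#'   to keep crops in memory.
#' @param side Square crop side in pixels.
#' @param conf_threshold,tolerance_px,expected,n_rows Post-processing
#'   parameters, see [postprocess_boxes()].
#' @param seed Seed forwarded to ordering.
#' @return A list with `manifest` (see [write_manifest()]), `crops`
#'   (list of arrays when `out_dir` is `NULL`), `skips` (skip log
#'   `data.frame`) and `exclusions` (frame exclusion log).
#' @export
build_dataset <- function(corpus, detector = "replay", out_dir = NULL,
                          side = 128, conf_threshold = 0.706,
                          tolerance_px = 10, expected = 8, n_rows = 3,
                          seed = 1L) {
  excl <- exclude_frames(corpus, expected = expected)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  replay <- identical(detector, "replay")
  man_rows <- list(); crops_out <- list(); skip_rows <- list()
  for (i in excl$kept) {
    img <- corpus_image(corpus, i)
    tr <- corpus$truth[[i]]
    raw <- if (replay) tr$boxes else detector(img)
    lay <- postprocess_boxes(raw, conf_threshold = conf_threshold,
                             tolerance_px = tolerance_px,
                             expected = expected, n_rows = n_rows,
                             seed = seed)
    if (lay$skip_reason != "none") {
      skip_rows[[length(skip_rows) + 1L]] <-
        data.frame(scene_id = i, skip_reason = lay$skip_reason,
                   t(lay$counts))
      next
    }
    # pair crops with labels: truth pairs indexed by ground-truth reading
    # order; the ordered layout is matched to truth boxes by max IoU
    m <- iou_matrix(lay$boxes, tr$boxes)
    truth_idx <- apply(m, 1, which.max)
    labels <- tr$pairs[truth_idx]
    crops <- crop_instances(img, lay, side = side)
    for (k in seq_along(crops)) {
      crop_path <- NA_character_
      if (!is.null(out_dir)) {
        crop_path <- file.path(out_dir,
                               sprintf("crop_%04d_%d.png", i, k))
        png::writePNG(crops[[k]], crop_path)
      } else {
        crops_out[[length(crops_out) + 1L]] <- crops[[k]]
      }
      man_rows[[length(man_rows) + 1L]] <-
        data.frame(crop_path = crop_path, pairs = labels[k], scene_id = i,
                   plant_idx = k, chamber_id = NA_character_)
    }
  }
  manifest <- if (length(man_rows) > 0) do.call(rbind, man_rows) else
    data.frame(crop_path = character(0), pairs = integer(0),
               scene_id = integer(0), plant_idx = integer(0),
               chamber_id = character(0))
  skips <- if (length(skip_rows) > 0) {
    do.call(rbind, skip_rows)
  } else {
    data.frame(scene_id = integer(0), skip_reason = character(0))
  }
  attr(manifest, "provenance") <- list(corpus_seed = corpus$seed,
                                       detector = if (replay) "replay"
                                       else "function",
                                       side = side)
  if (!is.null(out_dir))
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  list(manifest = manifest,
       crops = if (is.null(out_dir)) crops_out else NULL,
       skips = skips, exclusions = excl$log)
}

#' Write or read a sample manifest
#'
#' The manifest is the table pairing cropped-instance images with their
#' leaf-pair labels and provenance: columns `crop_path`, `pairs`,
#' `scene_id`, `plant_idx`, `chamber_id` and optionally `split`. No
#' duplicate `(scene_id, plant_idx)` combinations are allowed.
#'
#' @param manifest Manifest `data.frame`.
#' @param path CSV path.
#' @return `read_manifest` returns the manifest `data.frame`;
#'   `write_manifest` returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  m$chamber_id <- as.character(m$chamber_id)
  validate_manifest(m)
  m
}

validate_manifest <- function(m) {
  need <- c("crop_path", "pairs", "scene_id", "plant_idx")
  if (!all(need %in% names(m)))
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(m[, c("scene_id", "plant_idx")]))
    stop("duplicate (scene_id, plant_idx) in manifest", call. = FALSE)
  invisible(m)
}

#' Split a manifest into train / validation / test sets
#'
#' Seeded shuffle followed by contiguous slicing under the
#' floor-floor-remainder convention:
#' `n_train = floor(N * r_train)`, `n_val = floor(N * r_val)`, and the
#' remaining samples form the test set. The three parts are disjoint and
#' exhaustive, and membership is reproducible from the seed. For
#' N = 12,871 at 70:20:10 this yields 9,009 / 2,574 / 1,288.
#'
#' @param manifest Manifest `data.frame` (non-empty).
#' @param ratios Numeric length-3 `(train, val, test)` summing to 1.
#' @param seed Integer seed.
#' @return A list of three manifests (`train`, `val`, `test`), each with
#'   a `split` column added.
#' @export
split_dataset <- function(manifest, ratios = c(0.7, 0.2, 0.1), seed = 1L) {
  n <- nrow(manifest)
  if (n == 0) stop("cannot split an empty manifest", call. = FALSE)
  stopifnot(length(ratios) == 3, all(ratios >= 0))
  if (abs(sum(ratios) - 1) > 1e-9)
    stop("split ratios must sum to 1", call. = FALSE)
  perm <- with_seed(seed, sample(n))
  n_train <- floor(n * ratios[1])
  n_val <- floor(n * ratios[2])
  idx <- list(train = perm[seq_len(n_train)],
              val = perm[n_train + seq_len(n_val)],
              test = perm[setdiff(seq_len(n), seq_len(n_train + n_val))])
  out <- lapply(names(idx), function(nm) {
    m <- manifest[sort(idx[[nm]]), , drop = FALSE]
    m$split <- nm
    rownames(m) <- NULL
    m
  })
  names(out) <- names(idx)
  out
}

#' Grouped counts with a grand total
#'
#' Tabulates samples (or any records) by a grouping column and appends
#' the grand total, the form used for per-chamber image accounting.
#'
#' @param x A `data.frame`, or a named numeric vector of pre-computed
#'   group counts.
#' @param group_key Column name to group by (ignored for vectors).
#' @return A list with `counts` (named integer vector) and `total`.
#' @examples
#' tally(c(ch1 = 945, ch2 = 947, ch3 = 945))
#' @export
tally <- function(x, group_key = NULL) {
  if (is.data.frame(x)) {
    if (is.null(group_key) || !group_key %in% names(x))
      stop("group_key must name a column of x", call. = FALSE)
    counts <- table(x[[group_key]])
    counts <- stats::setNames(as.integer(counts), names(counts))
  } else {
    counts <- stats::setNames(as.integer(x), names(x))
  }
  list(counts = counts, total = sum(counts))
}
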