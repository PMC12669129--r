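#' Pipeline configuration
#'
#' All knobs of the integrated inference pipeline: detection, box
#' post-processing (confidence threshold 0.706, nested-box tolerance 10
#' px, exactly 8 plants expected, 3 rows), cropping and staging.
#'
#' @param detector `"reference"` (colour-based reference detector),
#'   `"replay"` (ground-truth replay, requires truth at inference) or a
#'   function `f(image)` returning a box table.
#' @param conf_threshold Confidence threshold (boxes strictly above are
#'   kept).
#' @param nested_tolerance_px Nested-box removal slack in pixels.
#' @param expected_count Expected plants per frame.
#' @param n_rows Number of plant rows.
#' @param crop_side Square side crops are extracted at.
#' @param max_pairs Clamp bound for integer pair counts.
#' @param rule A [stage_rule()].
#' @param seed Integer seed forwarded to ordering.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(detector = "reference", conf_threshold = 0.706,
                            nested_tolerance_px = 10, expected_count = 8,
                            n_rows = 3, crop_side = 128, max_pairs = 10,
                            rule = stage_rule(), seed = 1L) {
  stopifnot(conf_threshold >= 0, conf_threshold <= 1,
            nested_tolerance_px >= 0, expected_count >= 1, n_rows >= 1,
            max_pairs >= 1, inherits(rule, "stage_rule"))
  structure(list(detector = detector, conf_threshold = conf_threshold,
                 nested_tolerance_px = nested_tolerance_px,
                 expected_count = expected_count, n_rows = n_rows,
                 crop_side = crop_side, max_pairs = max_pairs,
                 rule = rule, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write or read a pipeline configuration as YAML
#'
#' @param cfg A [pipeline_config()].
#' @param path File path.
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  obj <- unclass(cfg)
  obj$detector <- if (is.character(obj$detector)) obj$detector else
    "function"
  obj$rule <- cfg$rule$boundaries
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  pipeline_config(detector = obj$detector,
                  conf_threshold = obj$conf_threshold,
                  nested_tolerance_px = obj$nested_tolerance_px,
                  expected_count = obj$expected_count,
                  n_rows = obj$n_rows, crop_side = obj$crop_side,
                  max_pairs = obj$max_pairs,
                  rule = stage_rule(unlist(obj$rule)), seed = obj$seed)
}

run_detector <- function(image, cfg, truth = NULL) {
  if (is.function(cfg$detector)) return(cfg$detector(image))
  switch(cfg$detector,
         reference = reference_detect(image),
         replay = {
           if (is.null(truth))
             stop("replay detector requires ground truth", call. = FALSE)
           truth$boxes
         },
         stop("unknown detector: ", cfg$detector, call. = FALSE))
}

#' Stage all plants in one frame
#'
#' The three pipeline steps on a single image: (i) detection plus box
#' post-processing and ordering, (ii) leaf-pair prediction on the
#' ordered crops, (iii) rounding/clamping and growth-level mapping.
#' Frames whose detections do not survive post-processing yield a skip
#' record instead of per-plant rows; near-black frames are skipped as
#' `dark_frame`.
#'
#' @param image Numeric `h x w x 3` array.
#' @param cfg A [pipeline_config()].
#' @param model A fitted [train_regressor()] model, or any function
#'   `f(crops)` returning one numeric prediction per crop (e.g. an
#'   oracle during testing).
#' @param truth Optional scene truth (needed for the replay detector).
#' @param scene_id Identifier copied into the output rows.
#' @return A list with `rows` (per-plant `data.frame`: `scene_id`,
#'   `plant_idx`, box coordinates, `conf`, `raw_pred`, `pairs`, `level`)
#'   and `skip` (`NULL`, or a one-row `data.frame` with `scene_id`,
#'   `skip_reason`).
#' @export
infer_frame <- function(image, cfg, model, truth = NULL, scene_id = 1L) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (mean(image) < 0.05)
    return(list(rows = NULL,
                skip = data.frame(scene_id = scene_id,
                                  skip_reason = "dark_frame")))
  raw <- run_detector(image, cfg, truth)
  lay <- postprocess_boxes(raw, conf_threshold = cfg$conf_threshold,
                           tolerance_px = cfg$nested_tolerance_px,
                           expected = cfg$expected_count,
                           n_rows = cfg$n_rows, seed = cfg$seed)
  if (lay$skip_reason != "none")
    return(list(rows = NULL,
                skip = data.frame(scene_id = scene_id,
                                  skip_reason = lay$skip_reason)))
  crops <- crop_instances(image, lay, side = cfg$crop_side)
  raw_pred <- if (is.function(model)) model(crops) else
    predict(model, crops)
  pairs <- round_clamp(raw_pred, cfg$max_pairs)
  level <- map_stage(pairs, cfg$rule)
  rows <- data.frame(scene_id = scene_id,
                     plant_idx = seq_len(nrow(lay$boxes)),
                     x1 = lay$boxes$x1, y1 = lay$boxes$y1,
                     x2 = lay$boxes$x2, y2 = lay$boxes$y2,
                     conf = lay$boxes$conf, row = lay$row_of,
                     raw_pred = raw_pred, pairs = pairs, level = level)
  list(rows = rows, skip = NULL)
}

#' Caption text for an annotated plant
#'
#' @param level Growth level (integer).
#' @param pairs Integer leaf-pair count.
#' @return Character, e.g. `"L2|4p"`.
#' @export
caption_text <- function(level, pairs) {
  sprintf("L%d|%dp", level, pairs)
}

# 3x5 bitmap glyphs for the caption alphabet
glyphs <- local({
  g <- list(
    "0" = "111101101101111", "1" = "010110010010111",
    "2" = "111001111100111", "3" = "111001111001111",
    "4" = "101101111001001", "5" = "111100111001111",
    "6" = "111100111101111", "7" = "111001001010010",
    "8" = "111101111101111", "9" = "111101111001111",
    "L" = "100100100100111", "|" = "010010010010010",
    "p" = "000110101110100")
  lapply(g, function(s)
    matrix(as.integer(strsplit(s, "")[[1]]) == 1L, 5, 3, byrow = TRUE))
})

draw_text <- function(image, text, x, y, scale = 2,
                      col = c(1, 1, 1)) {
  h <- dim(image)[1]; w <- dim(image)[2]
  cx <- x
  for (ch in strsplit(text, "")[[1]]) {
    gl <- glyphs[[ch]]
    if (!is.null(gl)) {
      for (r in 1:5) for (c in 1:3) {
        if (gl[r, c]) {
          rr <- y + (r - 1) * scale + seq_len(scale) - 1
          cc <- cx + (c - 1) * scale + seq_len(scale) - 1
          rr <- rr[rr >= 1 & rr <= h]; cc <- cc[cc >= 1 & cc <= w]
          if (length(rr) && length(cc))
            for (k in 1:3) image[rr, cc, k] <- col[k]
        }
      }
    }
    cx <- cx + 4 * scale
  }
  image
}

draw_box <- function(image, b, thick = 2, col = c(1, 1, 1)) {
  h <- dim(image)[1]; w <- dim(image)[2]
  r1 <- max(1, floor(b$y1) + 1); r2 <- min(h, ceiling(b$y2))
  c1 <- max(1, floor(b$x1) + 1); c2 <- min(w, ceiling(b$x2))
  rr <- r1:r2; cc <- c1:c2
  for (k in 1:3) {
    image[r1:min(r1 + thick - 1, r2), cc, k] <- col[k]
    image[max(r2 - thick + 1, r1):r2, cc, k] <- col[k]
    image[rr, c1:min(c1 + thick - 1, c2), k] <- col[k]
    image[rr, max(c2 - thick + 1, c1):c2, k] <- col[k]
  }
  image
}

#' Annotate a frame with predicted stages
#'
#' Draws each plant's bounding box and a caption of the form
#' `"L{level}|{pairs}p"` above it. With no rows the image is returned
#' unmodified.
#'
#' @param image Numeric `h x w x 3` array.
#' @param rows Per-plant rows as produced by [infer_frame()] for this
#'   frame.
#' @return The annotated image array.
#' @export
annotate <- function(image, rows) {
  if (is.null(rows) || nrow(rows) == 0) return(image)
  for (i in seq_len(nrow(rows))) {
    b <- rows[i, ]
    image <- draw_box(image, b)
    image <- draw_text(image, caption_text(b$level, b$pairs),
                       x = floor(b$x1) + 1, y = max(1, floor(b$y1) - 12))
  }
  image
}

#' Run the pipeline over a corpus or directory of frames
#'
#' Applies [infer_frame()] to every frame, aggregates the per-plant
#' stage report and the skip log, and optionally writes `report.csv`,
#' `skips.csv` and annotated PNGs to `out_dir`. Reruns with the same
#' configuration and seed produce byte-identical CSV output.
#'
#' @param input A `scene_corpus`, or a directory containing PNG frames.
#' @param cfg A [pipeline_config()].
#' @param model Regressor or oracle function, see [infer_frame()].
#' @param out_dir Output directory, or `NULL` to return results only.
#' @param write_annotated Also write annotated PNGs (requires
#'   `out_dir`).
#' @return A list with `report` (all per-plant rows) and `skips`
#'   (skip log).
#' @export
run_batch <- function(input, cfg, model, out_dir = NULL,
                      write_annotated = FALSE) {
  if (inherits(input, "scene_corpus")) {
    ids <- input$scenes$scene_id
    get_img <- function(i) corpus_image(input, which(ids == i))
    get_truth <- function(i) input$truth[[which(ids == i)]]
  } else {
    paths <- sort(list.files(input, pattern = "\\.png$",
                             full.names = TRUE))
    if (length(paths) == 0)
      warning("no PNG frames found in ", input)
    ids <- seq_along(paths)
    get_img <- function(i) png::readPNG(paths[i])
    get_truth <- function(i) NULL
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  all_rows <- list(); all_skips <- list()
  for (i in ids) {
    img <- tryCatch(get_img(i), error = function(e) NULL)
    if (is.null(img)) {
      all_skips[[length(all_skips) + 1L]] <-
        data.frame(scene_id = i, skip_reason = "read_error")
      next
    }
    res <- infer_frame(img, cfg, model, truth = get_truth(i),
                       scene_id = i)
    if (!is.null(res$skip)) {
      all_skips[[length(all_skips) + 1L]] <- res$skip
    } else {
      all_rows[[length(all_rows) + 1L]] <- res$rows
      if (!is.null(out_dir) && write_annotated)
        png::writePNG(annotate(img, res$rows),
                      file.path(out_dir, sprintf("annotated_%04d.png", i)))
    }
  }
  report <- if (length(all_rows)) do.call(rbind, all_rows) else
    data.frame(scene_id = integer(0), plant_idx = integer(0),
               x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
               y2 = numeric(0), conf = numeric(0), row = integer(0),
               raw_pred = numeric(0), pairs = integer(0),
               level = integer(0))
  skips <- if (length(all_skips)) do.call(rbind, all_skips) else
    data.frame(scene_id = integer(0), skip_reason = character(0))
  if (!is.null(out_dir)) {
    utils::write.csv(report, file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    utils::write.csv(skips, file.path(out_dir, "skips.csv"),
                     row.names = FALSE)
  }
  list(report = report, skips = skips)
}
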