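#' Specify a single synthetic rosette plant
#'
#' A plant is drawn as a decussate rosette: leaf pairs emerge opposite one
#' another from the shoot apex, each successive pair rotated 90 degrees and
#' strictly smaller than the previous one, so the apex region is never
#' fully covered from above. The apex itself is drawn last as a small
#' bright disk, mimicking the visually stable anchor used for counting
#' pairs in top-view images.
#'
#' @param center_xy Numeric length-2, pixel coordinates `(x, y)` of the
#'   rosette axis. May lie outside the canvas only when constructing
#'   out-of-frame anomalies.
#' @param n_pairs Non-negative integer, number of leaf pairs.
#' @param base_angle Orientation (radians) of the oldest pair.
#' @param leaf_length_px Length (pixels) of the oldest leaves; must be
#'   positive.
#' @param missing_leaves `NULL`, or a `data.frame` with columns `pair`
#'   (1-based index, oldest pair = 1) and `side` (`"left"` or `"right"`)
#'   marking leaves that are absent (abscised or removed) and are not
#'   drawn.
#' @param visible Logical, whether the apex lies inside the frame.
#' @return An object of class `plant_spec`.
#' @seealso [render_plant()], [effective_pairs()]
#' @export
plant_spec <- function(center_xy, n_pairs, base_angle = 0,
                       leaf_length_px = 40, missing_leaves = NULL,
                       visible = TRUE) {
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 0L)
    stop("n_pairs must be a non-negative integer", call. = FALSE)
  if (!is.numeric(leaf_length_px) || leaf_length_px <= 0)
    stop("leaf_length_px must be positive", call. = FALSE)
  if (is.null(missing_leaves)) {
    missing_leaves <- data.frame(pair = integer(0), side = character(0))
  }
  stopifnot(all(c("pair", "side") %in% names(missing_leaves)))
  if (nrow(missing_leaves) > 0) {
    if (any(missing_leaves$pair < 1L | missing_leaves$pair > n_pairs))
      stop("missing_leaves pair indices must be in 1..n_pairs", call. = FALSE)
    if (!all(missing_leaves$side %in% c("left", "right")))
      stop("missing_leaves side must be 'left' or 'right'", call. = FALSE)
  }
  structure(list(center_xy = as.numeric(center_xy), n_pairs = n_pairs,
                 base_angle = as.numeric(base_angle),
                 leaf_length_px = as.numeric(leaf_length_px),
                 missing_leaves = missing_leaves, visible = isTRUE(visible)),
            class = "plant_spec")
}

#' Effective leaf-pair count after leaf loss
#'
#' Leaf abscission or removal is handled at the counting stage rather than
#' by discarding the frame: a pair with only one leaf missing is still
#' counted as intact, whereas a pair with both leaves absent reduces the
#' count by one.
#'
#' @param n_pairs Non-negative integer, nominal number of pairs.
#' @param missing_leaves As in [plant_spec()]: `NULL` or a `data.frame`
#'   with columns `pair`, `side`.
#' @return Integer effective pair count, never negative and never larger
#'   than `n_pairs`.
#' @examples
#' effective_pairs(4, NULL)                                     # 4
#' effective_pairs(4, data.frame(pair = 1, side = "left"))      # 4
#' effective_pairs(4, data.frame(pair = c(1, 1, 2),
#'                               side = c("left", "right", "right")))  # 3
#' @export
effective_pairs <- function(n_pairs, missing_leaves = NULL) {
  n_pairs <- as.integer(n_pairs)
  stopifnot(n_pairs >= 0L)
  if (is.null(missing_leaves) || nrow(missing_leaves) == 0L) return(n_pairs)
  if (any(missing_leaves$pair < 1L | missing_leaves$pair > n_pairs))
    stop("missing_leaves pair indices must be in 1..n_pairs", call. = FALSE)
  ml <- unique(missing_leaves[, c("pair", "side")])
  both_gone <- sum(tapply(ml$side, ml$pair,
                          function(s) all(c("left", "right") %in% s)))
  n_pairs - as.integer(both_gone)
}

# deterministic per-leaf jitter in [0,1) without touching the RNG stream
leaf_hash <- function(pair, side_sign, base_angle) {
  x <- sin(pair * 12.9898 + side_sign * 78.233 + base_angle * 37.719) * 43758.5453
  x - floor(x)
}

# geometry of the leaves of one plant: one row per potential leaf
leaf_geometry <- function(spec) {
  n <- spec$n_pairs
  if (n == 0L)
    return(data.frame(pair = integer(0), side = character(0), ex = numeric(0),
                      ey = numeric(0), a = numeric(0), b = numeric(0),
                      theta = numeric(0)))
  r_apex <- apex_radius(spec)
  # leaf bases tuck just under the apex disk (drawn last, so the apex
  # stays visible) keeping the rosette a single connected blob
  gap <- r_apex - 1
  decay <- 0.8
  g <- expand.grid(pair = seq_len(n), side = c("left", "right"),
                   stringsAsFactors = FALSE)
  len <- spec$leaf_length_px * decay^(g$pair - 1)
  a <- len / 2
  b <- a * 0.42
  # near-decussate: successive pairs rotated ~90 degrees, with a small
  # fixed spiral deviation so older tiers remain visible from above
  theta <- spec$base_angle + (g$pair - 1) * (pi / 2 + 0.2) +
    ifelse(g$side == "right", 0, pi)
  d <- gap + a
  data.frame(pair = g$pair, side = g$side,
             ex = spec$center_xy[1] + d * cos(theta),
             ey = spec$center_xy[2] + d * sin(theta),
             a = a, b = b, theta = theta)
}

apex_radius <- function(spec) max(2.5, 0.10 * spec$leaf_length_px)

# analytic axis-aligned extent of the full rosette (ignores the canvas)
plant_extent <- function(spec) {
  r <- apex_radius(spec)
  x1 <- spec$center_xy[1] - r; x2 <- spec$center_xy[1] + r
  y1 <- spec$center_xy[2] - r; y2 <- spec$center_xy[2] + r
  geo <- leaf_geometry(spec)
  keep <- !leaf_is_missing(geo, spec$missing_leaves)
  geo <- geo[keep, , drop = FALSE]
  if (nrow(geo) > 0) {
    hx <- sqrt((geo$a * cos(geo$theta))^2 + (geo$b * sin(geo$theta))^2)
    hy <- sqrt((geo$a * sin(geo$theta))^2 + (geo$b * cos(geo$theta))^2)
    x1 <- min(x1, geo$ex - hx); x2 <- max(x2, geo$ex + hx)
    y1 <- min(y1, geo$ey - hy); y2 <- max(y2, geo$ey + hy)
  }
  c(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
}

leaf_is_missing <- function(geo, missing_leaves) {
  if (is.null(missing_leaves) || nrow(missing_leaves) == 0L)
    return(rep(FALSE, nrow(geo)))
  paste(geo$pair, geo$side) %in%
    paste(missing_leaves$pair, missing_leaves$side)
}

# linear indices (into an h x w plane) of the pixels covered by a filled
# rotated ellipse; pixel centers at (c - 0.5, r - 0.5)
ellipse_pixels <- function(ex, ey, a, b, theta, h, w) {
  half <- max(a, b) + 1
  cs <- max(1L, as.integer(floor(ex - half)) + 1L)
  ce <- min(w, as.integer(ceiling(ex + half)))
  rs <- max(1L, as.integer(floor(ey - half)) + 1L)
  re <- min(h, as.integer(ceiling(ey + half)))
  if (cs > ce || rs > re) return(integer(0))
  xs <- (cs:ce) - 0.5 - ex
  ys <- (rs:re) - 0.5 - ey
  ct <- cos(theta); st <- sin(theta)
  u <- outer(ys * st, xs * ct, `+`)        # rotated major-axis coord
  v <- outer(ys * ct, xs * -st, `+`)       # rotated minor-axis coord
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(inside)) return(integer(0))
  rows <- rep.int(rs:re, length(cs:ce))[inside]
  cols <- rep(cs:ce, each = length(rs:re))[inside]
  (cols - 1L) * h + rows
}

#' Render one rosette onto a canvas
#'
#' Composites the plant described by `spec` onto `canvas`, drawing the
#' oldest (largest) leaf pair first and the apex disk last so that the
#' apex is never overdrawn by the plant's own foliage. Leaves flagged in
#' `missing_leaves` are not drawn. Each leaf receives a small
#' deterministic hue perturbation so that neighbouring leaves remain
#' visually separable.
#'
#' @param spec A [plant_spec()].
#' @param canvas Numeric array `h x w x 3` with values in `[0, 1]`.
#' @return A list with elements `canvas` (updated array), `box` (tight
#'   axis-aligned bounding box of all drawn foliage pixels as a one-row
#'   box table, or `NULL` if nothing was drawn), `mask` (logical `h x w`
#'   matrix of this plant's pixels) and `apex_mask` (logical matrix of the
#'   apex disk pixels).
#' @export
render_plant <- function(spec, canvas) {
  stopifnot(inherits(spec, "plant_spec"))
  if (spec$leaf_length_px <= 0)
    stop("leaf_length_px must be positive", call. = FALSE)
  h <- dim(canvas)[1]; w <- dim(canvas)[2]
  plane <- h * w
  mask <- matrix(FALSE, h, w)
  geo <- leaf_geometry(spec)
  keep <- !leaf_is_missing(geo, spec$missing_leaves)
  geo <- geo[keep, , drop = FALSE]
  # oldest pair first so younger, smaller pairs sit on top
  geo <- geo[order(geo$pair), , drop = FALSE]
  for (i in seq_len(nrow(geo))) {
    jit <- leaf_hash(geo$pair[i], ifelse(geo$side[i] == "right", 1, 2),
                     spec$base_angle)
    # juvenile leaves are lighter: brightness rises with tier index, so
    # the stack of visible tiers is readable from above
    v <- min(0.38 + 0.085 * (geo$pair[i] - 1), 0.92) * (0.93 + 0.14 * jit)
    col <- c(0.35 * v, v, 0.30 * v)
    idx <- ellipse_pixels(geo$ex[i], geo$ey[i], geo$a[i], geo$b[i],
                          geo$theta[i], h, w)
    if (length(idx) == 0) next
    mask[idx] <- TRUE
    for (ch in 1:3) canvas[idx + (ch - 1L) * plane] <- col[ch]
  }
  r <- apex_radius(spec)
  aidx <- ellipse_pixels(spec$center_xy[1], spec$center_xy[2], r, r, 0, h, w)
  apex_mask <- matrix(FALSE, h, w)
  if (length(aidx) > 0) {
    apex_mask[aidx] <- TRUE
    acol <- c(0.45, 0.95, 0.45)
    for (ch in 1:3) canvas[aidx + (ch - 1L) * plane] <- acol[ch]
  }
  mask <- mask | apex_mask
  box <- NULL
  if (any(mask)) {
    idx <- which(mask, arr.ind = TRUE)
    box <- boxes(x1 = min(idx[, 2]) - 1, y1 = min(idx[, 1]) - 1,
                 x2 = max(idx[, 2]), y2 = max(idx[, 1]))
  }
  list(canvas = canvas, box = box, mask = mask, apex_mask = apex_mask)
}

#' Default 3-2-3 pot layout
#'
#' Eight pot anchors arranged around a central obstruction (a humidifier
#' disk): three in the top row, two in the middle row flanking the disk,
#' three in the bottom row. Anchors are listed in reading order (top row
#' left to right, then middle, then bottom), which is also the ground
#' truth labelling order.
#'
#' @param image_wh Integer length-2, canvas width and height in pixels.
#' @return A `data.frame` with columns `x`, `y`, `row`.
#' @export
default_layout <- function(image_wh = c(820, 616)) {
  w <- image_wh[1]; h <- image_wh[2]
  data.frame(
    x = c(0.2, 0.5, 0.8, 0.2, 0.8, 0.2, 0.5, 0.8) * w,
    y = c(0.2, 0.2, 0.2, 0.5, 0.5, 0.8, 0.8, 0.8) * h,
    row = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L))
}

SCENE_ANOMALIES <- c("none", "multi_seedling", "dark_frame", "out_of_frame",
                     "empty_pot", "leaf_removed")

#' Specify a synthetic bed scene
#'
#' Bundles the canvas size, pot layout, plant specs, photometric
#' conditions (LED colour cast, pixel noise) and an anomaly tag into a
#' renderable description of one top-view frame. Rendering is fully
#' deterministic given the spec (the `seed` drives only the additive
#' noise field).
#'
#' @param plants List of [plant_spec()] objects, one per occupied pot (in
#'   reading order). Each element may carry a `row` attribute giving its
#'   layout row; otherwise rows are taken from the nearest anchor.
#' @param image_wh Canvas `(width, height)` in pixels.
#' @param layout Pot anchor table as from [default_layout()]; must have at
#'   least one anchor.
#' @param jitter_px Maximum per-plant displacement from its anchor that
#'   was used when the plants were generated (recorded for provenance).
#' @param tint_rgb Length-3 multiplicative colour cast applied to the
#'   rendered frame, emulating LED lighting.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param anomaly One of `"none"`, `"multi_seedling"`, `"dark_frame"`,
#'   `"out_of_frame"`, `"empty_pot"`, `"leaf_removed"`.
#' @param seed Integer seed for the noise field.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(plants, image_wh = c(820, 616),
                       layout = default_layout(image_wh), jitter_px = 12,
                       tint_rgb = c(1, 1, 1), noise_sd = 0.02,
                       anomaly = "none", seed = 1L) {
  anomaly <- match.arg(anomaly, SCENE_ANOMALIES)
  if (nrow(layout) < 1L)
    stop("layout must contain at least one anchor", call. = FALSE)
  stopifnot(length(image_wh) == 2, all(image_wh > 0),
            length(tint_rgb) == 3, noise_sd >= 0)
  structure(list(image_wh = as.integer(image_wh), layout = layout,
                 plants = plants, jitter_px = jitter_px,
                 tint_rgb = as.numeric(tint_rgb), noise_sd = noise_sd,
                 anomaly = anomaly, seed = as.integer(seed)),
            class = "scene_spec")
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(i) * 7919) %% 2147483629)
}

#' Generate a randomized scene spec
#'
#' Draws per-plant pair counts, orientations, sizes and anchor jitter from
#' a seeded stream and returns a complete, renderable [scene_spec()].
#' Anomalies alter the construction: `multi_seedling` places a second,
#' overlapping rosette on one anchor; `out_of_frame` pushes one plant's
#' apex beyond the frame edge; `empty_pot` leaves one anchor unplanted;
#' `leaf_removed` removes both leaves of the oldest pair (and a single
#' leaf of the next pair when present) of one plant, so its effective
#' label drops by exactly one; `dark_frame` is handled at render time.
#'
#' @param seed Integer seed; the same seed always yields the same spec.
#' @param pair_range Integer length-2, inclusive range of leaf-pair
#'   counts.
#' @param anomaly Anomaly tag, see [scene_spec()].
#' @param image_wh,layout,jitter_px,noise_sd Passed through to
#'   [scene_spec()].
#' @return A `scene_spec`.
#' @export
random_scene <- function(seed, pair_range = c(1, 7), anomaly = "none",
                         image_wh = c(820, 616),
                         layout = default_layout(image_wh), jitter_px = 12,
                         noise_sd = 0.02) {
  anomaly <- match.arg(anomaly, SCENE_ANOMALIES)
  with_seed(seed, {
    n_anchor <- nrow(layout)
    occupied <- seq_len(n_anchor)
    if (anomaly == "empty_pot")
      occupied <- setdiff(occupied, sample(n_anchor, 1))
    plants <- list()
    for (k in occupied) {
      np <- sample(seq(pair_range[1], pair_range[2]), 1)
      len <- 24 + 2.2 * np + runif(1, -3, 3)
      ctr <- c(layout$x[k], layout$y[k]) + runif(2, -jitter_px, jitter_px)
      p <- plant_spec(ctr, np, base_angle = runif(1, 0, 2 * pi),
                      leaf_length_px = len)
      attr(p, "row") <- layout$row[k]
      plants[[length(plants) + 1L]] <- p
    }
    if (anomaly == "multi_seedling") {
      k <- sample(length(plants), 1)
      host <- plants[[k]]
      ang <- runif(1, 0, 2 * pi)
      off <- runif(1, 10, 18) * c(cos(ang), sin(ang))
      np <- sample(seq(pair_range[1], pair_range[2]), 1)
      extra <- plant_spec(host$center_xy + off, np,
                          base_angle = runif(1, 0, 2 * pi),
                          leaf_length_px = 24 + 2.2 * np + runif(1, -3, 3))
      attr(extra, "row") <- attr(host, "row")
      plants[[length(plants) + 1L]] <- extra
    }
    if (anomaly == "out_of_frame") {
      k <- sample(length(plants), 1)
      p <- plants[[k]]
      p$center_xy <- c(-0.2 * p$leaf_length_px, p$center_xy[2])
      p$visible <- FALSE
      attr(p, "row") <- attr(plants[[k]], "row")
      plants[[k]] <- p
    }
    if (anomaly == "leaf_removed") {
      cand <- which(vapply(plants, function(p) p$n_pairs >= 2L, logical(1)))
      if (length(cand) > 0) {
        k <- cand[sample(length(cand), 1)]
        p <- plants[[k]]
        ml <- data.frame(pair = c(1L, 1L), side = c("left", "right"))
        if (p$n_pairs >= 2L)
          ml <- rbind(ml, data.frame(pair = 2L, side = "left"))
        p$missing_leaves <- ml
        attr(p, "row") <- attr(plants[[k]], "row")
        plants[[k]] <- p
      }
    }
    tint <- runif(3, 0.6, 1.0)
    scene_spec(plants, image_wh = image_wh, layout = layout,
               jitter_px = jitter_px, tint_rgb = tint, noise_sd = noise_sd,
               anomaly = anomaly, seed = seed)
  })
}

#' Render a scene to an image plus exact ground truth
#'
#' Draws the soil background and central humidifier disk, composites each
#' plant, applies the multiplicative colour cast and seeded additive
#' noise, and assembles the ground truth: one tight bounding box and one
#' effective leaf-pair label per plant, plus row and reading-order
#' indices. For `dark_frame` scenes the frame is scaled to a mean
#' luminance below 8/255 and the truth box list is empty. For plants that
#' extend beyond the frame the (unclipped) analytic extent is reported so
#' that out-of-frame fractions can be measured downstream.
#'
#' @param spec A [scene_spec()].
#' @param keep_masks Logical; retain the per-plant logical paint masks in
#'   the truth object (memory-heavy, used by rendering invariants and
#'   crop purity checks).
#' @return A list with `image` (numeric `h x w x 3` array in `[0, 1]`) and
#'   `truth`, itself a list with `boxes` (box table), `pairs` (integer
#'   vector), `row_of`, `order`, `visible`, `anomaly` and (optionally)
#'   `masks`, `apex_masks`.
#' @export
render_scene <- function(spec, keep_masks = FALSE) {
  stopifnot(inherits(spec, "scene_spec"))
  w <- spec$image_wh[1]; h <- spec$image_wh[2]
  img <- array(0, c(h, w, 3))
  img[, , 1] <- 0.23; img[, , 2] <- 0.17; img[, , 3] <- 0.12
  # central obstruction: humidifier disk
  disk_r <- 0.09 * h
  didx <- ellipse_pixels(w / 2, h / 2, disk_r, disk_r, 0, h, w)
  dcol <- c(0.55, 0.56, 0.58)
  for (ch in 1:3) img[didx + (ch - 1L) * h * w] <- dcol[ch]
  n <- length(spec$plants)
  masks <- vector("list", n); apex_masks <- vector("list", n)
  box_rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- spec$plants[[i]]
    r <- render_plant(p, img)
    img <- r$canvas
    ext <- plant_extent(p)
    fully_inside <- ext["x1"] >= 0 && ext["y1"] >= 0 &&
      ext["x2"] <= w && ext["y2"] <= h
    if (fully_inside && !is.null(r$box)) {
      box_rows[[i]] <- r$box
    } else {
      box_rows[[i]] <- boxes(ext["x1"], ext["y1"], ext["x2"], ext["y2"])
    }
    masks[[i]] <- r$mask; apex_masks[[i]] <- r$apex_mask
  }
  bx <- if (n > 0) do.call(rbind, box_rows) else empty_boxes()
  bx$conf <- 1
  pairs <- vapply(spec$plants,
                  function(p) effective_pairs(p$n_pairs, p$missing_leaves),
                  integer(1))
  row_of <- vapply(spec$plants, function(p) {
    r <- attr(p, "row")
    if (is.null(r)) nearest_row(p$center_xy, spec$layout) else as.integer(r)
  }, integer(1))
  visible <- vapply(spec$plants, function(p) p$visible, logical(1))
  img <- sweep(img, 3, spec$tint_rgb, `*`)
  if (spec$noise_sd > 0) {
    img <- img + with_seed(spec$seed,
                           array(stats::rnorm(length(img), 0, spec$noise_sd),
                                 dim(img)))
  }
  img <- pmin(pmax(img, 0), 1)
  if (spec$anomaly == "dark_frame") {
    lum <- mean(img)
    img <- img * (0.008 / max(lum, 1e-8))
    truth <- list(boxes = empty_boxes(), pairs = integer(0),
                  row_of = integer(0), order = integer(0),
                  visible = logical(0), anomaly = "dark_frame")
    return(list(image = img, truth = truth))
  }
  truth <- list(boxes = bx, pairs = pairs, row_of = row_of,
                order = seq_len(n), visible = visible,
                anomaly = spec$anomaly)
  if (keep_masks) {
    truth$masks <- masks
    truth$apex_masks <- apex_masks
  }
  list(image = img, truth = truth)
}

nearest_row <- function(center_xy, layout) {
  d <- (layout$x - center_xy[1])^2 + (layout$y - center_xy[2])^2
  as.integer(layout$row[which.min(d)])
}

#' Generate a corpus of synthetic scenes
#'
#' Renders `n_scenes` seeded scenes, injecting anomalies by deterministic
#' assignment: scene indices are shuffled once with the corpus seed and
#' the first `floor(rate * n)` shuffled slots of each anomaly category
#' (taken in alphabetical order) receive that anomaly, so the corpus
#' composition is exactly reproducible -- there is no Bernoulli sampling.
#' Optionally writes each frame as a PNG plus a `truth.csv` ground-truth
#' table to `dir`.
#'
#' @param n_scenes Number of scenes.
#' @param dir Output directory (created if needed), or `NULL` to skip
#'   writing images.
#' @param pair_range Inclusive integer range of leaf-pair counts.
#' @param anomaly_rates Named numeric vector of per-category rates, names
#'   among the anomaly tags of [scene_spec()] (excluding `"none"`). Rates
#'   must sum to at most 1.
#' @param seed Corpus seed; per-scene seeds are derived from it.
#' @param keep_images Keep rendered arrays in memory (only sensible for
#'   small corpora).
#' @param keep_masks Keep per-plant paint masks (memory-heavy).
#' @return An object of class `scene_corpus`: a list with `scenes` (a
#'   `data.frame` with `scene_id`, `path`, `anomaly`, `seed`,
#'   `mean_luminance`), `truth` (list of per-scene truth objects),
#'   `images` (list or `NULL`) and `dir`.
#' @export
make_corpus <- function(n_scenes, dir = NULL, pair_range = c(1, 7),
                        anomaly_rates = c(), seed = 1L,
                        keep_images = is.null(dir), keep_masks = FALSE) {
  stopifnot(n_scenes >= 1)
  if (length(anomaly_rates) > 0) {
    if (!all(names(anomaly_rates) %in% setdiff(SCENE_ANOMALIES, "none")))
      stop("unknown anomaly category in anomaly_rates", call. = FALSE)
    if (sum(anomaly_rates) > 1 + 1e-9)
      stop("anomaly rates must sum to at most 1", call. = FALSE)
  }
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  assign_anom <- rep("none", n_scenes)
  if (length(anomaly_rates) > 0) {
    perm <- with_seed(seed, sample(n_scenes))
    pos <- 1L
    for (cat in sort(names(anomaly_rates))) {
      k <- floor(anomaly_rates[[cat]] * n_scenes)
      if (k > 0) {
        assign_anom[perm[pos:(pos + k - 1L)]] <- cat
        pos <- pos + k
      }
    }
  }
  scenes <- data.frame(scene_id = seq_len(n_scenes),
                       path = NA_character_, anomaly = assign_anom,
                       seed = vapply(seq_len(n_scenes),
                                     function(i) derive_seed(seed, i),
                                     integer(1)),
                       mean_luminance = NA_real_)
  truths <- vector("list", n_scenes)
  images <- if (keep_images) vector("list", n_scenes) else NULL
  truth_rows <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    sp <- random_scene(scenes$seed[i], pair_range = pair_range,
                       anomaly = assign_anom[i])
    r <- render_scene(sp, keep_masks = keep_masks)
    scenes$mean_luminance[i] <- mean(r$image)
    truths[[i]] <- r$truth
    if (keep_images) images[[i]] <- r$image
    if (!is.null(dir)) {
      path <- file.path(dir, sprintf("scene_%04d.png", i))
      png::writePNG(r$image, path)
      scenes$path[i] <- path
    }
    tb <- r$truth$boxes
    if (nrow(tb) > 0) {
      truth_rows[[i]] <- data.frame(scene_id = i,
                                    plant_idx = seq_len(nrow(tb)),
                                    x1 = tb$x1, y1 = tb$y1, x2 = tb$x2,
                                    y2 = tb$y2, pairs = r$truth$pairs,
                                    row = r$truth$row_of,
                                    order = r$truth$order,
                                    anomaly = r$truth$anomaly)
    }
  }
  truth_df <- do.call(rbind, truth_rows[!vapply(truth_rows, is.null,
                                                logical(1))])
  if (is.null(truth_df))
    truth_df <- data.frame(scene_id = integer(0), plant_idx = integer(0))
  if (!is.null(dir))
    utils::write.csv(truth_df, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  structure(list(scenes = scenes, truth = truths, truth_table = truth_df,
                 images = images, dir = dir, pair_range = pair_range,
                 image_wh = c(820L, 616L), seed = seed),
            class = "scene_corpus")
}

#' @export
print.scene_corpus <- function(x, ...) {
  cat("Synthetic scene corpus:", nrow(x$scenes), "scenes\n")
  tab <- table(x$scenes$anomaly)
  for (nm in names(tab)) cat(sprintf("  %-14s %d\n", nm, tab[[nm]]))
  if (!is.null(x$dir)) cat("  written to:", x$dir, "\n")
  invisible(x)
}

# fetch the rendered image of scene i, from memory or from disk
corpus_image <- function(corpus, i) {
  if (!is.null(corpus$images)) return(corpus$images[[i]])
  if (is.na(corpus$scenes$path[i]))
    stop("corpus holds neither images nor paths", call. = FALSE)
  png::readPNG(corpus$scenes$path[i])
}

#' Write or read a scene spec as YAML
#'
#' Serializes the scalar fields, layout and plant list of a
#' [scene_spec()] so that scene definitions can be version-controlled and
#' replayed.
#'
#' @param spec A `scene_spec`.
#' @param path File path.
#' @return `write_scene_spec` returns `path` invisibly; `read_scene_spec`
#'   returns a `scene_spec`.
#' @export
write_scene_spec <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  pl <- lapply(spec$plants, function(p) {
    list(center_xy = p$center_xy, n_pairs = p$n_pairs,
         base_angle = p$base_angle, leaf_length_px = p$leaf_length_px,
         missing_leaves = if (nrow(p$missing_leaves) > 0)
           list(pair = p$missing_leaves$pair,
                side = p$missing_leaves$side) else NULL,
         visible = p$visible, row = attr(p, "row"))
  })
  obj <- list(image_wh = spec$image_wh,
              layout = list(x = spec$layout$x, y = spec$layout$y,
                            row = spec$layout$row),
              jitter_px = spec$jitter_px, tint_rgb = spec$tint_rgb,
              noise_sd = spec$noise_sd, anomaly = spec$anomaly,
              seed = spec$seed, plants = pl)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  plants <- lapply(obj$plants, function(p) {
    ml <- NULL
    if (!is.null(p$missing_leaves))
      ml <- data.frame(pair = as.integer(unlist(p$missing_leaves$pair)),
                       side = as.character(unlist(p$missing_leaves$side)))
    sp <- plant_spec(unlist(p$center_xy), p$n_pairs, p$base_angle,
                     p$leaf_length_px, ml, p$visible)
    attr(sp, "row") <- p$row
    sp
  })
  layout <- data.frame(x = unlist(obj$layout$x), y = unlist(obj$layout$y),
                       row = as.integer(unlist(obj$layout$row)))
  scene_spec(plants, image_wh = unlist(obj$image_wh), layout = layout,
             jitter_px = obj$jitter_px, tint_rgb = unlist(obj$tint_rgb),
             noise_sd = obj$noise_sd, anomaly = obj$anomaly,
             seed = obj$seed)
}
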