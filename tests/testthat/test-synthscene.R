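test_that("effective pair counting follows the one-leaf-intact rule", {
  expect_identical(effective_pairs(4, NULL), 4L)
  # one leaf of a pair missing: pair still intact
  expect_identical(effective_pairs(4, data.frame(pair = 1, side = "left")),
                   4L)
  # both leaves of pair 1 missing, one leaf of pair 2: reduced by one
  ml <- data.frame(pair = c(1, 1, 2), side = c("left", "right", "right"))
  expect_identical(effective_pairs(4, ml), 3L)
  expect_error(effective_pairs(3, data.frame(pair = 5, side = "left")),
               "1..n_pairs")
})

test_that("effective pair count is monotone in leaf loss and never negative", {
  all_leaves <- expand.grid(pair = 1:5, side = c("left", "right"),
                            stringsAsFactors = FALSE)
  withr::with_seed(42, {
    for (rep in 1:50) {
      k <- sample(0:10, 1)
      sub <- all_leaves[sample(10, k), , drop = FALSE]
      v <- effective_pairs(5, sub)
      expect_gte(v, 0)
      expect_lte(v, 5)
      if (k < 10) {
        extra <- all_leaves[sample(setdiff(1:10,
                                           as.integer(rownames(sub))), 1), ,
                            drop = FALSE]
        expect_lte(effective_pairs(5, rbind(sub, extra)), v)
      }
    }
  })
  expect_identical(effective_pairs(5, all_leaves), 0L)
})

test_that("rendering a pairless stub draws only the apex disk", {
  canvas <- array(0.1, c(100, 100, 3))
  sp <- plant_spec(c(50, 50), 0, leaf_length_px = 30)
  r <- render_plant(sp, canvas)
  expect_true(all(r$mask == r$apex_mask))
  side <- 2 * apex_radius(sp)
  expect_lte(r$box$x2 - r$box$x1, side + 2)
  expect_lte(r$box$y2 - r$box$y1, side + 2)
})

test_that("missing leaves are not drawn", {
  canvas <- array(0.1, c(200, 200, 3))
  full <- render_plant(plant_spec(c(100, 100), 3, leaf_length_px = 40),
                       canvas)
  ml <- data.frame(pair = c(1, 1), side = c("left", "right"))
  part <- render_plant(plant_spec(c(100, 100), 3, leaf_length_px = 40,
                                  missing_leaves = ml), canvas)
  expect_lt(sum(part$mask), sum(full$mask))
  # remaining foliage is a subset of the full rosette
  expect_true(all(which(part$mask) %in% which(full$mask)))
})

test_that("invalid plant and scene specs are rejected", {
  expect_error(plant_spec(c(0, 0), 2, leaf_length_px = 0), "positive")
  expect_error(plant_spec(c(0, 0), -1), "non-negative")
  expect_error(scene_spec(list(), layout = data.frame(x = numeric(0),
                                                      y = numeric(0),
                                                      row = integer(0))),
               "anchor")
})

test_that("scene rendering is bit-deterministic for a fixed seed", {
  a <- render_scene(random_scene(7))
  b <- render_scene(random_scene(7))
  expect_identical(a$image, b$image)
  expect_identical(a$truth$boxes, b$truth$boxes)
})

test_that("clean scenes have eight disjoint truth boxes in reading order", {
  corpus <- clean_corpus()
  for (i in seq_len(nrow(corpus$scenes))) {
    tr <- corpus$truth[[i]]
    expect_equal(nrow(tr$boxes), 8)
    expect_equal(length(tr$pairs), nrow(tr$boxes))
    m <- iou_matrix(tr$boxes, tr$boxes)
    diag(m) <- 0
    expect_equal(max(m), 0)
    # reading order: rows non-decreasing, cx increasing within row
    ctr <- box_centers(tr$boxes)
    expect_true(all(diff(tr$row_of) >= 0))
    for (r in unique(tr$row_of))
      expect_true(all(diff(ctr$cx[tr$row_of == r]) > 0))
  }
})

test_that("every foliage pixel lies inside its plant's truth box", {
  corpus <- clean_corpus()
  for (i in seq_len(nrow(corpus$scenes))) {
    tr <- corpus$truth[[i]]
    for (k in seq_along(tr$masks)) {
      px <- which(tr$masks[[k]], arr.ind = TRUE)
      b <- tr$boxes[k, ]
      expect_true(all(px[, 2] - 1 >= b$x1 & px[, 2] <= b$x2 &
                        px[, 1] - 1 >= b$y1 & px[, 1] <= b$y2))
    }
  }
})

test_that("apex disks are never overdrawn in clean scenes", {
  corpus <- clean_corpus()
  for (i in seq_len(nrow(corpus$scenes))) {
    tr <- corpus$truth[[i]]
    for (k in seq_along(tr$apex_masks)) {
      apex <- tr$apex_masks[[k]]
      expect_gt(sum(apex), 0)
      # apex pixels belong to their own plant only
      for (j in setdiff(seq_along(tr$masks), k))
        expect_equal(sum(apex & tr$masks[[j]]), 0)
    }
  }
})

test_that("anomaly construction matches its tags", {
  corpus <- anomaly_corpus()
  tags <- corpus$scenes$anomaly
  expect_setequal(unique(tags), c("none", "multi_seedling", "dark_frame",
                                  "out_of_frame", "empty_pot",
                                  "leaf_removed"))
  dark <- which(tags == "dark_frame")
  expect_lte(corpus$scenes$mean_luminance[dark], 8 / 255)
  expect_equal(nrow(corpus$truth[[dark]]$boxes), 0)
  expect_equal(nrow(corpus$truth[[which(tags == "empty_pot")]]$boxes), 7)
  expect_equal(nrow(corpus$truth[[which(tags == "multi_seedling")]]$boxes),
               9)
  oofr <- corpus$truth[[which(tags == "out_of_frame")]]
  expect_true(any(!oofr$visible | oofr$boxes$x1 < 0))
  # leaf_removed: effective label below the nominal pair count somewhere
  lr <- which(tags == "leaf_removed")
  sp <- random_scene(corpus$scenes$seed[lr], anomaly = "leaf_removed")
  nominal <- vapply(sp$plants, function(p) p$n_pairs, integer(1))
  expect_true(any(corpus$truth[[lr]]$pairs < nominal))
})

test_that("corpus generation applies anomaly rates by exact assignment", {
  c1 <- make_corpus(20, anomaly_rates = c(dark_frame = 0.1), seed = 9,
                    keep_images = FALSE)
  expect_equal(sum(c1$scenes$anomaly == "dark_frame"), 2)
  c2 <- make_corpus(20, anomaly_rates = c(dark_frame = 0.1), seed = 9,
                    keep_images = FALSE)
  expect_identical(c1$scenes, c2$scenes)
  expect_identical(c1$truth_table, c2$truth_table)
  expect_error(make_corpus(5, anomaly_rates = c(dark_frame = 0.9,
                                                empty_pot = 0.5)),
               "at most 1")
})

test_that("a clean corpus yields eight truth boxes per scene", {
  corpus <- clean_corpus()
  expect_equal(nrow(corpus$truth_table), 6 * 8)
})

test_that("corpus files and truth CSV are reproducible on disk", {
  d1 <- file.path(tempdir(), "corpA")
  d2 <- file.path(tempdir(), "corpB")
  make_corpus(3, dir = d1, seed = 5, keep_images = FALSE)
  make_corpus(3, dir = d2, seed = 5, keep_images = FALSE)
  expect_identical(readLines(file.path(d1, "truth.csv")),
                   readLines(file.path(d2, "truth.csv")))
  expect_identical(readBin(file.path(d1, "scene_0001.png"), "raw", 1e6),
                   readBin(file.path(d2, "scene_0001.png"), "raw", 1e6))
})

test_that("scene specs round-trip through YAML", {
  sp <- random_scene(13, anomaly = "leaf_removed")
  path <- tempfile(fileext = ".yaml")
  write_scene_spec(sp, path)
  sp2 <- read_scene_spec(path)
  r1 <- render_scene(sp)
  r2 <- render_scene(sp2)
  expect_equal(r1$image, r2$image)
  expect_equal(r1$truth$pairs, r2$truth$pairs)
})
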