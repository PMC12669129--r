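test_that("frame exclusion drops the four fatal anomaly classes only", {
  corpus <- anomaly_corpus()
  excl <- exclude_frames(corpus)
  tags <- corpus$scenes$anomaly
  expect_setequal(excl$log$reason,
                  c("multi_seedling", "dark_frame", "out_of_frame",
                    "empty_pot"))
  # leaf-removed and clean frames are kept
  expect_true(all(which(tags %in% c("none", "leaf_removed")) %in%
                    excl$kept))
  expect_false(which(tags == "multi_seedling") %in% excl$kept)
})

test_that("nothing is excluded from a clean corpus", {
  excl <- exclude_frames(clean_corpus())
  expect_equal(nrow(excl$log), 0)
  expect_equal(length(excl$kept), 6)
})

test_that("dark frames are excluded photometrically, not by their tag", {
  corpus <- anomaly_corpus()
  dark <- which(corpus$scenes$anomaly == "dark_frame")
  stripped <- corpus
  stripped$scenes$anomaly[dark] <- "none"
  stripped$truth[[dark]]$anomaly <- "none"
  excl <- exclude_frames(stripped)
  expect_true(dark %in% excl$log$scene_id)
  expect_equal(excl$log$reason[excl$log$scene_id == dark], "dark_frame")
})

test_that("crops follow the half-open integer pixel convention", {
  img <- array(stats::runif(100 * 100 * 3), c(100, 100, 3))
  crops <- crop_instances(img, boxes(0, 0, 10, 10), side = NULL)
  expect_equal(dim(crops[[1]]), c(10, 10, 3))
  expect_equal(crops[[1]], img[1:10, 1:10, ])
  # fractional coordinates expand outwards
  crops2 <- crop_instances(img, boxes(0.4, 0.6, 10.2, 10.9), side = NULL)
  expect_equal(dim(crops2[[1]])[1:2], c(11, 11))
  expect_warning(crop_instances(img, boxes(-5, 0, 10, 10), side = NULL),
                 "clipped")
})

test_that("ordered crops contain only their own plant's foliage", {
  corpus <- clean_corpus()
  img <- corpus$images[[3]]
  tr <- corpus$truth[[3]]
  lay <- order_instances(tr$boxes)
  crops <- crop_instances(img, lay, side = NULL)
  expect_equal(length(crops), 8)
  for (k in seq_along(crops)) {
    b <- lay$boxes[k, ]
    tr_idx <- which.max(iou(b, tr$boxes))
    inside <- matrix(FALSE, nrow(img), ncol(img))
    inside[(floor(b$y1) + 1):ceiling(b$y2),
           (floor(b$x1) + 1):ceiling(b$x2)] <- TRUE
    for (j in setdiff(seq_along(tr$masks), tr_idx))
      expect_equal(sum(tr$masks[[j]] & inside), 0)
  }
})

test_that("the split convention reproduces the documented sizes", {
  man <- data.frame(crop_path = NA, pairs = 1,
                    scene_id = seq_len(12871), plant_idx = 1)
  parts <- split_dataset(man, c(0.7, 0.2, 0.1), seed = 1)
  expect_equal(vapply(parts, nrow, integer(1)),
               c(train = 9009L, val = 2574L, test = 1288L))
  man10 <- man[1:10, ]
  expect_equal(unname(vapply(split_dataset(man10, c(0.7, 0.2, 0.1),
                                           seed = 2), nrow, integer(1))),
               c(7L, 2L, 1L))
})

test_that("splits are deterministic, disjoint and exhaustive", {
  withr::with_seed(31, {
    for (i in 1:10) {
      n <- sample(10:400, 1)
      r <- c(stats::runif(2, 0.1, 0.4), 0)
      r[3] <- 1 - r[1] - r[2]
      man <- data.frame(crop_path = NA, pairs = 1, scene_id = seq_len(n),
                        plant_idx = 1)
      p1 <- split_dataset(man, r, seed = i)
      p2 <- split_dataset(man, r, seed = i)
      expect_identical(p1$train$scene_id, p2$train$scene_id)
      ids <- c(p1$train$scene_id, p1$val$scene_id, p1$test$scene_id)
      expect_equal(sort(ids), seq_len(n))
      expect_equal(nrow(p1$train), floor(n * r[1]))
      expect_equal(nrow(p1$val), floor(n * r[2]))
    }
  })
  expect_error(split_dataset(data.frame(crop_path = character(0),
                                        pairs = integer(0),
                                        scene_id = integer(0),
                                        plant_idx = integer(0))),
               "empty")
  man <- data.frame(crop_path = NA, pairs = 1, scene_id = 1:10,
                    plant_idx = 1)
  expect_error(split_dataset(man, c(0.7, 0.2, 0.2)), "sum to 1")
})

test_that("tallies reproduce their grand totals", {
  per_chamber <- c(945, 947, 945, 945, 943, 946, 957, 954, 937)
  expect_equal(tally(per_chamber)$total, 8519)
  post_filter <- c(334, 310, 237, 294, 357, 330, 307)
  expect_equal(tally(post_filter)$total, 2169)
  empty <- data.frame(chamber_id = character(0))
  t0 <- tally(empty, "chamber_id")
  expect_equal(t0$total, 0)
  expect_equal(length(t0$counts), 0)
  df <- data.frame(chamber_id = c("a", "a", "b"))
  expect_equal(tally(df, "chamber_id")$counts, c(a = 2L, b = 1L))
})

test_that("manifests round-trip through CSV and reject duplicates", {
  man <- data.frame(crop_path = c("a.png", "b.png"), pairs = c(3L, 5L),
                    scene_id = c(1L, 1L), plant_idx = c(1L, 2L),
                    chamber_id = c("c1", "c1"))
  path <- tempfile(fileext = ".csv")
  write_manifest(man, path)
  back <- read_manifest(path)
  expect_equal(back, man)
  dup <- man
  dup$plant_idx <- c(1L, 1L)
  expect_error(write_manifest(dup, tempfile()), "duplicate")
})

test_that("dataset construction pairs crops with effective labels", {
  corpus <- anomaly_corpus()
  ds <- build_dataset(corpus, detector = "replay", out_dir = NULL,
                      side = 32)
  # kept frames: clean + leaf_removed, 8 crops each
  expect_equal(nrow(ds$manifest), 16)
  expect_equal(length(ds$crops), 16)
  expect_true(all(vapply(ds$crops, function(x)
    identical(dim(x), c(32L, 32L, 3L)), logical(1))))
  # labels equal the generator's effective pair counts, in truth order
  for (i in unique(ds$manifest$scene_id)) {
    rows <- ds$manifest[ds$manifest$scene_id == i, ]
    expect_equal(rows$pairs, corpus$truth[[i]]$pairs)
  }
})
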