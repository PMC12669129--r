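test_that("IoU matches hand-computed overlaps", {
  a <- boxes(0, 0, 2, 2)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, boxes(5, 5, 7, 7)), 0)
  # 2x2 squares overlapping in a 1x2 strip: 2 / (4 + 4 - 2)
  expect_equal(iou(a, boxes(1, 0, 3, 2)), 1 / 3)
})

test_that("IoU is symmetric, bounded, and 1 only for identical boxes", {
  withr::with_seed(11, {
    for (i in 1:50) {
      a <- random_box(); b <- random_box()
      v <- iou(a, b)
      expect_equal(v, iou(b, a))
      expect_gte(v, 0); expect_lte(v, 1)
      same <- isTRUE(all.equal(unlist(a[1:4]), unlist(b[1:4])))
      if (!same) expect_lt(v, 1) else expect_equal(v, 1)
    }
  })
})

test_that("printed confusion counts give the expected precision and recall", {
  s <- detection_summary(tp = 352, fp = 0, fn = 1)
  expect_equal(s$precision, 1.000)
  expect_equal(round(s$recall, 3), 0.997)
})

test_that("matching preserves the count identities", {
  withr::with_seed(12, {
    for (i in 1:20) {
      preds <- random_boxes(sample(0:6, 1))
      truths <- random_boxes(sample(1:6, 1))
      m <- match_boxes(preds, truths, 0.3)
      expect_equal(m$tp + m$fn, nrow(truths))
      expect_equal(m$tp + m$fp, nrow(preds))
      expect_equal(m$tp, nrow(m$pairs))
      expect_true(!anyDuplicated(m$pairs$truth_idx))
      # raising the threshold never increases tp
      expect_lte(match_boxes(preds, truths, 0.6)$tp, m$tp)
    }
  })
})

test_that("exact predictions match perfectly", {
  t <- random_boxes(5)
  m <- match_boxes(t, t, 0.5)
  expect_equal(m$tp, 5)
  expect_equal(m$fp, 0)
  expect_equal(m$fn, 0)
})

# exhaustive assignment oracle: the maximum number of pred-truth pairs
# with IoU >= t under a one-to-one constraint
optimal_matches <- function(preds, truths, t) {
  ok <- iou_matrix(preds, truths) >= t
  np <- nrow(preds); nt <- nrow(truths)
  best <- 0
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  for (p in perms(seq_len(nt))) {
    k <- min(np, nt)
    hits <- sum(vapply(seq_len(k), function(i) ok[i, p[i]], logical(1)))
    best <- max(best, hits)
  }
  best
}

test_that("greedy matching never beats the optimal assignment", {
  withr::with_seed(13, {
    for (i in 1:15) {
      preds <- random_boxes(4, max_xy = 30)
      truths <- random_boxes(4, max_xy = 30)
      m <- match_boxes(preds, truths, 0.2)
      expect_lte(m$tp, optimal_matches(preds, truths, 0.2))
    }
    # equality on non-overlapping layouts, where matching is unambiguous
    truths <- boxes(c(0, 50, 100), c(0, 0, 0), c(10, 60, 110),
                    c(10, 10, 10))
    preds <- truths[sample(3), ]
    m <- match_boxes(preds, truths, 0.5)
    expect_equal(m$tp, optimal_matches(preds, truths, 0.5))
    expect_equal(m$tp, 3)
  })
})

test_that("the F1-confidence sweep finds the right threshold", {
  t <- random_boxes(4)
  good <- t
  good$conf <- c(0.95, 0.93, 0.9, 0.97)
  res <- f1_confidence_curve(list(good), list(t))
  expect_true(all(res$curve$f1[res$curve$threshold <= 0.9] == 1))
  expect_true(all(res$curve$f1 >= 0 & res$curve$f1 <= 1))
  expect_gte(nrow(res$curve), length(unique(good$conf)))

  # one spurious low-confidence detection: optimum cuts it away
  spurious <- rbind(good, boxes(500, 500, 510, 510, conf = 0.2))
  res2 <- f1_confidence_curve(list(spurious), list(t))
  expect_gt(res2$best_threshold, 0.2)
  expect_equal(max(res2$curve$f1), 1)

  expect_error(f1_confidence_curve(list(empty_boxes()), list(t)),
               "prediction")
  expect_error(f1_confidence_curve(list(good), list(empty_boxes())),
               "ground-truth")
})

test_that("average precision matches hand-computed PR integration", {
  t <- random_boxes(4)
  perfect <- t; perfect$conf <- c(0.9, 0.8, 0.85, 0.95)
  res <- average_precision(list(perfect), list(t))
  expect_true(all(res$ap == 1))
  expect_equal(res$map, 1)

  # detector missing half the truths, no false positives: AP = recall
  half <- t[1:2, ]; half$conf <- c(0.9, 0.8)
  res2 <- average_precision(list(half), list(t), iou_thresholds = 0.5)
  expect_equal(unname(res2$ap), 0.5)

  # 6-prediction toy set, checked against an independent step
  # integration computed from the TP/FP sequence
  truths <- boxes(c(0, 20, 40), c(0, 0, 0), c(10, 30, 50), c(10, 10, 10))
  preds <- rbind(
    boxes(0, 0, 10, 10, conf = 0.95),     # TP
    boxes(100, 100, 110, 110, conf = 0.9),# FP
    boxes(20, 0, 30, 10, conf = 0.8),     # TP
    boxes(200, 200, 210, 210, conf = 0.7),# FP
    boxes(40, 0, 50, 10, conf = 0.6),     # TP
    boxes(0, 1, 10, 11, conf = 0.5))      # FP (truth 1 already matched)
  res3 <- average_precision(list(preds), list(truths),
                            iou_thresholds = 0.5)
  is_tp <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  prec <- cumsum(is_tp) / seq_along(is_tp)
  rec <- cumsum(is_tp) / 3
  expected <- 0
  for (k in seq_along(is_tp)) {
    dr <- rec[k] - if (k == 1) 0 else rec[k - 1]
    expected <- expected + dr * max(prec[k:length(prec)])
  }
  expect_equal(unname(res3$ap), expected)
})

test_that("the reference detector finds all plants in a clean scene", {
  corpus <- clean_corpus()
  img <- corpus$images[[1]]
  det <- reference_detect(img)
  expect_equal(nrow(det), 8)
  m <- match_boxes(det, corpus$truth[[1]]$boxes, 0.5)
  expect_equal(m$tp, 8)
  expect_true(all(m$pairs$iou >= 0.5))
})

test_that("dark and empty frames yield no detections", {
  dark <- render_scene(random_scene(3, anomaly = "dark_frame"))
  expect_equal(nrow(reference_detect(dark$image)), 0)
  blank <- array(0.2, c(80, 80, 3))
  expect_equal(nrow(reference_detect(blank)), 0)
  expect_error(reference_detect(matrix(0.5, 50, 50)), "3-channel")
})

test_that("detections survive a CSV round trip", {
  det <- cbind(scene_id = 1L, random_boxes(3))
  path <- tempfile(fileext = ".csv")
  write_detections(det, path)
  back <- read_detections(path)
  expect_equal(back[["1"]]$x1, det$x1)
  expect_equal(back[["1"]]$conf, det$conf)
})
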