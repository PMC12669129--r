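# Shared fixtures, rendered once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# six clean scenes with per-plant paint masks kept in memory
clean_corpus <- function() {
  if (is.null(.fixtures$clean))
    .fixtures$clean <- make_corpus(6, keep_images = TRUE,
                                   keep_masks = TRUE, seed = 101)
  .fixtures$clean
}

# one scene of each anomaly category plus one clean scene
anomaly_corpus <- function() {
  if (is.null(.fixtures$anom)) {
    rates <- c(multi_seedling = 1 / 6, dark_frame = 1 / 6,
               out_of_frame = 1 / 6, empty_pot = 1 / 6,
               leaf_removed = 1 / 6)
    .fixtures$anom <- make_corpus(6, anomaly_rates = rates,
                                  keep_images = TRUE, seed = 202)
  }
  .fixtures$anom
}

# a tiny crop dataset for fast training tests (single shared render)
tiny_crops <- function() {
  if (is.null(.fixtures$crops)) {
    corpus <- make_corpus(10, keep_images = TRUE, seed = 303)
    ds <- build_dataset(corpus, detector = "replay", out_dir = NULL,
                        side = 32)
    .fixtures$crops <- list(x = ds$crops, y = ds$manifest$pairs)
  }
  .fixtures$crops
}

# fast, deterministic training configuration for mechanism tests
tiny_config <- function(...) {
  synthetic_train_config(channels = c(4, 8), input_side = 24,
                         batch_size = 16, max_epochs = 4, patience = 2,
                         seed = 7, ...)
}

# cheap deterministic stand-in trainer: linear model on greenness
# summary features of each crop (used where CNN training would only
# slow mechanism tests down)
greenness_features <- function(data) {
  t(vapply(data$x, function(cr) {
    g <- cr[, , 2]; r <- cr[, , 1]; b <- cr[, , 3]
    green <- g > 1.1 * r & g > 1.1 * b
    gx <- abs(g[-1, ] - g[-nrow(g), ])
    gy <- abs(g[, -1] - g[, -ncol(g)])
    c(fg = mean(green), mg = mean(g[green]),
      ed = mean(gx) + mean(gy),
      q = unname(stats::quantile(g[green], 0.9)))
  }, numeric(4)))
}

greenness_trainer <- function(train, val) {
  df <- data.frame(y = train$y, greenness_features(train))
  fit <- stats::lm(y ~ ., df)
  function(data)
    unname(stats::predict(fit, data.frame(greenness_features(data))))
}

random_box <- function(max_xy = 100, max_wh = 40) {
  x1 <- stats::runif(1, 0, max_xy)
  y1 <- stats::runif(1, 0, max_xy)
  boxes(x1, y1, x1 + stats::runif(1, 1, max_wh),
        y1 + stats::runif(1, 1, max_wh), conf = stats::runif(1))
}

random_boxes <- function(n, ...) {
  if (n == 0)
    return(boxes(numeric(0), numeric(0), numeric(0), numeric(0),
                 numeric(0)))
  do.call(rbind, lapply(seq_len(n), function(i) random_box(...)))
}
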