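test_that("Huber loss evaluates its closed form", {
  expect_equal(huber_loss(0, 0), 0)
  expect_equal(huber_loss(0.5, 0, delta = 1), 0.125)   # quadratic branch
  expect_equal(huber_loss(2, 0, delta = 1), 1.5)       # linear branch
  # sum over terms by default, mean on request
  expect_equal(huber_loss(c(0.5, 2), c(0, 0)), 0.125 + 1.5)
  expect_equal(huber_loss(c(0.5, 2), c(0, 0), reduction = "mean"),
               (0.125 + 1.5) / 2)
  expect_error(huber_loss(1:3, 1:2), "equal length")
  expect_error(huber_loss(numeric(0), numeric(0)), "empty")
  expect_error(huber_loss(1, 1, delta = 0))
})

test_that("Huber loss is continuous and smooth at the knee", {
  for (delta in c(0.5, 1, 2)) {
    below <- huber_loss(delta - 1e-9, 0, delta)
    above <- huber_loss(delta + 1e-9, 0, delta)
    expect_equal(below, above, tolerance = 1e-7)
    expect_equal(below, 0.5 * delta^2, tolerance = 1e-7)
  }
  # quadratic everywhere below delta; half squared error as delta grows
  e <- seq(-0.99, 0.99, by = 0.11)
  expect_equal(huber_loss(e, rep(0, length(e))), sum(0.5 * e^2))
  big <- seq(-30, 30, by = 3.7)
  expect_equal(huber_loss(big, rep(0, length(big)), delta = 1e6),
               sum(0.5 * big^2))
})

test_that("Huber gradient matches finite differences", {
  es <- c(-2.5, -1.2, -0.4, 0.3, 0.9, 1.1, 3)
  for (delta in c(0.7, 1)) {
    ana <- huber_grad(es, rep(0, length(es)), delta)
    num <- vapply(es, function(e)
      (huber_loss(e + 1e-6, 0, delta) - huber_loss(e - 1e-6, 0, delta)) /
        2e-6, numeric(1))
    expect_equal(ana, num, tolerance = 1e-6)
  }
})

test_that("network gradients match finite differences", {
  withr::with_seed(40, {
    for (setup in list(list(act = "leaky_relu", bk = "small_conv"),
                       list(act = "gelu", bk = "residual_small"))) {
      net <- phenostage:::nn_new(8, c(3, 5), setup$act, 0, setup$bk,
                                 seed = 2)
      x <- array(stats::runif(8 * 8 * 3 * 3), c(8, 8, 3, 3))
      y <- stats::runif(3, 0, 5)
      params <- phenostage:::nn_params(net)
      fw <- phenostage:::nn_forward(net, x)
      g <- phenostage:::grads_as_params(
        net, phenostage:::nn_backward(net, fw,
                                      huber_grad(fw$pred, y) / 3))
      loss_at <- function(p) {
        n2 <- phenostage:::nn_set_params(net, p)
        huber_loss(phenostage:::nn_forward(n2, x)$pred, y,
                   reduction = "mean")
      }
      for (nm in names(params)) {
        ii <- seq_len(min(3, length(params[[nm]])))
        num <- vapply(ii, function(j) {
          pp <- params
          pp[[nm]][j] <- pp[[nm]][j] + 1e-6
          l1 <- loss_at(pp)
          pp[[nm]][j] <- pp[[nm]][j] - 2e-6
          (l1 - loss_at(pp)) / 2e-6
        }, numeric(1))
        expect_equal(as.vector(g[[nm]])[ii], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("rounding is half-up and clamped", {
  expect_identical(round_clamp(3.4), 3L)
  expect_identical(round_clamp(2.5), 3L)
  expect_identical(round_clamp(-0.3, max_pairs = 10), 0L)
  expect_identical(round_clamp(c(11.7, 3.5, -2), max_pairs = 10),
                   c(10L, 4L, 0L))
})

test_that("augmentation is label-preserving, bounded and deterministic", {
  crop <- tiny_crops()$x[[1]]
  cfg0 <- augment_config(0, 0, 0, 0, 0, 0)
  expect_identical(augment(crop, cfg0, seed = 5), crop)
  # pure horizontal flip mirrors the image exactly
  flip_only <- augment_config(0, 0, 0, 0, hflip_p = 1, rot_deg = 0)
  expect_equal(augment(crop, flip_only, seed = 1),
               crop[, rev(seq_len(dim(crop)[2])), , drop = FALSE])
  # extreme jitter stays within the valid pixel range
  wild <- augment_config(brightness = 3, contrast = 3, saturation = 3,
                         hue = 0.5, hflip_p = 0.5, rot_deg = 45)
  withr::with_seed(41, {
    for (i in 1:10) {
      a <- augment(crop, wild, seed = i)
      expect_true(all(a >= 0 & a <= 1))
      expect_equal(dim(a), dim(crop))
    }
  })
  expect_identical(augment(crop, augment_config(), seed = 9),
                   augment(crop, augment_config(), seed = 9))
})

test_that("configs validate their fields", {
  expect_error(regressor_config(dropout = 1), "dropout")
  expect_error(regressor_config(lr = 0))
  expect_error(regressor_config(patience = 0))
  expect_error(regressor_config(input_side = 50, channels = c(4, 8)))
  expect_error(augment_config(hflip_p = 2))
  cfg <- regressor_config()
  expect_equal(cfg$lr, 3.67e-5)
  expect_equal(cfg$weight_decay, 4.81e-4)
  expect_equal(cfg$dropout, 0.134)
  expect_equal(cfg$patience, 7)
  expect_equal(cfg$activation, "leaky_relu")
})

test_that("a constant-label dataset is fit to that constant", {
  d <- tiny_crops()
  idx <- seq_len(min(40, length(d$y)))
  tr <- list(x = d$x[idx], y = rep(4, length(idx)))
  va <- list(x = d$x[idx[1:10]], y = rep(4, 10))
  fit <- train_regressor(tr, va, tiny_config(max_epochs = 6), aug = NULL)
  p <- predict(fit, va)
  expect_lt(mean(abs(p - 4)), 0.1)
})

test_that("training is seed-deterministic and honours early stopping", {
  d <- tiny_crops()
  n <- length(d$y)
  tr <- list(x = d$x[1:(n - 16)], y = d$y[1:(n - 16)])
  va <- list(x = d$x[(n - 15):n], y = d$y[(n - 15):n])
  cfg <- tiny_config(max_epochs = 5, patience = 2)
  f1 <- train_regressor(tr, va, cfg, aug = augment_config())
  f2 <- train_regressor(tr, va, cfg, aug = augment_config())
  expect_identical(predict(f1, va), predict(f2, va))
  expect_identical(f1$history, f2$history)
  # best-epoch validation loss is the minimum of the history
  expect_equal(f1$best_val_loss, min(f1$history$val_loss))
  expect_equal(f1$history$val_loss[f1$best_epoch], f1$best_val_loss)
  if (f1$early_stopped)
    expect_equal(f1$stopped_epoch - f1$best_epoch, f1$cfg$patience)
  # a plateauing run (learning rate too small to improve) stops within
  # patience of its best epoch
  trc <- list(x = tr$x[1:20], y = rep(3, 20))
  vac <- list(x = va$x[1:8], y = rep(3, 8))
  fc <- train_regressor(trc, vac, tiny_config(max_epochs = 30,
                                              patience = 2, lr = 1e-12),
                        aug = NULL)
  expect_true(fc$early_stopped)
  expect_equal(fc$stopped_epoch - fc$best_epoch, 2)
  expect_lt(fc$stopped_epoch, 30)
})

test_that("predictions are finite, batch-consistent and method-complete", {
  d <- tiny_crops()
  tr <- list(x = d$x[1:30], y = d$y[1:30])
  va <- list(x = d$x[31:40], y = d$y[31:40])
  fit <- train_regressor(tr, va, tiny_config(), aug = NULL)
  p_all <- predict(fit, va)
  p_one <- vapply(va$x, function(cr) predict(fit, cr), numeric(1))
  expect_equal(p_all, p_one, tolerance = 1e-10)
  blank <- array(0, c(24, 24, 3))
  expect_true(is.finite(predict(fit, blank)))
  expect_output(print(fit), "Leaf-pair regressor")
  s <- summary(fit)
  expect_s3_class(s, "summary.leafreg")
  expect_true(is.finite(s$val_metrics$mae))
  expect_equal(residuals(fit), fitted(fit) - va$y)
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})

test_that("hyperparameter search returns a valid config and prunes", {
  d <- tiny_crops()
  tr <- list(x = d$x[1:24], y = d$y[1:24])
  va <- list(x = d$x[25:32], y = d$y[25:32])
  space <- list(lr = structure(c(1e-4, 1e-2), log = TRUE),
                dropout = c(0, 0.2))
  base <- tiny_config(max_epochs = 3)
  r1 <- search_hyperparams(tr, va, space, n_trials = 1, seed = 5,
                           base_cfg = base, prune_epoch = 2)
  expect_s3_class(r1$best_config, "regressor_config")
  expect_equal(nrow(r1$trials), 1)
  r3 <- search_hyperparams(tr, va, space, n_trials = 4, seed = 5,
                           base_cfg = base, prune_epoch = 2)
  r3b <- search_hyperparams(tr, va, space, n_trials = 4, seed = 5,
                            base_cfg = base, prune_epoch = 2)
  expect_identical(r3$trials, r3b$trials)
  expect_true(is.finite(r3$best_val_loss))
  # at least the first two trials ran to completion (the median rule
  # needs two milestones before it can prune)
  expect_false(any(r3$trials$pruned[1:2]))
})
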