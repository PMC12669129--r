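#' Huber loss
#'
#' Robust regression loss: quadratic for residuals smaller than `delta`,
#' linear beyond it, so occasional mislabelled samples cannot dominate
#' training. Per term, with error `e = x - y`:
#' `l = e^2 / 2` when `|e| < delta`, and `l = delta * (|e| - delta / 2)`
#' otherwise. The two branches join continuously and with matching first
#' derivative at `|e| = delta`.
#'
#' @param x Numeric vector of predictions.
#' @param y Numeric vector of targets (same length, non-empty).
#' @param delta Positive transition threshold between the quadratic and
#'   the linear regime. Default 1.
#' @param reduction `"sum"` (the loss as classically written) or
#'   `"mean"` (per-sample average, used for training).
#' @return A non-negative scalar.
#' @examples
#' huber_loss(0.5, 0)        # 0.125
#' huber_loss(2, 0)          # 1.5
#' @export
huber_loss <- function(x, y, delta = 1, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (length(x) != length(y))
    stop("predictions and targets must have equal length", call. = FALSE)
  if (length(x) == 0) stop("empty batch", call. = FALSE)
  stopifnot(delta > 0)
  e <- abs(x - y)
  l <- ifelse(e < delta, 0.5 * e^2, delta * (e - 0.5 * delta))
  if (reduction == "sum") sum(l) else mean(l)
}

# dl/dx per term (for reduction = "mean" divide by n at the call site)
huber_grad <- function(x, y, delta = 1) {
  e <- x - y
  ifelse(abs(e) < delta, e, delta * sign(e))
}

#' Regressor training configuration
#'
#' Collects every hyperparameter of the leaf-pair regressor. The
#' defaults for optimiser and regularisation (learning rate 3.67e-5,
#' AdamW weight decay 4.81e-4, dropout 0.134, LeakyReLU, early-stopping
#' patience 7, no LR scheduler) are the tuned settings for the
#' full-resolution chamber data; [synthetic_train_config()] overrides
#' the learning rate for the small synthetic corpora this package trains
#' on, where 3.67e-5 is needlessly slow.
#'
#' @param backbone `"small_conv"` (default, a compact stack of
#'   conv-activation-pool blocks) or `"residual_small"` (each block gains
#'   a second convolution with an identity skip).
#' @param channels Integer vector of feature channels per block.
#' @param dropout Dropout fraction applied to the pooled features (head
#'   only), in `[0, 1)`.
#' @param activation `"leaky_relu"`, `"relu"` or `"gelu"`.
#' @param lr Learning rate (> 0).
#' @param weight_decay Decoupled (AdamW) weight-decay coefficient.
#' @param patience Early-stopping patience in epochs (>= 1).
#' @param delta Huber transition threshold (> 0).
#' @param batch_size Minibatch size.
#' @param max_epochs Upper bound on training epochs.
#' @param input_side Square model input side in pixels; must be divisible
#'   by `2^length(channels)`.
#' @param seed Integer seed controlling initialisation, shuffling,
#'   dropout and augmentation.
#' @return An object of class `regressor_config`.
#' @export
regressor_config <- function(backbone = c("small_conv", "residual_small"),
                             channels = c(8, 16, 32), dropout = 0.134,
                             activation = c("leaky_relu", "relu", "gelu"),
                             lr = 3.67e-5, weight_decay = 4.81e-4,
                             patience = 7, delta = 1, batch_size = 32,
                             max_epochs = 60, input_side = 48, seed = 1L) {
  backbone <- match.arg(backbone)
  activation <- match.arg(activation)
  stopifnot(dropout >= 0, dropout < 1, lr > 0, weight_decay >= 0,
            patience >= 1, delta > 0, batch_size >= 1, max_epochs >= 1,
            input_side %% 2^length(channels) == 0)
  structure(list(backbone = backbone, channels = channels,
                 dropout = dropout, activation = activation, lr = lr,
                 weight_decay = weight_decay, patience = patience,
                 delta = delta, batch_size = batch_size,
                 max_epochs = max_epochs,
                 input_side = as.integer(input_side),
                 seed = as.integer(seed)),
            class = "regressor_config")
}

#' @rdname regressor_config
#' @param ... Overrides passed to [regressor_config()].
#' @export
synthetic_train_config <- function(...) {
  args <- list(...)
  defaults <- list(lr = 3e-3, max_epochs = 60)
  args <- utils::modifyList(defaults, args)
  do.call(regressor_config, args)
}

#' Photometric and geometric augmentation configuration
#'
#' Label-preserving augmentation emulating lighting fluctuation and
#' viewpoint change: colour jitter in brightness (+-10.6%), contrast
#' (+-24.5%), saturation (+-36.6%) and hue (+-5.6%), horizontal flipping
#' with probability 26.3%, and rotation up to +-10 degrees. None of
#' these transforms can alter a crop's leaf-pair count.
#'
#' @param brightness,contrast,saturation,hue Maximum +- jitter fractions.
#' @param hflip_p Horizontal flip probability in `[0, 1]`.
#' @param rot_deg Maximum rotation magnitude in degrees.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(brightness = 0.106, contrast = 0.245,
                           saturation = 0.366, hue = 0.056,
                           hflip_p = 0.263, rot_deg = 10) {
  stopifnot(brightness >= 0, contrast >= 0, saturation >= 0, hue >= 0,
            hflip_p >= 0, hflip_p <= 1, rot_deg >= 0)
  structure(list(brightness = brightness, contrast = contrast,
                 saturation = saturation, hue = hue, hflip_p = hflip_p,
                 rot_deg = rot_deg),
            class = "augment_config")
}

#' Apply a random augmentation to one crop
#'
#' Draws all jitter magnitudes from a stream seeded by `seed`, so the
#' same `(crop, cfg, seed)` always yields the same output. Pixel values
#' are clamped back to `[0, 1]`.
#'
#' @param crop Numeric `h x w x 3` array in `[0, 1]`.
#' @param cfg An [augment_config()].
#' @param seed Integer seed.
#' @return Augmented crop of the same dimensions.
#' @export
augment <- function(crop, cfg = augment_config(), seed = 1L) {
  stopifnot(inherits(cfg, "augment_config"))
  with_seed(seed, {
    x <- crop
    if (cfg$brightness > 0)
      x <- x * (1 + stats::runif(1, -cfg$brightness, cfg$brightness))
    if (cfg$contrast > 0) {
      m <- mean(x)
      x <- (x - m) * (1 + stats::runif(1, -cfg$contrast, cfg$contrast)) + m
    }
    if (cfg$saturation > 0) {
      gray <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
      s <- 1 + stats::runif(1, -cfg$saturation, cfg$saturation)
      for (ch in 1:3) x[, , ch] <- gray + (x[, , ch] - gray) * s
    }
    x <- pmin(pmax(x, 0), 1)
    if (cfg$hue > 0) {
      dh <- stats::runif(1, -cfg$hue, cfg$hue)
      d <- dim(x)
      m <- matrix(aperm(x, c(3, 1, 2)), nrow = 3)
      hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
      hsv[1, ] <- (hsv[1, ] + dh) %% 1
      rgb <- grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])
      m2 <- grDevices::col2rgb(rgb) / 255
      x <- aperm(array(m2, c(3, d[1], d[2])), c(2, 3, 1))
    }
    if (cfg$hflip_p > 0 && stats::runif(1) < cfg$hflip_p)
      x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
    if (cfg$rot_deg > 0) {
      ang <- stats::runif(1, -cfg$rot_deg, cfg$rot_deg)
      x <- EBImage::rotate(x, ang, output.dim = dim(x)[1:2], bg.col = 0)
      x <- array(x, dim(crop))
    }
    pmin(pmax(x, 0), 1)
  })
}

standardize_crops <- function(x, norm) {
  for (ch in 1:3)
    x[, , ch, ] <- (x[, , ch, ] - norm$mean[ch]) / norm$sd[ch]
  x
}

# ---- data marshalling --------------------------------------------------

# accepts: a manifest data.frame (crop_path + pairs), or a list with
# elements x (list of crop arrays, or an (s,s,3,n) array) and y
load_crops <- function(data, side) {
  if (is.data.frame(data)) {
    n <- nrow(data)
    x <- array(0, c(side, side, 3, n))
    for (i in seq_len(n)) {
      im <- png::readPNG(data$crop_path[i])
      if (length(dim(im)) == 2) im <- array(rep(im, 3), c(dim(im), 3))
      if (!all(dim(im)[1:2] == side))
        im <- EBImage::resize(im[, , 1:3, drop = FALSE], w = side, h = side)
      x[, , , i] <- im[, , 1:3]
    }
    return(list(x = x, y = as.numeric(data$pairs)))
  }
  stopifnot(is.list(data), !is.null(data$x), !is.null(data$y))
  xs <- data$x
  if (is.array(xs) && length(dim(xs)) == 4) {
    if (all(dim(xs)[1:2] == side)) return(list(x = xs,
                                               y = as.numeric(data$y)))
    xs <- lapply(seq_len(dim(xs)[4]), function(i) xs[, , , i])
  }
  n <- length(xs)
  x <- array(0, c(side, side, 3, n))
  for (i in seq_len(n)) {
    im <- xs[[i]]
    if (!all(dim(im)[1:2] == side))
      im <- EBImage::resize(im, w = side, h = side)
    x[, , , i] <- im
  }
  list(x = x, y = as.numeric(data$y))
}

# ---- training ----------------------------------------------------------

#' Fit the leaf-pair regressor
#'
#' Trains a small convolutional network to predict the (continuous)
#' leaf-pair count of a cropped plant image, minimising the Huber loss
#' with AdamW. Training stops early when the validation loss has not
#' improved for `cfg$patience` consecutive epochs, and the weights of
#' the best validation epoch are returned. The run is deterministic for
#' a fixed `cfg$seed`.
#'
#' @param train,val Training and validation data: either manifest
#'   `data.frame`s (columns `crop_path`, `pairs`) or lists with elements
#'   `x` (list of `h x w x 3` crop arrays, or an `(s, s, 3, n)` array)
#'   and `y` (numeric labels).
#' @param cfg A [regressor_config()].
#' @param aug An [augment_config()] applied to training crops each
#'   epoch, or `NULL` to disable augmentation.
#' @param stop_check Optional `function(epoch, val_loss)` returning
#'   `TRUE` to abort the run (used by the hyperparameter search for
#'   median pruning).
#' @param verbose Print one line per epoch.
#' @return An object of class `leafreg`: the fitted network, the
#'   configuration, a per-epoch `history` data.frame (`epoch`,
#'   `train_loss`, `val_loss`), `best_epoch`, `stopped_epoch`,
#'   `early_stopped`, and the validation predictions of the best epoch.
#' @seealso [predict.leafreg()], [round_clamp()]
#' @export
train_regressor <- function(train, val, cfg = synthetic_train_config(),
                            aug = augment_config(), stop_check = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(cfg, "regressor_config"))
  tr <- load_crops(train, cfg$input_side)
  va <- load_crops(val, cfg$input_side)
  n <- length(tr$y)
  if (n == 0 || length(va$y) == 0)
    stop("train and val sets must be non-empty", call. = FALSE)
  # per-channel standardisation, estimated on the training set only
  norm <- list(mean = apply(tr$x, 3, mean),
               sd = pmax(apply(tr$x, 3, stats::sd), 1e-6))
  va$x <- standardize_crops(va$x, norm)
  net <- nn_new(cfg$input_side, cfg$channels, cfg$activation, cfg$dropout,
                cfg$backbone, seed = cfg$seed)
  net$dense_b <- mean(tr$y)   # start the head at the target mean
  params <- nn_params(net)
  opt <- adamw_new(params, cfg$lr, cfg$weight_decay)
  best <- list(val = Inf, params = params, epoch = 0L, val_pred = NULL)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  early <- FALSE
  epoch <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, epoch), sample(n))
    tot_loss <- 0
    for (bs in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      xb <- tr$x[, , , bs, drop = FALSE]
      if (!is.null(aug)) {
        for (k in seq_along(bs)) {
          aseed <- derive_seed(cfg$seed, epoch * 100003 + bs[k])
          xb[, , , k] <- augment(xb[, , , k], aug, seed = aseed)
        }
      }
      xb <- standardize_crops(xb, norm)
      yb <- tr$y[bs]
      net <- nn_set_params(net, params)
      fw <- with_seed(derive_seed(cfg$seed, epoch * 7 + bs[1]),
                      nn_forward(net, xb, train = TRUE))
      loss <- huber_loss(fw$pred, yb, cfg$delta, reduction = "mean")
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch,
             "; check learning rate and inputs", call. = FALSE)
      tot_loss <- tot_loss + loss * length(bs)
      dpred <- huber_grad(fw$pred, yb, cfg$delta) / length(bs)
      grads <- grads_as_params(net, nn_backward(net, fw, dpred))
      st <- adamw_step(opt, params, grads)
      opt <- st$opt
      params <- st$params
    }
    net <- nn_set_params(net, params)
    val_pred <- nn_forward(net, va$x, train = FALSE)$pred
    val_loss <- huber_loss(val_pred, va$y, cfg$delta, reduction = "mean")
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = tot_loss / n,
                                   val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      tot_loss / n, val_loss))
    if (val_loss < best$val - 1e-9) {
      best <- list(val = val_loss, params = params, epoch = epoch,
                   val_pred = val_pred)
    } else if (epoch - best$epoch >= cfg$patience) {
      early <- TRUE
      break
    }
    if (!is.null(stop_check) && isTRUE(stop_check(epoch, val_loss)))
      break
  }
  net <- nn_set_params(net, best$params)
  structure(list(net = net, cfg = cfg, aug = aug, norm = norm,
                 history = hist,
                 best_epoch = best$epoch, stopped_epoch = epoch,
                 early_stopped = early, best_val_loss = best$val,
                 val_pred = best$val_pred, val_y = va$y),
            class = "leafreg")
}

#' @export
print.leafreg <- function(x, ...) {
  cat("Leaf-pair regressor (", x$cfg$backbone, ", ",
      paste(x$cfg$channels, collapse = "-"), " channels, input ",
      x$cfg$input_side, "px)\n", sep = "")
  cat(sprintf("  epochs run %d, best epoch %d (val Huber %.4f)%s\n",
              x$stopped_epoch, x$best_epoch, x$best_val_loss,
              if (x$early_stopped) ", early-stopped" else ""))
  invisible(x)
}

#' @export
summary.leafreg <- function(object, ...) {
  m <- regression_metrics(object$val_pred, object$val_y)
  out <- list(cfg = object$cfg, history = object$history,
              best_epoch = object$best_epoch,
              stopped_epoch = object$stopped_epoch,
              early_stopped = object$early_stopped,
              val_metrics = m)
  class(out) <- "summary.leafreg"
  out
}

#' @export
print.summary.leafreg <- function(x, ...) {
  cat("Leaf-pair regressor fit\n")
  cat(sprintf("  epochs: %d (best %d%s)\n", x$stopped_epoch, x$best_epoch,
              if (x$early_stopped) ", early-stopped" else ""))
  cat(sprintf("  validation: MAE %.3f  RMSE %.3f  R2 %.3f\n",
              x$val_metrics$mae, x$val_metrics$rmse, x$val_metrics$r2))
  invisible(x)
}

#' Predict leaf-pair counts
#'
#' Forward pass in evaluation mode (no dropout): one finite real-valued
#' prediction per crop. Use [round_clamp()] to convert to integer
#' counts.
#'
#' @param object A fitted `leafreg` model.
#' @param newdata Crops in any of the forms accepted by
#'   [train_regressor()]; a single `h x w x 3` array is also accepted.
#' @param batch_size Crops evaluated per forward pass.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.leafreg <- function(object, newdata, batch_size = 64, ...) {
  if (is.array(newdata) && length(dim(newdata)) == 3)
    newdata <- list(x = list(newdata), y = NA_real_)
  if (is.list(newdata) && !is.data.frame(newdata) && is.null(newdata$y))
    newdata <- list(x = newdata, y = rep(NA_real_, length(newdata)))
  d <- load_crops(newdata, object$cfg$input_side)
  if (!is.null(object$norm)) d$x <- standardize_crops(d$x, object$norm)
  n <- dim(d$x)[4]
  preds <- numeric(n)
  for (bs in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fw <- nn_forward(object$net, d$x[, , , bs, drop = FALSE],
                     train = FALSE)
    preds[bs] <- fw$pred
  }
  preds
}

#' @export
residuals.leafreg <- function(object, ...) {
  object$val_pred - object$val_y
}

#' @export
fitted.leafreg <- function(object, ...) object$val_pred

#' Plot training history
#'
#' Training and validation Huber loss per epoch, with the best epoch
#' marked.
#'
#' @param x A fitted `leafreg`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.leafreg <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "Huber loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Convenience wrapper: predictions for a list of crops
#'
#' @param model A fitted `leafreg`.
#' @param crops List of crop arrays (or any form accepted by
#'   [predict.leafreg()]).
#' @return Numeric predictions.
#' @export
predict_pairs <- function(model, crops) {
  predict(model, crops)
}

#' Round and clamp continuous predictions
#'
#' Converts continuous leaf-pair predictions to integer counts by
#' half-up rounding (2.5 becomes 3) and clamping into `[0, max_pairs]`.
#'
#' @param predictions Numeric vector.
#' @param max_pairs Largest admissible pair count (>= 1).
#' @return Integer vector.
#' @examples
#' round_clamp(c(3.4, 2.5, -0.3), max_pairs = 10)  # 3 3 0
#' @export
round_clamp <- function(predictions, max_pairs = 10) {
  stopifnot(max_pairs >= 1)
  as.integer(pmin(pmax(floor(predictions + 0.5), 0), max_pairs))
}

#' Random hyperparameter search with median pruning
#'
#' Sequential random search over a user-defined space with
#' median-based pruning: each trial's validation loss at the pruning
#' epoch is compared against the median of all previous trials at that
#' epoch, and clearly worse trials are aborted. Returns the best
#' configuration by final validation loss and a full trial table.
#'
#' @param train,val Data as in [train_regressor()].
#' @param space Named list; each element is either a numeric length-2
#'   `c(min, max)` range (sampled log-uniformly if `log = TRUE` is set
#'   as an attribute, otherwise uniformly) or a vector of discrete
#'   choices.
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer seed; fixed seed gives an identical trial
#'   sequence.
#' @param base_cfg Configuration whose fields the sampled values
#'   override.
#' @param prune_epoch Epoch at which the median rule is applied.
#' @param aug Augmentation, as in [train_regressor()].
#' @return A list with `best_config`, `best_val_loss` and `trials` (a
#'   `data.frame` with one row per trial: sampled values, final
#'   validation loss, pruned flag).
#' @export
search_hyperparams <- function(train, val, space, n_trials = 10,
                               seed = 1L,
                               base_cfg = synthetic_train_config(),
                               prune_epoch = 5, aug = NULL) {
  stopifnot(n_trials >= 1)
  draws <- with_seed(seed, lapply(seq_len(n_trials), function(i) {
    vals <- lapply(space, function(sp) {
      if (is.numeric(sp) && length(sp) == 2 && is.null(attr(sp, "choices"))) {
        if (isTRUE(attr(sp, "log")))
          exp(stats::runif(1, log(sp[1]), log(sp[2])))
        else stats::runif(1, sp[1], sp[2])
      } else sp[[sample(length(sp), 1)]]
    })
    vals
  }))
  milestone_losses <- numeric(0)
  rows <- list()
  best <- list(val = Inf, cfg = NULL)
  for (i in seq_len(n_trials)) {
    cfg_args <- utils::modifyList(unclass(base_cfg), draws[[i]])
    cfg_args$seed <- derive_seed(seed, i)
    cfg <- do.call(regressor_config, cfg_args)
    pruned <- FALSE
    this_milestone <- NA_real_
    check <- function(epoch, val_loss) {
      if (epoch == prune_epoch) {
        this_milestone <<- val_loss
        if (length(milestone_losses) >= 2 &&
            val_loss > stats::median(milestone_losses)) {
          pruned <<- TRUE
          return(TRUE)
        }
      }
      FALSE
    }
    fit <- train_regressor(train, val, cfg, aug = aug, stop_check = check)
    if (!is.na(this_milestone))
      milestone_losses <- c(milestone_losses, this_milestone)
    final <- fit$best_val_loss
    rows[[i]] <- data.frame(trial = i,
                            as.data.frame(draws[[i]]),
                            val_loss = final, pruned = pruned)
    if (!pruned && final < best$val) best <- list(val = final, cfg = cfg)
    if (is.null(best$cfg)) best$cfg <- cfg   # n_trials == 1, pruned edge
  }
  list(best_config = best$cfg, best_val_loss = best$val,
       trials = do.call(rbind, rows))
}
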