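#' Growth-stage rule
#'
#' Interval thresholds mapping a non-negative leaf-pair count to a
#' discrete growth level. The default follows the three-level scheme
#' used for basil: Level 1 for at most 2 pairs, Level 2 for 3-4 pairs,
#' Level 3 for 5 or more. `boundaries` are the inclusive upper pair
#' counts of all levels but the last, so the mapping is total and
#' monotone by construction.
#'
#' @param boundaries Strictly increasing integer vector; level `k`
#'   covers counts in `(boundaries[k-1], boundaries[k]]`, and the last
#'   level is open-ended.
#' @return An object of class `stage_rule`.
#' @export
stage_rule <- function(boundaries = c(2, 4)) {
  b <- as.numeric(boundaries)
  if (length(b) < 1 || any(diff(b) <= 0))
    stop("boundaries must be strictly increasing", call. = FALSE)
  structure(list(boundaries = b, n_levels = length(b) + 1L),
            class = "stage_rule")
}

#' @export
print.stage_rule <- function(x, ...) {
  lo <- c(0, x$boundaries + 1)
  hi <- c(x$boundaries, Inf)
  for (k in seq_len(x$n_levels)) {
    rng <- if (is.finite(hi[k])) {
      if (lo[k] == hi[k]) sprintf("%d", lo[k])
      else sprintf("%d-%d", lo[k], hi[k])
    } else sprintf(">= %d", lo[k])
    cat(sprintf("  Level %d: %s leaf pairs\n", k, rng))
  }
  invisible(x)
}

#' Map leaf-pair counts to growth levels
#'
#' @param pairs Non-negative integer vector of leaf-pair counts.
#' @param rule A [stage_rule()].
#' @return Integer vector of levels (1-based).
#' @examples
#' map_stage(c(0, 2, 3, 4, 5, 9))  # 1 1 2 2 3 3
#' @export
map_stage <- function(pairs, rule = stage_rule()) {
  stopifnot(inherits(rule, "stage_rule"))
  if (any(pairs < 0)) stop("pairs must be non-negative", call. = FALSE)
  findInterval(pairs, rule$boundaries + 0.5) + 1L
}

#' Regression metrics
#'
#' Mean absolute error, mean squared error, its square root, and the
#' coefficient of determination `R^2 = 1 - SS_res / SS_tot`. `R^2` is
#' undefined for constant targets and raises an error rather than
#' returning `NaN`.
#'
#' @param predictions,targets Equal-length numeric vectors (at least 2
#'   elements for `r2`).
#' @return A list with `mae`, `mse`, `rmse`, `r2`.
#' @examples
#' regression_metrics(c(2, 2, 2), c(1, 2, 3))  # mae 2/3, r2 0
#' @export
regression_metrics <- function(predictions, targets) {
  if (length(predictions) != length(targets))
    stop("predictions and targets must have equal length", call. = FALSE)
  if (length(targets) < 2)
    stop("need at least two observations", call. = FALSE)
  e <- predictions - targets
  ss_tot <- sum((targets - mean(targets))^2)
  if (ss_tot == 0)
    stop("R^2 is undefined for zero-variance targets", call. = FALSE)
  mse <- mean(e^2)
  list(mae = mean(abs(e)), mse = mse, rmse = sqrt(mse),
       r2 = 1 - sum(e^2) / ss_tot)
}

#' Classification metrics for growth levels
#'
#' Accuracy, support-weighted F1 and the row-normalised confusion
#' matrix (rows = true levels, each realised row summing to 1). Per-level
#' F1 is taken as 0 when a level has neither true nor predicted
#' occurrences contributing to it.
#'
#' @param true_levels,pred_levels Equal-length integer vectors.
#' @param levels Set of levels the confusion matrix is laid out over;
#'   defaults to the union of observed values.
#' @return A list with `accuracy`, `weighted_f1`, `per_level` (a
#'   `data.frame` of precision/recall/F1/support per level) and
#'   `confusion` (row-normalised matrix).
#' @export
classification_metrics <- function(true_levels, pred_levels,
                                   levels = NULL) {
  if (length(true_levels) != length(pred_levels))
    stop("inputs must have equal length", call. = FALSE)
  if (length(true_levels) == 0) stop("empty input", call. = FALSE)
  if (is.null(levels))
    levels <- sort(unique(c(true_levels, pred_levels)))
  tt <- factor(true_levels, levels = levels)
  pp <- factor(pred_levels, levels = levels)
  cm <- table(true = tt, pred = pp)
  acc <- sum(diag(cm)) / sum(cm)
  per <- lapply(seq_along(levels), function(k) {
    tp <- cm[k, k]
    fp <- sum(cm[, k]) - tp
    fn <- sum(cm[k, ]) - tp
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(level = levels[k], precision = prec, recall = rec,
               f1 = f1, support = sum(cm[k, ]))
  })
  per <- do.call(rbind, per)
  wf1 <- sum(per$f1 * per$support) / sum(per$support)
  norm <- sweep(unclass(cm), 1, pmax(rowSums(cm), 1), `/`)
  list(accuracy = acc, weighted_f1 = wf1, per_level = per,
       confusion = norm)
}

#' K-fold cross-validation of the staging model
#'
#' Seeded k-way partition of the samples (fold sizes differing by at
#' most one); each fold is held out once, the model is fitted on the
#' remaining folds (with an inner validation split for early stopping),
#' and regression plus stage-classification metrics are computed on the
#' held-out fold. Folds are instance-level, matching how the flat
#' train/val/test split treats crops.
#'
#' @param data A list with `x` (crop list or array) and `y` (labels), or
#'   a manifest `data.frame`.
#' @param k Number of folds (>= 2, at most the number of samples).
#' @param trainer `function(train, val)` returning a model with a
#'   `predict` method; defaults to [train_regressor()] with `cfg`.
#' @param cfg Configuration for the default trainer.
#' @param rule Stage rule for classification metrics.
#' @param max_pairs Clamp bound for [round_clamp()].
#' @param val_frac Fraction of each training part reserved for early
#'   stopping.
#' @param seed Integer seed for the partition.
#' @return A list with `folds` (per-fold metric rows), `mean` and `sd`
#'   (named numeric vectors over metrics), and `assignments` (fold index
#'   per sample).
#' @export
kfold_cv <- function(data, k = 5, trainer = NULL,
                     cfg = synthetic_train_config(), rule = stage_rule(),
                     max_pairs = 10, val_frac = 0.15, seed = 1L) {
  if (is.data.frame(data)) {
    y <- data$pairs
    get_sub <- function(idx) data[idx, , drop = FALSE]
  } else {
    y <- data$y
    xs <- data$x
    if (is.array(xs) && length(dim(xs)) == 4)
      xs <- lapply(seq_len(dim(xs)[4]), function(i) xs[, , , i])
    get_sub <- function(idx) list(x = xs[idx], y = y[idx])
  }
  n <- length(y)
  stopifnot(k >= 2, n >= k)
  if (is.null(trainer))
    trainer <- function(train, val) train_regressor(train, val, cfg,
                                                    aug = NULL)
  fold_of <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold_of == f)
    tr_idx <- which(fold_of != f)
    n_val <- max(1L, floor(length(tr_idx) * val_frac))
    val_idx <- with_seed(derive_seed(seed, f),
                         sample(tr_idx, n_val))
    fit_idx <- setdiff(tr_idx, val_idx)
    model <- trainer(get_sub(fit_idx), get_sub(val_idx))
    preds <- if (is.function(model)) model(get_sub(test_idx)) else
      predict(model, get_sub(test_idx))
    rm <- regression_metrics(preds, y[test_idx])
    cls <- classification_metrics(map_stage(y[test_idx], rule),
                                  map_stage(round_clamp(preds, max_pairs),
                                            rule))
    rows[[f]] <- data.frame(fold = f, n = length(test_idx),
                            mae = rm$mae, mse = rm$mse, rmse = rm$rmse,
                            r2 = rm$r2, accuracy = cls$accuracy,
                            weighted_f1 = cls$weighted_f1)
  }
  folds <- do.call(rbind, rows)
  metric_cols <- c("mae", "mse", "rmse", "r2", "accuracy", "weighted_f1")
  list(folds = folds,
       mean = vapply(folds[metric_cols], mean, numeric(1)),
       sd = vapply(folds[metric_cols], stats::sd, numeric(1)),
       assignments = fold_of)
}
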