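# Minimal convolutional-network engine on base R matrix algebra.
#
# Internally batches use a channels-last layout (h, w, n, channels), so
# im2col and all reshapes are plain dim<- reinterpretations without any
# aperm copies; external callers pass the conventional (h, w, 3, n) and
# nn_forward transposes once on entry. Convolutions are 3x3, stride 1,
# zero padding 1, evaluated by im2col + GEMM so the heavy lifting goes
# through BLAS. Pooling is 2x2 average pooling, the head a global
# average pool, optional dropout and a single linear unit.

pad_batch <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  xp[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- x
  xp
}

# gather-index cache, keyed by input dims, reused across batches/epochs
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(d) {
  key <- paste(d, collapse = "x")
  idx <- .im2col_cache[[key]]
  if (!is.null(idx)) return(idx)
  h <- d[1]; w <- d[2]; n <- d[3]; cin <- d[4]
  hp <- h + 2L; wp <- w + 2L
  # linear index into the padded array for output row (i, j, m) and
  # column (kernel offset (dr, dc), channel ci)
  rowpart <- rep(seq_len(h), times = w * n) +
    hp * rep(rep(0:(w - 1L), each = h), times = n) +
    hp * wp * rep(0:(n - 1L), each = h * w)
  g <- expand.grid(dr = 0:2, dc = 0:2, ci = 0:(cin - 1L))
  colpart <- g$dr + hp * g$dc + hp * wp * n * g$ci
  idx <- outer(rowpart, colpart, `+`)
  .im2col_cache[[key]] <- idx
  idx
}

# (h, w, n, cin) -> (h*w*n, 9*cin); column (ci-1)*9 + k holds kernel
# position k (dr fastest within dc) of input channel ci
im2col <- function(x) {
  d <- dim(x)
  xp <- pad_batch(x)
  idx <- im2col_index(d)
  X <- xp[idx]
  dim(X) <- dim(idx)
  X
}

conv_forward <- function(x, W, b) {
  d <- dim(x)
  X <- im2col(x)
  Y <- X %*% W
  Y <- sweep(Y, 2L, b, `+`)
  dim(Y) <- c(d[1], d[2], d[3], length(b))
  list(y = Y, X = X, xdim = d)
}

conv_backward <- function(dy, cache, W) {
  d <- cache$xdim
  cin <- d[4]
  cout <- dim(W)[2]
  dY <- dy
  dim(dY) <- c(d[1] * d[2] * d[3], cout)
  dW <- crossprod(cache$X, dY)
  db <- colSums(dY)
  # input gradient of a stride-1, pad-1 3x3 conv is the convolution of
  # dy with the spatially flipped, channel-transposed kernel
  Wr <- W
  dim(Wr) <- c(9L, cin, cout)
  Wf <- aperm(Wr[9:1, , , drop = FALSE], c(1L, 3L, 2L))
  dim(Wf) <- c(9L * cout, cin)
  dx <- conv_forward(dy, Wf, numeric(cin))$y
  list(dx = dx, dW = dW, db = db)
}

act_forward <- function(x, kind) {
  switch(kind,
         relu = list(y = pmax(x, 0), cache = x),
         leaky_relu = list(y = pmax(x, 0) + 0.01 * pmin(x, 0), cache = x),
         gelu = {
           inner <- sqrt(2 / pi) * (x + 0.044715 * x^3)
           list(y = 0.5 * x * (1 + tanh(inner)), cache = x)
         },
         stop("unknown activation: ", kind, call. = FALSE))
}

act_backward <- function(dy, cache, kind) {
  x <- cache
  g <- switch(kind,
              relu = (x > 0) * 1,
              leaky_relu = 0.01 + 0.99 * (x > 0),
              gelu = {
                inner <- sqrt(2 / pi) * (x + 0.044715 * x^3)
                th <- tanh(inner)
                0.5 * (1 + th) +
                  0.5 * x * (1 - th^2) * sqrt(2 / pi) *
                  (1 + 3 * 0.044715 * x^2)
              })
  dy * g
}

pool_forward <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[1], by = 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], by = 2L); j2 <- j1 + 1L
  y <- (x[i1, j1, , , drop = FALSE] + x[i2, j1, , , drop = FALSE] +
        x[i1, j2, , , drop = FALSE] + x[i2, j2, , , drop = FALSE]) / 4
  list(y = y, xdim = d)
}

pool_backward <- function(dy, xdim) {
  dx <- array(0, xdim)
  i1 <- seq(1L, xdim[1], by = 2L); i2 <- i1 + 1L
  j1 <- seq(1L, xdim[2], by = 2L); j2 <- j1 + 1L
  q <- dy / 4
  dx[i1, j1, , ] <- q
  dx[i2, j1, , ] <- q
  dx[i1, j2, , ] <- q
  dx[i2, j2, , ] <- q
  dx
}

# (h, w, n, c) -> features (n, c)
gap_forward <- function(x) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  f <- colMeans(xm)
  dim(f) <- c(d[3], d[4])
  list(f = f, xdim = d)
}

gap_backward <- function(df, xdim) {
  hw <- xdim[1] * xdim[2]
  array(rep(as.vector(df) / hw, each = hw), xdim)
}

# ---- network assembly -------------------------------------------------

nn_new <- function(input_side, channels, activation, dropout,
                   backbone = "small_conv", seed = 1L) {
  stopifnot(input_side %% 2^length(channels) == 0)
  with_seed(seed, {
    cin <- 3L
    layers <- list()
    for (co in channels) {
      W <- matrix(stats::rnorm(9L * cin * co, 0, sqrt(2 / (9 * cin))),
                  9L * cin, co)
      layers[[length(layers) + 1L]] <- list(W = W, b = numeric(co))
      if (backbone == "residual_small") {
        W2 <- matrix(stats::rnorm(9L * co * co, 0, sqrt(2 / (9 * co))),
                     9L * co, co)
        layers[[length(layers)]]$W2 <- W2
        layers[[length(layers)]]$b2 <- numeric(co)
      }
      cin <- co
    }
    cl <- channels[length(channels)]
    list(layers = layers,
         dense_W = stats::rnorm(cl, 0, sqrt(1 / cl)), dense_b = 0,
         input_side = as.integer(input_side), channels = channels,
         activation = activation, dropout = dropout, backbone = backbone)
  })
}

# x arrives as (h, w, 3, n)
nn_forward <- function(net, x, train = FALSE) {
  x <- aperm(x, c(1L, 2L, 4L, 3L))
  caches <- list()
  for (i in seq_along(net$layers)) {
    L <- net$layers[[i]]
    cv <- conv_forward(x, L$W, L$b)
    ac <- act_forward(cv$y, net$activation)
    cache <- list(conv = cv, act = ac$cache)
    h <- ac$y
    if (net$backbone == "residual_small") {
      cv2 <- conv_forward(h, L$W2, L$b2)
      ac2 <- act_forward(cv2$y, net$activation)
      cache$conv2 <- cv2
      cache$act2 <- ac2$cache
      h <- ac2$y + h
    }
    pl <- pool_forward(h)
    cache$pool_dim <- pl$xdim
    caches[[i]] <- cache
    x <- pl$y
  }
  gp <- gap_forward(x)
  f <- gp$f                      # (n, channels)
  dmask <- NULL
  if (train && net$dropout > 0) {
    keep <- 1 - net$dropout
    dmask <- matrix(stats::rbinom(length(f), 1, keep) / keep, nrow(f),
                    ncol(f))
    f <- f * dmask
  }
  pred <- drop(f %*% net$dense_W) + net$dense_b
  list(pred = pred, caches = caches, gap = gp, feats = f, dmask = dmask)
}

nn_backward <- function(net, fw, dpred) {
  grads <- list(layers = vector("list", length(net$layers)))
  grads$dense_W <- drop(crossprod(fw$feats, dpred))
  grads$dense_b <- sum(dpred)
  df <- outer(dpred, net$dense_W)
  if (!is.null(fw$dmask)) df <- df * fw$dmask
  dx <- gap_backward(df, fw$gap$xdim)
  for (i in rev(seq_along(net$layers))) {
    cache <- fw$caches[[i]]
    L <- net$layers[[i]]
    dh <- pool_backward(dx, cache$pool_dim)
    g <- list()
    if (net$backbone == "residual_small") {
      da2 <- act_backward(dh, cache$act2, net$activation)
      bk2 <- conv_backward(da2, cache$conv2, L$W2)
      g$W2 <- bk2$dW; g$b2 <- bk2$db
      dh <- bk2$dx + dh            # skip connection
    }
    da <- act_backward(dh, cache$act, net$activation)
    bk <- conv_backward(da, cache$conv, L$W)
    g$W <- bk$dW; g$b <- bk$db
    grads$layers[[i]] <- g
    dx <- bk$dx
  }
  grads
}

# ---- flat parameter view + AdamW --------------------------------------

nn_params <- function(net) {
  out <- list()
  for (i in seq_along(net$layers)) {
    L <- net$layers[[i]]
    out[[paste0("W", i)]] <- L$W
    out[[paste0("b", i)]] <- L$b
    if (!is.null(L$W2)) {
      out[[paste0("W2_", i)]] <- L$W2
      out[[paste0("b2_", i)]] <- L$b2
    }
  }
  out$dense_W <- net$dense_W
  out$dense_b <- net$dense_b
  out
}

nn_set_params <- function(net, params) {
  for (i in seq_along(net$layers)) {
    net$layers[[i]]$W <- params[[paste0("W", i)]]
    net$layers[[i]]$b <- params[[paste0("b", i)]]
    if (!is.null(net$layers[[i]]$W2)) {
      net$layers[[i]]$W2 <- params[[paste0("W2_", i)]]
      net$layers[[i]]$b2 <- params[[paste0("b2_", i)]]
    }
  }
  net$dense_W <- params$dense_W
  net$dense_b <- params$dense_b
  net
}

grads_as_params <- function(net, grads) {
  out <- list()
  for (i in seq_along(grads$layers)) {
    g <- grads$layers[[i]]
    out[[paste0("W", i)]] <- g$W
    out[[paste0("b", i)]] <- g$b
    if (!is.null(g$W2)) {
      out[[paste0("W2_", i)]] <- g$W2
      out[[paste0("b2_", i)]] <- g$b2
    }
  }
  out$dense_W <- grads$dense_W
  out$dense_b <- grads$dense_b
  out
}

adamw_new <- function(params, lr, weight_decay, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, lr = lr, wd = weight_decay, beta1 = beta1, beta2 = beta2,
       eps = eps)
}

# decoupled weight decay: the decay term is applied directly to the
# parameters, outside the adaptive gradient scaling
adamw_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    mh <- opt$m[[nm]] / bc1
    vh <- opt$v[[nm]] / bc2
    decay <- if (grepl("^b", nm) || nm == "dense_b") 0 else opt$wd
    params[[nm]] <- params[[nm]] - opt$lr * (mh / (sqrt(vh) + opt$eps) +
                                               decay * params[[nm]])
  }
  list(opt = opt, params = params)
}
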