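#' Output length of a strided 1D convolution
#'
#' `floor((input_len + 2 * padding - kernel) / stride) + 1`.
#'
#' @param input_len,kernel,stride,padding Non-negative integers; the padded
#'   input must be at least as long as the kernel and `stride >= 1`.
#' @return Integer output length.
#' @examples
#' conv_output_len(200, 10, 6, 4)  # 34
#' @export
conv_output_len <- function(input_len, kernel, stride = 1L, padding = 0L) {
  if (stride < 1) stop("stride must be >= 1")
  if (input_len + 2 * padding < kernel)
    stop("kernel (", kernel, ") larger than padded input (",
         input_len + 2 * padding, ")")
  as.integer(floor((input_len + 2 * padding - kernel) / stride) + 1)
}

#' Configuration of the separable CNN (and its standard-CNN comparator)
#'
#' With the defaults, the depthwise stage maps 200 x 30 input epochs to
#' 34 x 30, the pointwise stage to 34 x 4, and the flattened feature vector
#' has 136 entries feeding a single-logit dense layer.
#'
#' @param input_len Epoch length in samples (H1).
#' @param n_channels EEG channels (Nc); one depthwise kernel per channel.
#' @param depth_kernel Depthwise kernel size (h).
#' @param stride,padding Depthwise convolution stride and zero padding.
#' @param n_pointwise Number of pointwise (size-1) kernels / standard-CNN
#'   output channels (n).
#' @return An object of class `sepcnn_config` with derived `out_len` (H2) and
#'   `flatten_dim`.
#' @export
sepcnn_config <- function(input_len = 200L, n_channels = 30L, depth_kernel = 10L,
                          stride = 6L, padding = 4L, n_pointwise = 4L) {
  vals <- c(input_len, n_channels, depth_kernel, stride, n_pointwise)
  if (any(vals < 1) || padding < 0) stop("invalid sepcnn_config parameters")
  out_len <- conv_output_len(input_len, depth_kernel, stride, padding)
  structure(list(
    input_len = as.integer(input_len), n_channels = as.integer(n_channels),
    depth_kernel = as.integer(depth_kernel), stride = as.integer(stride),
    padding = as.integer(padding), n_pointwise = as.integer(n_pointwise),
    out_len = out_len, flatten_dim = out_len * as.integer(n_pointwise)
  ), class = "sepcnn_config")
}

layer_desc <- function(kind, out_shape, ...) {
  c(list(kind = kind, out_shape = out_shape), list(...))
}

#' Build the separable CNN model specification
#'
#' Layer order: BatchNorm -> depthwise Conv1D (one kernel per channel) ->
#' BatchNorm -> pointwise Conv1D (size-1 kernels mixing channels) -> Tanh ->
#' Flatten -> Dense(1) -> Sigmoid. The dense layer carries a bias; the
#' sigmoid logit is the per-epoch target probability.
#'
#' @param config A [sepcnn_config()].
#' @return An object of class `model_spec` with fields `variant`, `config`,
#'   `layers` (ordered descriptors), `param_count`.
#' @export
build_sepcnn <- function(config = sepcnn_config()) {
  stopifnot(inherits(config, "sepcnn_config"))
  H2 <- config$out_len; Nc <- config$n_channels; n <- config$n_pointwise
  layers <- list(
    layer_desc("batchnorm", c(config$input_len, Nc), channels = Nc),
    layer_desc("depthconv", c(H2, Nc), kernel = config$depth_kernel,
               channels = Nc, stride = config$stride, padding = config$padding),
    layer_desc("batchnorm", c(H2, Nc), channels = Nc),
    layer_desc("pointconv", c(H2, n), in_channels = Nc, out_channels = n),
    layer_desc("tanh", c(H2, n)),
    layer_desc("flatten", config$flatten_dim),
    layer_desc("dense", 1L, in_dim = config$flatten_dim, out_dim = 1L),
    layer_desc("sigmoid", 1L)
  )
  structure(list(variant = "sepcnn", config = config, layers = layers,
                 param_count = spec_param_count(layers)),
            class = "model_spec")
}

#' Build the standard-CNN comparator specification
#'
#' Layer order: BatchNorm -> standard Conv1D (`n_pointwise` output channels,
#' same kernel/stride/padding as the depthwise stage) -> Tanh -> Flatten ->
#' Dense(1) -> Sigmoid.
#'
#' @param config A [sepcnn_config()].
#' @return A `model_spec`.
#' @export
build_standard_cnn <- function(config = sepcnn_config()) {
  stopifnot(inherits(config, "sepcnn_config"))
  H2 <- config$out_len; Nc <- config$n_channels; n <- config$n_pointwise
  layers <- list(
    layer_desc("batchnorm", c(config$input_len, Nc), channels = Nc),
    layer_desc("stdconv", c(H2, n), kernel = config$depth_kernel,
               in_channels = Nc, out_channels = n,
               stride = config$stride, padding = config$padding),
    layer_desc("tanh", c(H2, n)),
    layer_desc("flatten", H2 * n),
    layer_desc("dense", 1L, in_dim = H2 * n, out_dim = 1L),
    layer_desc("sigmoid", 1L)
  )
  structure(list(variant = "standard_cnn", config = config, layers = layers,
                 param_count = spec_param_count(layers)),
            class = "model_spec")
}

spec_param_count <- function(layers) {
  sum(vapply(layers, function(l) switch(l$kind,
    batchnorm = 2L * l$channels,
    depthconv = l$kernel * l$channels + l$channels,
    pointconv = l$in_channels * l$out_channels + l$out_channels,
    stdconv = l$kernel * l$in_channels * l$out_channels + l$out_channels,
    dense = l$in_dim * l$out_dim + l$out_dim,
    0L), integer(1)))
}

#' Per-layer output shapes of a model specification
#'
#' @param spec A `model_spec`.
#' @return List of integer vectors, one per layer (time x channels, or a
#'   scalar width for flatten/dense/sigmoid).
#' @export
model_shapes <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  lapply(spec$layers, `[[`, "out_shape")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s, %d trainable parameters\n", x$variant, x$param_count))
  for (l in x$layers)
    cat(sprintf("  %-10s -> %s\n", l$kind, paste(l$out_shape, collapse = " x ")))
  invisible(x)
}

#' Training hyper-parameters for the CNN classifiers
#'
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); the best-validation weights are restored.
#' @param val_fraction Fraction of training epochs held out for validation.
#' @param pos_weight Positive-class weight in the binary cross-entropy;
#'   `"auto"` uses the non-target:target ratio of the training set (8 under
#'   the default 9-stimulus protocol).
#' @param seed Seed fixing initialization, the train/validation split and
#'   batch order.
#' @return An object of class `train_hyper`.
#' @export
train_hyper <- function(lr = 1e-3, batch_size = 64L, max_epochs = 200L,
                        patience = 20L, val_fraction = 0.2,
                        pos_weight = "auto", seed = 1L) {
  if (lr <= 0 || batch_size < 1 || max_epochs < 1 || patience < 1)
    stop("lr, batch_size, max_epochs and patience must be positive")
  if (val_fraction < 0 || val_fraction >= 1)
    stop("val_fraction must lie in [0, 1)")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, pos_weight = pos_weight,
                 seed = as.integer(seed)),
            class = "train_hyper")
}

## ---- layer forward/backward kernels -------------------------------------
## Internal activation layout is channels-first: (C, B, T) arrays (and
## (D, B) matrices after flatten). R recycles vectors along the first
## dimension, so every per-channel scale/shift is a native vectorized op with
## no broadcast copies; the channel-mixing layers become single GEMMs.
## User-facing tensors stay (epochs, time, channels) and are permuted once
## per batch.

to_cbt <- function(x) aperm(x, c(3, 1, 2))   # (B, T, C) -> (C, B, T)

bn_forward <- function(x, p, st, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  M <- matrix(x, d[1], d[2] * d[3]); N <- ncol(M)
  if (training) {
    mu <- rowMeans(M)
    ctr <- M - mu
    var_b <- rowSums(ctr^2) / N
    st$run_mean <- (1 - momentum) * st$run_mean + momentum * mu
    st$run_var <- (1 - momentum) * st$run_var +
      momentum * var_b * N / max(N - 1, 1)
  } else {
    mu <- st$run_mean; var_b <- st$run_var
    ctr <- M - mu
  }
  invstd <- 1 / sqrt(var_b + eps)
  xhat <- ctr * invstd
  y <- xhat * p$gamma + p$beta
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, invstd = invstd, dims = d), state = st)
}

bn_backward <- function(dy, p, cache) {
  d <- cache$dims
  dY <- matrix(dy, d[1], d[2] * d[3]); N <- ncol(dY)
  xhat <- cache$xhat
  dgamma <- rowSums(dY * xhat)
  dbeta <- rowSums(dY)
  dxhat <- dY * p$gamma
  dx <- (dxhat - rowMeans(dxhat) - xhat * (rowSums(dxhat * xhat) / N)) *
    cache$invstd
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

pad_time <- function(x, padding) {
  if (padding == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2], d[3] + 2 * padding))
  xp[, , (padding + 1):(padding + d[3])] <- x
  xp
}

# Band positions of kernel tap k in the (Tp x H2) time-transfer matrix.
conv_band_idx <- function(kernel, stride, Tp, H2) {
  t <- seq_len(H2)
  lapply(seq_len(kernel), function(k) (t - 1L) * stride + k + (t - 1L) * Tp)
}

# The strided depthwise convolution of channel c is the GEMM
# X_c (B x Tp) %*% T_c (Tp x H2), where T_c is a banded matrix carrying
# kernel tap W[k, c] at row (t-1)*stride + k of column t. Per-channel GEMMs
# beat elementwise array arithmetic by a wide margin in R.
depthconv_forward <- function(x, p, l) {
  d <- dim(x); B <- d[2]
  xp <- pad_time(x, l$padding)
  Tp <- dim(xp)[3]; H2 <- l$out_shape[1]; C <- d[1]
  xp2 <- aperm(xp, c(2, 3, 1))            # (B, Tp, C): contiguous per channel
  band <- conv_band_idx(l$kernel, l$stride, Tp, H2)
  y2 <- array(0, c(B, H2, C))
  Tc <- matrix(0, Tp, H2)
  for (cc in seq_len(C)) {
    for (k in seq_len(l$kernel)) Tc[band[[k]]] <- p$W[k, cc]
    y2[, , cc] <- xp2[, , cc] %*% Tc
  }
  y <- aperm(y2, c(3, 1, 2)) + p$b
  list(y = y, cache = list(xp2 = xp2, dims = d, band = band, Tp = Tp))
}

depthconv_backward <- function(dy, p, l, cache) {
  d <- cache$dims; B <- d[2]; C <- d[1]; H2 <- l$out_shape[1]
  Tp <- cache$Tp; band <- cache$band
  dy2 <- aperm(dy, c(2, 3, 1))            # (B, H2, C)
  dW <- matrix(0, l$kernel, C)
  dxp2 <- array(0, c(B, Tp, C))
  Tc <- matrix(0, Tp, H2)
  for (cc in seq_len(C)) {
    G <- crossprod(cache$xp2[, , cc], dy2[, , cc])   # (Tp, H2)
    for (k in seq_len(l$kernel)) {
      dW[k, cc] <- sum(G[band[[k]]])
      Tc[band[[k]]] <- p$W[k, cc]
    }
    dxp2[, , cc] <- tcrossprod(dy2[, , cc], Tc)
  }
  db <- rowSums(matrix(dy, C))
  keep <- if (l$padding > 0) (l$padding + 1):(l$padding + d[3]) else seq_len(Tp)
  dx <- aperm(dxp2[, keep, , drop = FALSE], c(3, 1, 2))
  list(dx = dx, grads = list(W = dW, b = db))
}

stdconv_forward <- function(x, p, l) {
  d <- dim(x)
  xp <- pad_time(x, l$padding)
  H2 <- l$out_shape[1]; Fo <- l$out_channels
  acc <- matrix(0, Fo, d[2] * H2)
  for (k in seq_len(l$kernel)) {
    idx <- (seq_len(H2) - 1L) * l$stride + k
    Mk <- matrix(xp[, , idx, drop = FALSE], d[1], d[2] * H2)
    acc <- acc + crossprod(p$W[k, , ], Mk)
  }
  y <- acc + p$b
  dim(y) <- c(Fo, d[2], H2)
  list(y = y, cache = list(xp = xp, dims = d))
}

stdconv_backward <- function(dy, p, l, cache) {
  d <- cache$dims; H2 <- l$out_shape[1]
  dY <- matrix(dy, l$out_channels, d[2] * H2)
  dW <- array(0, dim(p$W))
  dxp <- array(0, dim(cache$xp))
  for (k in seq_len(l$kernel)) {
    idx <- (seq_len(H2) - 1L) * l$stride + k
    Mk <- matrix(cache$xp[, , idx, drop = FALSE], d[1], d[2] * H2)
    dW[k, , ] <- tcrossprod(Mk, dY)
    contrib <- p$W[k, , ] %*% dY
    dim(contrib) <- c(d[1], d[2], H2)
    dxp[, , idx] <- dxp[, , idx] + contrib
  }
  db <- rowSums(dY)
  dx <- if (l$padding > 0)
    dxp[, , (l$padding + 1):(l$padding + d[3]), drop = FALSE] else dxp
  list(dx = dx, grads = list(W = dW, b = db))
}

pointconv_forward <- function(x, p, l) {
  d <- dim(x)
  M <- matrix(x, d[1], d[2] * d[3])
  y <- crossprod(p$W, M) + p$b
  dim(y) <- c(l$out_channels, d[2], d[3])
  list(y = y, cache = list(M = M, dims = d))
}

pointconv_backward <- function(dy, p, l, cache) {
  d <- cache$dims
  dY <- matrix(dy, l$out_channels, d[2] * d[3])
  dM <- p$W %*% dY
  dim(dM) <- d
  list(dx = dM, grads = list(W = tcrossprod(cache$M, dY), b = rowSums(dY)))
}

# (F, B, H2) -> (F*H2, B); flattened feature order is channel-fastest.
flatten_forward <- function(x) {
  d <- dim(x)
  y <- matrix(aperm(x, c(1, 3, 2)), d[1] * d[3], d[2])
  list(y = y, cache = list(dims = d))
}

flatten_backward <- function(dy, cache) {
  d <- cache$dims
  dx <- aperm(array(dy, c(d[1], d[3], d[2])), c(1, 3, 2))
  list(dx = dx)
}

# x is (D, B); weights (D, out); output (out, B).
dense_forward <- function(x, p) {
  list(y = crossprod(p$W, x) + p$b, cache = list(x = x))
}

dense_backward <- function(dy, p, cache) {
  list(dx = p$W %*% dy,
       grads = list(W = tcrossprod(cache$x, dy), b = rowSums(dy)))
}

## ---- parameter initialization, forward, backward ------------------------

init_params <- function(spec) {
  unif <- function(nr, nc = NULL, fan_in) {
    bound <- 1 / sqrt(fan_in)
    if (is.null(nc)) stats::runif(nr, -bound, bound)
    else matrix(stats::runif(nr * nc, -bound, bound), nr, nc)
  }
  lapply(spec$layers, function(l) switch(l$kind,
    batchnorm = list(gamma = rep(1, l$channels), beta = rep(0, l$channels)),
    depthconv = list(W = unif(l$kernel, l$channels, l$kernel),
                     b = unif(l$channels, fan_in = l$kernel)),
    pointconv = list(W = unif(l$in_channels, l$out_channels, l$in_channels),
                     b = unif(l$out_channels, fan_in = l$in_channels)),
    stdconv = {
      fan <- l$kernel * l$in_channels
      W <- array(stats::runif(l$kernel * l$in_channels * l$out_channels,
                              -1 / sqrt(fan), 1 / sqrt(fan)),
                 c(l$kernel, l$in_channels, l$out_channels))
      list(W = W, b = unif(l$out_channels, fan_in = fan))
    },
    dense = list(W = unif(l$in_dim, l$out_dim, l$in_dim),
                 b = unif(l$out_dim, fan_in = l$in_dim)),
    list()))
}

init_state <- function(spec) {
  lapply(spec$layers, function(l)
    if (l$kind == "batchnorm")
      list(run_mean = rep(0, l$channels), run_var = rep(1, l$channels))
    else list())
}

nn_forward <- function(spec, params, state, x, training = FALSE) {
  x <- to_cbt(x)  # user tensors are (epochs, time, channels)
  caches <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]; p <- params[[i]]
    r <- switch(l$kind,
      batchnorm = {
        out <- bn_forward(x, p, state[[i]], training)
        state[[i]] <- out$state
        out
      },
      depthconv = depthconv_forward(x, p, l),
      stdconv = stdconv_forward(x, p, l),
      pointconv = pointconv_forward(x, p, l),
      tanh = { y <- tanh(x); list(y = y, cache = list(y = y)) },
      flatten = flatten_forward(x),
      dense = dense_forward(x, p),
      sigmoid = list(y = stats::plogis(x), cache = NULL))
    caches[[i]] <- r$cache
    x <- r$y
  }
  list(out = x, caches = caches, state = state)
}

# Backward pass from d(loss)/d(logit); the terminal sigmoid is folded into
# the loss gradient, so backprop starts above it.
nn_backward <- function(spec, params, caches, dlogit) {
  grads <- vector("list", length(spec$layers))
  dy <- dlogit
  for (i in rev(seq_along(spec$layers))) {
    l <- spec$layers[[i]]; p <- params[[i]]
    r <- switch(l$kind,
      sigmoid = list(dx = dy),
      dense = dense_backward(dy, p, caches[[i]]),
      flatten = flatten_backward(dy, caches[[i]]),
      tanh = list(dx = dy * (1 - caches[[i]]$y^2)),
      pointconv = pointconv_backward(dy, p, l, caches[[i]]),
      stdconv = stdconv_backward(dy, p, l, caches[[i]]),
      depthconv = depthconv_backward(dy, p, l, caches[[i]]),
      batchnorm = bn_backward(dy, p, caches[[i]]))
    grads[i] <- list(if (is.null(r$grads)) list() else r$grads)
    dy <- r$dx
  }
  grads
}

weighted_bce <- function(p, y, w) {
  eps <- 1e-12
  -mean(w * (y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps))))
}

adam_init <- function(params) {
  list(m = rapply(params, function(x) x * 0, how = "replace"),
       v = rapply(params, function(x) x * 0, how = "replace"), t = 0)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  for (i in seq_along(params)) {
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      opt$m[[i]][[nm]] <- beta1 * opt$m[[i]][[nm]] + (1 - beta1) * g
      opt$v[[i]][[nm]] <- beta2 * opt$v[[i]][[nm]] + (1 - beta2) * g^2
      mhat <- opt$m[[i]][[nm]] / (1 - beta1^opt$t)
      vhat <- opt$v[[i]][[nm]] / (1 - beta2^opt$t)
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, opt = opt)
}

## ---- training and scoring -----------------------------------------------

#' Train a CNN classifier on an epoch set
#'
#' Minimizes class-weighted binary cross-entropy with Adam, using batch
#' statistics in the BatchNorm layers during training and their running
#' averages at inference. A seeded fraction of the data is held out to drive
#' early stopping; the weights with the best validation loss are kept.
#' Identical (data, spec, hyper) reproduce the trained network bit for bit.
#'
#' @param spec A `model_spec` from [build_sepcnn()] or [build_standard_cnn()].
#' @param epochs An `epoch_set` whose tensor matches the spec's input shape.
#' @param hyper A [train_hyper()] object.
#' @return An object of class `nn_scorer` (a `p300_scorer`): the frozen
#'   weights, BatchNorm running statistics, config, and loss history.
#' @export
train_network <- function(spec, epochs, hyper = train_hyper()) {
  stopifnot(inherits(spec, "model_spec"), inherits(epochs, "epoch_set"),
            inherits(hyper, "train_hyper"))
  d <- dim(epochs$tensor)
  cfg <- spec$config
  if (d[2] != cfg$input_len || d[3] != cfg$n_channels)
    stop("epoch tensor is ", d[2], " x ", d[3], " but the model expects ",
         cfg$input_len, " x ", cfg$n_channels)
  y <- as.numeric(epochs$labels)
  if (length(unique(y)) < 2)
    stop("training set must contain both target and non-target epochs")
  pos_w <- if (identical(hyper$pos_weight, "auto"))
    sum(y == 0) / sum(y == 1) else as.numeric(hyper$pos_weight)

  local_seed(hyper$seed, {
    n <- d[1]
    n_val <- floor(hyper$val_fraction * n)
    perm <- sample.int(n)
    val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(perm, val_idx)
    if (length(unique(y[tr_idx])) < 2) { tr_idx <- seq_len(n); val_idx <- integer(0) }
    x_tr <- epochs$tensor[tr_idx, , , drop = FALSE]; y_tr <- y[tr_idx]
    x_val <- epochs$tensor[val_idx, , , drop = FALSE]; y_val <- y[val_idx]

    params <- init_params(spec)
    state <- init_state(spec)
    opt <- adam_init(params)
    best <- list(loss = Inf, params = params, state = state)
    wait <- 0L
    history <- numeric(0)
    monitor_val <- length(val_idx) > 0

    for (ep in seq_len(hyper$max_epochs)) {
      ord <- sample.int(length(tr_idx))
      ep_loss <- 0; n_seen <- 0
      for (start in seq(1, length(ord), by = hyper$batch_size)) {
        bi <- ord[start:min(start + hyper$batch_size - 1, length(ord))]
        xb <- x_tr[bi, , , drop = FALSE]
        yb <- y_tr[bi]
        wb <- ifelse(yb == 1, pos_w, 1)
        fw <- nn_forward(spec, params, state, xb, training = TRUE)
        state <- fw$state
        pb <- as.numeric(fw$out)
        ep_loss <- ep_loss + weighted_bce(pb, yb, wb) * length(bi)
        n_seen <- n_seen + length(bi)
        dlogit <- matrix(wb * (pb - yb) / length(bi), nrow = 1)
        grads <- nn_backward(spec, params, fw$caches, dlogit)
        upd <- adam_step(params, grads, opt, hyper$lr)
        params <- upd$params; opt <- upd$opt
      }
      history <- c(history, ep_loss / n_seen)

      mon <- if (monitor_val) {
        pv <- as.numeric(nn_forward(spec, params, state, x_val, training = FALSE)$out)
        weighted_bce(pv, y_val, ifelse(y_val == 1, pos_w, 1))
      } else history[length(history)]
      if (mon < best$loss - 1e-7) {
        best <- list(loss = mon, params = params, state = state)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= hyper$patience) break
      }
    }

    structure(list(spec = spec, params = best$params, state = best$state,
                   hyper = hyper, pos_weight = pos_w,
                   train_loss = history, monitor_loss = best$loss,
                   method = spec$variant),
              class = c("nn_scorer", "p300_scorer"))
  })
}

#' Score epochs with a trained model
#'
#' Generic scoring contract shared by the CNNs and the classical baselines:
#' one scalar per epoch, higher = more target-like. CNN scorers return the
#' sigmoid probability in `[0, 1]`; linear scorers return the (real-valued)
#' discriminant value.
#'
#' @param scorer A fitted `p300_scorer`.
#' @param epochs An `epoch_set` with the shapes seen at fit time.
#' @return Numeric vector, one score per epoch.
#' @export
score_epochs <- function(scorer, epochs) UseMethod("score_epochs")

#' @export
score_epochs.nn_scorer <- function(scorer, epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$tensor)
  cfg <- scorer$spec$config
  if (d[2] != cfg$input_len || d[3] != cfg$n_channels)
    stop("epoch tensor is ", d[2], " x ", d[3], " but the model expects ",
         cfg$input_len, " x ", cfg$n_channels)
  as.numeric(nn_forward(scorer$spec, scorer$params, scorer$state,
                        epochs$tensor, training = FALSE)$out)
}

#' @export
print.nn_scorer <- function(x, ...) {
  cat(sprintf("<nn_scorer> %s, %d parameters, %d training epoch(s), monitor loss %.4g\n",
              x$method, x$spec$param_count, length(x$train_loss), x$monitor_loss))
  invisible(x)
}
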