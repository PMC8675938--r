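#' 1D CNN architecture specification
#'
#' Describes the per-channel classifier: three convolutional blocks
#' (convolution, ReLU, then max-pooling; block 1 adds batch normalization
#' after the ReLU, blocks 2 and 3 add dropout), a flatten, two fully
#' connected ReLU layers with dropout 0.5, and a 2-unit softmax output over
#' the CAD / non-CAD classes. Defaults are the reference architecture:
#' filters (32, 16, 16), kernel size 10 in every convolution, pool size 2,
#' fully connected widths (1000, 1000). Convolutions use "same" padding so
#' the 750-sample input halves cleanly through the three pooling stages
#' (750 -> 375 -> 187 -> 93).
#'
#' @param input_len Input feature-vector length.
#' @param filters Integer vector of 3 filter counts.
#' @param kernel Convolution kernel size.
#' @param pool Max-pool size.
#' @param conv_dropout Dropout rate in blocks 2 and 3.
#' @param fc_units Integer vector of 2 fully connected widths.
#' @param fc_dropout Dropout rate after each fully connected layer.
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @return An object of class `cnn_spec`.
#' @export
cnn_spec <- function(input_len = 750L,
                     filters = c(32L, 16L, 16L),
                     kernel = 10L,
                     pool = 2L,
                     conv_dropout = 0.25,
                     fc_units = c(1000L, 1000L),
                     fc_dropout = 0.5,
                     lr = 1e-3,
                     batch_size = 32L) {
  stopifnot(length(filters) == 3, length(fc_units) == 2,
            kernel >= 1, pool >= 1, input_len >= kernel,
            conv_dropout >= 0, conv_dropout < 1,
            fc_dropout >= 0, fc_dropout < 1, lr > 0, batch_size >= 1)
  structure(list(input_len = as.integer(input_len),
                 filters = as.integer(filters),
                 kernel = as.integer(kernel),
                 pool = as.integer(pool),
                 conv_dropout = conv_dropout,
                 fc_units = as.integer(fc_units),
                 fc_dropout = fc_dropout,
                 lr = lr,
                 batch_size = as.integer(batch_size)),
            class = "cnn_spec")
}

## ---- layer primitives -------------------------------------------------
## Activations are (B*L) x C matrices with row index b + (l-1)*B (batch
## fastest), so flatten/reshape between conv and dense stages are free
## reinterpretations. Convolution and pooling run in compiled code
## (src/cnn_ops.cpp); everything else is BLAS on matrices.

conv1d_fwd <- function(X2, W, b, B, L, k) conv1d_fwd_cpp(X2, W, b, B, L, k)

conv1d_bwd <- function(dY, cache, W, B, L, k, Cin)
  conv1d_bwd_cpp(dY, cache$Xc, W, B, L, k, Cin)

maxpool_fwd <- function(X2, B, L, p = 2L) maxpool_fwd_cpp(X2, B, L, p)

maxpool_bwd <- function(dY, cache, B, p = 2L)
  maxpool_bwd_cpp(dY, cache$idx, B, cache$L, p)

## Batch normalization over batch and length, per channel column.
bn_fwd <- function(Xm, gamma, beta, run_mean, run_var, training,
                   momentum = 0.9, eps = 1e-5) {
  nr <- nrow(Xm)
  if (training) {
    mu <- colMeans(Xm)
    xc <- Xm - rep(mu, each = nr)
    v <- colMeans(xc^2)
  } else {
    mu <- run_mean; v <- run_var
    xc <- Xm - rep(mu, each = nr)
  }
  xhat <- xc / rep(sqrt(v + eps), each = nr)
  Y <- xhat * rep(gamma, each = nr) + rep(beta, each = nr)
  list(Y = Y, xhat = xhat, mu = mu, v = v, eps = eps,
       run_mean = if (training) momentum * run_mean + (1 - momentum) * mu else run_mean,
       run_var = if (training) momentum * run_var + (1 - momentum) * v else run_var)
}

bn_bwd <- function(dY, cache, gamma) {
  nr <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(gamma, each = nr)
  istd <- 1 / sqrt(cache$v + cache$eps)
  t1 <- dxhat - rep(colMeans(dxhat), each = nr)
  t2 <- cache$xhat * rep(colMeans(dxhat * cache$xhat), each = nr)
  list(dX = (t1 - t2) * rep(istd, each = nr), dgamma = dgamma, dbeta = dbeta)
}

## ---- parameter initialization -----------------------------------------

init_params <- function(spec) {
  he <- function(nin, nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nin)), nr, nc)
  k <- spec$kernel; f <- spec$filters
  L1 <- spec$input_len %/% spec$pool
  L2 <- L1 %/% spec$pool
  L3 <- L2 %/% spec$pool
  flat <- L3 * f[3]
  list(
    conv1 = list(W = he(k * 1L, k * 1L, f[1]), b = numeric(f[1])),
    bn1 = list(gamma = rep(1, f[1]), beta = numeric(f[1]),
               run_mean = numeric(f[1]), run_var = rep(1, f[1])),
    conv2 = list(W = he(k * f[1], k * f[1], f[2]), b = numeric(f[2])),
    conv3 = list(W = he(k * f[2], k * f[2], f[3]), b = numeric(f[3])),
    fc1 = list(W = he(flat, flat, spec$fc_units[1]), b = numeric(spec$fc_units[1])),
    fc2 = list(W = he(spec$fc_units[1], spec$fc_units[1], spec$fc_units[2]),
               b = numeric(spec$fc_units[2])),
    out = list(W = he(spec$fc_units[2], spec$fc_units[2], 2L), b = numeric(2L))
  )
}

dropout_mask <- function(nr, nc, rate) {
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

## Forward pass. `training` toggles dropout and batch-norm statistics.
## Returns probabilities and (optionally) the caches needed for backprop.
## Layer lengths: L0 = input_len, L1 = L0/p, L2 = L1/p, L3 = L2/p.
cnn_forward <- function(params, spec, X, training = FALSE, keep_cache = FALSE) {
  B <- nrow(X); k <- spec$kernel; p <- spec$pool
  L0 <- spec$input_len; L1 <- L0 %/% p; L2 <- L1 %/% p; L3 <- L2 %/% p
  A <- matrix(as.vector(X), B * L0, 1L)  # row index b + (l-1)*B

  c1 <- conv1d_fwd(A, params$conv1$W, params$conv1$b, B, L0, k)
  r1 <- pmax(c1$Y, 0)
  b1 <- bn_fwd(r1, params$bn1$gamma, params$bn1$beta,
               params$bn1$run_mean, params$bn1$run_var, training)
  p1 <- maxpool_fwd(b1$Y, B, L0, p)

  c2 <- conv1d_fwd(p1$Y, params$conv2$W, params$conv2$b, B, L1, k)
  r2 <- pmax(c2$Y, 0)
  p2 <- maxpool_fwd(r2, B, L1, p)
  if (training && spec$conv_dropout > 0) {
    m2 <- dropout_mask(nrow(p2$Y), ncol(p2$Y), spec$conv_dropout)
    a2 <- p2$Y * m2
  } else { m2 <- NULL; a2 <- p2$Y }

  c3 <- conv1d_fwd(a2, params$conv3$W, params$conv3$b, B, L2, k)
  r3 <- pmax(c3$Y, 0)
  p3 <- maxpool_fwd(r3, B, L2, p)
  if (training && spec$conv_dropout > 0) {
    m3 <- dropout_mask(nrow(p3$Y), ncol(p3$Y), spec$conv_dropout)
    a3 <- p3$Y * m3
  } else { m3 <- NULL; a3 <- p3$Y }

  flat <- matrix(as.vector(a3), B, L3 * spec$filters[3])
  z1 <- flat %*% params$fc1$W
  z1 <- z1 + rep(params$fc1$b, each = B)
  h1 <- pmax(z1, 0)
  if (training && spec$fc_dropout > 0) {
    mf1 <- dropout_mask(B, ncol(h1), spec$fc_dropout)
    d1 <- h1 * mf1
  } else { mf1 <- NULL; d1 <- h1 }
  z2 <- d1 %*% params$fc2$W + rep(params$fc2$b, each = B)
  h2 <- pmax(z2, 0)
  if (training && spec$fc_dropout > 0) {
    mf2 <- dropout_mask(B, ncol(h2), spec$fc_dropout)
    d2 <- h2 * mf2
  } else { mf2 <- NULL; d2 <- h2 }
  logits <- d2 %*% params$out$W + rep(params$out$b, each = B)
  mx <- pmax(logits[, 1], logits[, 2])
  e <- exp(logits - mx)
  probs <- e / rowSums(e)

  cache <- NULL
  if (keep_cache)
    cache <- list(c1 = c1, b1 = b1, p1 = p1,
                  c2 = c2, p2 = p2, m2 = m2, a2 = a2,
                  c3 = c3, p3 = p3, m3 = m3, a3 = a3,
                  flat = flat, z1 = z1, d1 = d1, z2 = z2, d2 = d2,
                  mf1 = mf1, mf2 = mf2)
  list(probs = probs, cache = cache, bn_run = list(mean = b1$run_mean,
                                                   var = b1$run_var))
}

cnn_backward <- function(params, spec, cache, probs, y01) {
  B <- nrow(probs); k <- spec$kernel; p <- spec$pool; f <- spec$filters
  L0 <- spec$input_len; L1 <- L0 %/% p; L2 <- L1 %/% p; L3 <- L2 %/% p
  onehot <- cbind(1 - y01, y01)
  dlogits <- (probs - onehot) / B

  g <- list()
  g$out <- list(W = crossprod(cache$d2, dlogits), b = colSums(dlogits))
  dd2 <- tcrossprod(dlogits, params$out$W)
  if (!is.null(cache$mf2)) dd2 <- dd2 * cache$mf2
  dz2 <- dd2 * (cache$z2 > 0)
  g$fc2 <- list(W = crossprod(cache$d1, dz2), b = colSums(dz2))
  dd1 <- tcrossprod(dz2, params$fc2$W)
  if (!is.null(cache$mf1)) dd1 <- dd1 * cache$mf1
  dz1 <- dd1 * (cache$z1 > 0)
  g$fc1 <- list(W = crossprod(cache$flat, dz1), b = colSums(dz1))
  dflat <- tcrossprod(dz1, params$fc1$W)

  da3 <- matrix(as.vector(dflat), B * L3, f[3])
  if (!is.null(cache$m3)) da3 <- da3 * cache$m3
  dr3 <- maxpool_bwd(da3, cache$p3, B, p)
  dc3 <- dr3 * (cache$c3$Y > 0)
  bw3 <- conv1d_bwd(dc3, cache$c3, params$conv3$W, B, L2, k, f[2])
  g$conv3 <- list(W = bw3$dW, b = as.numeric(bw3$db))

  da2 <- bw3$dX
  if (!is.null(cache$m2)) da2 <- da2 * cache$m2
  dr2 <- maxpool_bwd(da2, cache$p2, B, p)
  dc2 <- dr2 * (cache$c2$Y > 0)
  bw2 <- conv1d_bwd(dc2, cache$c2, params$conv2$W, B, L1, k, f[1])
  g$conv2 <- list(W = bw2$dW, b = as.numeric(bw2$db))

  db1 <- maxpool_bwd(bw2$dX, cache$p1, B, p)
  bnb <- bn_bwd(db1, cache$b1, params$bn1$gamma)
  g$bn1 <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
  dc1 <- bnb$dX * (cache$c1$Y > 0)
  bw1 <- conv1d_bwd(dc1, cache$c1, params$conv1$W, B, L0, k, 1L)
  g$conv1 <- list(W = bw1$dW, b = as.numeric(bw1$db))
  g
}

## ---- user-facing training/prediction ----------------------------------

encode_labels <- function(labels) {
  if (!all(labels %in% c("CAD", "nonCAD")))
    stop("labels must be 'CAD' or 'nonCAD' (unknown labels are rejected at training time)")
  as.integer(labels == "CAD")
}

#' Build an untrained channel classifier
#'
#' Initializes the network of a [cnn_spec()] with He-scaled Gaussian weights
#' under the given seed. Two builds with the same seed have identical
#' initial weights.
#'
#' @param spec A [cnn_spec()].
#' @param seed Integer seed.
#' @param channel Optional channel name stored for provenance.
#' @return An object of class `channel_cnn` (untrained).
#' @export
build_model <- function(spec = cnn_spec(), seed = 1L, channel = NA_character_) {
  set.seed(seed)
  structure(list(spec = spec, params = init_params(spec), channel = channel,
                 trained = FALSE, history = NULL, selected_epoch = NA_integer_,
                 seed = as.integer(seed)),
            class = "channel_cnn")
}

#' @export
print.channel_cnn <- function(x, ...) {
  f <- x$spec$filters
  cat(sprintf("channel_cnn [%s]: conv(%d,%d,%d, k=%d) + fc(%d,%d) -> softmax(2)\n",
              ifelse(is.na(x$channel), "?", x$channel), f[1], f[2], f[3],
              x$spec$kernel, x$spec$fc_units[1], x$spec$fc_units[2]))
  if (x$trained)
    cat(sprintf("  trained %d epochs; selected epoch %d (val accuracy %.3f)\n",
                length(x$history$val_acc), x$selected_epoch,
                x$history$val_acc[x$selected_epoch]))
  else cat("  untrained\n")
  invisible(x)
}

#' Train one channel classifier
#'
#' Minimizes softmax cross-entropy (equivalent to binary cross-entropy for
#' the 2-unit output) with Adam. After every epoch the model is evaluated on
#' the validation set; the returned weights are those of the epoch with the
#' highest validation accuracy (earliest epoch on ties). Training is fully
#' reproducible from (data, spec, seed).
#'
#' @param train_x,val_x Numeric matrices, rows = feature vectors.
#' @param train_y,val_y Character labels (`"CAD"` / `"nonCAD"`).
#' @param spec A [cnn_spec()].
#' @param epochs Number of training epochs.
#' @param seed Integer seed.
#' @param channel Optional channel name stored for provenance.
#' @return A trained `channel_cnn` with `history` (per-epoch `train_loss`,
#'   `val_acc`) and `selected_epoch`.
#' @export
train_channel <- function(train_x, train_y, val_x, val_y,
                          spec = cnn_spec(), epochs = 100L, seed = 1L,
                          channel = NA_character_) {
  train_x <- as.matrix(train_x); val_x <- as.matrix(val_x)
  y_tr <- encode_labels(train_y); y_va <- encode_labels(val_y)
  if (length(unique(y_tr)) < 2) stop("training set must contain both classes")
  if (length(unique(y_va)) < 2) stop("validation set must contain both classes")
  if (ncol(train_x) != spec$input_len || ncol(val_x) != spec$input_len)
    stop("feature vectors must have length ", spec$input_len)

  set.seed(seed)
  params <- init_params(spec)
  fit <- cnn_train_cpp(params, train_x, y_tr, val_x, y_va,
                       spec$kernel, spec$pool, spec$conv_dropout,
                       spec$fc_dropout, spec$lr,
                       min(spec$batch_size, nrow(train_x)),
                       as.integer(epochs))
  structure(list(spec = spec, params = fit$params, channel = channel,
                 trained = TRUE,
                 history = list(train_loss = fit$train_loss,
                                val_acc = fit$val_acc),
                 selected_epoch = fit$selected_epoch,
                 seed = as.integer(seed)),
            class = "channel_cnn")
}

#' Predict per-cycle CAD probabilities
#'
#' Forward pass in evaluation mode (dropout off, batch-norm running
#' statistics); returns the CAD-class softmax component per input vector.
#'
#' @param model A trained `channel_cnn`.
#' @param features Numeric matrix (rows = feature vectors) or a single
#'   vector of length `spec$input_len`.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_cycles <- function(model, features) {
  stopifnot(inherits(model, "channel_cnn"))
  if (!model$trained) stop("model is untrained")
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  features <- as.matrix(features)
  if (ncol(features) != model$spec$input_len)
    stop("feature vectors must have length ", model$spec$input_len)
  cnn_forward(model$params, model$spec, features, training = FALSE)$probs[, 2]
}

#' @export
predict.channel_cnn <- function(object, newdata, ...) {
  predict_cycles(object, newdata)
}

#' Save / load a channel classifier
#'
#' Self-describing JSON archive holding the architecture spec, weights,
#' training history, selected epoch and seed.
#'
#' @param model A `channel_cnn`.
#' @param path File path.
#' @return `load_model` returns the restored `channel_cnn`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "channel_cnn"))
  ser <- list(spec = unclass(model$spec), channel = model$channel,
              trained = model$trained, history = model$history,
              selected_epoch = model$selected_epoch, seed = model$seed,
              params = lapply(model$params, function(l)
                lapply(l, function(p)
                  if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
                  else list(dim = NULL, data = as.numeric(p)))))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(cnn_spec, ser$spec[names(ser$spec) %in% names(formals(cnn_spec))])
  params <- lapply(ser$params, function(l)
    lapply(l, function(p)
      if (!is.null(p$dim)) matrix(p$data, p$dim[1], p$dim[2]) else p$data))
  structure(list(spec = spec, params = params, channel = ser$channel,
                 trained = ser$trained, history = ser$history,
                 selected_epoch = ser$selected_epoch, seed = ser$seed),
            class = "channel_cnn")
}
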