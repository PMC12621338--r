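#' Classifier configuration
#'
#' Architecture and training hyper-parameters of the dual-branch
#' recurrent/convolutional activity classifier. The time branch runs the
#' 30 x 12 filtered window through a two-layer LSTM (384 then 256 units)
#' with dropout (20% and 45%); the image branch runs the 8 x 8 x 12
#' spectrogram tensor through a 128-filter 3 x 3 convolution, 2 x 2 max
#' pooling, 40% dropout and a 256-unit dense projection applied
#' position-wise before flattening (set `cnn_dense_after_flatten = TRUE`
#' for the conventional flatten-then-dense order). Branch outputs are
#' concatenated, passed through a 256-unit ReLU fusion layer and an 8-way
#' softmax. Training uses categorical cross-entropy with Adam.
#'
#' @param lstm_units,lstm_dropout two-layer LSTM sizes and dropout rates.
#' @param conv_filters,conv_dropout convolution filters and dropout rate.
#' @param cnn_dense_units,fusion_units dense projection / fusion layer sizes.
#' @param n_classes number of activity classes (8).
#' @param learning_rate,batch_size,max_epochs,early_stop_patience Adam
#'   learning rate and training schedule.
#' @param seed RNG seed for parameter initialisation and batch shuffling.
#' @param cnn_dense_after_flatten use flatten-then-dense ordering in the
#'   image branch.
#' @param branch `"fused"`, `"lstm"` or `"cnn"` (single-branch ablations).
#' @return Object of class `model_config`.
#' @export
model_config <- function(lstm_units = c(384, 256),
                         lstm_dropout = c(0.20, 0.45),
                         conv_filters = 128, conv_dropout = 0.40,
                         cnn_dense_units = 256, fusion_units = 256,
                         n_classes = 8, learning_rate = 1e-3,
                         batch_size = 32, max_epochs = 200,
                         early_stop_patience = 20, seed = 1,
                         cnn_dense_after_flatten = FALSE,
                         branch = c("fused", "lstm", "cnn")) {
  branch <- match.arg(branch)
  stopifnot(length(lstm_units) == 2, length(lstm_dropout) == 2,
            all(lstm_dropout >= 0), all(lstm_dropout < 1),
            conv_dropout >= 0, conv_dropout < 1, n_classes >= 2)
  structure(list(lstm_units = as.integer(lstm_units),
                 lstm_dropout = lstm_dropout,
                 conv_filters = as.integer(conv_filters),
                 conv_dropout = conv_dropout,
                 cnn_dense_units = as.integer(cnn_dense_units),
                 fusion_units = as.integer(fusion_units),
                 n_classes = as.integer(n_classes),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed),
                 cnn_dense_after_flatten = isTRUE(cnn_dense_after_flatten),
                 branch = branch),
            class = "model_config")
}

cnn_flat_dim <- function(config) {
  if (config$cnn_dense_after_flatten) config$cnn_dense_units
  else 16L * config$cnn_dense_units
}

fusion_input_dim <- function(config) {
  switch(config$branch,
         fused = config$lstm_units[2] + cnn_flat_dim(config),
         lstm = config$lstm_units[2],
         cnn = cnn_flat_dim(config))
}

init_params <- function(config) {
  H1 <- config$lstm_units[1]
  H2 <- config$lstm_units[2]
  FF <- config$conv_filters
  D <- config$cnn_dense_units
  p <- list()
  if (config$branch != "cnn") {
    l1 <- lstm_init(12L, H1)
    l2 <- lstm_init(H1, H2)
    # standard forget-gate bias of 1 stabilises early training
    l1$b[(H1 + 1):(2 * H1)] <- 1
    l2$b[(H2 + 1):(2 * H2)] <- 1
    p <- c(p, list(Wx1 = l1$Wx, Wh1 = l1$Wh, b1 = l1$b,
                   Wx2 = l2$Wx, Wh2 = l2$Wh, b2 = l2$b))
  }
  if (config$branch != "lstm") {
    p$Wc <- glorot(9L * 12L, FF)
    p$bc <- rep(0, FF)
    if (config$cnn_dense_after_flatten) p$Wd <- glorot(16L * FF, D)
    else p$Wd <- glorot(FF, D)
    p$bd <- rep(0, D)
  }
  p$Wf <- glorot(fusion_input_dim(config), config$fusion_units)
  p$bf <- rep(0, config$fusion_units)
  p$Wo <- glorot(config$fusion_units, config$n_classes)
  p$bo <- rep(0, config$n_classes)
  p
}

#' Total trainable parameter count
#'
#' @param config a [model_config()].
#' @return Integer parameter count (a deterministic function of the config).
#' @export
param_count <- function(config) {
  set.seed(0)
  sum(vapply(init_params(config), length, 0L))
}

#' Build an untrained classifier
#'
#' Initialises all parameters (Glorot-uniform weights, zero biases except a
#' forget-gate bias of 1) from the config seed; two builds with the same
#' config produce identical parameters.
#'
#' @param config a [model_config()].
#' @return Object of class `adl_model`.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  structure(list(config = config, params = init_params(config),
                 classes = adl_classes()[seq_len(config$n_classes)],
                 norm_stats = NULL, history = NULL),
            class = "adl_model")
}

# forward pass; Xseq list of 30 (B x 12), Ximg B x 8 x 8 x 12 array
model_forward <- function(params, config, Xseq, Ximg, training = FALSE) {
  cache <- list()
  parts <- list()
  B <- if (config$branch != "cnn") attr(Xseq, "batch") else dim(Ximg)[1]
  if (config$branch != "cnn") {
    H1 <- config$lstm_units[1]
    H2 <- config$lstm_units[2]
    fw1 <- lstm_forward(Xseq, list(Wx = params$Wx1, Wh = params$Wh1,
                                   b = params$b1), H1, B)
    X2 <- fw1$H
    if (training && config$lstm_dropout[1] > 0) {
      mask1 <- dropout_mask(dim(X2), config$lstm_dropout[1])
      X2 <- X2 * mask1
      cache$mask1 <- mask1
    }
    fw2 <- lstm_forward(X2, list(Wx = params$Wx2, Wh = params$Wh2,
                                 b = params$b2), H2, B)
    hlast <- lstm_last(fw2)
    if (training && config$lstm_dropout[2] > 0) {
      m2 <- dropout_mask(dim(hlast), config$lstm_dropout[2])
      hlast <- hlast * m2
      cache$mask2 <- m2
    }
    cache$fw1 <- fw1
    cache$fw2 <- fw2
    parts$time <- hlast
  }
  if (config$branch != "lstm") {
    FF <- config$conv_filters
    A <- array(Ximg, dim = c(dim(Ximg)[1], 64L, 12L))
    cols <- im2col(A)
    conv <- cols %*% params$Wc
    conv <- sweep(conv, 2, params$bc, "+")
    relu_c <- conv > 0
    conv[!relu_c] <- 0
    carr <- array(conv, dim = c(B, 64L, FF))
    pl <- maxpool_forward(carr)
    pooled <- pl$out
    if (training && config$conv_dropout > 0) {
      mc <- dropout_mask(dim(pooled), config$conv_dropout)
      pooled <- pooled * mc
      cache$mask_c <- mc
    }
    if (config$cnn_dense_after_flatten) {
      flat0 <- matrix(pooled, B, 16L * FF)
      dns <- flat0 %*% params$Wd
      dns <- sweep(dns, 2, params$bd, "+")
      relu_d <- dns > 0
      dns[!relu_d] <- 0
      img_vec <- dns
      cache$flat0 <- flat0
    } else {
      pm <- matrix(pooled, B * 16L, FF)
      dns <- pm %*% params$Wd
      dns <- sweep(dns, 2, params$bd, "+")
      relu_d <- dns > 0
      dns[!relu_d] <- 0
      img_vec <- matrix(array(dns, dim = c(B, 16L, config$cnn_dense_units)),
                        B, 16L * config$cnn_dense_units)
      cache$pm <- pm
    }
    cache$cols <- cols
    cache$relu_c <- relu_c
    cache$pool_arg <- pl$arg
    cache$relu_d <- relu_d
    parts$img <- img_vec
  }
  fin <- switch(config$branch,
                fused = cbind(parts$time, parts$img),
                lstm = parts$time, cnn = parts$img)
  fuse <- fin %*% params$Wf
  fuse <- sweep(fuse, 2, params$bf, "+")
  relu_f <- fuse > 0
  fuse[!relu_f] <- 0
  logits <- fuse %*% params$Wo
  logits <- sweep(logits, 2, params$bo, "+")
  probs <- softmax_rows(logits)
  cache$fin <- fin
  cache$relu_f <- relu_f
  cache$fuse <- fuse
  cache$B <- B
  list(probs = probs, cache = cache)
}

model_backward <- function(params, config, fwd, Y) {
  cache <- fwd$cache
  B <- cache$B
  g <- list()
  dlogits <- (fwd$probs - Y) / B
  g$Wo <- crossprod(cache$fuse, dlogits)
  g$bo <- colSums(dlogits)
  dfuse <- tcrossprod(dlogits, params$Wo)
  dfuse[!cache$relu_f] <- 0
  g$Wf <- crossprod(cache$fin, dfuse)
  g$bf <- colSums(dfuse)
  dfin <- tcrossprod(dfuse, params$Wf)
  H2 <- config$lstm_units[2]
  dtime <- dimg <- NULL
  if (config$branch == "fused") {
    dtime <- dfin[, seq_len(H2), drop = FALSE]
    dimg <- dfin[, -seq_len(H2), drop = FALSE]
  } else if (config$branch == "lstm") dtime <- dfin else dimg <- dfin

  if (!is.null(dtime)) {
    if (!is.null(cache$mask2)) dtime <- dtime * cache$mask2
    bw2 <- lstm_backward(dtime, cache$fw2,
                         list(Wx = params$Wx2, Wh = params$Wh2,
                              b = params$b2), H2)
    dH1 <- bw2$dX
    if (!is.null(cache$mask1)) dH1 <- dH1 * cache$mask1
    bw1 <- lstm_backward(dH1, cache$fw1,
                         list(Wx = params$Wx1, Wh = params$Wh1,
                              b = params$b1), config$lstm_units[1])
    g$Wx1 <- bw1$dWx; g$Wh1 <- bw1$dWh; g$b1 <- bw1$db
    g$Wx2 <- bw2$dWx; g$Wh2 <- bw2$dWh; g$b2 <- bw2$db
  }
  if (!is.null(dimg)) {
    FF <- config$conv_filters
    D <- config$cnn_dense_units
    if (config$cnn_dense_after_flatten) {
      ddns <- dimg
      ddns[!cache$relu_d] <- 0
      g$Wd <- crossprod(cache$flat0, ddns)
      g$bd <- colSums(ddns)
      dpool <- array(tcrossprod(ddns, params$Wd), dim = c(B, 16L, FF))
    } else {
      ddns <- matrix(array(dimg, dim = c(B, 16L, D)), B * 16L, D)
      ddns[!cache$relu_d] <- 0
      g$Wd <- crossprod(cache$pm, ddns)
      g$bd <- colSums(ddns)
      dpool <- array(tcrossprod(ddns, params$Wd), dim = c(B, 16L, FF))
    }
    if (!is.null(cache$mask_c)) dpool <- dpool * cache$mask_c
    dcarr <- maxpool_backward(dpool, cache$pool_arg)
    dconv <- matrix(dcarr, B * 64L, FF)
    dconv[!cache$relu_c] <- 0
    g$Wc <- crossprod(cache$cols, dconv)
    g$bc <- colSums(dconv)
  }
  g[names(params)]
}

cross_entropy <- function(probs, Y) {
  -mean(log(pmax(rowSums(probs * Y), 1e-12)))
}

one_hot <- function(labels, k) {
  Y <- matrix(0, length(labels), k)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}

# N x T x D array -> time-stacked (T*B) x D matrix (blocks of B rows per
# timestep; array column-major order yields exactly this layout)
seq_slices <- function(Xarr, idx) {
  B <- length(idx)
  out <- matrix(Xarr[idx, , , drop = FALSE], B * dim(Xarr)[2], dim(Xarr)[3])
  attr(out, "batch") <- B
  out
}

img_slices <- function(Tarr, idx) {
  out <- Tarr[idx, , , , drop = FALSE]
  out
}

# batched eval-mode forward over a whole set
forward_all <- function(params, config, Xarr, Tarr, chunk = 128L) {
  n <- dim(Xarr)[1]
  probs <- matrix(0, n, config$n_classes)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    fw <- model_forward(params, config, seq_slices(Xarr, idx),
                        img_slices(Tarr, idx), training = FALSE)
    probs[idx, ] <- fw$probs
  }
  probs
}

#' Train the classifier
#'
#' Minimises categorical cross-entropy with Adam, shuffled mini-batches, a
#' per-epoch validation pass, and early stopping: training stops after
#' `early_stop_patience` epochs without a validation-loss improvement and
#' the parameters of the best validation epoch are retained.
#' Normalisation statistics (per-channel mean/SD of windows and tensors)
#' are computed from the training set only, stored in the model, and
#' applied to the validation data and later predictions.
#'
#' @param model an `adl_model` from [build_model()].
#' @param train,val lists with `windows` (N x 30 x 12 array), `tensors`
#'   (N x 8 x 8 x 12 array) and `labels` (integers in `1..n_classes`).
#' @param verbose print a line per epoch.
#' @return The trained `adl_model`, with `history` (per-epoch losses and
#'   accuracies) and `norm_stats` filled in.
#' @export
train_model <- function(model, train, val, verbose = FALSE) {
  stopifnot(inherits(model, "adl_model"))
  config <- model$config
  if (!length(train$labels) || !length(val$labels))
    stop("train_model: empty training or validation split")
  nw <- normalize_windows(train$windows)
  nt <- normalize_tensors(train$tensors)
  model$norm_stats <- list(windows = nw$stats, tensors = nt$stats)
  Xtr <- nw$windows
  Ttr <- nt$tensors
  Xva <- normalize_windows(val$windows, nw$stats)$windows
  Tva <- normalize_tensors(val$tensors, nt$stats)$tensors
  ytr <- train$labels
  yva <- val$labels
  n <- length(ytr)
  k <- config$n_classes
  Ytr <- one_hot(ytr, k)

  params <- model$params
  state <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- list()
  set.seed(config$seed + 1L)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    tr_loss <- 0
    tr_correct <- 0
    nb <- 0L
    for (s in seq(1L, n, by = config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      Yb <- Ytr[idx, , drop = FALSE]
      fw <- model_forward(params, config, seq_slices(Xtr, idx),
                          img_slices(Ttr, idx), training = TRUE)
      loss <- cross_entropy(fw$probs, Yb)
      if (!is.finite(loss))
        stop("train_model: non-finite loss at epoch ", epoch)
      grads <- model_backward(params, config, fw, Yb)
      upd <- adam_step(params, grads, state, lr = config$learning_rate)
      params <- upd$params
      state <- upd$state
      tr_loss <- tr_loss + loss
      tr_correct <- tr_correct +
        sum(max.col(fw$probs, ties.method = "first") == ytr[idx])
      nb <- nb + 1L
    }
    pva <- forward_all(params, config, Xva, Tva)
    va_loss <- cross_entropy(pva, one_hot(yva, k))
    va_acc <- mean(max.col(pva, ties.method = "first") == yva)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tr_loss / nb,
                                train_acc = tr_correct / n,
                                val_loss = va_loss, val_acc = va_acc)
    if (verbose)
      message(sprintf("epoch %3d  train loss %.4f acc %.3f  val loss %.4f acc %.3f",
                      epoch, tr_loss / nb, tr_correct / n, va_loss, va_acc))
    if (va_loss < best$loss - 1e-6) {
      best <- list(loss = va_loss, params = params, epoch = epoch)
    } else if (epoch - best$epoch >= config$early_stop_patience) {
      break
    }
  }
  model$params <- best$params
  model$best_epoch <- best$epoch
  model$history <- do.call(rbind, hist)
  model
}

#' Predict class probabilities / labels
#'
#' `predict_model` returns an N x 8 matrix of class probabilities (each row
#' sums to 1); `classify` returns the argmax label, ties broken by lowest
#' class index. Inputs are raw filtered windows/tensors; the model's stored
#' training normalisation statistics are applied internally. Dropout is
#' inactive, so repeated calls on the same input are identical.
#'
#' @param model a trained `adl_model`.
#' @param windows N x 30 x 12 array (a single 30 x 12 matrix is accepted).
#' @param tensors N x 8 x 8 x 12 array (or a single 8 x 8 x 12 tensor).
#' @return Probability matrix with class-name columns, or for `classify` a
#'   character vector of labels.
#' @export
predict_model <- function(model, windows, tensors) {
  stopifnot(inherits(model, "adl_model"))
  if (is.matrix(windows)) windows <- array(windows, c(1L, dim(windows)))
  if (length(dim(tensors)) == 3) tensors <- array(tensors, c(1L, dim(tensors)))
  if (is.null(model$norm_stats))
    stop("predict_model: model has no normalisation statistics; train first")
  Xn <- normalize_windows(windows, model$norm_stats$windows)$windows
  Tn <- normalize_tensors(tensors, model$norm_stats$tensors)$tensors
  probs <- forward_all(model$params, model$config, Xn, Tn)
  colnames(probs) <- model$classes
  probs
}

#' @rdname predict_model
#' @export
classify <- function(model, windows, tensors) {
  probs <- predict_model(model, windows, tensors)
  model$classes[max.col(probs, ties.method = "first")]
}

#' Persist / restore a trained model
#'
#' Saves learned parameters in RDS form alongside a JSON sidecar carrying
#' the config, class ordering and normalisation statistics (everything
#' needed for exact re-inference).
#'
#' @param model a trained `adl_model`.
#' @param dir directory to write to / read from.
#' @return `save_model` returns `dir` invisibly; `load_model` the model.
#' @export
save_model <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  saveRDS(model$params, file.path(dir, "params.rds"))
  side <- list(config = unclass(model$config), classes = model$classes,
               norm_stats = model$norm_stats, best_epoch = model$best_epoch)
  jsonlite::write_json(side, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  cfg <- side$config
  config <- model_config(lstm_units = cfg$lstm_units,
                         lstm_dropout = cfg$lstm_dropout,
                         conv_filters = cfg$conv_filters,
                         conv_dropout = cfg$conv_dropout,
                         cnn_dense_units = cfg$cnn_dense_units,
                         fusion_units = cfg$fusion_units,
                         n_classes = cfg$n_classes,
                         learning_rate = cfg$learning_rate,
                         batch_size = cfg$batch_size,
                         max_epochs = cfg$max_epochs,
                         early_stop_patience = cfg$early_stop_patience,
                         seed = cfg$seed,
                         cnn_dense_after_flatten = cfg$cnn_dense_after_flatten,
                         branch = cfg$branch)
  ns <- side$norm_stats
  structure(list(config = config,
                 params = readRDS(file.path(dir, "params.rds")),
                 classes = side$classes,
                 norm_stats = list(windows = list(mean = ns$windows$mean,
                                                  sd = ns$windows$sd),
                                   tensors = list(mean = ns$tensors$mean,
                                                  sd = ns$tensors$sd)),
                 best_epoch = side$best_epoch, history = NULL),
            class = "adl_model")
}
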