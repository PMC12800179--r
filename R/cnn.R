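# Lightweight convolutional classifier: three 3x3 conv + ReLU + 2x2
# max-pool blocks followed by two fully connected layers, trained with
# Adam and early stopping on validation loss. Forward and backward passes
# are built on the package's compiled conv/pool primitives; the backward
# pass also yields the input-pixel gradient required by the adversarial
# attacks. Class index convention: 1 = real, 2 = manipulated.

#' CNN configuration
#'
#' @param input_size input side length in pixels.
#' @param stem_pool initial average-pooling factor applied before the
#'   first convolution. The default (4) trades a modest loss of spatial
#'   resolution for an order-of-magnitude reduction in CPU cost; set to 1
#'   for full resolution. `input_size / stem_pool` must be divisible by 8.
#' @param widths channel widths of the three convolution blocks.
#' @param fc width of the first fully connected layer (the second always
#'   has two outputs, real vs manipulated).
#' @param lr Adam learning rate.
#' @param batch minibatch size.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement greater than `min_delta`).
#' @param max_epochs epoch cap.
#' @param min_delta minimum validation-loss improvement that resets the
#'   patience counter.
#' @return a `cnn_config` list.
#' @export
cnn_config <- function(input_size = 224L, stem_pool = 4L,
                       widths = c(16L, 32L, 64L), fc = 128L,
                       lr = 1e-3, batch = 32L, patience = 5L,
                       max_epochs = 50L, min_delta = 1e-4) {
  if ((input_size / stem_pool) %% 8 != 0)
    stop_param("input_size / stem_pool must be divisible by 8")
  if (length(widths) != 3L || any(widths < 1))
    stop_param("widths must give three positive channel counts")
  structure(list(input_size = as.integer(input_size),
                 stem_pool = as.integer(stem_pool),
                 widths = as.integer(widths), fc = as.integer(fc),
                 lr = lr, batch = as.integer(batch),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 min_delta = min_delta),
            class = "cnn_config")
}

cnn_init_weights <- function(config, seed) {
  w <- config$widths
  side <- config$input_size / config$stem_pool / 8L
  flat <- side * side * w[3]
  with_seed(seed, list(
    W1 = he_init(1, w[1], 3), b1 = numeric(w[1]),
    W2 = he_init(w[1], w[2], 3), b2 = numeric(w[2]),
    W3 = he_init(w[2], w[3], 3), b3 = numeric(w[3]),
    W4 = matrix(rnorm(config$fc * flat, sd = sqrt(2 / flat)), config$fc, flat),
    b4 = numeric(config$fc),
    W5 = matrix(rnorm(2 * config$fc, sd = sqrt(2 / config$fc)), 2, config$fc),
    b5 = numeric(2)))
}

# Fused forward (and optional backward) pass through the compiled
# network. `y_idx = NULL` returns the class probabilities only; with a
# label index the loss and parameter gradients are returned, and with
# `want_dx` also the input-pixel gradient. The input standardization is a
# fixed centering at mid-scale.
cnn_pass <- function(wts, config, x, y_idx = NULL, want_dx = FALSE) {
  xc <- array(x - 0.5, dim = c(nrow(x), ncol(x), 1L))
  out <- cpp_cnn_pass(xc, config$stem_pool,
                      wts$W1, wts$b1, wts$W2, wts$b2, wts$W3, wts$b3,
                      wts$W4, wts$b4, wts$W5, wts$b5,
                      if (is.null(y_idx)) 0L else as.integer(y_idx),
                      isTRUE(want_dx))
  if (!is.null(y_idx)) {
    out$grads <- list(W1 = out$dW1, b1 = as.numeric(out$db1),
                      W2 = out$dW2, b2 = as.numeric(out$db2),
                      W3 = out$dW3, b3 = as.numeric(out$db3),
                      W4 = out$dW4, b4 = as.numeric(out$db4),
                      W5 = out$dW5, b5 = as.numeric(out$db5))
    if (want_dx) out$dx <- matrix(out$dx, nrow(x), ncol(x))
  }
  out$p <- as.numeric(out$p)
  out
}

label_index <- function(label) ifelse(as_label(label) == "manipulated", 2L, 1L)

sample_pixels <- function(s) if (inherits(s, "image_sample")) s$pixels else s

# stack (centered) pixel grids into an H x W x B array for the batched
# compiled kernels
stack_pixels <- function(samples, idx = seq_along(samples)) {
  x1 <- sample_pixels(samples[[idx[1]]])
  arr <- array(0, dim = c(nrow(x1), ncol(x1), length(idx)))
  for (k in seq_along(idx))
    arr[, , k] <- sample_pixels(samples[[idx[k]]]) - 0.5
  arr
}

cnn_batch_prob <- function(wts, config, samples, idx = seq_along(samples)) {
  cpp_cnn_batch_prob(stack_pixels(samples, idx), config$stem_pool,
                     wts$W1, wts$b1, wts$W2, wts$b2, wts$W3, wts$b3,
                     wts$W4, wts$b4, wts$W5, wts$b5)
}

cnn_mean_loss <- function(wts, config, samples) {
  p <- cnn_batch_prob(wts, config, samples)
  yi <- vapply(samples, function(s) label_index(s$label), 0L)
  mean(-log(p[cbind(seq_along(samples), yi)] + 1e-12))
}

#' Train the convolutional classifier
#'
#' Minimizes the two-class cross-entropy with Adam over seeded shuffled
#' minibatches. After every epoch the validation loss is evaluated; the
#' weights with the lowest validation loss are kept, and training stops
#' early once the validation loss has failed to improve by `min_delta`
#' for `patience` consecutive epochs (or at the epoch cap). Training is
#' deterministic for a fixed seed.
#'
#' @param train,val lists of labeled [image_sample()]s (preprocessed).
#' @param config a [cnn_config()].
#' @param seed RNG seed for the initialization and the batch shuffles.
#' @param init_weights optional weight list to warm-start from (e.g. the
#'   clean-trained network when fine-tuning on adversarially augmented
#'   data); by default weights are freshly initialized from the seed.
#' @return an object of class `tamper_cnn` with elements `weights`
#'   (best-validation-loss weights), `config`, `history` (per-epoch
#'   train/val loss), `best_epoch`, `stopped_epoch` and `seed`.
#' @export
train_cnn <- function(train, val, config = cnn_config(), seed = 1L,
                      init_weights = NULL) {
  if (length(train) == 0 || length(val) == 0)
    stop_param("train and val must be nonempty")
  wts <- if (is.null(init_weights)) cnn_init_weights(config, seed)
         else init_weights
  mstate <- lapply(wts, function(w) w * 0)
  vstate <- lapply(wts, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  y_idx <- vapply(train, function(s) label_index(s$label), 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- Inf; best_wts <- wts; best_epoch <- 0L; stall <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(derive_seed(seed, paste0("epoch", epoch)),
                     sample.int(length(train)))
    ep_loss <- 0
    for (start in seq(1, length(ord), by = config$batch)) {
      batch <- ord[start:min(start + config$batch - 1L, length(ord))]
      res <- cpp_cnn_batch_train(stack_pixels(train, batch),
                                 config$stem_pool,
                                 wts$W1, wts$b1, wts$W2, wts$b2,
                                 wts$W3, wts$b3, wts$W4, wts$b4,
                                 wts$W5, wts$b5, y_idx[batch])
      if (!is.finite(res$loss_sum))
        stop_param("non-finite training loss at epoch %d", epoch)
      ep_loss <- ep_loss + res$loss_sum
      scale <- 1 / length(batch)
      t <- t + 1
      for (nm in names(wts)) {
        gr <- res[[paste0("d", nm)]] * scale
        if (is.null(dim(wts[[nm]]))) gr <- as.numeric(gr)
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gr
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gr^2
        mhat <- mstate[[nm]] / (1 - b1^t)
        vhat <- vstate[[nm]] / (1 - b2^t)
        wts[[nm]] <- wts[[nm]] - config$lr * mhat / (sqrt(vhat) + eps)
      }
    }
    val_loss <- cnn_mean_loss(wts, config, val)
    if (!is.finite(val_loss))
      stop_param("non-finite validation loss at epoch %d", epoch)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / length(ord), val_loss = val_loss))
    if (val_loss < best - config$min_delta) {
      best <- val_loss; best_wts <- wts; best_epoch <- epoch; stall <- 0L
    } else {
      if (val_loss < best) { best <- val_loss; best_wts <- wts; best_epoch <- epoch }
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  structure(list(weights = best_wts, config = config, history = history,
                 best_epoch = best_epoch, stopped_epoch = max(history$epoch),
                 val_loss = best, seed = as.integer(seed)),
            class = "tamper_cnn")
}

#' @export
print.tamper_cnn <- function(x, ...) {
  cat(sprintf(paste0("<tamper_cnn> conv %s + fc %d->2, input %d (stem %d)\n",
                     "  trained %d epochs, best val loss %.4f at epoch %d\n"),
              paste(x$config$widths, collapse = "/"), x$config$fc,
              x$config$input_size, x$config$stem_pool,
              x$stopped_epoch, x$val_loss, x$best_epoch))
  invisible(x)
}

#' @rdname predict_proba
#' @export
predict_proba.tamper_cnn <- function(model, x, ...) {
  if (is.matrix(x))
    return(cnn_pass(model$weights, model$config, x)$p[2])
  cnn_batch_prob(model$weights, model$config, x)[, 2]
}

#' @rdname loss_and_gradient
#' @export
loss_and_gradient.tamper_cnn <- function(model, x, y, ...) {
  check_pixels(x)
  y_idx <- label_index(y)
  fw <- cnn_pass(model$weights, model$config, x, y_idx = y_idx, want_dx = TRUE)
  list(loss = fw$loss, gradient = fw$dx)
}
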