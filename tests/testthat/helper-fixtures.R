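# Shared fixtures, generated in code at test time.

# small blob-vs-background task: linearly separable by local intensity
make_blob_sample <- function(has_blob, id, size = 32L) {
  img <- matrix(runif(size * size, 0, 0.3), size, size)
  msk <- NULL
  if (has_blob) {
    cx <- sample(seq(8L, size - 8L), 2)
    rr <- matrix(seq_len(size), size, size)
    msk <- ((rr - cx[1])^2 + (t(rr) - cx[2])^2) <= 16
    img[msk] <- 0.9
  }
  image_sample(id, img, label = if (has_blob) "manipulated" else "real",
               mask = msk)
}

make_blob_set <- function(n, seed, size = 32L) {
  mriforensics:::with_seed(seed, lapply(seq_len(n), function(i)
    make_blob_sample(i %% 2 == 0, sprintf("b%03d", i), size)))
}

# tiny CNN geometry used throughout the unit tests
tiny_cnn_config <- function(max_epochs = 12L, ...) {
  cnn_config(input_size = 32L, stem_pool = 1L, widths = c(4L, 8L, 8L),
             fc = 16L, max_epochs = max_epochs, ...)
}

# a single-feature logistic "gradient model" with known weight, used as
# an analytic oracle for the attacks (probability of "manipulated" is
# plogis(w * sum(x) + b))
logistic_model <- function(w = 2, b = -1) {
  structure(list(w = w, b = b), class = "toy_logistic")
}

predict_proba.toy_logistic <- function(model, x, ...) {
  stats::plogis(model$w * sum(x) + model$b)
}

loss_and_gradient.toy_logistic <- function(model, x, y, ...) {
  p <- stats::plogis(model$w * sum(x) + model$b)
  if (y == "manipulated") {
    list(loss = -log(p + 1e-15),
         gradient = matrix(-(1 - p) * model$w, nrow(x), ncol(x)))
  } else {
    list(loss = -log(1 - p + 1e-15),
         gradient = matrix(p * model$w, nrow(x), ncol(x)))
  }
}

registerS3method("predict_proba", "toy_logistic", predict_proba.toy_logistic,
                 envir = asNamespace("mriforensics"))
registerS3method("loss_and_gradient", "toy_logistic",
                 loss_and_gradient.toy_logistic,
                 envir = asNamespace("mriforensics"))

expect_in_range <- function(x, lo, hi) {
  expect_true(all(x >= lo - 1e-12 & x <= hi + 1e-12))
}
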