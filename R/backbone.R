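# Deep feature backbone: a seeded convolutional network whose
# global-average-pooled penultimate activation has length 2048. Weights
# are randomly initialized (He scheme) from a fixed seed; random
# convolutional features act as a fixed nonlinear projection and are fully
# deterministic, so no weight download is ever required. Externally
# trained weights can be supplied through the `weights` argument.

# per-channel standardization constants (the common RGB training
# convention for ImageNet-style backbones; the grayscale input is
# replicated to three channels first)
BACKBONE_MEAN <- c(0.485, 0.456, 0.406)
BACKBONE_SD <- c(0.229, 0.224, 0.225)

he_init <- function(n_in, n_out, k) {
  matrix(rnorm(n_in * k * k * n_out, sd = sqrt(2 / (n_in * k * k))),
         nrow = n_in * k * k, ncol = n_out)
}

#' Construct the deep feature backbone
#'
#' Topology: 4x average-pool stem, then three 3x3 convolution + ReLU +
#' 2x2 max-pool stages (32/64/128 channels), a 1x1 convolution to 2048
#' channels with ReLU, and global average pooling. The penultimate output
#' therefore has length 2048 for any valid input.
#'
#' @param seed RNG seed for the weight initialization.
#' @param input_size expected input side length (pixels).
#' @param weights optional externally trained weight list with the same
#'   shapes; by default seeded random weights are used.
#' @return an object of class `deep_backbone`.
#' @export
deep_backbone <- function(seed = 1L, input_size = 224L, weights = NULL) {
  if (input_size %% 32 != 0) stop_param("backbone input size must be divisible by 32")
  if (is.null(weights)) {
    weights <- with_seed(seed, list(
      W1 = he_init(3, 32, 3), b1 = numeric(32),
      W2 = he_init(32, 64, 3), b2 = numeric(64),
      W3 = he_init(64, 128, 3), b3 = numeric(128),
      W4 = he_init(128, 2048, 1), b4 = numeric(2048)))
  }
  structure(list(weights = weights, seed = as.integer(seed),
                 input_size = as.integer(input_size), dim = 2048L),
            class = "deep_backbone")
}

#' @export
print.deep_backbone <- function(x, ...) {
  cat(sprintf("<deep_backbone> %dx%d input -> 2048-dim GAP features (seed %d)\n",
              x$input_size, x$input_size, x$seed))
  invisible(x)
}

#' Deep penultimate-layer features
#'
#' The grayscale image is replicated to three channels, standardized with
#' the backbone's per-channel training constants, and propagated through
#' the network; the global-average-pooled penultimate activation is
#' returned. Output is bit-identical for identical input and weights.
#'
#' @param pixels numeric matrix (preprocessed, `input_size` square), or a
#'   list of such matrices / [image_sample()]s for batch extraction.
#' @param backbone a [deep_backbone()].
#' @return a length-2048 numeric vector, or an `n x 2048` matrix for a
#'   batch (row `i` equals the single-image call on image `i`).
#' @export
deep_features <- function(pixels, backbone = deep_backbone()) {
  stopifnot(inherits(backbone, "deep_backbone"))
  if (is.list(pixels)) {
    mats <- lapply(pixels, function(p) if (inherits(p, "image_sample")) p$pixels else p)
    out <- t(vapply(mats, function(m) deep_features(m, backbone),
                    numeric(backbone$dim)))
    return(out)
  }
  check_pixels(pixels)
  n <- backbone$input_size
  if (nrow(pixels) != n || ncol(pixels) != n)
    stop_param("backbone expects a %dx%d input", n, n)
  x <- array(0, dim = c(n, n, 3))
  for (c in 1:3) x[, , c] <- (pixels - BACKBONE_MEAN[c]) / BACKBONE_SD[c]
  w <- backbone$weights
  a <- cpp_avgpool(x, 4L)
  a <- pmax(cpp_conv2d(a, w$W1, w$b1, 3L), 0)
  a <- cpp_maxpool2(a)$y
  a <- pmax(cpp_conv2d(a, w$W2, w$b2, 3L), 0)
  a <- cpp_maxpool2(a)$y
  a <- pmax(cpp_conv2d(a, w$W3, w$b3, 3L), 0)
  a <- cpp_maxpool2(a)$y
  a <- pmax(cpp_conv2d(a, w$W4, w$b4, 1L), 0)
  colMeans(matrix(a, nrow = dim(a)[1] * dim(a)[2]))
}
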