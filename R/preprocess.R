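# Canonical preprocessing applied to every image before feature
# extraction or attack crafting.

#' Preprocessing configuration
#'
#' @param size target side length in pixels (square output).
#' @param sigma Gaussian denoising scale in pixels (`>= 0`; 0 disables).
#' @param interp interpolation scheme; only `"bilinear"` is supported.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(size = 224L, sigma = 1.5, interp = "bilinear") {
  if (size < 1) stop_param("preprocess.size must be positive")
  if (sigma < 0) stop_param("preprocess.sigma must be >= 0")
  if (!identical(interp, "bilinear"))
    stop_param("preprocess.interp: only 'bilinear' is supported")
  structure(list(size = as.integer(size), sigma = sigma, interp = interp),
            class = "preprocess_config")
}

#' Preprocess an image
#'
#' Pipeline (in this order): bilinear resize to `size x size`, per-image
#' min-max normalization to `[0, 1]`, Gaussian denoising at `sigma` with
#' reflective boundaries, final clip to `[0, 1]`. A constant image maps to
#' all zeros (the min-max convention when `max == min`).
#'
#' @param pixels numeric matrix with nonnegative intensities, any size.
#' @param config a [preprocess_config()].
#' @return `size` x `size` matrix with values in `[0, 1]`.
#' @export
preprocess <- function(pixels, config = preprocess_config()) {
  check_pixels(pixels)
  if (min(pixels) < 0) stop_param("input intensities must be nonnegative")
  x <- resize_bilinear(pixels, config$size, config$size)
  rng <- range(x)
  x <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1])
       else matrix(0, nrow(x), ncol(x))
  if (config$sigma > 0) x <- gaussian_blur(x, config$sigma)
  clip01(x)
}

#' Preprocess every sample in a list
#'
#' Applies [preprocess()] to each sample's pixels (and resamples the
#' ground-truth mask to the target geometry when present), preserving all
#' other metadata.
#'
#' @param samples list of [image_sample()]s.
#' @param config a [preprocess_config()].
#' @return the list with preprocessed pixels.
#' @export
preprocess_samples <- function(samples, config = preprocess_config()) {
  lapply(samples, function(s) {
    s$pixels <- preprocess(s$pixels, config)
    if (!is.null(s$mask) && !identical(dim(s$mask), dim(s$pixels)))
      s$mask <- resize_bilinear(s$mask * 1, config$size, config$size) > 0.5
    s
  })
}
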