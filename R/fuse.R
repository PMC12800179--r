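# Feature fusion: deep features first, HOG second, concatenated without
# rescaling (scaling is the classifier pipeline's responsibility).

DEEP_DIM <- 2048L
HOG_DIM <- 3780L
FUSED_DIM <- DEEP_DIM + HOG_DIM  # 5828

#' Fuse deep and HOG feature vectors
#'
#' Concatenates the length-2048 deep vector and the length-3780 HOG vector
#' into the 5828-dimensional fused representation: positions 1-2048 hold
#' the deep features, positions 2049-5828 the HOG features. Values are
#' passed through unchanged.
#'
#' @param deep numeric vector of length 2048.
#' @param hog numeric vector of length 3780.
#' @return numeric vector of length 5828.
#' @export
fuse <- function(deep, hog) {
  if (length(deep) != DEEP_DIM)
    stop_param("deep feature vector must have length %d", DEEP_DIM)
  if (length(hog) != HOG_DIM)
    stop_param("HOG feature vector must have length %d", HOG_DIM)
  if (any(!is.finite(deep)) || any(!is.finite(hog)))
    stop_param("fused features must be finite")
  c(as.numeric(deep), as.numeric(hog))
}

#' Fused feature matrix for a set of samples
#'
#' Runs the deep backbone and the HOG descriptor on every sample and
#' fuses the results row-wise.
#'
#' @param samples list of [image_sample()]s (preprocessed pixels).
#' @param backbone a [deep_backbone()].
#' @param hog a [hog_config()].
#' @return `n x 5828` numeric matrix.
#' @export
featurize <- function(samples, backbone = deep_backbone(),
                      hog = hog_config()) {
  t(vapply(samples, function(s) {
    px <- if (inherits(s, "image_sample")) s$pixels else s
    fuse(deep_features(px, backbone), hog_features(px, hog))
  }, numeric(FUSED_DIM)))
}
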