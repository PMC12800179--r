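# Elementary image operations: bilinear resampling and separable Gaussian
# smoothing with reflective boundaries. Conventions are pinned here because
# downstream descriptors depend on them bit-for-bit.

#' Bilinear image resize
#'
#' Resamples a grayscale image to a target geometry using bilinear
#' interpolation with the half-pixel-center alignment convention
#' (source coordinate `(d - 0.5) * scale + 0.5` for 1-based target index
#' `d`), clamped at the borders. Resizing to the input geometry is the
#' identity.
#'
#' @param pixels numeric matrix (rows x cols).
#' @param height,width target geometry in pixels.
#' @return numeric `height` x `width` matrix.
#' @export
resize_bilinear <- function(pixels, height, width) {
  check_pixels(pixels)
  if (height < 1 || width < 1) stop_param("target size must be positive")
  h <- nrow(pixels); w <- ncol(pixels)
  if (h == height && w == width) return(pixels)
  interp_mat <- function(n_out, n_in) {
    s <- (seq_len(n_out) - 0.5) * (n_in / n_out) + 0.5
    s <- pmin(pmax(s, 1), n_in)
    lo <- pmin(floor(s), n_in - 1L)
    if (n_in == 1L) lo <- rep(1, n_out)
    fr <- s - lo
    M <- matrix(0, n_out, n_in)
    M[cbind(seq_len(n_out), lo)] <- 1 - fr
    M[cbind(seq_len(n_out), pmin(lo + 1, n_in))] <-
      M[cbind(seq_len(n_out), pmin(lo + 1, n_in))] + fr
    M
  }
  R <- interp_mat(height, h)
  C <- interp_mat(width, w)
  R %*% pixels %*% t(C)
}

# Reflective ("mirror with edge repetition") index folding into 1..n.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n
  j <- ((i - 1L) %% p + p) %% p  # 0 .. 2n-1
  ifelse(j < n, j + 1L, p - j)
}

#' Gaussian smoothing with reflective boundaries
#'
#' Separable Gaussian filter; the kernel is truncated at `ceiling(3 * sigma)`
#' and renormalized. Boundary handling mirrors the image with edge
#' repetition, which keeps local means stable near the border (no dark
#' halo). `sigma = 0` is the identity.
#'
#' @param pixels numeric matrix.
#' @param sigma standard deviation of the kernel, in pixels (`>= 0`).
#' @return smoothed matrix of identical geometry.
#' @export
gaussian_blur <- function(pixels, sigma) {
  check_pixels(pixels)
  if (sigma < 0) stop_param("sigma must be >= 0")
  if (sigma == 0) return(pixels)
  r <- as.integer(ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_mat <- function(n) {
    B <- matrix(0, n, n)
    for (d in -r:r) {
      src <- reflect_index(seq_len(n) + d, n)
      B[cbind(seq_len(n), src)] <- B[cbind(seq_len(n), src)] + k[d + r + 1]
    }
    B
  }
  Bh <- blur_mat(nrow(pixels))
  Bw <- blur_mat(ncol(pixels))
  Bh %*% pixels %*% t(Bw)
}
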