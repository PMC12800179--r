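# Histogram of Oriented Gradients descriptor. The canonical detection
# window (64 x 128, 8 px cells, 2 x 2-cell blocks at 1-cell stride,
# 9 unsigned bins, L2-Hys normalization) is the unique standard geometry
# that yields the 3780-dimensional descriptor, so input images are
# resampled to that window internally.

#' HOG descriptor configuration
#'
#' @param window_width,window_height detection window in pixels.
#' @param cell cell side length in pixels.
#' @param block block side length in cells.
#' @param n_bins number of unsigned orientation bins over 0-180 degrees.
#' @param clip L2-Hys clipping threshold.
#' @return a `hog_config` list. The descriptor length is
#'   `blocks_x * blocks_y * block^2 * n_bins` (7 * 15 * 4 * 9 = 3780 under
#'   the defaults).
#' @export
hog_config <- function(window_width = 64L, window_height = 128L,
                       cell = 8L, block = 2L, n_bins = 9L, clip = 0.2) {
  if (window_width %% cell != 0 || window_height %% cell != 0)
    stop_param("HOG window must be divisible by the cell size")
  structure(list(window_width = as.integer(window_width),
                 window_height = as.integer(window_height),
                 cell = as.integer(cell), block = as.integer(block),
                 n_bins = as.integer(n_bins), clip = clip),
            class = "hog_config")
}

hog_length <- function(config) {
  cx <- config$window_width / config$cell
  cy <- config$window_height / config$cell
  bx <- cx - config$block + 1
  by <- cy - config$block + 1
  as.integer(bx * by * config$block^2 * config$n_bins)
}

#' HOG features of an image
#'
#' The image is resampled (bilinear) to the configured window, gradients
#' are taken by central differences with replicated edges, and unsigned
#' *edge* orientations (gradient direction rotated by 90 degrees, so a
#' vertical edge votes into the 90-degree bin) are accumulated per cell
#' with magnitude-weighted linear interpolation between the two nearest
#' bins. Blocks of `block x block` cells at 1-cell stride are
#' L2-Hys-normalized (L2 norm, clip at `clip`, renormalize; an all-zero
#' block stays zero). Blocks are scanned row-major (down the window first),
#' cells within a block column-major, bins fastest.
#'
#' @param pixels numeric matrix (typically a preprocessed image).
#' @param config a [hog_config()].
#' @return numeric vector of length [hog_length] (3780 by default).
#' @export
hog_features <- function(pixels, config = hog_config()) {
  check_pixels(pixels)
  h <- config$window_height; w <- config$window_width
  img <- resize_bilinear(pixels, h, w)
  # central differences, replicated edges
  gx <- img[, c(2:w, w)] - img[, c(1, 1:(w - 1))]   # horizontal
  gy <- img[c(2:h, h), ] - img[c(1, 1:(h - 1)), ]   # vertical
  mag <- sqrt(gx^2 + gy^2)
  # unsigned edge orientation in [0, 180)
  theta <- (atan2(gy, gx) * 180 / pi + 90) %% 180
  nb <- config$n_bins
  bw <- 180 / nb
  b <- theta / bw - 0.5
  lo <- floor(b)
  w_hi <- b - lo
  bin_lo <- (as.integer(lo) %% nb) + 1L
  bin_hi <- (bin_lo %% nb) + 1L
  # cell index per pixel
  cs <- config$cell
  cy <- h / cs; cx <- w / cs
  crow <- (matrix(seq_len(h), h, w) - 1L) %/% cs
  ccol <- (matrix(rep(seq_len(w), each = h), h, w) - 1L) %/% cs
  cell_id <- crow + cy * ccol  # 0-based, column-major over (crow, ccol)
  acc_idx <- function(bin) cell_id * nb + bin  # 1 .. cy*cx*nb
  hist <- numeric(cy * cx * nb)
  add <- function(idx, val) {
    t <- rowsum(val, as.integer(idx))
    at <- as.integer(rownames(t))
    hist[at] <<- hist[at] + t[, 1]
  }
  add(acc_idx(bin_lo), as.vector(mag * (1 - w_hi)))
  add(acc_idx(bin_hi), as.vector(mag * w_hi))
  cells <- array(hist, dim = c(nb, cy, cx))
  # block normalization
  bs <- config$block
  by <- cy - bs + 1; bx <- cx - bs + 1
  out <- numeric(hog_length(config))
  pos <- 0L
  blen <- bs * bs * nb
  for (i in seq_len(by)) {          # blocks: row-major over the window
    for (j in seq_len(bx)) {
      v <- as.vector(cells[, i:(i + bs - 1), j:(j + bs - 1)])
      nrm <- sqrt(sum(v^2))
      if (nrm > 0) {
        v <- pmin(v / sqrt(sum(v^2) + 1e-10), config$clip)
        n2 <- sqrt(sum(v^2))
        if (n2 > 0) v <- v / sqrt(sum(v^2) + 1e-10)
      }
      out[pos + seq_len(blen)] <- v
      pos <- pos + blen
    }
  }
  out
}
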