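# Shared internal helpers: seeding, clipping, argument checks.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a stage seed from a root seed
#'
#' All randomness in a pipeline run flows from one root seed; each stage
#' (corpus generation, splitting, attack initialization, training, ...)
#' receives a seed derived deterministically from the root and a stage tag,
#' so stages are independently reproducible.
#'
#' @param root integer root seed.
#' @param tag character stage tag.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root, tag) {
  stopifnot(is.numeric(root), length(root) == 1, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(root) %% 1000003) * 2017 + (h %% 999983) + 1)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

check_pixels <- function(pixels, name = "pixels") {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0)
    stop_param("%s must be a nonempty numeric matrix", name)
  if (any(!is.finite(pixels)))
    stop_param("%s contains non-finite values", name)
  invisible(pixels)
}

as_label <- function(x) {
  x <- as.character(x)
  if (!all(x %in% c("real", "manipulated")))
    stop_param("labels must be 'real' or 'manipulated'")
  x
}

# Binary morphological dilation of a logical mask with a square
# structuring element of half-width `r` (Chebyshev ball).
dilate_mask <- function(mask, r) {
  stopifnot(is.matrix(mask), r >= 0)
  if (r == 0) return(mask)
  out <- mask
  h <- nrow(mask); w <- ncol(mask)
  for (dj in -r:r) {
    cs <- max(1, 1 - dj):min(w, w - dj)
    cd <- cs + dj
    for (di in -r:r) {
      rs <- max(1, 1 - di):min(h, h - di)
      rd <- rs + di
      out[rd, cd] <- out[rd, cd] | mask[rs, cs]
    }
  }
  out
}
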