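# Synthetic brain-like phantoms and local manipulations (tumor insertion,
# tumor removal by classical inpainting). These stand in for genuine and
# tampered scans: they are not photorealistic MRI, but they reproduce the
# statistical task -- subtle, spatially local edits inside otherwise
# untouched anatomy.

#' Construct an image sample
#'
#' The basic unit of the corpus: a grayscale pixel grid in `[0, 1]` with a
#' class label, an optional ground-truth manipulation mask and a provenance
#' tag.
#'
#' @param id character identifier.
#' @param pixels numeric matrix with values in `[0, 1]`.
#' @param label `"real"` or `"manipulated"`.
#' @param mask optional logical matrix of the manipulated region; must be
#'   present and nonempty iff `label == "manipulated"`.
#' @param provenance one of `"phantom"`, `"inserted"`, `"removed"`,
#'   `"adv_fgsm"`, `"adv_pgd"`.
#' @param head optional list describing the head ellipse
#'   (`center`, `axes`), carried by phantoms so that tumor placement can be
#'   validated.
#' @return an object of class `image_sample`.
#' @export
image_sample <- function(id, pixels, label = "real", mask = NULL,
                         provenance = "phantom", head = NULL) {
  check_pixels(pixels)
  if (min(pixels) < -1e-12 || max(pixels) > 1 + 1e-12)
    stop_param("pixel intensities must lie in [0, 1]")
  label <- as_label(label)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(pixels)))
      stop_param("mask geometry must match pixels")
    if (any(mask) != (label == "manipulated"))
      stop_param("mask must be nonempty iff the sample is manipulated")
  }
  structure(list(id = as.character(id), pixels = clip01(pixels),
                 label = label, mask = mask, provenance = provenance,
                 head = head),
            class = "image_sample")
}

#' @export
print.image_sample <- function(x, ...) {
  cat(sprintf("<image_sample %s> %dx%d  label=%s  provenance=%s%s\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$label, x$provenance,
              if (!is.null(x$mask)) sprintf("  mask=%d px", sum(x$mask)) else ""))
  invisible(x)
}

#' Phantom generation parameters
#'
#' @param size image side length in pixels (square image, `>= 64`).
#' @param head_axes semi-axes of the head ellipse in pixels (row, col).
#' @param texture_amplitude amplitude of the band-limited tissue texture.
#' @param texture_sigma smoothing scale (pixels) of the tissue texture;
#'   larger values give smoother, more tissue-like intensity variation.
#' @param background intensity of the area outside the head.
#' @param jitter relative random variation of the anatomy geometry between
#'   phantoms (0 disables).
#' @param seed RNG seed.
#' @return a `phantom_params` list.
#' @export
phantom_params <- function(size = 224L,
                           head_axes = c(0.42, 0.34) * size,
                           texture_amplitude = 0.08,
                           texture_sigma = 3,
                           background = 0.05,
                           jitter = 0.06,
                           seed = 1L) {
  if (size < 64) stop_param("image size must be >= 64")
  if (texture_amplitude < 0 || background < 0 || any(head_axes <= 0))
    stop_param("amplitudes and axes must be nonnegative")
  structure(list(size = as.integer(size), head_axes = head_axes,
                 texture_amplitude = texture_amplitude,
                 texture_sigma = texture_sigma, background = background,
                 jitter = jitter, seed = as.integer(seed)),
            class = "phantom_params")
}

# logical mask of an axis-aligned ellipse
ellipse_mask <- function(size, center, axes) {
  rr <- matrix(seq_len(size), size, size)
  cc <- t(rr)
  ((rr - center[1]) / axes[1])^2 + ((cc - center[2]) / axes[2])^2 <= 1
}

#' Generate a brain-like phantom image
#'
#' Draws a deterministic (per seed) head phantom: dark background, bright
#' skull rim, mid-intensity brain tissue, darker ventricles, plus
#' band-limited tissue texture (white noise smoothed at
#' `texture_sigma`, scaled to `texture_amplitude`). With
#' `texture_amplitude = 0` the image is piecewise constant.
#'
#' @param params a [phantom_params()] object.
#' @return an [image_sample()] with `label = "real"`.
#' @export
generate_phantom <- function(params = phantom_params()) {
  if (!inherits(params, "phantom_params")) stop_param("invalid phantom params")
  n <- params$size
  with_seed(params$seed, {
    j <- function(x) x * (1 + params$jitter * runif(length(x), -1, 1))
    center <- c(n / 2, n / 2) + params$jitter * n * runif(2, -0.25, 0.25)
    axes <- j(params$head_axes)
    img <- matrix(params$background, n, n)
    skull <- ellipse_mask(n, center, axes)
    brain <- ellipse_mask(n, center, axes - 6)
    img[skull] <- 0.85
    img[brain] <- 0.55
    # two ventricle lobes, mirrored about the midline
    voff <- j(c(0.10 * n, 0.06 * n))
    vax <- j(c(0.11 * n, 0.035 * n))
    vent1 <- ellipse_mask(n, center + c(-voff[1] * 0.3, -voff[2]), vax)
    vent2 <- ellipse_mask(n, center + c(-voff[1] * 0.3, voff[2]), vax)
    img[(vent1 | vent2) & brain] <- 0.25
    if (params$texture_amplitude > 0) {
      tex <- gaussian_blur(matrix(rnorm(n * n), n, n), params$texture_sigma)
      tex <- tex / max(sd(tex), 1e-12) * params$texture_amplitude
      img[brain] <- img[brain] + tex[brain]
    }
    image_sample(id = sprintf("phantom_%08d", params$seed),
                 pixels = clip01(img), label = "real",
                 provenance = "phantom",
                 head = list(center = center, axes = axes - 6))
  })
}

#' Tumor shape and appearance parameters
#'
#' @param center blob center `(row, col)` in pixels.
#' @param radii semi-axes of the base ellipse in pixels (`> 0`).
#' @param irregularity boundary irregularity in `[0, 1]`; 0 gives an exact
#'   ellipse, larger values add smooth low-frequency radial perturbation
#'   (up to +/-40 percent of the radius at 1).
#' @param intensity_offset additive intensity of the lesion core (positive
#'   = bright lesion).
#' @param texture_amplitude amplitude of intra-lesion texture.
#' @return a `tumor_params` list.
#' @export
tumor_params <- function(center, radii, irregularity = 0.3,
                         intensity_offset = 0.25, texture_amplitude = 0.05) {
  if (any(radii <= 0)) stop_param("tumor radii must be > 0")
  if (irregularity < 0 || irregularity > 1)
    stop_param("irregularity must lie in [0, 1]")
  structure(list(center = center, radii = radii, irregularity = irregularity,
                 intensity_offset = intensity_offset,
                 texture_amplitude = texture_amplitude),
            class = "tumor_params")
}

# feather scale (pixels) of the insertion blend; support of the smoothed
# boundary extends at most ceiling(3 * FEATHER_SIGMA) beyond the mask
FEATHER_SIGMA <- 2

# rasterize the irregular blob support
tumor_support <- function(size, tumor, seed) {
  rr <- matrix(seq_len(size), size, size)
  cc <- t(rr)
  dy <- rr - tumor$center[1]
  dx <- cc - tumor$center[2]
  rho <- sqrt((dy / tumor$radii[1])^2 + (dx / tumor$radii[2])^2)
  if (tumor$irregularity > 0) {
    with_seed(seed, {
      a <- runif(4, -1, 1)
      phi <- runif(4, 0, 2 * pi)
    })
    theta <- atan2(dy, dx)
    g <- matrix(0, size, size)
    for (h in 1:4) g <- g + a[h] * cos((h + 1) * theta + phi[h])
    g <- g / max(sum(abs(a)), 1e-12)
    bound <- 1 + 0.4 * tumor$irregularity * g
  } else bound <- 1
  rho <= bound
}

#' Insert a synthetic tumor into a real sample
#'
#' Blends an irregular blob (offset intensity plus intra-lesion texture)
#' into the image with a Gaussian-feathered boundary, so the edit is
#' locally seamless. The returned sample is labeled `manipulated`; its mask
#' is the blob support, and pixels farther than the feather support
#' (`ceiling(3 * 2) = 6` px) from the mask are bit-identical to the input.
#'
#' @param sample an [image_sample()] with `label = "real"`.
#' @param tumor a [tumor_params()] object.
#' @param seed RNG seed for shape irregularity and texture.
#' @return a manipulated [image_sample()].
#' @export
insert_tumor <- function(sample, tumor, seed = 1L) {
  stopifnot(inherits(sample, "image_sample"), inherits(tumor, "tumor_params"))
  if (sample$label != "real") stop_param("tumors are inserted into real samples")
  n <- nrow(sample$pixels)
  support <- tumor_support(n, tumor, seed)
  if (!any(support)) stop_param("tumor support is empty")
  inside <- if (!is.null(sample$head))
    ellipse_mask(n, sample$head$center, sample$head$axes) else
      sample$pixels > 0.1
  if (any(support & !inside))
    stop_param("tumor placement error: blob extends outside the head region")
  w <- gaussian_blur(support * 1, FEATHER_SIGMA)
  tex <- with_seed(seed + 1L, gaussian_blur(matrix(rnorm(n * n), n, n), 1))
  tex <- tex / max(sd(tex), 1e-12) * tumor$texture_amplitude
  out <- clip01(sample$pixels + w * (tumor$intensity_offset + tex))
  image_sample(id = paste0(sample$id, "_ins"), pixels = out,
               label = "manipulated", mask = support,
               provenance = "inserted", head = sample$head)
}

#' Remove (inpaint) a region of an image
#'
#' Classical tumor-removal edit: the region is (a) filled from the
#' intensity statistics of a surrounding boundary ring, (b) given additive
#' synthetic texture whose variance matches the ring, and (c) affinely
#' renormalized so that the region mean and standard deviation match the
#' ring within numerical tolerance, then clipped to `[0, 1]`. Pixels
#' outside `region_mask` are untouched.
#'
#' @param sample an [image_sample()].
#' @param region_mask nonempty logical matrix of the region to fill.
#' @param seed RNG seed for the synthetic texture.
#' @param ring_width width (pixels) of the boundary ring used for the
#'   statistics.
#' @return a manipulated [image_sample()] with `mask = region_mask`.
#' @export
remove_tumor <- function(sample, region_mask, seed = 1L, ring_width = 4L) {
  stopifnot(inherits(sample, "image_sample"))
  if (!is.matrix(region_mask) || !identical(dim(region_mask), dim(sample$pixels)))
    stop_param("region_mask geometry must match the image")
  region_mask <- region_mask & TRUE
  if (!any(region_mask)) stop_param("region_mask is empty")
  ring <- dilate_mask(region_mask, ring_width) & !region_mask
  if (!any(ring))
    stop_param("no surrounding tissue: mask leaves no boundary ring")
  mu <- mean(sample$pixels[ring])
  sdev <- sd(sample$pixels[ring])
  if (!is.finite(sdev)) sdev <- 0
  m <- sum(region_mask)
  fill <- rep(mu, m)                                     # (a) region fill
  tex <- with_seed(seed, rnorm(m))                       # (b) texture
  vals <- fill + sdev * tex
  s <- sd(vals)                                          # (c) affine renorm
  vals <- if (m > 1 && s > 1e-12 && sdev > 1e-12)
    (vals - mean(vals)) / s * sdev + mu else rep(mu, m)
  out <- sample$pixels
  out[region_mask] <- vals
  image_sample(id = paste0(sample$id, "_rem"), pixels = clip01(out),
               label = "manipulated", mask = region_mask,
               provenance = "removed", head = sample$head)
}
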