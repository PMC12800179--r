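# Corpus assembly: phantom + manipulation sampling, PNG materialization,
# CSV manifests and stratified train/val/test splitting.

round_half_up <- function(x) floor(x + 0.5)

#' Write / read a grayscale PNG image
#'
#' Images are stored as lossless 8-bit grayscale PNG, one sample per file.
#'
#' @param pixels numeric matrix in `[0, 1]`.
#' @param path file path.
#' @return `read_image` returns the pixel matrix.
#' @export
write_image <- function(pixels, path) {
  check_pixels(pixels)
  png::writePNG(clip01(pixels), target = path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Write / read a corpus manifest
#'
#' The manifest is a CSV with header `id,path,label,split,provenance`.
#'
#' @param manifest data frame with those columns.
#' @param path CSV path.
#' @return `read_manifest` returns the manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[, c("id", "path", "label", "split", "provenance")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# draw one random tumor geometry fitting inside the head of `sample`
sample_tumor <- function(sample) {
  h <- sample$head
  repeat {
    d <- runif(2, -0.6, 0.6) * h$axes
    radii <- runif(2, 6, 16)
    margin <- max(radii) * 1.4 + 7  # irregular boundary + feather support
    if (((abs(d[1]) + margin) / h$axes[1])^2 +
        ((abs(d[2]) + margin) / h$axes[2])^2 <= 1) break
  }
  tumor_params(center = h$center + d, radii = radii,
               irregularity = runif(1, 0.2, 0.5),
               intensity_offset = runif(1, 0.15, 0.35),
               texture_amplitude = 0.05)
}

#' Build a synthetic detection corpus
#'
#' Generates `n_total` samples: genuine phantoms plus manipulated copies,
#' with manipulations split between tumor insertion and tumor removal
#' (insertion takes the remainder when the count is odd). Defaults emulate
#' a 1378-scan study corpus with 774 genuine and 604 altered scans; other
#' totals preserve that class ratio. Generation is fully reproducible from
#' the seed.
#'
#' @param n_total total number of samples.
#' @param dir optional output directory; when given, every sample is
#'   materialized as an 8-bit grayscale PNG and a `manifest.csv` is written.
#' @param seed root RNG seed.
#' @param image_size image side length in pixels.
#' @param removal_fraction fraction of manipulated samples produced by
#'   tumor removal (default half; insertion receives the remainder).
#' @param n_real,n_manipulated explicit class counts; by default derived
#'   from `n_total` at the 774:604 ratio.
#' @return a list of class `tamper_corpus` with elements `manifest`
#'   (data frame `id,path,label,split,provenance`) and `samples`
#'   (list of [image_sample()]).
#' @export
build_corpus <- function(n_total = 1378L, dir = NULL, seed = 1L,
                         image_size = 224L, removal_fraction = 0.5,
                         n_real = NULL, n_manipulated = NULL) {
  if (is.null(n_real)) n_real <- as.integer(round_half_up(n_total * 774 / 1378))
  if (is.null(n_manipulated)) n_manipulated <- as.integer(n_total - n_real)
  stopifnot(n_real >= 1, n_manipulated >= 0)
  n_rem <- as.integer(floor(n_manipulated * removal_fraction))
  n_ins <- n_manipulated - n_rem  # remainder goes to insertion
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)

  samples <- vector("list", n_real + n_manipulated)
  idx <- 0L
  mk_phantom <- function(s)
    generate_phantom(phantom_params(size = image_size, seed = s))
  base_seed <- derive_seed(seed, "corpus")
  for (i in seq_len(n_real)) {
    ph <- mk_phantom(base_seed + i)
    ph$id <- sprintf("real_%05d", i)
    idx <- idx + 1L; samples[[idx]] <- ph
  }
  with_seed(derive_seed(seed, "tumors"), {
    for (i in seq_len(n_ins)) {
      ph <- mk_phantom(base_seed + n_real + i)
      s <- insert_tumor(ph, sample_tumor(ph),
                        seed = base_seed + 7L * i)
      s$id <- sprintf("ins_%05d", i)
      idx <- idx + 1L; samples[[idx]] <- s
    }
    for (i in seq_len(n_rem)) {
      ph <- mk_phantom(base_seed + n_real + n_ins + i)
      ins <- insert_tumor(ph, sample_tumor(ph),
                          seed = base_seed + 11L * i)
      region <- dilate_mask(ins$mask, 6L)  # cover the feathered footprint
      s <- remove_tumor(ins, region, seed = base_seed + 13L * i)
      s$id <- sprintf("rem_%05d", i)
      idx <- idx + 1L; samples[[idx]] <- s
    }
  })
  ids <- vapply(samples, `[[`, "", "id")
  manifest <- data.frame(
    id = ids,
    path = if (is.null(dir)) NA_character_ else
      file.path(dir, paste0(ids, ".png")),
    label = vapply(samples, `[[`, "", "label"),
    split = NA_character_,
    provenance = vapply(samples, `[[`, "", "provenance"),
    stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    for (i in seq_along(samples))
      write_image(samples[[i]]$pixels, manifest$path[i])
    write_manifest(manifest, file.path(dir, "manifest.csv"))
  }
  structure(list(manifest = manifest, samples = samples),
            class = "tamper_corpus")
}

#' @export
print.tamper_corpus <- function(x, ...) {
  tab <- table(x$manifest$label)
  cat(sprintf("<tamper_corpus> %d samples (%s)\n", nrow(x$manifest),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Stratified train/validation/test split
#'
#' Assigns each manifest record to `train`, `val` or `test`, stratified by
#' class label. Within each class the records are shuffled with the given
#' seed; the test and validation counts are `round(frac * n_class)`
#' (half-up) and training takes the remainder. For a 1378-sample corpus
#' with 774 genuine scans this yields a 964/207/207 partition.
#'
#' @param manifest manifest data frame (columns `id`, `label` at minimum).
#' @param fractions train/val/test fractions, summing to 1.
#' @param seed RNG seed for the per-class shuffles.
#' @return the manifest with its `split` column filled in.
#' @export
stratified_split <- function(manifest, fractions = c(0.70, 0.15, 0.15),
                             seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9)
    stop_param("fractions must be three values summing to 1")
  if (any(fractions < 0)) stop_param("fractions must be nonnegative")
  labs <- unique(manifest$label)
  if (length(labs) < 1L || any(!table(manifest$label) >= 1))
    stop_param("at least one sample per class is required")
  manifest$split <- NA_character_
  with_seed(seed, {
    for (lab in sort(labs)) {
      rows <- which(manifest$label == lab)
      rows <- rows[sample.int(length(rows))]
      n <- length(rows)
      n_test <- round_half_up(fractions[3] * n)
      n_val <- round_half_up(fractions[2] * n)
      if (n_test + n_val > n) stop_param("class '%s' too small to split", lab)
      manifest$split[rows[seq_len(n_test)]] <- "test"
      manifest$split[rows[n_test + seq_len(n_val)]] <- "val"
      manifest$split[rows[-seq_len(n_test + n_val)]] <- "train"
    }
  })
  manifest
}

#' Apply a split to a corpus
#'
#' Convenience wrapper: runs [stratified_split()] on the corpus manifest
#' and returns the corpus with per-split sample lists attached.
#'
#' @param corpus a `tamper_corpus`.
#' @inheritParams stratified_split
#' @return the corpus with an updated manifest and a `splits` element
#'   (named list of sample lists).
#' @export
split_corpus <- function(corpus, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(inherits(corpus, "tamper_corpus"))
  corpus$manifest <- stratified_split(corpus$manifest, fractions, seed)
  corpus$splits <- lapply(c(train = "train", val = "val", test = "test"),
                          function(s) corpus$samples[corpus$manifest$split == s])
  corpus
}
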