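test_that("phantom generation is deterministic, bounded and structured", {
  a <- generate_phantom(phantom_params(seed = 7))
  b <- generate_phantom(phantom_params(seed = 7))
  expect_identical(a$pixels, b$pixels)
  expect_in_range(a$pixels, 0, 1)
  expect_identical(a$label, "real")
  # no texture -> piecewise-constant anatomy
  flat <- generate_phantom(phantom_params(texture_amplitude = 0, seed = 3))
  expect_lte(length(unique(as.vector(flat$pixels))), 8)
  # a different seed gives a different phantom
  expect_false(identical(a$pixels,
                         generate_phantom(phantom_params(seed = 8))$pixels))
  expect_error(phantom_params(size = 32), "size")
})

test_that("tumor insertion is local, bounded, with a disc-sized mask", {
  ph <- generate_phantom(phantom_params(seed = 11))
  tm <- tumor_params(center = ph$head$center, radii = c(8, 8),
                     irregularity = 0)
  ins <- insert_tumor(ph, tm, seed = 5)
  expect_identical(ins$label, "manipulated")
  expect_in_range(ins$pixels, 0, 1)
  # mask of an ideal r=8 disc rasterization, within 20 percent
  expect_gte(sum(ins$mask), 0.8 * pi * 64)
  expect_lte(sum(ins$mask), 1.2 * pi * 64)
  # pixels outside the feather-dilated mask are untouched
  outside <- !mriforensics:::dilate_mask(ins$mask, 6L)
  expect_identical(ins$pixels[outside], ph$pixels[outside])
  # placement outside the head errors
  bad <- tumor_params(center = c(5, 5), radii = c(8, 8))
  expect_error(insert_tumor(ph, bad, seed = 1), "placement")
})

test_that("tumor removal matches ring statistics and is local", {
  ph <- generate_phantom(phantom_params(seed = 13))
  tm <- tumor_params(center = ph$head$center, radii = c(10, 12))
  ins <- insert_tumor(ph, tm, seed = 2)
  region <- mriforensics:::dilate_mask(ins$mask, 6L)
  rem <- remove_tumor(ins, region, seed = 4)
  ring <- mriforensics:::dilate_mask(region, 4L) & !region
  expect_lte(abs(mean(rem$pixels[region]) - mean(rem$pixels[ring])), 0.02)
  expect_lte(abs(sd(rem$pixels[region]) - sd(rem$pixels[ring])), 0.02)
  expect_identical(rem$pixels[!region], ins$pixels[!region])
  # and outside the region the original phantom is recovered exactly
  expect_identical(rem$pixels[!region], ph$pixels[!region])
  # degenerate constant image: region refilled with the constant
  const <- image_sample("c", matrix(0.7, 64, 64))
  msk <- matrix(FALSE, 64, 64); msk[20:30, 20:30] <- TRUE
  out <- remove_tumor(const, msk, seed = 1)
  expect_equal(unique(out$pixels[msk]), 0.7)
  # mask with no surrounding tissue errors
  expect_error(remove_tumor(const, matrix(TRUE, 64, 64), seed = 1),
               "surrounding")
})

test_that("corpus generation hits the requested composition and is reproducible", {
  co <- build_corpus(n_total = 20, seed = 1, image_size = 96)
  expect_equal(nrow(co$manifest), 20)
  expect_equal(sum(co$manifest$label == "real"), 11)
  expect_setequal(unique(co$manifest$provenance),
                  c("phantom", "inserted", "removed"))
  co2 <- build_corpus(n_total = 20, seed = 1, image_size = 96)
  expect_identical(lapply(co$samples, `[[`, "pixels"),
                   lapply(co2$samples, `[[`, "pixels"))
  # ratio-preserving scaling: 10 total -> 6 real / 4 manipulated
  co10 <- build_corpus(n_total = 10, seed = 2, image_size = 96)
  expect_equal(sum(co10$manifest$label == "real"), 6)
  expect_equal(sum(co10$manifest$label == "manipulated"), 4)
  # every manipulated sample differs from some pixels but carries a mask
  for (s in co$samples)
    if (s$label == "manipulated") expect_gt(sum(s$mask), 0)
})

test_that("materialized corpus round-trips through PNG and CSV", {
  dir <- withr::local_tempdir()
  co <- build_corpus(n_total = 8, dir = dir, seed = 3, image_size = 96)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 8)
  expect_true(all(file.exists(man$path)))
  img <- read_image(man$path[1])
  # 8-bit quantization
  expect_lte(max(abs(img - co$samples[[1]]$pixels)), 1 / 255)
})

test_that("stratified split follows the rounding rule and stratifies", {
  man <- data.frame(id = sprintf("s%04d", 1:1378),
                    label = rep(c("real", "manipulated"), c(774, 604)),
                    stringsAsFactors = FALSE)
  sp <- stratified_split(man, seed = 1)
  expect_equal(sum(sp$split == "test"), 207)
  expect_equal(sum(sp$split == "val"), 207)
  expect_equal(sum(sp$split == "train"), 964)
  # partition: every id in exactly one split
  expect_false(any(is.na(sp$split)))
  # per-split class ratio within one sample of the global per-class share
  for (s in c("train", "val", "test")) {
    n_s <- sum(sp$split == s)
    for (lab in c("real", "manipulated")) {
      expected <- n_s * sum(man$label == lab) / nrow(man)
      expect_lte(abs(sum(sp$split == s & sp$label == lab) - expected), 1)
    }
  }
  # balanced 10/10 corpus: each split stays balanced within one sample
  man20 <- data.frame(id = as.character(1:20),
                      label = rep(c("real", "manipulated"), each = 10))
  sp20 <- stratified_split(man20, seed = 2)
  for (s in unique(sp20$split)) {
    d <- abs(sum(sp20$split == s & sp20$label == "real") -
             sum(sp20$split == s & sp20$label == "manipulated"))
    expect_lte(d, 1)
  }
  expect_error(stratified_split(man20, fractions = c(0.5, 0.3, 0.3)),
               "sum")
  # reproducibility
  expect_identical(stratified_split(man20, seed = 5),
                   stratified_split(man20, seed = 5))
})
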