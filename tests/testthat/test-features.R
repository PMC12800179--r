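test_that("HOG descriptor has the canonical length and the formula holds", {
  set.seed(1)
  img <- matrix(runif(224 * 224), 224, 224)
  v <- hog_features(img)
  expect_length(v, 3780)
  cfg <- hog_config()
  bx <- cfg$window_width / cfg$cell - cfg$block + 1
  by <- cfg$window_height / cfg$cell - cfg$block + 1
  expect_equal(bx * by * cfg$block^2 * cfg$n_bins,
               mriforensics:::hog_length(cfg))
  expect_equal(bx, 7); expect_equal(by, 15)
  # constant image: zero gradients everywhere -> all-zero descriptor
  expect_equal(hog_features(matrix(0.5, 224, 224)), numeric(3780))
  expect_error(hog_config(window_width = 60), "divisible")
})

test_that("every L2-Hys block has norm at most one", {
  set.seed(2)
  for (rep in 1:3) {
    v <- hog_features(matrix(runif(128 * 64), 128, 64))
    blocks <- matrix(v, nrow = 36)
    expect_true(all(sqrt(colSums(blocks^2)) <= 1 + 1e-9))
  }
})

test_that("a vertical edge dominates the 90-degree bin (brute-force oracle)", {
  # image with a sharp vertical edge: left dark, right bright
  img <- cbind(matrix(0.1, 128, 32), matrix(0.9, 128, 32))
  v <- hog_features(img)  # 64x128 window: input already at window geometry
  impl_bins <- rowSums(matrix(v, nrow = 9))
  # independent per-pixel accumulator with the stated conventions
  h <- 128; w <- 64
  gx <- img[, c(2:w, w)] - img[, c(1, 1:(w - 1))]
  gy <- img[c(2:h, h), ] - img[c(1, 1:(h - 1)), ]
  mag <- sqrt(gx^2 + gy^2)
  theta <- (atan2(gy, gx) * 180 / pi + 90) %% 180
  ref <- numeric(9)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mag[i, j] == 0) next
    b <- theta[i, j] / 20 - 0.5
    lo <- floor(b); fr <- b - lo
    ref[(lo %% 9) + 1] <- ref[(lo %% 9) + 1] + mag[i, j] * (1 - fr)
    ref[((lo + 1) %% 9) + 1] <- ref[((lo + 1) %% 9) + 1] + mag[i, j] * fr
  }
  # bin 5 covers 90 degrees (bin centers 10, 30, ..., 90 at index 5)
  expect_equal(which.max(ref), 5)
  expect_equal(which.max(impl_bins), 5)
  expect_gt(impl_bins[5], 0.5 * sum(impl_bins))
})

test_that("deep features are 2048-long, deterministic and batch-consistent", {
  bb <- deep_backbone(seed = 7)
  set.seed(3)
  imgs <- lapply(1:3, function(i) matrix(runif(224 * 224), 224, 224))
  v1 <- deep_features(imgs[[1]], bb)
  expect_length(v1, 2048)
  expect_true(all(is.finite(v1)))
  expect_identical(v1, deep_features(imgs[[1]], bb))
  batch <- deep_features(imgs, bb)
  expect_equal(dim(batch), c(3L, 2048L))
  for (i in 1:3) expect_equal(batch[i, ], deep_features(imgs[[i]], bb))
  # different seeds give different projections
  expect_false(identical(v1, deep_features(imgs[[1]], deep_backbone(seed = 8))))
  expect_error(deep_features(matrix(0.5, 64, 64), bb), "224")
})

test_that("fusion concatenates deep-first with exact value preservation", {
  set.seed(4)
  d <- runif(2048); h <- runif(3780)
  f <- fuse(d, h)
  expect_length(f, 5828)
  expect_identical(f[1:2048], d)
  expect_identical(f[2049:5828], h)
  # worked positions: deep[1] lands at 1, hog[1] at 2049
  d[1] <- 0.03; h[1] <- 0.12
  f <- fuse(d, h)
  expect_equal(f[1], 0.03)
  expect_equal(f[2049], 0.12)
  expect_identical(fuse(numeric(2048), numeric(3780)), numeric(5828))
  expect_error(fuse(numeric(100), h), "2048")
  expect_error(fuse(d, numeric(100)), "3780")
})
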