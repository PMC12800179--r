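test_that("weights are the normalized validation AUCs", {
  w <- compute_weights(0.75, 0.78)
  expect_equal(w$svm, 0.75 / 1.53)
  expect_equal(w$cnn, 0.78 / 1.53)
  expect_equal(w$svm + w$cnn, 1, tolerance = 1e-12)
  sym <- compute_weights(0.8, 0.8)
  expect_equal(sym$svm, 0.5)
  # random valid inputs always normalize
  set.seed(1)
  for (rep in 1:20) {
    a <- runif(2, 0.01, 1)
    w <- compute_weights(a[1], a[2])
    expect_equal(w$svm + w$cnn, 1, tolerance = 1e-12)
    expect_in_range(c(w$svm, w$cnn), 0, 1)
  }
  expect_error(compute_weights(0, 0.5), "AUC")
  expect_error(compute_weights(0.5, 1.2), "AUC")
})

test_that("ensemble prediction is a thresholded convex combination", {
  w <- list(svm = 0.5, cnn = 0.5)
  r <- ensemble_predict(0.4, 0.8, w)
  expect_equal(r$p_final, 0.6)
  expect_identical(r$label, "manipulated")
  expect_identical(ensemble_predict(0, 0, w)$label, "real")
  # tie at exactly 0.5 flags manipulated
  expect_identical(ensemble_predict(0.5, 0.5, w)$label, "manipulated")
  expect_error(ensemble_predict(0.4, 0.8, list(svm = 0.7, cnn = 0.5)),
               "sum to 1")
  expect_error(ensemble_predict(1.4, 0.8, w), "probabilities")
})

test_that("convexity, monotonicity and agreement properties hold", {
  set.seed(2)
  for (rep in 1:50) {
    w <- compute_weights(runif(1, 0.2, 1), runif(1, 0.2, 1))
    p1 <- runif(1); p2 <- runif(1)
    pf <- ensemble_predict(p1, p2, w)$p_final
    expect_gte(pf, min(p1, p2) - 1e-12)
    expect_lte(pf, max(p1, p2) + 1e-12)
    # monotonicity in each argument
    d <- runif(1, 0, 1 - p1)
    expect_gte(ensemble_predict(p1 + d, p2, w)$p_final, pf - 1e-12)
    d2 <- runif(1, 0, 1 - p2)
    expect_gte(ensemble_predict(p1, p2 + d2, w)$p_final, pf - 1e-12)
    # agreement with margin: both members on the same side of 0.5
    delta <- runif(1, 0.01, 0.4)
    hi <- ensemble_predict(0.5 + delta, 0.5 + runif(1, delta, 0.5), w)
    expect_identical(hi$label, "manipulated")
    lo <- ensemble_predict(0.5 - delta, 0.5 - runif(1, delta, 0.49), w)
    expect_identical(lo$label, "real")
  }
})
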