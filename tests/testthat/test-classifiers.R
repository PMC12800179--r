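make_cloud <- function(n_per, offset, seed) {
  mriforensics:::with_seed(seed, {
    X <- rbind(matrix(rnorm(2 * n_per, -offset, 0.3), n_per, 2),
               matrix(rnorm(2 * n_per, offset, 0.3), n_per, 2))
    list(X = X, y = rep(c("real", "manipulated"), each = n_per))
  })
}

test_that("SVM separates offset point clouds (perceptron oracle first)", {
  tr <- make_cloud(20, 1, seed = 1)
  va <- make_cloud(10, 1, seed = 2)
  # oracle: a perceptron converges on the training set, so it is separable
  w <- c(0, 0); b <- 0; yy <- ifelse(tr$y == "manipulated", 1, -1)
  for (pass in 1:100) {
    mistakes <- 0
    for (i in seq_along(yy)) {
      if (yy[i] * (sum(w * tr$X[i, ]) + b) <= 0) {
        w <- w + yy[i] * tr$X[i, ]; b <- b + yy[i]; mistakes <- mistakes + 1
      }
    }
    if (mistakes == 0) break
  }
  expect_equal(mistakes, 0)
  m <- train_svm(tr$X, tr$y, va$X, va$y, seed = 1)
  p_tr <- predict_proba(m, tr$X)
  expect_equal(mean((p_tr >= 0.5) == (tr$y == "manipulated")), 1)
  # perfectly separated: positives at or above 0.5
  p_va <- predict_proba(m, va$X)
  expect_in_range(p_va, 0, 1)
  expect_true(all(p_va[va$y == "manipulated"] >= 0.5))
})

test_that("SVM grid selection is deterministic with pinned tie-breaks", {
  tr <- make_cloud(15, 1, seed = 3)
  va <- make_cloud(8, 1, seed = 4)
  m1 <- train_svm(tr$X, tr$y, va$X, va$y, seed = 5)
  m2 <- train_svm(tr$X, tr$y, va$X, va$y, seed = 5)
  expect_identical(m1$report[c("C", "gamma")], m2$report[c("C", "gamma")])
  # with a fully separable task every grid point ties at AUC 1:
  # the smallest C then smallest gamma must win
  expect_equal(m1$report$C, min(m1$report$grid$C))
  tied <- m1$report$grid[m1$report$grid$C == m1$report$C, ]
  expect_equal(m1$report$gamma, min(tied$gamma[tied$val_auc == max(tied$val_auc)]))
  # grid of one point selects that point
  m3 <- train_svm(tr$X, tr$y, va$X, va$y, c_grid = 10, gamma_grid = 0.5)
  expect_equal(m3$report$C, 10)
  expect_equal(m3$report$gamma, 0.5)
  expect_error(train_svm(tr$X, rep("real", 30), va$X, va$y), "classes")
})

test_that("SVM standardization uses training statistics only", {
  tr <- make_cloud(15, 1, seed = 6)
  va <- make_cloud(8, 1, seed = 7)
  m1 <- train_svm(tr$X, tr$y, va$X, va$y)
  # shuffling the validation split must not change the frozen stats
  ord <- rev(seq_along(va$y))
  m2 <- train_svm(tr$X, tr$y, va$X[ord, ], va$y[ord])
  expect_identical(m1$mu, m2$mu)
  expect_identical(m1$sd, m2$sd)
  expect_equal(m1$mu, colMeans(tr$X))
})

test_that("CNN learns the easy blob task (threshold oracle first)", {
  tr <- make_blob_set(80, seed = 61)
  va <- make_blob_set(40, seed = 62)
  # oracle: the task is separable by mean intensity alone
  mu <- vapply(tr, function(s) mean(s$pixels), 0)
  y <- vapply(tr, `[[`, "", "label") == "manipulated"
  cut <- (max(mu[!y]) + min(mu[y])) / 2
  expect_true(all((mu > cut) == y))
  cnn <- train_cnn(tr, va, tiny_cnn_config(), seed = 8)
  p <- predict_proba(cnn, va)
  yv <- vapply(va, `[[`, "", "label") == "manipulated"
  expect_gte(mean((p >= 0.5) == yv), 0.9)
  expect_in_range(p, 0, 1)
  # stopping epoch within the cap; best weights = min of the val trace
  expect_lte(cnn$stopped_epoch, cnn$config$max_epochs)
  expect_equal(cnn$val_loss, min(cnn$history$val_loss))
  expect_equal(cnn$history$val_loss[cnn$best_epoch], cnn$val_loss)
})

test_that("CNN training is deterministic under a fixed seed", {
  tr <- make_blob_set(20, seed = 71)
  va <- make_blob_set(10, seed = 72)
  cfg <- tiny_cnn_config(max_epochs = 4L)
  a <- train_cnn(tr, va, cfg, seed = 9)
  b <- train_cnn(tr, va, cfg, seed = 9)
  expect_identical(a$history, b$history)
  expect_identical(a$weights, b$weights)
  # probabilities sum to one
  fw <- mriforensics:::cnn_pass(a$weights, cfg, tr[[1]]$pixels)
  expect_equal(sum(fw$p), 1, tolerance = 1e-6)
})

test_that("adversarial training trades a little clean accuracy for robustness", {
  tr <- make_blob_set(60, seed = 81)
  va <- make_blob_set(30, seed = 82)
  cfg <- tiny_cnn_config()
  clean_cnn <- train_cnn(tr, va, cfg, seed = 10)
  atk <- attack_config(epsilon = 0.1, alpha = 0.03, iters = 5)
  aug <- adversarial_augment(clean_cnn, tr, atk, fraction = 1, seed = 1)
  hard_cnn <- train_cnn(aug, va, cfg, seed = 10,
                        init_weights = clean_cnn$weights)
  yv <- vapply(va, `[[`, "", "label")
  acc <- function(model, samples, labels) {
    p <- vapply(samples, function(s)
      predict_proba(model, if (is.matrix(s)) s else s$pixels), 0)
    mean((p >= 0.5) == (labels == "manipulated"))
  }
  adv_va_clean <- lapply(va, function(s)
    pgd_attack(clean_cnn, s$pixels, s$label, atk))
  adv_va_hard <- lapply(va, function(s)
    pgd_attack(hard_cnn, s$pixels, s$label, atk))
  clean_drop <- acc(clean_cnn, va, yv) - acc(hard_cnn, va, yv)
  robust_gain <- acc(hard_cnn, adv_va_hard, yv) - acc(clean_cnn, adv_va_clean, yv)
  expect_gte(robust_gain, clean_drop)
})
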