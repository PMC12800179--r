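test_that("FGSM matches the analytic logistic-model oracle", {
  m <- logistic_model(w = 2, b = -1)
  set.seed(1)
  x <- matrix(runif(16, 0.2, 0.8), 4, 4)
  # true label "real": dJ/dx = p * w > 0 everywhere, so x_adv = x + eps
  adv <- fgsm_attack(m, x, "real", 0.05)
  expect_equal(adv, mriforensics:::clip01(x + 0.05))
  # label "manipulated": gradient is -(1-p) w < 0, so x_adv = x - eps
  adv2 <- fgsm_attack(m, x, "manipulated", 0.05)
  expect_equal(adv2, mriforensics:::clip01(x - 0.05))
  # zero budget is the identity
  expect_identical(fgsm_attack(m, x, "real", 0), x)
  # clipping binds at the upper bound
  ones <- matrix(1, 3, 3)
  expect_equal(fgsm_attack(m, ones, "real", 0.3), ones)
  expect_error(fgsm_attack(m, x, "real", -0.1), "epsilon")
})

test_that("PGD respects the epsilon ball and the pixel range", {
  m <- logistic_model(w = -3, b = 1)
  set.seed(2)
  for (rep in 1:5) {
    x <- matrix(runif(25), 5, 5)
    eps <- runif(1, 0.01, 0.2)
    cfg <- attack_config(epsilon = eps, alpha = runif(1, 0.005, 0.1),
                         iters = sample(0:6, 1), seed = rep)
    adv <- pgd_attack(m, x, sample(c("real", "manipulated"), 1), cfg)
    # brute-force per-pixel bound check
    expect_true(all(abs(adv - x) <= eps + 1e-9))
    expect_in_range(adv, 0, 1)
  }
  # degenerate ball
  x <- matrix(runif(9), 3, 3)
  expect_identical(pgd_attack(m, x, "real", attack_config(epsilon = 0)), x)
  # k = 0 is the seeded random init, projected and clipped
  cfg0 <- attack_config(epsilon = 0.1, iters = 0, seed = 9)
  init <- mriforensics:::with_seed(9, matrix(runif(9, -0.1, 0.1), 3, 3))
  expect_equal(pgd_attack(m, x, "real", cfg0),
               mriforensics:::clip01(pmin(pmax(x + init, x - 0.1), x + 0.1)))
})

test_that("FGSM equals PGD with k = 1, alpha = eps and no random init", {
  set.seed(3)
  tr <- make_blob_set(20, seed = 31)
  va <- make_blob_set(10, seed = 32)
  cnn <- train_cnn(tr, va, tiny_cnn_config(max_epochs = 3L), seed = 1)
  for (rep in 1:3) {
    x <- matrix(runif(32 * 32), 32, 32)
    eps <- runif(1, 0.01, 0.1)
    a <- fgsm_attack(cnn, x, "real", eps)
    b <- pgd_attack(cnn, x, "real",
                    attack_config(epsilon = eps, alpha = eps, iters = 1,
                                  random_init = FALSE))
    expect_equal(a, b)
  }
})

test_that("adversarial augmentation preserves labels and counts", {
  tr <- make_blob_set(20, seed = 41)
  va <- make_blob_set(10, seed = 42)
  cnn <- train_cnn(tr, va, tiny_cnn_config(max_epochs = 2L), seed = 2)
  cfg <- attack_config(iters = 2)
  expect_identical(adversarial_augment(cnn, tr, cfg, fraction = 0), tr)
  aug <- adversarial_augment(cnn, tr, cfg, fraction = 1, seed = 7)
  expect_length(aug, 3 * length(tr))
  orig_labels <- vapply(tr, `[[`, "", "label")
  adv <- aug[-seq_along(tr)]
  for (s in adv) {
    src <- sub("_(fgsm|pgd)$", "", s$id)
    expect_identical(s$label, orig_labels[vapply(tr, `[[`, "", "id") == src])
    expect_true(s$provenance %in% c("adv_fgsm", "adv_pgd"))
  }
  # half fraction with one method: n + round(0.5 n_class) per class
  aug2 <- adversarial_augment(cnn, tr, cfg, methods = "fgsm",
                              fraction = 0.5, seed = 1)
  expect_length(aug2, length(tr) + 10)
  expect_error(adversarial_augment(cnn, tr, cfg, fraction = 1.2), "fraction")
})

test_that("attacks reduce accuracy of an unhardened CNN on separable data", {
  tr <- make_blob_set(40, seed = 51)
  va <- make_blob_set(20, seed = 52)
  cnn <- train_cnn(tr, va, tiny_cnn_config(), seed = 3)
  y <- vapply(va, `[[`, "", "label")
  p_clean <- predict_proba(cnn, va)
  acc_clean <- mean((p_clean >= 0.5) == (y == "manipulated"))
  adv <- lapply(va, function(s)
    fgsm_attack(cnn, s$pixels, s$label, 0.1))
  p_adv <- vapply(adv, function(x) predict_proba(cnn, x), 0)
  acc_adv <- mean((p_adv >= 0.5) == (y == "manipulated"))
  expect_lte(acc_adv, acc_clean)
})
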