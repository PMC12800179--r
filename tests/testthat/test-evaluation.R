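test_that("confusion metrics match hand counts and guard division by zero", {
  labels <- rep(c("real", "manipulated"), c(116, 91))
  preds <- c(rep("real", 107), rep("manipulated", 9),
             rep("manipulated", 83), rep("real", 8))
  cm <- confusion_and_metrics(labels, preds)
  expect_equal(cm$true_real, 107)
  expect_equal(cm$true_manip, 83)
  expect_equal(cm$false_pos, 9)
  expect_equal(cm$false_neg, 8)
  expect_equal(cm$accuracy, 190 / 207)
  expect_equal(cm$precision, 83 / 92)
  expect_equal(cm$recall, 83 / 91)
  all_right <- confusion_and_metrics(labels, labels)
  expect_equal(all_right$accuracy, 1)
  expect_equal(all_right$f1, 1)
  # no predicted positives: precision undefined, not zero
  none <- confusion_and_metrics(c("real", "manipulated"), c("real", "real"))
  expect_true(is.na(none$precision))
  expect_true(is.na(none$f1))
  expect_error(confusion_and_metrics(character(), character()), "empty")
})

test_that("AUC equals brute-force pair counting (oracle equivalence)", {
  r <- roc_auc(c("manipulated", "real", "manipulated", "real"),
               c(0.9, 0.8, 0.4, 0.2))
  expect_equal(r$auc, 3 / 4)
  expect_equal(roc_auc(c("manipulated", "real"), c(1, 0))$auc, 1)
  expect_equal(roc_auc(rep(c("manipulated", "real"), 4), rep(0.3, 8))$auc, 0.5)
  pair_auc <- function(pos, neg) {
    s <- 0
    for (p in pos) for (n in neg)
      s <- s + (p > n) + 0.5 * (p == n)
    s / (length(pos) * length(neg))
  }
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    y <- sample(c("real", "manipulated"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), sample(1:3, 1))  # coarse scores force ties
    expect_equal(roc_auc(y, s)$auc,
                 pair_auc(s[y == "manipulated"], s[y == "real"]))
  }
  expect_true(is.na(roc_auc(rep("real", 5), runif(5))$auc))
})

test_that("average precision follows step interpolation and is rank-based", {
  expect_equal(pr_curve(c("manipulated", "real"), c(0.9, 0.1))$ap, 1)
  expect_equal(pr_curve(c("manipulated", "real"), c(0.3, 0.7))$ap, 0.5)
  set.seed(2)
  y <- sample(c("real", "manipulated"), 50, replace = TRUE)
  s <- runif(50)
  ap1 <- pr_curve(y, s)$ap
  ap2 <- pr_curve(y, stats::plogis(5 * (s - 0.5)))$ap  # monotone transform
  expect_equal(ap1, ap2)
})

test_that("calibration bins a calibrated predictor within 0.05", {
  cal <- calibration_curve(rep("manipulated", 4), rep(1, 4))
  expect_equal(nrow(cal), 1)
  expect_equal(cal$mean_score, 1)
  expect_equal(cal$fraction_positive, 1)
  expect_equal(cal$count, 4)
  set.seed(3)
  n <- 10000
  p <- runif(n)
  y <- ifelse(runif(n) < p, "manipulated", "real")
  tab <- calibration_curve(y, p, n_bins = 10)
  expect_equal(sum(tab$count), n)
  expect_lte(max(abs(tab$fraction_positive - tab$mean_score)), 0.05)
  expect_error(calibration_curve(y, p, n_bins = 0), "n_bins")
})

test_that("probability summary uses linear-interpolation quantiles", {
  ps <- probability_summary(c(0.2, 0.4, 0.6))
  expect_equal(ps$median, 0.4)
  cst <- probability_summary(rep(0.3, 10))
  expect_equal(cst$q75 - cst$q25, 0)
  set.seed(4)
  u <- runif(10001)
  expect_lt(abs(probability_summary(u)$median - 0.5), 0.02)
  expect_error(probability_summary(numeric()), "empty")
})

test_that("Wilcoxon exact p matches full sign enumeration", {
  a <- c(1, 2, 3, 4, 5, 6)
  w <- wilcoxon_signed_rank(a + 0.1, a)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 2 / 64)
  ident <- wilcoxon_signed_rank(a, a)
  expect_true(is.na(ident$statistic))
  expect_equal(ident$p_value, 1)
  # antisymmetry
  set.seed(5)
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               wilcoxon_signed_rank(y, x)$p_value)
  # independent enumeration oracle over all 2^n assignments
  enum_p <- function(d) {
    d <- d[d != 0]; n <- length(d)
    r <- rank(abs(d))
    w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
    hits <- 0
    for (m in 0:(2^n - 1)) {
      sgn <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
      wp <- sum(r[sgn])
      if (min(wp, sum(r) - wp) <= w_obs + 1e-9) hits <- hits + 1
    }
    hits / 2^n
  }
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    x <- round(rnorm(n), 1); y <- round(rnorm(n), 1)  # ties likely
    if (all(x == y)) next
    expect_equal(wilcoxon_signed_rank(x, y)$p_value, enum_p(x - y))
  }
  # matches stats::wilcox.test in the tie-free exact regime
  set.seed(6)
  x <- rnorm(9); y <- rnorm(9)
  ours <- wilcoxon_signed_rank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(ours$p_value, ref$p.value)
})

test_that("evaluation report fields are internally consistent", {
  set.seed(7)
  y <- sample(c("real", "manipulated"), 60, replace = TRUE)
  s <- ifelse(y == "manipulated", rbeta(60, 3, 1.5), rbeta(60, 1.5, 3))
  rep <- evaluation_report(y, s)
  cm <- rep$confusion
  expect_equal(cm$true_real + cm$true_manip + cm$false_pos + cm$false_neg,
               rep$n)
  expect_equal(cm$accuracy, (cm$true_real + cm$true_manip) / rep$n)
  expect_equal(cm$precision, cm$true_manip / (cm$true_manip + cm$false_pos))
  expect_equal(cm$recall, cm$true_manip / (cm$true_manip + cm$false_neg))
  expect_equal(sum(rep$calibration$count), rep$n)
  expect_in_range(c(rep$auc, rep$ap), 0, 1)
})
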