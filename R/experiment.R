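# Repeated-seed experiment driver: corpus -> split -> adversarially
# trained detector -> test evaluation, then Wilcoxon signed-rank
# comparison of the ensemble against its members across seeds.

#' Run the full detection experiment
#'
#' For every seed: generates a synthetic corpus, applies the stratified
#' 70/15/15 split, preprocesses all images, fits the detector (with
#' adversarial augmentation) and evaluates SVM, CNN and ensemble on the
#' held-out test split. Across seeds, the ensemble is compared with each
#' base model by the Wilcoxon signed-rank test on the per-seed AUC and F1
#' values; both raw and Holm-adjusted p-values are reported.
#'
#' @param config a [run_config()].
#' @param seeds integer vector of root seeds (one run each).
#' @param out_dir optional directory; when given, a JSON report and a CSV
#'   comparison table are written there.
#' @return list of class `tamper_experiment` with `runs` (per-seed list:
#'   `reports` for ensemble/svm/cnn, `weights`, `detector` metadata),
#'   `metrics` (per-seed data frame), and `comparisons` (Wilcoxon table).
#' @export
run_experiment <- function(config = run_config(), seeds = 1L,
                           out_dir = NULL) {
  if (length(seeds) < 1) stop_param("at least one seed is required")
  stage <- function(name, seed, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop_param("stage '%s' (seed %d) failed: %s", name, seed,
                 conditionMessage(e)))
    message(sprintf("[%s] seed=%d elapsed=%.1fs", name, seed,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    r
  }
  runs <- list()
  for (seed in seeds) {
    corpus <- stage("generate", seed,
      build_corpus(n_total = config$corpus$n_total, seed = seed,
                   image_size = config$corpus$image_size,
                   removal_fraction = config$corpus$removal_fraction))
    corpus <- stage("split", seed,
      split_corpus(corpus, config$corpus$fractions,
                   seed = derive_seed(seed, "split")))
    pp <- do.call(preprocess_config, config$preprocess)
    splits <- stage("preprocess", seed,
                    lapply(corpus$splits, preprocess_samples, config = pp))
    det <- stage("train", seed,
      fit_detector(splits$train, splits$val, config, seed = seed))
    reports <- stage("evaluate", seed, {
      y_test <- vapply(splits$test, `[[`, "", "label")
      pr <- predict(det, splits$test, type = "prob")
      list(ensemble = evaluation_report(y_test, pr$p_ensemble,
                                        config$ensemble$threshold),
           svm = evaluation_report(y_test, pr$p_svm,
                                   config$ensemble$threshold),
           cnn = evaluation_report(y_test, pr$p_cnn,
                                   config$ensemble$threshold))
    })
    runs[[as.character(seed)]] <- list(seed = seed, reports = reports,
                                       weights = det$weights,
                                       val_auc = det$val_auc)
  }
  metrics <- do.call(rbind, lapply(runs, function(r) {
    do.call(rbind, lapply(names(r$reports), function(m) {
      rep <- r$reports[[m]]
      data.frame(seed = r$seed, model = m, accuracy = rep$confusion$accuracy,
                 f1 = rep$confusion$f1, auc = rep$auc, ap = rep$ap)
    }))
  }))
  rownames(metrics) <- NULL
  comparisons <- NULL
  if (length(seeds) >= 2) {
    get <- function(model, what) metrics[[what]][metrics$model == model]
    rows <- list()
    for (other in c("svm", "cnn")) for (what in c("auc", "f1")) {
      wt <- wilcoxon_signed_rank(get("ensemble", what), get(other, what))
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste0("ensemble_vs_", other), metric = what,
        statistic = wt$statistic, p_value = wt$p_value, n = wt$n)
    }
    comparisons <- do.call(rbind, rows)
    comparisons$p_holm <- stats::p.adjust(comparisons$p_value, "holm")
  }
  out <- structure(list(runs = runs, metrics = metrics,
                        comparisons = comparisons, config = config,
                        seeds = seeds),
                   class = "tamper_experiment")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(experiment_json(out),
                         file.path(out_dir, "experiment.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(comparisons))
      utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
  }
  out
}

# serializable view of an experiment (no model objects)
experiment_json <- function(x) {
  list(seeds = x$seeds,
       metrics = x$metrics,
       comparisons = x$comparisons,
       runs = lapply(x$runs, function(r) list(
         seed = r$seed,
         weights = list(svm = r$weights$svm, cnn = r$weights$cnn),
         val_auc = r$val_auc,
         reports = lapply(r$reports, function(rep) list(
           confusion = unclass(rep$confusion), auc = rep$auc, ap = rep$ap,
           probability = rep$probability, calibration = rep$calibration,
           threshold = rep$threshold, n = rep$n)))))
}

#' @export
print.tamper_experiment <- function(x, ...) {
  cat(sprintf("<tamper_experiment> %d seed(s), corpus n=%d\n",
              length(x$seeds), x$config$corpus$n_total))
  agg <- stats::aggregate(cbind(accuracy, auc) ~ model, data = x$metrics, FUN = mean)
  print(agg, row.names = FALSE)
  if (!is.null(x$comparisons)) {
    cat("Wilcoxon signed-rank comparisons:\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}
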