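# The fitted detector: adversarially trained SVM + CNN base classifiers
# combined by AUC-weighted soft voting. `fit_detector` is the one-stop
# modelling entry point; the returned object carries everything needed
# for prediction on new images.

#' Fit the tamper detector
#'
#' End-to-end training on preprocessed, labeled samples:
#' 1. a base CNN is trained on the clean training split;
#' 2. the training split is adversarially augmented (FGSM and PGD crafted
#'    against the base CNN, original labels kept);
#' 3. the final CNN is trained on the augmented images, and the RBF-SVM on
#'    their fused HOG + deep features;
#' 4. ensemble weights are the validation-AUC-normalized weights of the
#'    two members.
#'
#' Attacks are crafted against the CNN only (the SVM exposes no pixel
#' gradient); the perturbed images nevertheless harden the SVM too, since
#' its features are extracted from them.
#'
#' @param train,val lists of labeled, preprocessed [image_sample()]s.
#' @param config a [run_config()] (attack, CNN, SVM and ensemble settings
#'   are taken from it).
#' @param backbone a [deep_backbone()] used for the deep features.
#' @param seed root seed for this fit.
#' @return an object of class `tamper_detector`.
#' @export
fit_detector <- function(train, val, config = run_config(),
                         backbone = NULL, seed = 1L) {
  if (is.null(backbone))
    backbone <- deep_backbone(seed = config$backbone$seed,
                              input_size = config$preprocess$size)
  cnn_cfg <- do.call(cnn_config, config$cnn)
  atk_cfg <- attack_config(epsilon = config$attack$epsilon,
                           alpha = config$attack$alpha,
                           iters = config$attack$iters,
                           seed = derive_seed(seed, "pgd_init"))
  base_cnn <- train_cnn(train, val, cnn_cfg, seed = derive_seed(seed, "cnn0"))
  aug <- adversarial_augment(base_cnn, train, atk_cfg,
                             methods = config$attack$methods,
                             fraction = config$attack$fraction,
                             seed = derive_seed(seed, "augment"))
  # fine-tune from the clean-trained weights on the augmented set
  cnn <- train_cnn(aug, val, cnn_cfg, seed = derive_seed(seed, "cnn"),
                   init_weights = base_cnn$weights)
  hog_cfg <- hog_config()
  x_aug <- featurize(aug, backbone, hog_cfg)
  x_val <- featurize(val, backbone, hog_cfg)
  y_aug <- vapply(aug, `[[`, "", "label")
  y_val <- vapply(val, `[[`, "", "label")
  svm <- train_svm(x_aug, y_aug, x_val, y_val,
                   c_grid = config$svm$c_grid,
                   gamma_grid = config$svm$gamma_grid,
                   seed = derive_seed(seed, "svm"))
  p_val_cnn <- predict_proba(cnn, val)
  auc_svm <- roc_auc(y_val, svm$p_val)$auc
  auc_cnn <- roc_auc(y_val, p_val_cnn)$auc
  weights <- compute_weights(auc_svm, auc_cnn)
  structure(list(svm = svm, cnn = cnn, base_cnn = base_cnn,
                 backbone = backbone, hog = hog_cfg, weights = weights,
                 threshold = config$ensemble$threshold,
                 val_auc = list(svm = auc_svm, cnn = auc_cnn),
                 config = config, seed = as.integer(seed)),
            class = "tamper_detector")
}

#' Predict on new samples with a fitted detector
#'
#' @param object a `tamper_detector`.
#' @param newdata list of preprocessed [image_sample()]s (or pixel
#'   matrices).
#' @param type `"prob"` for the three probability columns (svm, cnn,
#'   ensemble) or `"label"` for the thresholded ensemble label.
#' @param ... ignored.
#' @return a data frame of probabilities or a character vector of labels.
#' @export
predict.tamper_detector <- function(object, newdata, type = c("prob", "label"),
                                    ...) {
  type <- match.arg(type)
  x <- featurize(newdata, object$backbone, object$hog)
  p_svm <- predict_proba(object$svm, x)
  p_cnn <- predict_proba(object$cnn, newdata)
  ens <- ensemble_predict(p_svm, p_cnn, object$weights, object$threshold)
  if (type == "label") return(ens$label)
  data.frame(p_svm = p_svm, p_cnn = p_cnn, p_ensemble = ens$p_final,
             label = ens$label)
}

#' @rdname predict_proba
#' @export
predict_proba.tamper_detector <- function(model, x, ...) {
  predict(model, x, type = "prob")$p_ensemble
}

#' @export
print.tamper_detector <- function(x, ...) {
  cat(sprintf(paste0("<tamper_detector> AUC-weighted SVM+CNN ensemble\n",
                     "  weights: svm %.3f / cnn %.3f  (val AUC %.3f / %.3f)\n",
                     "  threshold %.2f\n"),
              x$weights$svm, x$weights$cnn,
              x$val_auc$svm, x$val_auc$cnn, x$threshold))
  invisible(x)
}

#' @export
summary.tamper_detector <- function(object, ...) {
  print(object)
  cat("SVM: "); print(object$svm)
  cat("CNN: "); print(object$cnn)
  invisible(object)
}
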