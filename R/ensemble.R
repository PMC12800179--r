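# AUC-weighted soft-voting ensemble of the SVM and CNN base classifiers.

#' Validation-AUC-normalized ensemble weights
#'
#' `w_i = AUC_i / (AUC_SVM + AUC_CNN)`. Both AUCs must lie in `(0, 1]`;
#' the weights are nonnegative and sum to one.
#'
#' @param auc_svm,auc_cnn validation AUC of the two base classifiers.
#' @return an `ensemble_weights` list with elements `svm` and `cnn`.
#' @export
compute_weights <- function(auc_svm, auc_cnn) {
  if (!is.finite(auc_svm) || !is.finite(auc_cnn) ||
      auc_svm <= 0 || auc_cnn <= 0 || auc_svm > 1 || auc_cnn > 1)
    stop_param("validation AUCs must lie in (0, 1]")
  s <- auc_svm + auc_cnn
  structure(list(svm = auc_svm / s, cnn = auc_cnn / s),
            class = "ensemble_weights")
}

#' Weighted-voting ensemble prediction
#'
#' Convex combination of the two member probabilities,
#' `p_final = w_svm * p_svm + w_cnn * p_cnn`, thresholded at 0.5. A score
#' of exactly 0.5 is labeled `manipulated` (ambiguous cases are flagged as
#' suspicious).
#'
#' @param p_svm,p_cnn member probabilities of `"manipulated"`, in `[0, 1]`
#'   (vectorized).
#' @param weights an [compute_weights()] result (or list with `svm`/`cnn`
#'   weights summing to 1).
#' @param threshold decision threshold.
#' @return list with `p_final` (numeric vector) and `label`
#'   (`"real"` / `"manipulated"` per input).
#' @export
ensemble_predict <- function(p_svm, p_cnn, weights, threshold = 0.5) {
  if (abs(weights$svm + weights$cnn - 1) > 1e-9 ||
      weights$svm < 0 || weights$cnn < 0)
    stop_param("ensemble weights must be nonnegative and sum to 1")
  if (any(p_svm < 0 | p_svm > 1) || any(p_cnn < 0 | p_cnn > 1))
    stop_param("member probabilities must lie in [0, 1]")
  p_final <- weights$svm * p_svm + weights$cnn * p_cnn
  list(p_final = p_final,
       label = ifelse(p_final >= threshold, "manipulated", "real"))
}
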