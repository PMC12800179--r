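# Gradient-based adversarial attacks (FGSM, PGD) against any classifier
# exposing a pixel-gradient of the cross-entropy loss, plus the
# adversarial augmentation step used for robust training.

#' Probability of manipulation
#'
#' Generic classifier contract: returns the predicted probability of the
#' `"manipulated"` class for each input.
#'
#' @param model a fitted classifier.
#' @param x input (pixel matrix, list of matrices / samples, or feature
#'   matrix, depending on the model).
#' @param ... method-specific arguments.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, x, ...) UseMethod("predict_proba")

#' Cross-entropy loss and its pixel gradient
#'
#' Generic gradient-model contract used by the attacks: returns the scalar
#' cross-entropy loss of the model at input `x` against label `y`, and the
#' gradient of that loss with respect to every pixel.
#'
#' @param model a gradient-capable classifier.
#' @param x pixel matrix in `[0, 1]`.
#' @param y true label, `"real"` or `"manipulated"`.
#' @param ... method-specific arguments.
#' @return list with elements `loss` (scalar, `>= 0`) and `gradient`
#'   (matrix of the same geometry as `x`).
#' @export
loss_and_gradient <- function(model, x, y, ...) UseMethod("loss_and_gradient")

#' Adversarial attack configuration
#'
#' @param epsilon infinity-norm perturbation budget in intensity units.
#' @param alpha PGD per-iteration step size.
#' @param iters PGD iteration count (`>= 0`).
#' @param seed seed for the PGD random initialization.
#' @param random_init start PGD from a uniform point in the epsilon-ball
#'   (disable to start exactly at the input).
#' @return an `attack_config` list.
#' @export
attack_config <- function(epsilon = 0.03, alpha = 0.007, iters = 10L,
                          seed = 1L, random_init = TRUE) {
  if (epsilon < 0) stop_param("attack.epsilon must be >= 0")
  if (alpha < 0) stop_param("attack.alpha must be >= 0")
  if (iters < 0 || iters != round(iters))
    stop_param("attack.iters must be a nonnegative integer")
  structure(list(epsilon = epsilon, alpha = alpha, iters = as.integer(iters),
                 seed = seed, random_init = isTRUE(random_init)),
            class = "attack_config")
}

grad_of <- function(model, x, y) {
  g <- loss_and_gradient(model, x, y)$gradient
  if (any(!is.finite(g)))
    stop_param("non-finite gradient encountered during attack crafting")
  g
}

#' Fast Gradient Sign Method attack
#'
#' Single-step attack: `x_adv = clip(x + epsilon * sign(grad_x J), 0, 1)`,
#' with `sign(0) = 0`. The result deviates from `x` by at most `epsilon`
#' per pixel and stays in `[0, 1]`.
#'
#' @param model a gradient-capable classifier (see [loss_and_gradient()]).
#' @param x pixel matrix in `[0, 1]`.
#' @param y true label of `x`.
#' @param epsilon perturbation budget (`>= 0`).
#' @return adversarial pixel matrix of the same geometry.
#' @export
fgsm_attack <- function(model, x, y, epsilon) {
  check_pixels(x)
  if (epsilon < 0) stop_param("epsilon must be >= 0")
  if (epsilon == 0) return(x)
  clip01(x + epsilon * sign(grad_of(model, x, y)))
}

#' Projected Gradient Descent attack
#'
#' Iterated signed-gradient attack: starting from a seeded uniform point
#' in the epsilon-ball around `x` (or from `x` itself when
#' `random_init = FALSE`), takes `iters` steps of size `alpha` along the
#' gradient sign, after each step projecting back onto the epsilon-ball
#' and clipping to `[0, 1]`. The gradient is recomputed at the current
#' iterate each iteration.
#'
#' @inheritParams fgsm_attack
#' @param config an [attack_config()].
#' @return adversarial pixel matrix with
#'   `max |x_adv - x| <= epsilon` and values in `[0, 1]`.
#' @export
pgd_attack <- function(model, x, y, config = attack_config()) {
  check_pixels(x)
  eps <- config$epsilon
  if (eps == 0) return(x)
  project <- function(z) clip01(pmin(pmax(z, x - eps), x + eps))
  xa <- if (config$random_init)
    x + with_seed(config$seed,
                  matrix(runif(length(x), -eps, eps), nrow(x), ncol(x)))
  else x
  xa <- project(xa)
  for (i in seq_len(config$iters))
    xa <- project(xa + config$alpha * sign(grad_of(model, xa, y)))
  xa
}

#' Adversarially augment a sample set
#'
#' For a seeded random subset of each class (of size
#' `round(fraction * n_class)`), appends FGSM- and/or PGD-perturbed copies
#' carrying the ORIGINAL labels, so that robust training sees both clean
#' and attacked versions of the same content. Provenance of the copies is
#' flagged `adv_fgsm` / `adv_pgd`.
#'
#' @param model gradient-capable classifier the attacks are crafted
#'   against.
#' @param samples list of [image_sample()]s (preprocessed pixels).
#' @param config an [attack_config()].
#' @param methods subset of `c("fgsm", "pgd")`.
#' @param fraction fraction of each class to perturb, in `[0, 1]`.
#' @param seed seed for the subset selection.
#' @return list of samples: the originals followed by the adversarial
#'   copies.
#' @export
adversarial_augment <- function(model, samples, config = attack_config(),
                                methods = c("fgsm", "pgd"), fraction = 0.5,
                                seed = 1L) {
  if (fraction < 0 || fraction > 1) stop_param("fraction must lie in [0, 1]")
  methods <- match.arg(methods, c("fgsm", "pgd"), several.ok = TRUE)
  if (fraction == 0) return(samples)
  labels <- vapply(samples, `[[`, "", "label")
  chosen <- with_seed(seed, {
    unlist(lapply(unique(labels), function(lab) {
      pool <- which(labels == lab)
      pool[sample.int(length(pool), round_half_up(fraction * length(pool)))]
    }))
  })
  adv <- list()
  for (i in sort(chosen)) {
    s <- samples[[i]]
    if ("fgsm" %in% methods) {
      a <- s
      a$pixels <- fgsm_attack(model, s$pixels, s$label, config$epsilon)
      a$id <- paste0(s$id, "_fgsm"); a$provenance <- "adv_fgsm"
      adv[[length(adv) + 1L]] <- a
    }
    if ("pgd" %in% methods) {
      cfg <- config
      cfg$seed <- derive_seed(seed, paste0("pgd_", s$id))
      a <- s
      a$pixels <- pgd_attack(model, s$pixels, s$label, cfg)
      a$id <- paste0(s$id, "_pgd"); a$provenance <- "adv_pgd"
      adv[[length(adv) + 1L]] <- a
    }
  }
  c(samples, adv)
}
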