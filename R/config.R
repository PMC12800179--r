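# Run configuration: documented defaults for every stage, YAML loading
# with flat dotted-key fallback, and validation that reports every bad
# key at once.

#' Run configuration with documented defaults
#'
#' Nested configuration for a full pipeline run. Every field has a
#' default; unknown keys are rejected.
#'
#' Sections and defaults:
#' * `corpus`: `n_total` 1378, `image_size` 224, `removal_fraction` 0.5,
#'   `fractions` (0.70, 0.15, 0.15).
#' * `preprocess`: `size` 224, `sigma` 1.5, `interp` "bilinear".
#' * `attack`: `epsilon` 0.03, `alpha` 0.007, `iters` 10,
#'   `fraction` 0.5, `methods` ("fgsm", "pgd").
#' * `cnn`: see [cnn_config()].
#' * `svm`: `c_grid` (0.1, 1, 10, 100), `gamma_grid` NULL (defaults to
#'   `{1e-4, 1e-3, 1e-2, 1e-1, 1/d}` at fit time).
#' * `ensemble`: `threshold` 0.5.
#' * `backbone`: `seed` 7 (weight initialization of the deep feature
#'   extractor).
#'
#' @param ... named overrides, either nested lists (`corpus = list(...)`)
#'   or flat dotted keys (`"attack.epsilon" = 0.05`).
#' @return a validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    corpus = list(n_total = 1378L, image_size = 224L,
                  removal_fraction = 0.5, fractions = c(0.70, 0.15, 0.15)),
    preprocess = list(size = 224L, sigma = 1.5, interp = "bilinear"),
    attack = list(epsilon = 0.03, alpha = 0.007, iters = 10L,
                  fraction = 0.5, methods = c("fgsm", "pgd")),
    cnn = list(input_size = 224L, stem_pool = 4L, widths = c(16L, 32L, 64L),
               fc = 128L, lr = 1e-3, batch = 32L, patience = 5L,
               max_epochs = 50L, min_delta = 1e-4),
    svm = list(c_grid = c(0.1, 1, 10, 100), gamma_grid = NULL),
    ensemble = list(threshold = 0.5),
    backbone = list(seed = 7L))
  apply_overrides(cfg, list(...))
}

# merge overrides (nested or dotted) into cfg, collecting every bad key
apply_overrides <- function(cfg, overrides) {
  errs <- character()
  set_key <- function(section, key, value) {
    if (!section %in% names(cfg)) {
      errs <<- c(errs, sprintf("unknown section '%s'", section))
    } else if (!key %in% names(cfg[[section]])) {
      errs <<- c(errs, sprintf("unknown key '%s.%s'", section, key))
    } else {
      old <- cfg[[section]][[key]]
      if (is.numeric(old) && !is.null(value) && !is.numeric(value)) {
        errs <<- c(errs, sprintf("type mismatch for '%s.%s' (expected numeric)",
                                 section, key))
      } else cfg[[section]][[key]] <<- value
    }
  }
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    if (grepl(".", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      set_key(parts[1], paste(parts[-1], collapse = "."), v)
    } else if (is.list(v)) {
      for (k in names(v)) set_key(nm, k, v[[k]])
    } else errs <- c(errs, sprintf("unknown key '%s'", nm))
  }
  errs <- c(errs, validate_config_values(cfg))
  if (length(errs) > 0)
    stop_param("invalid configuration:\n  %s", paste(errs, collapse = "\n  "))
  structure(cfg, class = "run_config")
}

validate_config_values <- function(cfg) {
  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(cfg$corpus$n_total >= 2, "'corpus.n_total' must be >= 2")
  chk(abs(sum(cfg$corpus$fractions) - 1) < 1e-9,
      "'corpus.fractions' must sum to 1")
  chk(cfg$preprocess$sigma >= 0, "'preprocess.sigma' must be >= 0")
  chk(cfg$preprocess$size >= 1, "'preprocess.size' must be positive")
  chk(cfg$attack$epsilon >= 0, "'attack.epsilon' must be >= 0")
  chk(cfg$attack$alpha >= 0, "'attack.alpha' must be >= 0")
  chk(cfg$attack$iters >= 0, "'attack.iters' must be >= 0")
  chk(cfg$attack$fraction >= 0 && cfg$attack$fraction <= 1,
      "'attack.fraction' must lie in [0, 1]")
  chk(all(cfg$attack$methods %in% c("fgsm", "pgd")),
      "'attack.methods' must be a subset of fgsm, pgd")
  chk(cfg$ensemble$threshold >= 0 && cfg$ensemble$threshold <= 1,
      "'ensemble.threshold' must lie in [0, 1]")
  chk(cfg$cnn$lr > 0, "'cnn.lr' must be > 0")
  errs
}

#' Load / save a run configuration
#'
#' The file is YAML; either nested sections or flat dotted keys
#' (`attack.eps: 0.05`) are accepted. Defaults are merged in; every
#' unknown key or invalid value is reported in a single error. An empty
#' file yields the full-default configuration. `save_config` /
#' `load_config` round-trip exactly.
#'
#' @param path file path.
#' @param config a `run_config`.
#' @return `load_config` returns a validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_param("config file '%s' not found", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(run_config, raw)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
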