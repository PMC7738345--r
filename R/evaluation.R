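# Metrics and the experiment grid: 4 reductions (DWMD / SPA / PCA / IRIV)
# crossed with 3 regressors (PLSR / ELM / GA-ELM), all cells sharing the
# same simulated data, reference, split and per-reduction features.

#' Coefficient of determination
#'
#' `R^2 = 1 - SSE/SST`; equals 1 iff predictions are exact.
#'
#' @param y_true Observed values (>= 2 samples, nonzero variance).
#' @param y_pred Predictions.
#' @return R-squared (<= 1; negative when worse than the mean predictor).
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2) stop("need at least 2 samples")
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) stop("zero variance in y_true")
  1 - sum((y_true - y_pred)^2) / sst
}

#' Root mean square error
#'
#' @param y_true Observed values.
#' @param y_pred Predictions.
#' @return RMSE (same units as the response, mg/g for N deficiency).
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 1) stop("need at least 1 sample")
  sqrt(mean((y_true - y_pred)^2))
}

#' Build features for one reduction method
#'
#' Dispatches to the four reductions, always fitting any data-driven choice
#' (wavelet selection, band selection, loadings) on the training split only.
#'
#' @param diffs A split `difference_set`.
#' @param method `"dwmd"`, `"spa"`, `"pca"` or `"iriv"`.
#' @param options Method options (see Details).
#' @param seed Seed for seeded sub-steps.
#' @return List with `train`, `val` (feature matrices), `y_train`, `y_val`
#'   and `info` (method-specific provenance: chosen spec, bands, ...).
#'
#' @details Options by method: `dwmd`: `spec` (a [wavelet_spec()]; default
#'   selects via [select_wavelet_and_level()]); `spa`: `candidate_N`,
#'   `k0_candidates`, `folds`; `pca`: `n_components`; `iriv`: `intervals`,
#'   `n_joint`, `sipls_folds`, `max_rounds`, `n_rows`, `folds`,
#'   `r_threshold`.
#' @export
reduce_features <- function(diffs, method = c("dwmd", "spa", "pca", "iriv"),
                            options = list(), seed = 1) {
  method <- match.arg(method)
  tr <- split_side(diffs, "train")
  va <- split_side(diffs, "validation")
  o <- options
  out <- switch(method,
    dwmd = {
      spec <- o$spec
      if (is.null(spec)) spec <- select_wavelet_and_level(tr$X)$spec
      list(train = wavelet_features(tr$X, spec),
           val = wavelet_features(va$X, spec),
           info = list(spec = spec))
    },
    spa = {
      sel <- spa_select(tr$X, tr$y,
                        candidate_N = o$candidate_N %||% 2:10,
                        k0_candidates = o$k0_candidates,
                        folds = o$folds %||% 10, seed = seed)
      list(train = tr$X[, sel$bands, drop = FALSE],
           val = va$X[, sel$bands, drop = FALSE],
           info = sel)
    },
    pca = {
      k <- o$n_components %||% 5
      pc <- pca_extract(tr$X, va$X, k)
      list(train = pc$scores_train, val = pc$scores_val, info = pc)
    },
    iriv = {
      sel <- iriv_select(tr$X, tr$y,
                         intervals = o$intervals,
                         n_joint = o$n_joint %||% 4,
                         sipls_folds = o$sipls_folds %||% 10,
                         max_rounds = o$max_rounds %||% 5,
                         n_rows = o$n_rows %||% 50,
                         folds = o$folds %||% 5,
                         r_threshold = o$r_threshold %||% 0.9,
                         seed = seed)
      list(train = tr$X[, sel$bands, drop = FALSE],
           val = va$X[, sel$bands, drop = FALSE],
           info = sel)
    })
  out$y_train <- tr$y
  out$y_val <- va$y
  out$method <- method
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit one inversion model on a feature set
#'
#' @param X Training features.
#' @param y Training response.
#' @param model `"plsr"`, `"elm"` or `"gaelm"`.
#' @param options Model options: `plsr`: `ncomp`; `elm`/`gaelm`: `s2`;
#'   `gaelm` additionally `pop_size`, `generations`, `k_c`, `k_m`.
#' @param seed Seed for the stochastic models.
#' @return Fitted model object with a `predict` method.
#' @export
fit_model <- function(X, y, model = c("plsr", "elm", "gaelm"),
                      options = list(), seed = 1) {
  model <- match.arg(model)
  o <- options
  switch(model,
    plsr = plsr_fit(X, y, ncomp = o$ncomp, seed = seed),
    elm = elm_fit(X, y, s2 = o$s2 %||% 20, seed = seed),
    gaelm = ga_elm_fit(X, y, s2 = o$s2 %||% 20,
                       pop_size = o$pop_size %||% 30,
                       generations = o$generations %||% 100,
                       k_c = o$k_c %||% 0.5, k_m = o$k_m %||% 0.5,
                       seed = seed))
}

#' Experiment grid configuration
#'
#' @param seed Master seed; every random draw of the grid flows from it.
#' @param simulate Arguments for [sim_config()] (seed is derived).
#' @param split `list(fraction, )` for [split_train_validation()].
#' @param reductions Subset of `c("dwmd", "spa", "pca", "iriv")`.
#' @param models Subset of `c("plsr", "elm", "gaelm")`.
#' @param reduce_options Named list of per-method options
#'   (see [reduce_features()]).
#' @param model_options Named list of per-model options (see [fit_model()]).
#' @return Config list for [run_grid()].
#' @export
grid_config <- function(seed = 1, simulate = list(),
                        split = list(fraction = 189 / 259),
                        reductions = c("dwmd", "spa", "pca", "iriv"),
                        models = c("plsr", "elm", "gaelm"),
                        reduce_options = list(), model_options = list()) {
  list(seed = as.integer(seed), simulate = simulate, split = split,
       reductions = reductions, models = models,
       reduce_options = reduce_options, model_options = model_options)
}

#' Run the reduction-by-model experiment grid
#'
#' Simulates one dataset, builds the standard reference and difference set,
#' splits once, builds features once per reduction, and fits every requested
#' model on the identical features, reporting train/validation R-squared and
#' RMSE per cell. A cell failure is recorded as an error row and the run
#' continues.
#'
#' @param config A [grid_config()].
#' @return List of class `experiment_grid` with `reports` (one row per
#'   cell: method, reduction, r2/rmse on both sides, n_features, error),
#'   `features` (per reduction), `diffs` and `config`.
#' @export
run_grid <- function(config) {
  sim_args <- config$simulate
  sim_args$seed <- config$seed
  cfg <- do.call(sim_config, sim_args)
  samples <- generate_samples(cfg)
  yields <- generate_yields(cfg)
  ref <- build_reference(samples, select_standard(yields))
  diffs <- compute_differences(samples, ref)
  diffs <- split_train_validation(diffs,
                                  fraction = config$split$fraction %||% (189 / 259),
                                  seed = config$seed + 1L)
  features <- list()
  rows <- list()
  for (red in config$reductions) {
    feats <- tryCatch(
      reduce_features(diffs, red, config$reduce_options[[red]] %||% list(),
                      seed = config$seed + 2L),
      error = function(e) e)
    features[[red]] <- feats
    for (mod in config$models) {
      row <- data.frame(reduction = red, model = mod,
                        r2_train = NA_real_, rmse_train = NA_real_,
                        r2_val = NA_real_, rmse_val = NA_real_,
                        n_features = NA_integer_, error = NA_character_)
      if (inherits(feats, "error")) {
        row$error <- conditionMessage(feats)
      } else {
        res <- tryCatch({
          fit <- fit_model(feats$train, feats$y_train, mod,
                           config$model_options[[mod]] %||% list(),
                           seed = config$seed + 3L)
          pt <- predict(fit, feats$train)
          pv <- predict(fit, feats$val)
          list(r2_train = r_squared(feats$y_train, pt),
               rmse_train = rmse(feats$y_train, pt),
               r2_val = r_squared(feats$y_val, pv),
               rmse_val = rmse(feats$y_val, pv),
               n_features = ncol(feats$train))
        }, error = function(e) e)
        if (inherits(res, "error")) {
          row$error <- conditionMessage(res)
        } else {
          row[names(res)] <- res
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  structure(list(reports = do.call(rbind, rows), features = features,
                 diffs = diffs, config = config),
            class = "experiment_grid")
}

#' @export
print.experiment_grid <- function(x, ...) {
  cat("<experiment_grid>\n")
  print(x$reports, digits = 4)
  invisible(x)
}
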