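# Principal component analysis of the difference spectra. Components are
# fitted on the training split only; held-out scores use the training
# loadings and centering, which keeps the validation set out of the
# feature construction.

#' Principal component features of difference spectra
#'
#' @param X_train Training difference-spectrum matrix.
#' @param X_val Optional held-out matrix scored with the training loadings.
#' @param n_components Component count (default 5).
#' @return Object of class `pca_result` with `loadings` (bands x
#'   components, orthonormal columns), `scores_train`, `scores_val`,
#'   `explained_variance` (decreasing) and `center`.
#' @export
pca_extract <- function(X_train, X_val = NULL, n_components = 5) {
  X_train <- as.matrix(X_train)
  if (nrow(X_train) <= n_components)
    stop("need more samples than components")
  pc <- stats::prcomp(X_train, center = TRUE, scale. = FALSE)
  if (n_components > ncol(pc$rotation))
    stop("n_components exceeds the rank of the training data")
  k <- seq_len(n_components)
  loadings <- pc$rotation[, k, drop = FALSE]
  scores_val <- NULL
  if (!is.null(X_val)) {
    X_val <- as.matrix(X_val)
    if (ncol(X_val) != ncol(X_train)) stop("band grid mismatch")
    scores_val <- sweep(X_val, 2, pc$center) %*% loadings
  }
  structure(list(loadings = loadings,
                 scores_train = pc$x[, k, drop = FALSE],
                 scores_val = scores_val,
                 explained_variance = pc$sdev[k]^2,
                 center = pc$center),
            class = "pca_result")
}
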