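# Compact SIMPLS kernel for a univariate response. IRIV and the
# synergy-interval screening evaluate tens of thousands of small PLS models
# under cross-validation, so the kernel returns the whole coefficient path
# (1..ncomp latent variables) from a single decomposition.

#' Fit a univariate-response PLS model (SIMPLS)
#'
#' @param X Predictor matrix (samples x variables).
#' @param y Numeric response.
#' @param ncomp Number of latent variables (capped at the effective rank;
#'   extraction stops early when the score norm underflows).
#' @return Object of class `pls1_fit` with the coefficient path `coefs`
#'   (variables x components, column a = model using a latent variables),
#'   centers, and `ncomp` actually extracted.
#' @export
pls1_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), ncomp >= 1)
  ncomp <- min(ncomp, ncol(X), nrow(X) - 1)
  if (ncomp < 1) stop("not enough samples/variables for one latent variable")
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xc <- sweep(X, 2, x_center)
  yc <- y - y_center
  p <- ncol(X)
  s <- crossprod(Xc, yc)
  V <- matrix(0, p, ncomp)
  R <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  a_done <- 0L
  for (a in seq_len(ncomp)) {
    r <- s
    t <- Xc %*% r
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) break
    t <- t / nt
    r <- r / nt
    pl <- crossprod(Xc, t)
    Q[a] <- sum(yc * t)
    v <- pl
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pl)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    V[, a] <- v
    R[, a] <- r
    s <- s - v * sum(v * s)
    a_done <- a
  }
  if (a_done == 0L) stop("rank deficiency below one latent variable")
  coefs <- matrix(0, p, a_done)
  acc <- numeric(p)
  for (a in seq_len(a_done)) {
    acc <- acc + R[, a] * Q[a]
    coefs[, a] <- acc
  }
  rownames(coefs) <- colnames(X)
  structure(list(coefs = coefs, x_center = x_center, y_center = y_center,
                 ncomp = a_done),
            class = "pls1_fit")
}

#' Predict from a `pls1_fit`
#'
#' @param object A `pls1_fit`.
#' @param newdata Matrix with the same variables as the training data.
#' @param ncomp Latent-variable count to use (default: all extracted).
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.pls1_fit <- function(object, newdata, ncomp = object$ncomp, ...) {
  ncomp <- min(ncomp, object$ncomp)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$coefs)) stop("feature width mismatch")
  as.vector(sweep(newdata, 2, object$x_center) %*%
              object$coefs[, ncomp]) + object$y_center
}

#' Deterministic fold assignment
#'
#' @param n Sample count.
#' @param folds Fold count (2..n).
#' @param seed Integer seed.
#' @return Integer fold id per sample.
#' @export
make_folds <- function(n, folds, seed = 1) {
  if (folds > n) stop("fold count exceeds sample count")
  if (folds < 2) stop("need at least 2 folds")
  set.seed(seed)
  sample(rep_len(seq_len(folds), n))
}

#' Cross-validated RMSE of a PLS model
#'
#' @param X Predictors.
#' @param y Response.
#' @param ncomp Maximum latent variables; the RMSECV path for 1..ncomp is
#'   returned.
#' @param fold_id Fold assignment (e.g. from [make_folds()]); recycled
#'   callers should pass the same assignment to compare subsets fairly.
#' @return Numeric vector: RMSECV for each latent-variable count (entries
#'   beyond the extractable rank carry the last attainable value).
#' @export
pls_rmsecv <- function(X, y, ncomp, fold_id) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(fold_id) == n)
  press <- matrix(NA_real_, n, ncomp)
  for (f in unique(fold_id)) {
    hold <- fold_id == f
    fit <- pls1_fit(X[!hold, , drop = FALSE], y[!hold], ncomp)
    Xc <- sweep(X[hold, , drop = FALSE], 2, fit$x_center)
    pred <- Xc %*% fit$coefs + fit$y_center
    if (fit$ncomp < ncomp)
      pred <- cbind(pred, matrix(pred[, fit$ncomp],
                                 sum(hold), ncomp - fit$ncomp))
    press[hold, ] <- (pred - y[hold])^2
  }
  sqrt(colMeans(press))
}

#' Partial least squares regression with CV-chosen dimensionality
#'
#' Chooses the latent-variable count by 10-fold cross-validated RMSE over
#' 1..min(15, rank) unless `ncomp` is given, then refits on all samples.
#'
#' @param X Training features.
#' @param y Training response (N deficiency, mg/g).
#' @param ncomp Fixed latent-variable count; `NULL` (default) selects by CV.
#' @param folds CV folds for selection.
#' @param seed Seed for the fold assignment.
#' @return Object of class `plsr_model` (contains the underlying
#'   [pls1_fit()], the chosen `ncomp` and the RMSECV path).
#' @export
plsr_fit <- function(X, y, ncomp = NULL, folds = 10, seed = 1) {
  X <- as.matrix(X)
  cap <- min(15L, ncol(X), nrow(X) - ceiling(nrow(X) / folds) - 1L)
  if (is.null(ncomp)) {
    fold_id <- make_folds(nrow(X), folds, seed)
    path <- pls_rmsecv(X, y, cap, fold_id)
    ncomp <- which.min(path)
  } else {
    path <- NULL
    ncomp <- min(ncomp, cap)
  }
  fit <- pls1_fit(X, y, ncomp)
  structure(list(fit = fit, ncomp = fit$ncomp, rmsecv_path = path),
            class = "plsr_model")
}

#' @export
predict.plsr_model <- function(object, newdata, ...) {
  predict(object$fit, newdata, ncomp = object$ncomp)
}
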