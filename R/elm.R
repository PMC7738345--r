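# Extreme learning machine: single hidden layer with logistic-sigmoid
# activation, random input weights and biases in [-1, 1], identity output
# map, and output weights solved in closed form by least squares on the
# hidden activations. Inputs are rescaled to [-1, 1] per feature using the
# training ranges so the sigmoids work in their active region.

# input conditioning: center and whiten by the training principal axes so
# random projections excite every feature direction equally; collinear
# feature sets (e.g. wavelet approximation coefficients) would otherwise
# hide their low-variance, signal-bearing directions from the random
# hidden layer. Directions with relative SD below 1e-6 are dropped.
.elm_scaling <- function(X) {
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  keep <- pc$sdev > pc$sdev[1] * 1e-6
  if (!any(keep)) keep <- 1
  transform <- sweep(pc$rotation[, keep, drop = FALSE], 2, pc$sdev[keep], "/")
  list(center = pc$center, transform = transform)
}

.elm_hidden <- function(X, scaling, W, b) {
  Xn <- sweep(X, 2, scaling$center) %*% scaling$transform
  stats::plogis(Xn %*% W + rep(b, each = nrow(X)))
}

# least-squares output weights (intercept + s2 hidden units) via the
# Moore-Penrose pseudo-inverse; singular values below rel_tol * d_max are
# treated as zero, which doubles as the ridge-like guard for degenerate
# activation matrices
.elm_solve <- function(H, y, rel_tol = 1e-12) {
  Hb <- cbind(1, H)
  s <- svd(Hb)
  keep <- s$d > s$d[1] * rel_tol
  as.vector(s$v[, keep, drop = FALSE] %*%
              (crossprod(s$u[, keep, drop = FALSE], y) / s$d[keep]))
}

.elm_build <- function(X, y, W, b, scaling, seed = NA_integer_) {
  H <- .elm_hidden(X, scaling, W, b)
  beta <- .elm_solve(H, y)
  structure(list(s1 = ncol(X), s2 = ncol(W), s3 = 1L,
                 input_weights = W, hidden_bias = b,
                 output_weights = beta, scaling = scaling,
                 seed = seed),
            class = "elm_network")
}

#' Fit an extreme learning machine
#'
#' Input weights and hidden biases are drawn uniformly from `[-1, 1]` under
#' the given seed and are never adjusted; only the output weights are
#' trained, by the Moore-Penrose pseudo-inverse of the hidden activation
#' matrix (singular values below 1e-12 of the largest are truncated, which
#' regularizes degenerate activation matrices).
#'
#' @param X Training features.
#' @param y Training response (N deficiency, mg/g).
#' @param s2 Hidden-node count (default 20).
#' @param seed Integer seed for the random layer.
#' @return Object of class `elm_network`.
#' @export
elm_fit <- function(X, y, s2 = 20, seed = 1) {
  X <- as.matrix(X)
  stopifnot(s2 >= 1, nrow(X) == length(y))
  set.seed(seed)
  scaling <- .elm_scaling(X)
  k <- ncol(scaling$transform)
  W <- matrix(stats::runif(k * s2, -1, 1), k, s2)
  b <- stats::runif(s2, -1, 1)
  .elm_build(X, y, W, b, scaling, seed = as.integer(seed))
}

#' @export
predict.elm_network <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$s1) stop("feature width mismatch")
  H <- .elm_hidden(newdata, object$scaling, object$input_weights,
                   object$hidden_bias)
  as.vector(cbind(1, H) %*% object$output_weights)
}

#' @export
print.elm_network <- function(x, ...) {
  cat(sprintf("<elm_network> %d-%d-%d, sigmoid hidden layer, identity output\n",
              x$s1, x$s2, x$s3))
  invisible(x)
}
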