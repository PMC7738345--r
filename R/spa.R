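# Successive projections algorithm (SPA): forward band selection that
# minimizes collinearity. Stage 1 grows projection chains k(0)..k(N-1);
# stage 2 scores each candidate (k0, N) chain by cross-validated RMSE of an
# ordinary least-squares model; stage 3 prunes the winning chain by backward
# elimination.

#' Project columns orthogonally to a pivot column
#'
#' One SPA projection step: for every column j in `S`,
#' `P x_j = x_j - x_k (x_j' x_k) / (x_k' x_k)` where `x_k` is the pivot.
#'
#' @param X Working matrix (samples x bands).
#' @param k_prev Pivot column index.
#' @param S Indices of the columns to project.
#' @return Matrix of the projected columns (samples x `length(S)`).
#' @export
spa_project <- function(X, k_prev, S) {
  xk <- X[, k_prev]
  denom <- sum(xk^2)
  if (denom < 1e-300) stop("zero pivot column in SPA projection")
  Xs <- X[, S, drop = FALSE]
  Xs - xk %*% (crossprod(xk, Xs) / denom)
}

#' Grow an SPA selection chain
#'
#' Starting from `k0`, repeatedly projects all unselected columns orthogonal
#' to the last selected one and picks the column with the largest projected
#' norm. The total number of single-column projections performed equals
#' `(N - 1) * (J - N / 2)` and is attached as attribute `"projections"`.
#'
#' @param X Training matrix (samples x J bands).
#' @param k0 Initial band position.
#' @param N Chain length (`N <= min(samples, J)`).
#' @return Integer vector of N distinct positions, attribute
#'   `"projections"` = projection count.
#' @export
spa_chain <- function(X, k0, N) {
  X <- as.matrix(X)
  J <- ncol(X)
  if (N > min(nrow(X), J)) stop("N exceeds the rank limit min(samples, J)")
  chain <- k0
  n_proj <- 0L
  W <- X
  while (length(chain) < N) {
    S <- setdiff(seq_len(J), chain)
    W[, S] <- spa_project(W, chain[length(chain)], S)
    n_proj <- n_proj + length(S)
    norms <- colSums(W[, S, drop = FALSE]^2)
    if (max(norms) < 1e-20) stop("N exceeds the effective rank of X")
    chain <- c(chain, S[which.max(norms)])
  }
  structure(chain, projections = n_proj)
}

# RMSECV of an OLS model on the given band subset
.ols_rmsecv <- function(X, y, bands, fold_id) {
  Xb <- X[, bands, drop = FALSE]
  press <- numeric(length(y))
  for (f in unique(fold_id)) {
    hold <- fold_id == f
    d <- cbind(1, Xb[!hold, , drop = FALSE])
    beta <- qr.coef(qr(d), y[!hold])
    beta[is.na(beta)] <- 0
    press[hold] <- (cbind(1, Xb[hold, , drop = FALSE]) %*% beta - y[hold])^2
  }
  sqrt(mean(press))
}

#' SPA band selection (all three stages)
#'
#' Runs a chain from every candidate start position (the initial band is not
#' part of the method's definition, so all candidates are tried), scores
#' every `(k0, N)` prefix by RMSECV of an OLS model of the N deficiency on
#' the chain's bands, picks the minimum, and finally removes bands whose
#' elimination does not worsen RMSECV by more than `prune_tol` (relative).
#'
#' @param X Training difference-spectrum matrix.
#' @param y Training N deficiency (mg/g).
#' @param candidate_N Candidate chain lengths (e.g. `2:10`, or a single
#'   value to force the subset size).
#' @param k0_candidates Start positions (default: every column).
#' @param folds CV folds for the RMSE scoring.
#' @param seed Seed for the fold assignment.
#' @param prune_tol Relative RMSECV tolerance of the backward pruning.
#' @return List with `bands` (sorted selected positions), `rmsecv`,
#'   `chain` (the winning unpruned chain) and `k0`.
#' @export
spa_select <- function(X, y, candidate_N = 2:10,
                       k0_candidates = NULL, folds = 10, seed = 1,
                       prune_tol = 0.01) {
  X <- as.matrix(X)
  J <- ncol(X)
  N_max <- max(candidate_N)
  if (N_max > min(nrow(X), J)) stop("candidate_N exceeds rank limits")
  if (is.null(k0_candidates)) k0_candidates <- seq_len(J)
  fold_id <- make_folds(nrow(X), folds, seed)
  best <- list(rmsecv = Inf)
  for (k0 in k0_candidates) {
    chain <- spa_chain(X, k0, N_max)
    for (N in candidate_N) {
      r <- .ols_rmsecv(X, y, chain[seq_len(N)], fold_id)
      if (r < best$rmsecv)
        best <- list(rmsecv = r, chain = chain[seq_len(N)], k0 = k0)
    }
  }
  # stage 3: backward elimination at a relative tolerance
  bands <- best$chain
  rms <- best$rmsecv
  while (length(bands) > 1) {
    drop_rms <- vapply(seq_along(bands), function(i) {
      .ols_rmsecv(X, y, bands[-i], fold_id)
    }, numeric(1))
    i_best <- which.min(drop_rms)
    if (drop_rms[i_best] <= rms * (1 + prune_tol) + 1e-12) {
      bands <- bands[-i_best]
      rms <- drop_rms[i_best]
    } else break
  }
  list(bands = sort(bands), rmsecv = rms, chain = best$chain, k0 = best$k0)
}
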