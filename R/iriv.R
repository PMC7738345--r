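# Iteratively retaining informative variables (IRIV), with the
# synergy-interval PLS pre-screening that reduces the 600-band grid to a
# joint interval of a few contiguous 20-band blocks, and a final pruning of
# highly correlated neighbours.

#' Tile the band grid into contiguous intervals
#'
#' The 600-band grid splits into 30 intervals of 20 bands each; interval k
#' covers bands `20(k-1)+1 .. 20k`.
#'
#' @param n_bands Grid size (default 600).
#' @param width Interval width in bands (default 20).
#' @return List of integer index vectors, one per interval.
#' @export
iriv_intervals <- function(n_bands = 600, width = 20) {
  if (n_bands %% width != 0) stop("grid does not tile into equal intervals")
  lapply(seq_len(n_bands / width), function(k) ((k - 1) * width + 1):(k * width))
}

#' Wavelength bounds of an interval
#'
#' @param k Interval number, 1..30.
#' @return `c(nm_lo, nm_hi)`: interval k spans `401 + 20(k-1)` to
#'   `400 + 20k` nm.
#' @export
interval_bounds <- function(k) {
  if (any(k < 1 | k > 30)) stop("interval number must be in 1..30")
  c(401 + 20 * (k - 1), 400 + 20 * k)
}

#' Synergy-interval PLS screening of the joint interval
#'
#' Evaluates a PLS model on every combination of `n_joint` intervals by
#' cross-validated RMSE and returns the combination with the minimum.
#'
#' @param X Training difference-spectrum matrix.
#' @param y Training N deficiency.
#' @param intervals List of interval index vectors (default: the full
#'   30-interval tiling of `ncol(X)`).
#' @param n_joint Intervals per combination (default 4).
#' @param folds CV folds (default 10).
#' @param ncomp Latent variables of the screening PLS models.
#' @param seed Seed for the fold assignment.
#' @return List with `intervals` (chosen interval numbers), `bands` (their
#'   band indices), `rmsecv`, and `n_combinations` evaluated.
#' @export
sipls_joint_interval <- function(X, y, intervals = NULL, n_joint = 4,
                                 folds = 10, ncomp = 5, seed = 1) {
  X <- as.matrix(X)
  if (is.null(intervals)) intervals <- iriv_intervals(ncol(X))
  if (folds > nrow(X)) stop("fold count exceeds sample count")
  fold_id <- make_folds(nrow(X), folds, seed)
  combos <- utils::combn(length(intervals), n_joint)
  best <- list(rmsecv = Inf)
  for (i in seq_len(ncol(combos))) {
    sel <- combos[, i]
    bands <- unlist(intervals[sel], use.names = FALSE)
    r <- min(pls_rmsecv(X[, bands, drop = FALSE], y, ncomp, fold_id))
    if (r < best$rmsecv)
      best <- list(rmsecv = r, intervals = sel, bands = bands)
  }
  best$n_combinations <- ncol(combos)
  best
}

# RMSECV of a PLS model on a band subset (best over 1..ncomp components)
.pls_subset_rmsecv <- function(X, y, bands, fold_id, ncomp) {
  min(pls_rmsecv(X[, bands, drop = FALSE], y,
                 min(ncomp, length(bands)), fold_id))
}

#' Iteratively retaining informative variables
#'
#' Each round draws a random binary inclusion matrix over the current bands,
#' scores every row-combination by cross-validated PLS RMSE, and classifies
#' each band by the difference of mean RMSECV between combinations without
#' and with it (positive difference = the band helps) together with a
#' two-sided Mann-Whitney U test. Strongly (P < `alpha`) and weakly
#' informative bands are kept; uninformative and interfering ones are
#' dropped. Iterates until the kept set is stable or `max_rounds` is
#' reached, then runs one backward-elimination pass.
#'
#' @param X Training difference-spectrum matrix.
#' @param y Training N deficiency.
#' @param bands Candidate band indices (default: all columns).
#' @param max_rounds Maximum rounds (default 5).
#' @param n_rows Rows of the binary inclusion matrix per round.
#' @param p_incl Inclusion probability per cell.
#' @param folds CV folds of the row models.
#' @param ncomp Latent-variable cap of the row models.
#' @param alpha Mann-Whitney significance level.
#' @param seed Integer seed.
#' @return List with `retained` (band indices), `n_rounds`, and
#'   `classification` (per-round data frames: band, dmean, p_value, class).
#' @export
iriv_iterate <- function(X, y, bands = NULL, max_rounds = 5, n_rows = 50,
                         p_incl = 0.5, folds = 5, ncomp = 5, alpha = 0.05,
                         seed = 1) {
  X <- as.matrix(X)
  if (is.null(bands)) bands <- seq_len(ncol(X))
  if (length(bands) < 1) stop("need at least one band")
  if (length(bands) == 1) return(list(retained = bands, n_rounds = 0L,
                                      classification = list()))
  set.seed(seed)
  fold_id <- make_folds(nrow(X), folds, seed)
  current <- bands
  history <- list()
  round <- 0L
  while (round < max_rounds && length(current) >= 2) {
    round <- round + 1L
    k <- length(current)
    B <- matrix(stats::runif(n_rows * k) < p_incl, n_rows, k)
    short <- rowSums(B) < 2
    for (r in which(short)) B[r, sample.int(k, 2)] <- TRUE
    row_rms <- vapply(seq_len(n_rows), function(r) {
      .pls_subset_rmsecv(X, y, current[B[r, ]], fold_id, ncomp)
    }, numeric(1))
    dmean <- numeric(k)
    pval <- numeric(k)
    for (j in seq_len(k)) {
      w <- row_rms[B[, j]]
      wo <- row_rms[!B[, j]]
      if (length(w) == 0 || length(wo) == 0) { # unassessable: keep
        dmean[j] <- 1; pval[j] <- 1; next
      }
      dmean[j] <- mean(wo) - mean(w)
      pval[j] <- suppressWarnings(stats::wilcox.test(w, wo)$p.value)
    }
    class <- ifelse(dmean > 0,
                    ifelse(pval < alpha, "strong", "weak"),
                    ifelse(pval < alpha, "interfering", "uninformative"))
    history[[round]] <- data.frame(band = current, dmean = dmean,
                                   p_value = pval, class = class)
    keep <- current[dmean > 0]
    if (length(keep) == 0)
      stop("IRIV dropped every band; response carries no detectable signal")
    stable <- length(keep) == length(current)
    current <- keep
    if (stable) break
  }
  # backward elimination on the survivors
  if (length(current) > 1) {
    base <- .pls_subset_rmsecv(X, y, current, fold_id, ncomp)
    repeat {
      if (length(current) == 1) break
      drop_rms <- vapply(seq_along(current), function(i) {
        .pls_subset_rmsecv(X, y, current[-i], fold_id, ncomp)
      }, numeric(1))
      i_best <- which.min(drop_rms)
      if (drop_rms[i_best] < base) {
        current <- current[-i_best]
        base <- drop_rms[i_best]
      } else break
    }
  }
  list(retained = current, n_rounds = round, classification = history)
}

#' Prune mutually correlated bands
#'
#' Groups bands whose pairwise absolute correlation exceeds `r_threshold`
#' (transitively, i.e. connected components of the correlation graph) and
#' keeps one representative per group: the band most correlated with the
#' response.
#'
#' @param X Training difference-spectrum matrix.
#' @param y Training N deficiency.
#' @param bands Band indices to prune.
#' @param r_threshold Absolute-correlation threshold (default 0.9).
#' @return Sorted integer vector of retained band indices.
#' @export
correlation_prune <- function(X, y, bands, r_threshold = 0.9) {
  if (length(bands) < 1) stop("need at least one band")
  if (length(bands) == 1) return(bands)
  X <- as.matrix(X)
  C <- abs(stats::cor(X[, bands, drop = FALSE]))
  C[is.na(C)] <- 0
  adj <- C > r_threshold
  k <- length(bands)
  comp <- integer(k)
  cid <- 0L
  for (i in seq_len(k)) {
    if (comp[i] != 0L) next
    cid <- cid + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  ycor <- abs(apply(X[, bands, drop = FALSE], 2, stats::cor, y))
  ycor[is.na(ycor)] <- 0
  kept <- vapply(seq_len(cid), function(g) {
    members <- which(comp == g)
    bands[members[which.max(ycor[members])]]
  }, numeric(1))
  sort(as.integer(kept))
}

#' Full IRIV reduction: screening, iteration and pruning
#'
#' Convenience wrapper chaining [sipls_joint_interval()], [iriv_iterate()]
#' and [correlation_prune()].
#'
#' @inheritParams iriv_iterate
#' @param intervals Interval tiling passed to the screening stage.
#' @param n_joint Intervals in the joint combination.
#' @param sipls_folds CV folds of the screening stage.
#' @param r_threshold Correlation-pruning threshold.
#' @return List with `bands` (final selection), `joint` (screening result)
#'   and `iriv` (iteration result).
#' @export
iriv_select <- function(X, y, intervals = NULL, n_joint = 4,
                        sipls_folds = 10, max_rounds = 5, n_rows = 50,
                        folds = 5, ncomp = 5, alpha = 0.05,
                        r_threshold = 0.9, seed = 1) {
  joint <- sipls_joint_interval(X, y, intervals = intervals,
                                n_joint = n_joint, folds = sipls_folds,
                                ncomp = ncomp, seed = seed)
  it <- iriv_iterate(X, y, bands = joint$bands, max_rounds = max_rounds,
                     n_rows = n_rows, folds = folds, ncomp = ncomp,
                     alpha = alpha, seed = seed)
  bands <- correlation_prune(X, y, it$retained, r_threshold)
  list(bands = bands, joint = joint, iriv = it)
}
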