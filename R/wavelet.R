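# Discrete wavelet multiscale decomposition (DWMD) of difference spectra.
#
# No wavelet transform ships with the package's dependency set, so the
# decimated single- and multi-level transform is implemented here directly.
# Analysis filters are the standard orthogonal Daubechies-10, coiflet-5 and
# symlet-8 coefficient tables; synthesis filters follow from the usual
# quadrature-mirror relations rec_lo = rev(dec_lo),
# rec_hi[k] = (-1)^(k-1) dec_lo[k], dec_hi = rev(rec_hi).

.dwt_dec_lo <- list(
  db10 = c(
    -1.32642028945212443e-05, 9.35886703200695919e-05, -1.16466855129285449e-04,
    -6.85856694959711619e-04, 1.99240529518505613e-03, 1.39535174705290106e-03,
    -1.07331754833305745e-02, 3.60655356695616970e-03, 3.32126740593410019e-02,
    -2.94575368218758134e-02, -7.13941471663970817e-02, 9.30573646035723484e-02,
    1.27369340335793252e-01, -1.95946274377377050e-01, -2.49846424327315381e-01,
    2.81172343660577473e-01, 6.88459039453603538e-01, 5.27201188931725628e-01,
    1.88176800077691497e-01, 2.66700579005555542e-02),
  coif5 = c(
    -9.60401011276789415e-08, -1.62379951720483376e-07, 2.06122039857887835e-06,
    3.70072771133947962e-06, -2.12702216725156143e-05, -4.12198619242655010e-05,
    1.40356328123732431e-04, 3.01857941668244784e-04, -6.37558926125881154e-04,
    -1.66162730392987882e-03, 2.43157544253828862e-03, 6.76152022062041693e-03,
    -9.15950733867616253e-03, -1.97583916009654650e-02, 3.26747994670573555e-02,
    4.12875304721178338e-02, -1.05563151307337233e-01, -6.20377515749819600e-02,
    4.37982306659163378e-01, 7.74293622860327435e-01, 4.21571266730754346e-01,
    -5.20466702535547637e-02, -9.19215880600860874e-02, 2.81697442705323535e-02,
    2.34083221189277831e-02, -1.01315848469002764e-02, -4.15931262757864018e-03,
    2.17829437784569473e-03, 3.58577741161757678e-04, -2.12081862067494000e-04),
  sym8 = c(
    -3.38241595100612557e-03, -5.42132331791148124e-04, 3.16950878114929807e-02,
    7.60748732491760542e-03, -1.43294238350809705e-01, -6.12733590676585241e-02,
    4.81359651258372212e-01, 7.77185751700523508e-01, 3.64441894835331404e-01,
    -5.19458381077090373e-02, -2.72190299170560028e-02, 4.91371796736075062e-02,
    3.80875201389061510e-03, -1.49522583370482309e-02, -3.02920514721366800e-04,
    1.88995033275946088e-03)
)

#' Supported wavelet families
#'
#' The three orthogonal families used for multiscale decomposition of
#' difference spectra: the order-10 Daubechies wavelet (20-tap filter), the
#' order-5 coiflet (30 taps) and the order-8 symlet (16 taps).
#'
#' @return Character vector of family names.
#' @export
wavelet_families <- function() names(.dwt_dec_lo)

#' Analysis and synthesis filters of a wavelet family
#'
#' @param family One of `wavelet_families()`.
#' @return List with `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi` and the tap count
#'   `length`.
#' @export
wavelet_filters <- function(family) {
  family <- match.arg(family, wavelet_families())
  lo <- .dwt_dec_lo[[family]]
  L <- length(lo)
  rec_lo <- rev(lo)
  rec_hi <- lo * (-1)^(seq_len(L) - 1)
  list(dec_lo = lo, dec_hi = rev(rec_hi), rec_lo = rec_lo, rec_hi = rec_hi,
       length = L)
}

#' Wavelet decomposition specification
#'
#' @param family One of `wavelet_families()`.
#' @param level Decomposition depth (integer >= 1).
#' @return Object of class `wavelet_spec` with fields `family`,
#'   `filter_length` and `level`.
#' @export
wavelet_spec <- function(family, level) {
  family <- match.arg(family, wavelet_families())
  level <- as.integer(level)
  if (level < 1) stop("decomposition level must be >= 1")
  structure(list(family = family,
                 filter_length = length(.dwt_dec_lo[[family]]),
                 level = level),
            class = "wavelet_spec")
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf("<wavelet_spec> %s (%d taps), level %d\n",
              x$family, x$filter_length, x$level))
  invisible(x)
}

#' Approximation-coefficient count of the decimated transform
#'
#' Closed form of the coefficient-count recursion of the decimated discrete
#' wavelet transform with boundary extension: `a_0 = n`,
#' `a_j = floor((a_{j-1} + filter_length - 1) / 2)`.
#'
#' @param n Input signal length.
#' @param filter_length Filter tap count.
#' @param level Decomposition depth; `level = 0` returns `n`.
#' @return Integer coefficient count at depth `level`.
#' @export
approx_length <- function(n, filter_length, level) {
  stopifnot(n >= 1, level >= 0)
  a <- as.integer(n)
  for (j in seq_len(level)) a <- (a + as.integer(filter_length) - 1L) %/% 2L
  a
}

# one analysis step: half-point symmetric extension by L-1 samples each side,
# valid convolution, keep even-indexed outputs -> floor((n + L - 1)/2) coeffs
.dwt_step_sym <- function(x, lo, hi) {
  L <- length(lo)
  n <- length(x)
  # half-point symmetric index map onto 1..n (edge samples repeat)
  pos <- seq(-(L - 2), n + L - 1)
  q <- (pos - 1) %% (2 * n)
  ext <- x[ifelse(q < n, q + 1, 2 * n - q)]
  m <- embed(ext, L)
  keep <- seq(2, nrow(m), by = 2)
  list(a = as.vector(m[keep, , drop = FALSE] %*% lo),
       d = as.vector(m[keep, , drop = FALSE] %*% hi))
}

# one analysis step with circular (periodic) boundary: orthogonal for even n
.dwt_step_per <- function(x, lo, hi) {
  L <- length(lo)
  n <- length(x)
  if (n %% 2 == 1) { x <- c(x, x[n]); n <- n + 1 }
  idx <- outer(seq(0, n - 1), seq(0, L - 1), function(i, j) ((i - j) %% n) + 1)
  m <- matrix(x[idx], n, L)
  keep <- seq(2, n, 2)
  list(a = as.vector(m[keep, , drop = FALSE] %*% lo),
       d = as.vector(m[keep, , drop = FALSE] %*% hi))
}

# one synthesis step (symmetric boundary): upsample, convolve, trim to out_len
.idwt_step_sym <- function(a, d, rec_lo, rec_hi, out_len) {
  L <- length(rec_lo)
  la <- length(a)
  up <- function(v) { u <- numeric(2 * la); u[seq(1, 2 * la, 2)] <- v; u }
  conv_full <- function(u, f) {
    uext <- c(numeric(L - 1), u, numeric(L - 1))
    as.vector(embed(uext, L) %*% f)
  }
  y <- conv_full(up(a), rec_lo) + conv_full(up(d), rec_hi)
  y <- y[(L - 1):(length(y) - (L - 1))]
  y[seq_len(out_len)]
}

# synthesis for the periodic step is the adjoint of the analysis operator
.idwt_step_per <- function(a, d, lo, hi, out_len) {
  n <- 2 * length(a)
  idx <- outer(seq(0, n - 1), seq(0, length(lo) - 1),
               function(i, j) ((i - j) %% n) + 1)
  keep <- seq(2, n, 2)
  x <- numeric(n)
  for (r in seq_along(keep)) {
    pos <- idx[keep[r], ]
    x[pos] <- x[pos] + a[r] * lo + d[r] * hi
  }
  x[seq_len(out_len)]
}

#' Multiscale wavelet decomposition of a spectrum
#'
#' Applies the decimated discrete wavelet transform recursively to the
#' approximation branch. The default half-point symmetric boundary extension
#' yields `floor((a + L - 1)/2)` coefficients per step; the `"periodic"`
#' boundary is the orthogonal (energy-conserving) variant with `a/2`
#' coefficients per step.
#'
#' @param x Numeric spectrum (e.g. a 600-band difference spectrum).
#' @param spec A [wavelet_spec()].
#' @param boundary `"symmetric"` (default) or `"periodic"`.
#' @return Object of class `dwt_decomposition` with `approx` (final-level
#'   approximation coefficients), `details` (list, level 1 = finest),
#'   `lengths_by_level`, `n`, `spec`, `boundary`.
#' @export
dwt_decompose <- function(x, spec, boundary = c("symmetric", "periodic")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(spec, "wavelet_spec"), all(is.finite(x)))
  f <- wavelet_filters(spec$family)
  step <- if (boundary == "symmetric") .dwt_step_sym else .dwt_step_per
  a <- as.numeric(x)
  details <- vector("list", spec$level)
  lens <- integer(spec$level)
  for (j in seq_len(spec$level)) {
    if (length(a) < 2) stop("signal too short for decomposition level ", j)
    s <- step(a, f$dec_lo, f$dec_hi)
    details[[j]] <- s$d
    a <- s$a
    lens[j] <- length(a)
  }
  structure(list(approx = a, details = details, lengths_by_level = lens,
                 n = length(x), spec = spec, boundary = boundary),
            class = "dwt_decomposition")
}

#' Reconstruct a spectrum from its wavelet decomposition
#'
#' @param dec A `dwt_decomposition`.
#' @param approx_only If `TRUE`, zero all detail coefficients before
#'   synthesis (the profile reconstruction used for the correlation
#'   criterion).
#' @return Numeric vector of length `dec$n`.
#' @export
dwt_reconstruct <- function(dec, approx_only = FALSE) {
  stopifnot(inherits(dec, "dwt_decomposition"))
  f <- wavelet_filters(dec$spec$family)
  istep <- if (dec$boundary == "symmetric") {
    function(a, d, out_len) .idwt_step_sym(a, d, f$rec_lo, f$rec_hi, out_len)
  } else {
    function(a, d, out_len) .idwt_step_per(a, d, f$dec_lo, f$dec_hi, out_len)
  }
  a <- dec$approx
  for (j in rev(seq_len(dec$spec$level))) {
    d <- dec$details[[j]]
    if (approx_only) d <- numeric(length(d))
    out_len <- if (j == 1) dec$n else dec$lengths_by_level[j - 1]
    a <- istep(a, d, out_len)
  }
  a
}

#' Correlation between a spectrum and its approximation-only reconstruction
#'
#' Pearson correlation of the original signal with the signal rebuilt from
#' the final-level approximation coefficients alone (details zeroed); this is
#' the "relevance" column of the mother-wavelet / level selection report.
#'
#' @param x Numeric spectrum with nonzero variance.
#' @param spec A [wavelet_spec()]; `level = 0` is not represented, use
#'   [stats::cor()] directly for the identity case.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
reconstruction_correlation <- function(x, spec) {
  if (stats::sd(x) == 0) stop("input spectrum has zero variance")
  stats::cor(x, dwt_reconstruct(dwt_decompose(x, spec), approx_only = TRUE))
}

#' Mother-wavelet and decomposition-level selection report
#'
#' For every (family, level) pair, records the approximation-coefficient
#' count, the compression ratio `100 * count / n` (percent) and the
#' correlation of the approximation-only reconstruction with the signal.
#' The correlation is computed on the mean of the supplied difference
#' spectra.
#'
#' @param delta_spectra Matrix of difference spectra (samples x bands) or a
#'   single spectrum.
#' @param families Candidate families, default all of [wavelet_families()].
#' @param levels Candidate depths, default `1:12`.
#' @return `data.frame` with columns `family`, `level`, `approx_count`,
#'   `compression_ratio`, `correlation`.
#' @export
scale_selection_report <- function(delta_spectra,
                                   families = wavelet_families(),
                                   levels = 1:12) {
  if (is.null(dim(delta_spectra))) {
    delta_spectra <- matrix(delta_spectra, nrow = 1)
  }
  if (nrow(delta_spectra) < 1) stop("need at least one spectrum")
  if (length(families) < 1) stop("need at least one candidate family")
  m <- colMeans(delta_spectra)
  n <- length(m)
  grid <- expand.grid(level = levels, family = families,
                      stringsAsFactors = FALSE)[, 2:1]
  grid$approx_count <- mapply(function(fam, lev) {
    approx_length(n, length(.dwt_dec_lo[[fam]]), lev)
  }, grid$family, grid$level)
  grid$compression_ratio <- 100 * grid$approx_count / n
  grid$correlation <- mapply(function(fam, lev) {
    reconstruction_correlation(m, wavelet_spec(fam, lev))
  }, grid$family, grid$level)
  rownames(grid) <- NULL
  grid
}

#' Select the mother wavelet and decomposition level
#'
#' Applies the selection rule used for the compression study: among cells
#' whose approximation count has stabilized (count unchanged from the
#' previous level, or level >= 10), choose the one with the lowest
#' approximation count; ties are broken by the highest reconstruction
#' correlation, then by the shallower level.
#'
#' @inheritParams scale_selection_report
#' @return List with `spec` (the chosen [wavelet_spec()]) and `report` (the
#'   full [scale_selection_report()]).
#' @export
select_wavelet_and_level <- function(delta_spectra,
                                     families = wavelet_families(),
                                     levels = 1:12) {
  report <- scale_selection_report(delta_spectra, families, levels)
  stab <- logical(nrow(report))
  for (i in seq_len(nrow(report))) {
    prev <- report$approx_count[report$family == report$family[i] &
                                report$level == report$level[i] - 1]
    stab[i] <- report$level[i] >= 10 ||
      (length(prev) == 1 && prev == report$approx_count[i])
  }
  cand <- report[stab, ]
  if (nrow(cand) == 0) cand <- report
  ord <- order(cand$approx_count, -cand$correlation, cand$level)
  best <- cand[ord[1], ]
  list(spec = wavelet_spec(best$family, best$level), report = report)
}

#' Wavelet approximation-coefficient features
#'
#' Decomposes every difference spectrum and stacks the final-level
#' approximation coefficients into the design matrix used by the inversion
#' models.
#'
#' @param delta_r Matrix of difference spectra (samples x bands).
#' @param spec A [wavelet_spec()].
#' @return Numeric matrix, samples x `approx_length(ncol(delta_r),
#'   filter_length, level)`, columns named `A1`, `A2`, ...
#' @export
wavelet_features <- function(delta_r, spec) {
  stopifnot(is.matrix(delta_r))
  out <- t(apply(delta_r, 1, function(x) dwt_decompose(x, spec)$approx))
  if (nrow(delta_r) == 1) out <- matrix(out, nrow = 1)
  colnames(out) <- paste0("A", seq_len(ncol(out)))
  rownames(out) <- rownames(delta_r)
  out
}
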