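# published approximation-coefficient counts for a 600-band signal,
# levels 1..12 (columns of the compression study)
.counts <- list(
  db10 = c(309, 164, 91, 55, 37, 28, 23, 21, 20, 19, 19, 19),
  coif5 = c(314, 171, 100, 64, 46, 37, 33, 31, 30, 29, 29, 29),
  sym8 = c(307, 161, 88, 51, 33, 24, 19, 17, 16, 15, 15, 15)
)

test_that("coefficient-count recursion reproduces all 36 published counts", {
  for (fam in names(.counts)) {
    L <- wavelet_filters(fam)$length
    expect_equal(sapply(1:12, function(j) approx_length(600, L, j)),
                 .counts[[fam]])
    expect_equal(approx_length(600, L, 0), 600)
  }
})

test_that("the actual transform emits coefficient vectors of those lengths", {
  set.seed(1)
  x <- rnorm(600)
  for (fam in names(.counts)) {
    dec <- dwt_decompose(x, wavelet_spec(fam, 12))
    expect_equal(dec$lengths_by_level, .counts[[fam]])
  }
  expect_length(dwt_decompose(x, wavelet_spec("sym8", 10))$approx, 15)
})

test_that("perfect reconstruction holds to machine precision", {
  set.seed(2)
  for (case in list(c("db10", 5), c("sym8", 10), c("coif5", 3))) {
    x <- rnorm(600)
    dec <- dwt_decompose(x, wavelet_spec(case[1], as.integer(case[2])))
    expect_lt(max(abs(dwt_reconstruct(dec) - x)), 1e-10)
  }
  # periodic boundary as well (even lengths throughout at level 3)
  x <- rnorm(600)
  dec <- dwt_decompose(x, wavelet_spec("db10", 3), boundary = "periodic")
  expect_lt(max(abs(dwt_reconstruct(dec) - x)), 1e-10)
})

test_that("constant spectra put nothing into the detail coefficients", {
  dec <- dwt_decompose(rep(2.5, 600), wavelet_spec("sym8", 6))
  expect_lt(max(abs(unlist(dec$details))), 1e-8)
})

test_that("the transform is linear", {
  set.seed(3)
  x <- rnorm(600); y <- rnorm(600)
  sp <- wavelet_spec("db10", 4)
  lhs <- dwt_decompose(2.5 * x - 1.25 * y, sp)
  rhs_a <- 2.5 * dwt_decompose(x, sp)$approx - 1.25 * dwt_decompose(y, sp)$approx
  expect_lt(max(abs(lhs$approx - rhs_a)), 1e-10)
})

test_that("the periodic transform conserves energy (orthogonality)", {
  set.seed(4)
  x <- rnorm(600)
  for (fam in wavelet_families()) {
    dec <- dwt_decompose(x, wavelet_spec(fam, 3), boundary = "periodic")
    e <- sum(dec$approx^2) + sum(unlist(dec$details)^2)
    expect_lt(abs(e - sum(x^2)), 1e-8)
  }
})

test_that("approximation-only reconstruction tracks smooth signals", {
  wl <- seq(0, 1, length.out = 600)
  smooth <- 1 + 2 * wl - 3 * wl^2 + wl^3
  expect_gt(reconstruction_correlation(smooth, wavelet_spec("sym8", 3)), 0.99)
  # non-increasing in level on a monotone signal
  r <- sapply(1:10, function(j) {
    reconstruction_correlation(exp(wl), wavelet_spec("db10", j))
  })
  expect_true(all(diff(r) <= 1e-6))
  expect_error(reconstruction_correlation(rep(1, 600), wavelet_spec("sym8", 2)),
               "variance")
})

test_that("selection report matches the published counts and ratios", {
  p <- small_pipeline()
  tr <- split_side(p$diffs, "train")
  rep_ <- scale_selection_report(tr$X)
  expect_equal(nrow(rep_), 36)
  for (fam in names(.counts)) {
    rows <- rep_[rep_$family == fam, ]
    expect_equal(rows$approx_count[order(rows$level)], .counts[[fam]])
    expect_equal(round(rows$compression_ratio[order(rows$level)], 3),
                 round(100 * .counts[[fam]] / 600, 3))
  }
})

test_that("the selection rule picks the 16-tap symlet at level 10", {
  p <- small_pipeline()
  tr <- split_side(p$diffs, "train")
  sel <- select_wavelet_and_level(tr$X)
  expect_equal(sel$spec$family, "sym8")
  expect_equal(sel$spec$level, 10)
  # independent application of the rule to the report
  r <- sel$report
  stab <- r$level >= 10 |
    mapply(function(f, l, c) {
      prev <- r$approx_count[r$family == f & r$level == l - 1]
      length(prev) == 1 && prev == c
    }, r$family, r$level, r$approx_count)
  cand <- r[stab, ]
  cand <- cand[order(cand$approx_count, -cand$correlation, cand$level), ]
  expect_equal(cand$family[1], sel$spec$family)
  expect_equal(cand$level[1], sel$spec$level)
  one <- select_wavelet_and_level(tr$X[1, , drop = FALSE],
                                  families = "coif5", levels = 4)
  expect_equal(one$spec$family, "coif5")
  expect_equal(one$spec$level, 4)
  expect_error(scale_selection_report(tr$X, families = character(0)), "family")
})

test_that("wavelet features have the expected shape and scale linearly", {
  p <- small_pipeline()
  tr <- split_side(p$diffs, "train")
  sp <- wavelet_spec("sym8", 10)
  f <- wavelet_features(tr$X[1:189, ], sp)
  expect_equal(dim(f), c(189, 15))
  z <- wavelet_features(matrix(0, 1, 600), sp)
  expect_lt(max(abs(z)), 1e-12)
  doubled <- wavelet_features(2 * tr$X[1:3, ], sp)
  expect_lt(max(abs(doubled - 2 * wavelet_features(tr$X[1:3, ], sp))), 1e-10)
})

test_that("degenerate one-sample signals error cleanly", {
  # the boundary-extended count recursion never drops below 2, so only a
  # single-sample input is too short to decompose
  expect_error(dwt_decompose(3.3, wavelet_spec("sym8", 1)), "too short")
})
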