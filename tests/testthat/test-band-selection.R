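test_that("PCA components are orthonormal with decreasing, decorrelated scores", {
  set.seed(1)
  X <- matrix(rnorm(80 * 30), 80, 30)
  pc <- pca_extract(X, n_components = 5)
  expect_lt(max(abs(crossprod(pc$loadings) - diag(5))), 1e-8)
  expect_true(all(diff(pc$explained_variance) <= 0))
  cv <- cov(pc$scores_train)
  expect_lt(max(abs(cv - diag(diag(cv)))), 1e-8)
})

test_that("rank-deficient data put no variance past the true rank", {
  set.seed(2)
  basis <- matrix(rnorm(2 * 30), 2, 30)
  X <- matrix(rnorm(100 * 2), 100, 2) %*% basis
  pc <- pca_extract(X, n_components = 5)
  expect_lt(max(pc$explained_variance[3:5]), 1e-10)
  # exact reconstruction of rank-5 data from 5 components
  basis5 <- matrix(rnorm(5 * 30), 5, 30)
  X5 <- matrix(rnorm(100 * 5), 100, 5) %*% basis5
  pc5 <- pca_extract(X5, n_components = 5)
  rebuilt <- sweep(pc5$scores_train %*% t(pc5$loadings), 2, pc5$center, "+")
  expect_lt(max(abs(rebuilt - X5)), 1e-8)
})

test_that("held-out scores use the training centering and loadings", {
  set.seed(3)
  X <- matrix(rnorm(60 * 20), 60, 20)
  Xv <- matrix(rnorm(10 * 20), 10, 20)
  pc <- pca_extract(X, Xv, n_components = 4)
  manual <- sweep(Xv, 2, colMeans(X)) %*% pc$loadings
  expect_lt(max(abs(pc$scores_val - manual)), 1e-10)
  expect_error(pca_extract(X[1:4, ], n_components = 5), "samples")
  expect_error(pca_extract(X, Xv[, 1:5], n_components = 4), "mismatch")
})

test_that("interval tiling matches the published wavelength regions", {
  iv <- iriv_intervals()
  expect_length(iv, 30)
  expect_identical(sort(unlist(iv)), 1:600)
  expect_equal(interval_bounds(5), c(481, 500))
  expect_equal(interval_bounds(9), c(561, 580))
  expect_equal(interval_bounds(10), c(581, 600))
  expect_equal(interval_bounds(16), c(701, 720))
  expect_equal(interval_bounds(1), c(401, 420))
  expect_error(interval_bounds(31), "1..30")
  expect_error(interval_bounds(0), "1..30")
  # interval k indexes bands whose wavelengths are its bounds
  wl <- wavelength_grid()
  expect_equal(range(wl[iv[[16]]]), c(701, 720))
})

test_that("interval screening recovers a planted joint interval", {
  set.seed(1)
  X <- matrix(rnorm(150 * 600), 150, 600)
  iv <- iriv_intervals()
  tgt <- c(5, 9, 10, 16)
  y <- rowMeans(X[, unlist(iv[tgt])[seq(1, 80, 5)]]) * 3 + rnorm(150, 0, 0.1)
  r <- sipls_joint_interval(X, y, intervals = iv[1:16], n_joint = 4,
                            folds = 10, seed = 1)
  expect_equal(sort(r$intervals), tgt)
  expect_equal(r$n_combinations, choose(16, 4))
  r2 <- sipls_joint_interval(X, y, intervals = iv[1:16], n_joint = 4,
                             folds = 10, seed = 1)
  expect_identical(r$intervals, r2$intervals)
  expect_error(sipls_joint_interval(X[1:5, ], y[1:5], intervals = iv[1:6],
                                    folds = 10), "fold")
})

test_that("IRIV retains planted bands and drops noise bands", {
  p <- make_planted_problem(n = 150, n_bands = 40, planted = c(10, 30), seed = 5)
  it <- iriv_iterate(p$X, p$y, seed = 7)
  expect_true(all(p$planted %in% it$retained))
  expect_lte(length(setdiff(it$retained, p$planted)), 8) # <= 20% of 38 noise bands
  expect_true(all(it$retained %in% 1:40))
  expect_lte(it$n_rounds, 5)
})

test_that("IRIV degenerate inputs behave as specified", {
  p <- make_planted_problem(n = 50, n_bands = 10, planted = 3, seed = 1)
  one <- iriv_iterate(p$X, p$y, bands = 4L)
  expect_identical(one$retained, 4L)
  sub <- iriv_iterate(p$X, p$y, bands = 1:6, max_rounds = 2, seed = 2)
  expect_true(all(sub$retained %in% 1:6))
})

test_that("correlation pruning keeps one representative per correlated group", {
  set.seed(4)
  z <- rnorm(100)
  w <- rnorm(100)
  X <- cbind(z + rnorm(100, 0, 0.01), z + rnorm(100, 0, 0.01),
             z + rnorm(100, 0, 0.01), w)
  y <- z + 0.5 * w
  kept <- correlation_prune(X, y, 1:4, r_threshold = 0.9)
  expect_length(kept, 2)
  expect_true(4 %in% kept)
  # brute-force grouping oracle: the clique member most correlated with y
  clique_best <- which.max(abs(cor(X[, 1:3], y)))
  expect_true(clique_best %in% kept)
  # identical bands collapse to one
  Xi <- cbind(z, z)
  expect_length(correlation_prune(Xi, y, 1:2), 1)
  # uncorrelated bands pass through unchanged
  Xu <- matrix(rnorm(300), 100, 3)
  expect_equal(correlation_prune(Xu, y, 1:3), 1:3)
})
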