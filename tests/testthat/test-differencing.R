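test_that("max-yield rule picks the 100 kg/ha treatment from the field yields", {
  y <- observed_yields()
  expect_equal(select_standard(y), 100)
  expect_equal(select_standard(y[sample.int(4), ]), 100)
  expect_equal(select_standard(y[3, ]), 100)
  tie <- data.frame(treatment = c(0, 50), yield = c(300, 300))
  expect_error(select_standard(tie), "tie")
})

test_that("reference is the arithmetic mean over standard-treatment samples", {
  wl <- paste0("R", 401:1000)
  spec <- runif(600, 0, 1)
  two <- data.frame(sample_id = c("a", "b"), plot_id = "p", treatment = 100,
                    n_content = c(2, 4))
  two[wl] <- rep(spec, each = 2)
  ref <- build_reference(two, 100)
  expect_equal(unname(ref$standard_spectrum), spec)
  expect_equal(ref$standard_n, 3.0)
  one <- two[1, ]
  ref1 <- build_reference(one, 100)
  expect_equal(unname(ref1$standard_spectrum), spec)
  expect_equal(ref1$standard_n, 2)
  expect_error(build_reference(two, 150), "no samples")
})

test_that("simulated standard N lands within 3 SE of the configured mean", {
  p <- small_pipeline()
  sel <- p$samples$treatment == 100
  expect_equal(p$ref$standard_n, mean(p$samples$n_content[sel]))
  cfg_mean <- p$cfg$n_mean_by_treatment[p$cfg$treatments == 100]
  se <- p$cfg$n_sd / sqrt(sum(sel))
  expect_lt(abs(p$ref$standard_n - cfg_mean), 3 * se + 0.05) # 0.05: clip bias
})

test_that("differences are signed, exclude the standard plots, and invert exactly", {
  p <- small_pipeline()
  d <- p$diffs
  expect_equal(nrow(d$delta_r) + sum(p$samples$treatment == 100),
               nrow(p$samples))
  expect_false(any(d$treatment == 100))
  # signed deficits: N0 samples sit below the standard on average
  expect_lt(mean(d$delta_n[d$treatment == 0]), 0)
  # exact inversion back to the raw values
  raw <- reflectance_matrix(p$samples[p$samples$treatment != 100, ])
  rebuilt <- sweep(d$delta_r, 2, p$ref$standard_spectrum, "+")
  expect_lt(max(abs(rebuilt - raw)), 1e-12)
  n_rebuilt <- d$delta_n + p$ref$standard_n
  expect_lt(max(abs(n_rebuilt - p$samples$n_content[p$samples$treatment != 100])),
            1e-12)
})

test_that("a sample equal to the reference yields zero differences", {
  p <- small_pipeline()
  fake <- p$samples[1, ]
  fake$treatment <- 0
  fake$n_content <- p$ref$standard_n
  fake[paste0("R", 401:1000)] <- as.list(p$ref$standard_spectrum)
  d <- compute_differences(fake, p$ref)
  expect_lt(max(abs(d$delta_r)), 1e-14)
  expect_equal(d$delta_n, 0)
})

test_that("grid mismatch between samples and reference errors", {
  p <- small_pipeline()
  ref_bad <- p$ref
  ref_bad$standard_spectrum <- ref_bad$standard_spectrum[1:100]
  expect_error(compute_differences(p$samples, ref_bad), "grid")
})

test_that("train/validation split reproduces the 189/70 partition and is seeded", {
  p <- small_pipeline()
  d <- p$diffs
  # synthetic difference set truncated to the campaign's 259 samples
  d259 <- d
  keep <- 1:259
  d259$delta_r <- d$delta_r[keep, ]
  d259$delta_n <- d$delta_n[keep]
  d259$sample_id <- d$sample_id[keep]
  d259$treatment <- d$treatment[keep]
  d259$split <- d$split[keep]
  s <- split_train_validation(d259, fraction = 0.73, seed = 5)
  expect_equal(sum(s$split == "train"), 189)
  expect_equal(sum(s$split == "validation"), 70)
  s2 <- split_train_validation(d259, fraction = 0.73, seed = 5)
  expect_identical(s$split, s2$split)
  expect_true(all(s$split %in% c("train", "validation")))
  # 10-sample half split
  d10 <- d259
  d10$delta_r <- d259$delta_r[1:10, ]
  d10$delta_n <- d259$delta_n[1:10]
  d10$sample_id <- d259$sample_id[1:10]
  d10$treatment <- d259$treatment[1:10]
  d10$split <- d259$split[1:10]
  s10 <- split_train_validation(d10, fraction = 0.5, seed = 1)
  expect_equal(as.vector(table(s10$split)), c(5, 5))
})

test_that("difference sets round-trip through CSV", {
  p <- small_pipeline()
  path <- tempfile(fileext = ".csv")
  write_difference_set(p$diffs, path)
  back <- read_difference_set(path)
  expect_equal(back$delta_n, p$diffs$delta_n, tolerance = 1e-12)
  expect_lt(max(abs(back$delta_r - p$diffs$delta_r)), 1e-12)
  expect_identical(back$split, p$diffs$split)
  expect_equal(back$reference$standard_n, p$diffs$reference$standard_n,
               tolerance = 1e-12)
  unlink(c(path, paste0(path, ".reference.csv")))
})
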