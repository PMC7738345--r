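test_that("chromosome length follows l = s1*s2 + s2*s3 + s2 + s3", {
  expect_equal(individual_length(5, 10, 1), 71L)
  expect_equal(individual_length(1, 1, 1), 4L)
  expect_equal(individual_length(15, 20, 1), 341L)
})

test_that("fitness is 1/(1+E) and selection is fitness-proportional", {
  expect_equal(ga_fitness(0), 1.0)
  expect_equal(ga_fitness(1), 0.5)
  expect_equal(ga_fitness(3), 0.25)
  expect_error(ga_fitness(-0.1), ">= 0")
  expect_equal(selection_probability(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(selection_probability(5), 1.0)
  expect_equal(selection_probability(rep(2, 4)), rep(0.25, 4))
  expect_error(selection_probability(numeric(0)), "empty")
  expect_error(selection_probability(c(1, 0)), "positive")
})

test_that("adaptive rates vanish for the fittest and cap below the mean", {
  expect_equal(adaptive_rate(0.9, 0.9, 0.5, 0.5), 0)
  expect_equal(adaptive_rate(0.3, 0.9, 0.5, 0.5), 0.5)
  # both branch formulas agree at the branch point f_op = f_bar
  expect_equal(adaptive_rate(0.5, 0.9, 0.5, 0.5),
               0.5 * (0.9 - 0.5) / (0.9 - 0.5))
  expect_equal(adaptive_rate(0.7, 0.7, 0.7, 0.5), 0) # degenerate population
  expect_error(adaptive_rate(0.5, 0.4, 0.6, 0.5), "f_max")
})

test_that("encode/decode is a bijection in the block ordering", {
  set.seed(1)
  for (dims in list(c(5, 10, 1), c(3, 4, 2), c(1, 1, 1))) {
    v <- runif(individual_length(dims[1], dims[2], dims[3]), -1, 1)
    blocks <- decode_individual(v, dims[1], dims[2], dims[3])
    expect_equal(encode_individual(blocks), v)
    expect_equal(dim(blocks$input_weights), dims[1:2])
    expect_length(blocks$hidden_bias, dims[2])
  }
  expect_error(decode_individual(runif(10), 5, 10, 1), "length")
})

test_that("zero generations returns the best random initialization", {
  np <- make_nonlinear_problem(n = 80, seed = 2)
  g <- ga_elm_fit(np$X, np$y, s2 = 8, pop_size = 10, generations = 0, seed = 3)
  expect_length(g$history, 1)
  train_rmse <- rmse(np$y, predict(g, np$X))
  expect_equal(g$best_fitness, 1 / (1 + train_rmse), tolerance = 1e-10)
})

test_that("elitism makes the best fitness non-decreasing", {
  np <- make_nonlinear_problem(n = 100, seed = 4)
  g <- ga_elm_fit(np$X, np$y, s2 = 8, pop_size = 12, generations = 25, seed = 5)
  expect_length(g$history, 26)
  expect_true(all(diff(g$history) >= 0))
})

test_that("zero crossover and mutation rates leave only selection", {
  np <- make_nonlinear_problem(n = 80, seed = 6)
  g <- ga_elm_fit(np$X, np$y, s2 = 8, pop_size = 10, generations = 10,
                  k_c = 0, k_m = 0, seed = 7)
  # no new genetic material can appear, so the elite never improves
  expect_true(all(g$history == g$history[1]))
})

test_that("population below two individuals errors", {
  np <- make_nonlinear_problem(n = 50, seed = 8)
  expect_error(ga_elm_fit(np$X, np$y, pop_size = 1, seed = 1), "2 individuals")
})

test_that("a hand-built single-hidden-node network predicts the closed form", {
  net <- structure(list(
    s1 = 2L, s2 = 1L, s3 = 1L,
    input_weights = matrix(c(0.5, -0.25), 2, 1),
    hidden_bias = 0.1,
    output_weights = c(1.5, 2.0), # intercept, hidden weight
    scaling = list(center = c(0, 0), transform = diag(2))),
    class = "elm_network")
  x <- c(0.8, 0.4)
  manual <- 1.5 + 2.0 * plogis(0.5 * 0.8 - 0.25 * 0.4 + 0.1)
  expect_equal(predict(net, matrix(x, 1, 2)), manual, tolerance = 1e-12)
})

test_that("GA initialization matches plain ELM accuracy at matched capacity", {
  # hidden layer sized to the small training set (n = 110) for both models
  cmp <- sapply(1:11, function(sd) {
    np <- make_nonlinear_problem(n = 150, n_features = 10, seed = sd)
    tr <- 1:110; va <- 111:150
    c(elm = rmse(np$y[va],
                 predict(elm_fit(np$X[tr, ], np$y[tr], s2 = 12, seed = sd),
                         np$X[va, ])),
      gaelm = rmse(np$y[va],
                   predict(ga_elm_fit(np$X[tr, ], np$y[tr], s2 = 12, seed = sd),
                           np$X[va, ])))
  })
  expect_lte(median(cmp["gaelm", ]), median(cmp["elm", ]))
})
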