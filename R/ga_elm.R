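# Real-coded genetic optimization of the ELM's random layer. Each
# individual encodes the full weight set of an s1-s2-1 network; its error
# E is the training RMSE of the ELM obtained by solving the output weights
# from the encoded hidden layer, and its fitness is 1/(1+E). Selection is
# fitness-proportional within the above-average subpopulation; arithmetic
# crossover and Gaussian mutation are gated by adaptive rates that fall to
# zero for the fittest individuals.

#' Chromosome length of an s1-s2-s3 network
#'
#' `l = s1*s2 + s2*s3 + s2 + s3`: input weights, output weights, hidden
#' biases, output bias.
#'
#' @param s1,s2,s3 Input, hidden and output node counts.
#' @return Integer chromosome length.
#' @export
individual_length <- function(s1, s2, s3 = 1) {
  stopifnot(s1 >= 1, s2 >= 1, s3 >= 1)
  as.integer(s1 * s2 + s2 * s3 + s2 + s3)
}

#' Decode a chromosome into network weight blocks
#'
#' Block order matches [individual_length()]: input weights (s1 x s2),
#' output weights (s2 x s3), hidden biases (s2), output bias (s3). Only the
#' input weights and hidden biases parameterize the ELM; the output blocks
#' are carried for completeness and are overwritten by the least-squares
#' solve.
#'
#' @param v Numeric chromosome of length [individual_length()].
#' @param s1,s2,s3 Node counts.
#' @return List with `input_weights`, `output_weights`, `hidden_bias`,
#'   `output_bias`.
#' @export
decode_individual <- function(v, s1, s2, s3 = 1) {
  if (length(v) != individual_length(s1, s2, s3)) stop("chromosome length mismatch")
  i <- 0
  take <- function(k) { out <- v[i + seq_len(k)]; i <<- i + k; out }
  list(input_weights = matrix(take(s1 * s2), s1, s2),
       output_weights = matrix(take(s2 * s3), s2, s3),
       hidden_bias = take(s2),
       output_bias = take(s3))
}

#' Encode network weight blocks into a chromosome
#'
#' Inverse of [decode_individual()].
#'
#' @param blocks List as returned by [decode_individual()].
#' @return Numeric chromosome.
#' @export
encode_individual <- function(blocks) {
  c(as.vector(blocks$input_weights), as.vector(blocks$output_weights),
    blocks$hidden_bias, blocks$output_bias)
}

#' Fitness of an individual from its error
#'
#' `f = 1 / (1 + E)`, strictly decreasing in the network output error E.
#'
#' @param E Non-negative error (training RMSE of the induced ELM).
#' @return Fitness in (0, 1].
#' @export
ga_fitness <- function(E) {
  if (any(E < 0)) stop("error value must be >= 0")
  1 / (1 + E)
}

#' Fitness-proportional selection probabilities
#'
#' `p_i = f_i / sum(f)`.
#'
#' @param fitness Vector of positive fitness values.
#' @return Probability vector summing to 1.
#' @export
selection_probability <- function(fitness) {
  if (length(fitness) == 0) stop("empty population")
  if (any(fitness <= 0)) stop("fitness values must be positive")
  fitness / sum(fitness)
}

#' Adaptive crossover/mutation rate
#'
#' `p = k (f_max - f_op) / (f_max - f_bar)` for individuals at or above the
#' population mean fitness, and `p = k` below it. A degenerate uniform
#' population (`f_max == f_bar`) returns 0 for the above-average branch.
#'
#' @param f_op Fitness of the individual about to be crossed/mutated.
#' @param f_max Maximum population fitness.
#' @param f_bar Mean population fitness (`f_max >= f_bar`).
#' @param k Rate ceiling (k_c or k_m, a real number < 1... typically 0.5).
#' @return Rate in `[0, k]`.
#' @export
adaptive_rate <- function(f_op, f_max, f_bar, k) {
  if (f_max < f_bar) stop("f_max must be >= f_bar")
  if (f_op < f_bar) return(k)
  if (f_max == f_bar) return(0)
  k * (f_max - f_op) / (f_max - f_bar)
}

#' Genetic-algorithm-optimized extreme learning machine
#'
#' Evolves a population of real-coded chromosomes (input weights + hidden
#' biases, [individual_length()] genes in `[-1, 1]`). Each individual's
#' error is the training RMSE of the ELM induced by its hidden layer
#' (output weights solved by least squares); fitness is `1/(1+E)`.
#' Each generation retains the above-average-fitness subpopulation for
#' breeding, selects parents fitness-proportionally, applies arithmetic
#' crossover and Gaussian mutation gated by the adaptive rates, and carries
#' the best individual over unchanged (elitism), so the best fitness is
#' non-decreasing. The returned network is the ELM solved from the best
#' individual.
#'
#' @param X Training features.
#' @param y Training response (N deficiency, mg/g).
#' @param s2 Hidden-node count (default 20).
#' @param pop_size Population size m (default 30, must be >= 2).
#' @param generations Generation count G (default 100; 0 = best of the
#'   random initial population).
#' @param k_c,k_m Crossover and mutation rate ceilings (default 0.5 each).
#' @param mutation_sd Gaussian mutation SD (default 0.1).
#' @param mutation_frac Fraction of genes perturbed when an individual
#'   mutates (default 0.1).
#' @param seed Integer seed.
#' @return Object of class `ga_elm_fit`: `network` (an `elm_network`),
#'   `history` (best fitness per generation, index 1 = initial population),
#'   `best_fitness`.
#' @export
ga_elm_fit <- function(X, y, s2 = 20, pop_size = 30, generations = 100,
                       k_c = 0.5, k_m = 0.5, mutation_sd = 0.1,
                       mutation_frac = 0.1, seed = 1) {
  X <- as.matrix(X)
  if (pop_size < 2) stop("population must have at least 2 individuals")
  set.seed(seed)
  scaling <- .elm_scaling(X)
  s1 <- ncol(scaling$transform) # whitened input width
  l <- individual_length(s1, s2, 1)
  eval_error <- function(v) {
    d <- decode_individual(v, s1, s2, 1)
    H <- .elm_hidden(X, scaling, d$input_weights, d$hidden_bias)
    beta <- .elm_solve(H, y)
    sqrt(mean((as.vector(cbind(1, H) %*% beta) - y)^2))
  }
  P <- matrix(stats::runif(pop_size * l, -1, 1), pop_size, l)
  E <- apply(P, 1, eval_error)
  f <- ga_fitness(E)
  history <- max(f)
  for (g in seq_len(generations)) {
    f_bar <- mean(f)
    f_max <- max(f)
    sub <- which(f >= f_bar)
    if (length(sub) < 2) sub <- order(f, decreasing = TRUE)[1:2]
    p_sel <- selection_probability(f[sub])
    elite <- which.max(f)
    newP <- matrix(NA_real_, pop_size, l)
    newP[1, ] <- P[elite, ]
    new_E <- rep(NA_real_, pop_size)
    new_E[1] <- E[elite]
    i <- 1L
    while (i < pop_size) {
      pair <- sub[sample.int(length(sub), 2, replace = TRUE, prob = p_sel)]
      c1 <- P[pair[1], ]
      c2 <- P[pair[2], ]
      f_pair <- max(f[pair])
      if (stats::runif(1) < adaptive_rate(f_pair, f_max, f_bar, k_c)) {
        a <- stats::runif(1)
        tmp <- a * c1 + (1 - a) * c2
        c2 <- a * c2 + (1 - a) * c1
        c1 <- tmp
      }
      for (child in list(c1, c2)) {
        if (i >= pop_size) break
        if (stats::runif(1) < adaptive_rate(f_pair, f_max, f_bar, k_m)) {
          idx <- sample.int(l, max(1, ceiling(mutation_frac * l)))
          child[idx] <- pmin(pmax(child[idx] +
                                    stats::rnorm(length(idx), 0, mutation_sd),
                                  -1), 1)
        }
        i <- i + 1L
        newP[i, ] <- child
      }
    }
    P <- newP
    E <- new_E
    for (r in which(is.na(new_E))) E[r] <- eval_error(P[r, ])
    f <- ga_fitness(E)
    history <- c(history, max(f))
  }
  best <- decode_individual(P[which.max(f), ], s1, s2, 1)
  network <- .elm_build(X, y, best$input_weights, best$hidden_bias, scaling)
  structure(list(network = network, history = history,
                 best_fitness = max(f)),
            class = "ga_elm_fit")
}

#' @export
predict.ga_elm_fit <- function(object, newdata, ...) {
  predict(object$network, newdata, ...)
}

#' @export
print.ga_elm_fit <- function(x, ...) {
  cat(sprintf("<ga_elm_fit> best fitness %.4f after %d generations\n",
              x$best_fitness, length(x$history) - 1))
  invisible(x)
}
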