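# Seed-reproducible synthetic generator for the rice leaf N study design:
# four N treatments (0/50/100/150 kg/ha) in replicated plots, leaf N content
# in mg/g, and leaf reflectance on the fixed 401-1000 nm grid (600 bands).

#' The fixed wavelength grid
#'
#' @return Integer vector 401..1000 nm (600 bands at 1 nm).
#' @export
wavelength_grid <- function() 401:1000

# yield response (kg/667 m^2) as a quadratic in the N rate, calibrated by
# least squares to the observed per-treatment yields so the grid maximum sits
# at 100 kg/ha
.yield_coef <- c(258.897, 2.53194, -0.013422)

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: four N treatments in
#' replicated plots, per-treatment leaf N content distributions whose pooled
#' moments approximate the field campaign (pooled mean about 2.9 mg/g), and
#' a chlorophyll-driven reflectance response.
#'
#' @param seed Integer seed; every random draw flows from it.
#' @param n_plots_per_treatment Plots per treatment (default 4).
#' @param n_samples_per_plot Leaf samples per plot (default 22, about three
#'   growth stages of repeated sampling).
#' @param treatments N rates in kg/ha, strictly increasing.
#' @param noise_sd I.i.d. Gaussian reflectance noise (reflectance units).
#' @param n_mean_by_treatment Mean leaf N content (mg/g) per treatment.
#' @param n_sd Within-treatment N content standard deviation (mg/g).
#' @param chl_noise_sd SD of the sample-level deviation between the
#'   chlorophyll proxy and its N-driven expectation (on the 0-1 chlorophyll
#'   scale). This decouples the spectrum from leaf N imperfectly, putting a
#'   realistic ceiling on the attainable inversion accuracy.
#' @param structure_sd Amplitude SD (reflectance units) of smooth
#'   N-unrelated spectral nuisance (leaf structure/water/clip geometry),
#'   drawn per sample as a few random Gaussian bumps.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_plots_per_treatment = 4,
                       n_samples_per_plot = 22,
                       treatments = c(0, 50, 100, 150),
                       noise_sd = 0.008,
                       n_mean_by_treatment = c(1.8, 2.6, 3.3, 3.8),
                       n_sd = 0.45,
                       chl_noise_sd = 0.12,
                       structure_sd = 0.025) {
  if (length(treatments) < 1 || any(diff(treatments) <= 0))
    stop("treatments must be strictly increasing")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_plots_per_treatment < 1 || n_samples_per_plot < 1)
    stop("counts must be >= 1")
  if (length(n_mean_by_treatment) != length(treatments))
    stop("n_mean_by_treatment must match treatments in length")
  if (n_sd < 0) stop("n_sd must be >= 0")
  if (chl_noise_sd < 0 || structure_sd < 0) stop("noise SDs must be >= 0")
  structure(list(seed = as.integer(seed),
                 n_plots_per_treatment = as.integer(n_plots_per_treatment),
                 n_samples_per_plot = as.integer(n_samples_per_plot),
                 treatments = treatments,
                 noise_sd = noise_sd,
                 n_mean_by_treatment = n_mean_by_treatment,
                 n_sd = n_sd,
                 chl_noise_sd = chl_noise_sd,
                 structure_sd = structure_sd),
            class = "sim_config")
}

#' Noiseless leaf reflectance curve for a given N content
#'
#' Stylized Gaussian-feature leaf model: low visible reflectance, a green
#' peak near 550 nm and a red absorption trough near 672 nm whose depths vary
#' with chlorophyll (proxied by leaf N content), a red-edge rise near
#' 700-750 nm, and a NIR plateau around 0.5. Higher N means more
#' chlorophyll, hence lower green/red reflectance.
#'
#' @param n_content Leaf N content in mg/g (scalar).
#' @param wl Wavelength grid in nm.
#' @return Reflectance vector in `[0, 1]`.
#' @export
reflectance_curve <- function(n_content, wl = wavelength_grid()) {
  .curve_from_chl(pmin(pmax((n_content - 1) / 4, 0), 1), wl)
}

.curve_from_chl <- function(chl, wl) {
  # Beer-Lambert-type saturating response: visible reflectance decays
  # exponentially with pigment load, so the spectrum-N relation is
  # nonlinear (flat at high N). The red edge shifts to longer wavelengths
  # and the NIR plateau rises slightly with chlorophyll/N, making the N
  # signal spectrally broad rather than confined to the green/red bands.
  base <- 0.05 + (0.42 + 0.05 * chl) * stats::plogis((wl - (712 + 16 * chl)) / 18)
  green <- 0.17 * exp(-1.8 * chl) * exp(-((wl - 550)^2) / (2 * 35^2))
  red <- 0.05 * (1 - exp(-3 * chl)) * exp(-((wl - 672)^2) / (2 * 28^2))
  pmin(pmax(base + green - red, 0), 1)
}

# N-unrelated spectral nuisance per sample: a small global brightness
# offset (clip geometry) plus several random local bumps (leaf texture,
# water pockets, surface artifacts) whose centers and widths differ per
# sample, so the difference matrix carries structured variance that no
# fixed low-rank basis removes
.structure_nuisance <- function(wl, sd) {
  if (sd == 0) return(numeric(length(wl)))
  k <- 8
  centers <- stats::runif(k, 420, 980)
  widths <- stats::runif(k, 15, 50)
  amps <- stats::rnorm(k, 0, sd)
  offset <- stats::rnorm(1, 0, sd / 2)
  offset + colSums(amps * exp(-outer(centers, wl, "-")^2 / (2 * widths^2)))
}

#' Generate a synthetic leaf sample table
#'
#' One row per leaf sample: `sample_id`, `plot_id`, `treatment` (kg/ha),
#' `n_content` (mg/g, drawn per treatment from a normal clipped to
#' `[1, 5]` mg/g), and reflectance columns `R401`..`R1000`.
#'
#' @param config A [sim_config()].
#' @return `data.frame` with 600 reflectance columns; deterministic for a
#'   fixed seed.
#' @export
generate_samples <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  wl <- wavelength_grid()
  rows <- list()
  i <- 0L
  for (ti in seq_along(config$treatments)) {
    for (p in seq_len(config$n_plots_per_treatment)) {
      for (s in seq_len(config$n_samples_per_plot)) {
        i <- i + 1L
        n_content <- stats::rnorm(1, config$n_mean_by_treatment[ti], config$n_sd)
        n_content <- min(max(n_content, 1.0), 5.0)
        chl <- (n_content - 1) / 4
        if (config$chl_noise_sd > 0)
          chl <- chl + stats::rnorm(1, 0, config$chl_noise_sd)
        chl <- min(max(chl, 0), 1)
        refl <- .curve_from_chl(chl, wl) +
          .structure_nuisance(wl, config$structure_sd)
        if (config$noise_sd > 0)
          refl <- refl + stats::rnorm(length(wl), 0, config$noise_sd)
        refl <- pmin(pmax(refl, 0), 1)
        rows[[i]] <- c(treatment = config$treatments[ti], plot = p,
                       n_content = n_content, refl)
      }
    }
  }
  m <- do.call(rbind, rows)
  out <- data.frame(
    sample_id = sprintf("S%04d", seq_len(nrow(m))),
    plot_id = sprintf("N%g_P%d", m[, "treatment"], m[, "plot"]),
    treatment = m[, "treatment"],
    n_content = m[, "n_content"]
  )
  refl <- m[, -(1:3), drop = FALSE]
  colnames(refl) <- paste0("R", wl)
  cbind(out, refl)
}

#' Generate the per-treatment yield table
#'
#' Evaluates the calibrated quadratic yield response (kg/667 m^2) at the
#' configured N rates; the response peaks near 94 kg/ha so the grid maximum
#' falls on the 100 kg/ha treatment.
#'
#' @param config A [sim_config()].
#' @return `data.frame` with columns `treatment` and `yield`, one row per
#'   treatment.
#' @export
generate_yields <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  t <- config$treatments
  y <- .yield_coef[1] + .yield_coef[2] * t + .yield_coef[3] * t^2
  if (any(y <= 0)) stop("yield response is non-positive for some treatment")
  data.frame(treatment = t, yield = y)
}

#' Reflectance columns of a sample table as a matrix
#'
#' @param samples A sample table from [generate_samples()] (or the same
#'   schema read from CSV).
#' @return Numeric matrix (samples x bands), rownames = sample ids.
#' @export
reflectance_matrix <- function(samples) {
  cols <- grep("^R[0-9]+$", names(samples), value = TRUE)
  m <- as.matrix(samples[, cols])
  rownames(m) <- samples$sample_id
  m
}

#' Synthetic planted-band regression problem
#'
#' Builds a design matrix of independent Gaussian band columns in which a
#' few "planted" columns carry amplified variance, and a response that is a
#' linear function of exactly those columns. Used by the planted-signal
#' recovery checks for the band-selection methods.
#'
#' @param n Samples.
#' @param n_bands Candidate bands.
#' @param planted Indices of the informative bands.
#' @param planted_scale Standard deviation multiplier of planted columns
#'   (noise columns have unit SD).
#' @param coefs Regression coefficients of the planted bands (recycled).
#' @param y_noise_sd Response noise SD (0 = noiseless response).
#' @param seed Integer seed.
#' @return List with `X`, `y`, `planted`.
#' @export
make_planted_problem <- function(n = 150, n_bands = 40, planted = c(10, 30),
                                 planted_scale = 1, coefs = 1,
                                 y_noise_sd = 0, seed = 1) {
  stopifnot(all(planted >= 1), all(planted <= n_bands))
  set.seed(seed)
  X <- matrix(stats::rnorm(n * n_bands), n, n_bands)
  X[, planted] <- X[, planted] * planted_scale
  coefs <- rep_len(coefs, length(planted))
  y <- as.vector(X[, planted, drop = FALSE] %*% coefs)
  if (y_noise_sd > 0) y <- y + stats::rnorm(n, 0, y_noise_sd)
  colnames(X) <- paste0("B", seq_len(n_bands))
  list(X = X, y = y, planted = planted)
}

#' Synthetic nonlinear inversion problem
#'
#' The reference problem for comparing the inversion regressors: features
#' are independent standard-normal columns and the response is a smooth
#' nonlinear function of the first three features (two linear terms plus a
#' curvature term in the third) with additive Gaussian noise, mimicking an
#' N-deficiency signal of a few mg/g whose spectrum-N link saturates.
#'
#' @param n Samples (default 259, the campaign's sample count).
#' @param n_features Feature columns (default 5: three informative, the
#'   rest pure noise).
#' @param noise_sd Response noise SD in mg/g (default 0.2).
#' @param seed Integer seed.
#' @return List with `X`, `y`.
#' @export
make_nonlinear_problem <- function(n = 259, n_features = 5,
                                   noise_sd = 0.2, seed = 1) {
  stopifnot(n_features >= 3)
  set.seed(seed)
  X <- matrix(stats::rnorm(n * n_features), n, n_features)
  y <- 1.2 * X[, 1] + 0.9 * X[, 2] + 0.7 * (X[, 3]^2 - 1) +
    stats::rnorm(n, 0, noise_sd)
  colnames(X) <- paste0("F", seq_len(n_features))
  list(X = X, y = y)
}
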