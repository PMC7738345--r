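# Standard-field selection and construction of the difference dataset:
# the treatment with the highest yield defines the reference ("standard
# field"); its mean spectrum and mean leaf N content are subtracted from
# every non-standard sample to give the signed difference spectra and the
# N deficiency values that the inversion models work on.

#' Select the standard treatment by the max-yield rule
#'
#' @param yields Yield table with columns `treatment` and `yield`.
#' @return The treatment (kg/ha) with strictly maximal yield.
#' @export
select_standard <- function(yields) {
  stopifnot(is.data.frame(yields), nrow(yields) >= 1,
            all(c("treatment", "yield") %in% names(yields)))
  top <- which(yields$yield == max(yields$yield))
  if (length(top) > 1)
    stop("tie in maximal yield between treatments ",
         paste(yields$treatment[top], collapse = ", "))
  yields$treatment[top]
}

#' Build the standard reference
#'
#' The standard spectrum is the arithmetic mean reflectance over all samples
#' of the standard treatment; the standard N content is their mean leaf N.
#'
#' @param samples Sample table (see [generate_samples()]).
#' @param standard_treatment Treatment selected by [select_standard()].
#' @return Object of class `standard_reference` with `standard_treatment`,
#'   `standard_spectrum` (600-vector) and `standard_n` (mg/g).
#' @export
build_reference <- function(samples, standard_treatment) {
  sel <- samples$treatment == standard_treatment
  if (!any(sel)) stop("no samples with treatment ", standard_treatment)
  refl <- reflectance_matrix(samples[sel, , drop = FALSE])
  structure(list(standard_treatment = standard_treatment,
                 standard_spectrum = colMeans(refl),
                 standard_n = mean(samples$n_content[sel])),
            class = "standard_reference")
}

#' @export
print.standard_reference <- function(x, ...) {
  cat(sprintf("<standard_reference> treatment %g kg/ha, standard N %.3f mg/g, %d bands\n",
              x$standard_treatment, x$standard_n, length(x$standard_spectrum)))
  invisible(x)
}

#' Compute signed difference spectra and N deficiencies
#'
#' For every sample from a non-standard plot, subtracts the standard
#' spectrum from its reflectance (`delta_r`, signed) and the standard N
#' content from its leaf N (`delta_n`, mg/g; negative = deficit).
#' Standard-treatment samples are excluded.
#'
#' @param samples Sample table.
#' @param reference A `standard_reference`.
#' @return Object of class `difference_set` with `delta_r` (samples x
#'   bands), `delta_n`, `sample_id`, `treatment`, `split` (NA until
#'   [split_train_validation()]) and `reference`.
#' @export
compute_differences <- function(samples, reference) {
  stopifnot(inherits(reference, "standard_reference"))
  refl <- reflectance_matrix(samples)
  if (ncol(refl) != length(reference$standard_spectrum))
    stop("band grid of samples does not match the reference")
  keep <- samples$treatment != reference$standard_treatment
  refl <- refl[keep, , drop = FALSE]
  delta_r <- sweep(refl, 2, reference$standard_spectrum)
  colnames(delta_r) <- sub("^R", "D", colnames(delta_r))
  structure(list(delta_r = delta_r,
                 delta_n = samples$n_content[keep] - reference$standard_n,
                 sample_id = samples$sample_id[keep],
                 treatment = samples$treatment[keep],
                 split = rep(NA_character_, sum(keep)),
                 reference = reference),
            class = "difference_set")
}

#' @export
print.difference_set <- function(x, ...) {
  cat(sprintf("<difference_set> %d samples x %d bands; split: %s\n",
              nrow(x$delta_r), ncol(x$delta_r),
              if (all(is.na(x$split))) "unassigned"
              else paste0(sum(x$split == "train"), " train / ",
                          sum(x$split == "validation"), " validation")))
  invisible(x)
}

#' Assign a random train/validation split
#'
#' Uniform random split without stratification; the training set has
#' `round(n * fraction)` samples.
#'
#' @param diffs A `difference_set`.
#' @param fraction Training fraction in (0, 1); the default 189/259
#'   reproduces the campaign's 189/70 partition.
#' @param seed Integer seed for the assignment.
#' @return The `difference_set` with `split` filled in.
#' @export
split_train_validation <- function(diffs, fraction = 189 / 259, seed = 1) {
  stopifnot(inherits(diffs, "difference_set"),
            fraction > 0, fraction < 1)
  n <- nrow(diffs$delta_r)
  if (n < 2) stop("need at least 2 samples to split")
  n_train <- round(n * fraction)
  set.seed(seed)
  idx <- sample.int(n, n_train)
  diffs$split <- rep("validation", n)
  diffs$split[idx] <- "train"
  diffs
}

#' Extract one side of the split as a (features, response) pair
#'
#' @param diffs A split `difference_set`.
#' @param which `"train"` or `"validation"`.
#' @return List with `X` (delta_r rows of that side) and `y` (delta_n).
#' @export
split_side <- function(diffs, which = c("train", "validation")) {
  which <- match.arg(which)
  if (all(is.na(diffs$split))) stop("difference set has no split assigned")
  sel <- diffs$split == which
  list(X = diffs$delta_r[sel, , drop = FALSE], y = diffs$delta_n[sel])
}
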