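# Plain-text interchange: sample/yield tables and difference sets as CSV
# with one-line headers; fitted models as a documented JSON container.

#' Write / read a sample or yield table as CSV
#'
#' @param x Data frame (sample table with `R401..R1000` columns, or yield
#'   table).
#' @param path Output path.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Write a difference set as CSV (+ reference sidecar)
#'
#' Main file: `sample_id`, `treatment`, `split`, `delta_n`, `D401..D1000`.
#' Sidecar `<path>.reference.csv`: the standard spectrum and standard N.
#'
#' @param diffs A `difference_set`.
#' @param path Output path of the main CSV.
#' @export
write_difference_set <- function(diffs, path) {
  stopifnot(inherits(diffs, "difference_set"))
  main <- data.frame(sample_id = diffs$sample_id,
                     treatment = diffs$treatment,
                     split = diffs$split,
                     delta_n = diffs$delta_n)
  main <- cbind(main, as.data.frame(diffs$delta_r))
  utils::write.csv(main, path, row.names = FALSE)
  ref <- diffs$reference
  side <- data.frame(field = c("standard_treatment", "standard_n",
                               names(ref$standard_spectrum)),
                     value = c(ref$standard_treatment, ref$standard_n,
                               unname(ref$standard_spectrum)))
  utils::write.csv(side, paste0(path, ".reference.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a difference set written by [write_difference_set()]
#'
#' @param path Path of the main CSV.
#' @return A `difference_set`.
#' @export
read_difference_set <- function(path) {
  main <- utils::read.csv(path, check.names = FALSE)
  side <- utils::read.csv(paste0(path, ".reference.csv"), check.names = FALSE)
  spec_rows <- grepl("^R[0-9]+$", side$field)
  ref <- structure(list(
    standard_treatment = side$value[side$field == "standard_treatment"],
    standard_spectrum = stats::setNames(side$value[spec_rows],
                                        side$field[spec_rows]),
    standard_n = side$value[side$field == "standard_n"]),
    class = "standard_reference")
  dcols <- grep("^D[0-9]+$", names(main), value = TRUE)
  delta_r <- as.matrix(main[, dcols])
  rownames(delta_r) <- main$sample_id
  structure(list(delta_r = delta_r, delta_n = main$delta_n,
                 sample_id = main$sample_id, treatment = main$treatment,
                 split = as.character(main$split), reference = ref),
            class = "difference_set")
}

#' Serialize a fitted model to JSON
#'
#' Supports `elm_network`, `ga_elm_fit` (its network is stored) and
#' `plsr_model`. The container records the class, dimensions and all
#' weights needed to reproduce predictions exactly.
#'
#' @param model Fitted model object.
#' @param path Output path.
#' @export
model_to_json <- function(model, path) {
  if (inherits(model, "ga_elm_fit")) model <- model$network
  obj <- if (inherits(model, "elm_network")) {
    list(type = "elm_network", s1 = model$s1, s2 = model$s2, s3 = model$s3,
         k = nrow(model$input_weights),
         input_weights = as.vector(model$input_weights),
         hidden_bias = model$hidden_bias,
         output_weights = model$output_weights,
         scaling_center = model$scaling$center,
         scaling_transform = as.vector(model$scaling$transform),
         seed = model$seed)
  } else if (inherits(model, "plsr_model")) {
    list(type = "plsr_model", ncomp = model$ncomp,
         coefs = as.vector(model$fit$coefs[, model$fit$ncomp]),
         x_center = model$fit$x_center, y_center = model$fit$y_center)
  } else stop("unsupported model class")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a model serialized by [model_to_json()]
#'
#' @param path JSON path.
#' @return An `elm_network` or `plsr_model` giving identical predictions.
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$type == "elm_network") {
    structure(list(s1 = obj$s1, s2 = obj$s2, s3 = obj$s3,
                   input_weights = matrix(obj$input_weights, obj$k, obj$s2),
                   hidden_bias = obj$hidden_bias,
                   output_weights = obj$output_weights,
                   scaling = list(center = obj$scaling_center,
                                  transform = matrix(obj$scaling_transform,
                                                     obj$s1, obj$k)),
                   seed = obj$seed),
              class = "elm_network")
  } else if (obj$type == "plsr_model") {
    fit <- structure(list(coefs = matrix(obj$coefs, ncol = 1),
                          x_center = obj$x_center, y_center = obj$y_center,
                          ncomp = 1L),
                     class = "pls1_fit")
    structure(list(fit = fit, ncomp = 1L, rmsecv_path = NULL),
              class = "plsr_model")
  } else stop("unknown model type in JSON: ", obj$type)
}
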