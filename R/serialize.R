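#' Serialize package objects to JSON
#'
#' Round-trip generator coefficients ([calibrate_generator()]), scenario
#' configurations ([scenario_config()]) and fitted models ([fit_logit()];
#' intercept, coefficients, spline knots, lambda and flags) through JSON
#' files, so study configurations and fitted models can be stored alongside
#' result tables.
#'
#' @param x A `gen_coefs`, `scenario_config` or `imblogit` object.
#' @param path JSON file path.
#' @return `write_json_object()` returns `path` invisibly;
#'   `read_json_object()` returns the restored object.
#' @examples
#' cf <- calibrate_generator(3, 0.3)
#' f <- tempfile(fileext = ".json")
#' write_json_object(cf, f)
#' read_json_object(f)$beta == cf$beta
#' @export
write_json_object <- function(x, path) {
  cls <- intersect(class(x), c("gen_coefs", "scenario_config", "imblogit"))
  if (!length(cls)) stop("unsupported object class: ", paste(class(x), collapse = "/"))
  payload <- unclass(x)
  payload$call <- NULL
  payload$cv <- NULL
  payload[[".class"]] <- cls[1]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_json_object
#' @export
read_json_object <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- payload$.class
  payload$.class <- NULL
  if (identical(cls, "imblogit")) {
    payload$coef <- unlist(payload$coef)
    payload$basis$knots <- lapply(payload$basis$knots, unlist)
    if (!length(payload$basis$vars)) payload$basis$vars <- NULL
    if (!length(payload$basis$knots)) payload$basis$knots <- NULL
  }
  if (identical(cls, "scenario_config")) {
    ints <- c("n_train", "p", "n_reps", "n_test", "base_seed", "scenario_id")
    payload[ints] <- lapply(payload[ints], as.integer)
  }
  structure(payload, class = cls)
}
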