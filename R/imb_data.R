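#' Construct a prediction dataset
#'
#' The unit of data flowing through the package: an `n x p` predictor matrix
#' with a binary outcome vector, and (for simulated data) the true event
#' probability of each row.
#'
#' @param x Numeric matrix of predictors (rows are individuals). Column names
#'   default to `x1..xp`.
#' @param y Binary outcome vector (0/1), one entry per row of `x`.
#' @param pi_true Optional vector of true event probabilities in (0, 1);
#'   available only for generated data.
#' @return An object of class `imb_data`: a list with elements `x`, `y` and
#'   (possibly `NULL`) `pi_true`.
#' @examples
#' d <- imb_data(matrix(rnorm(20), 10, 2), rep(c(0, 1), 5))
#' d
#' @export
imb_data <- function(x, y, pi_true = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (!all(y %in% c(0L, 1L))) stop("y must be coded 0/1")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (!is.null(pi_true)) {
    pi_true <- as.double(pi_true)
    if (length(pi_true) != length(y)) stop("pi_true must match length(y)")
    if (any(pi_true <= 0 | pi_true >= 1)) stop("pi_true must lie in (0, 1)")
  }
  structure(list(x = x, y = y, pi_true = pi_true), class = "imb_data")
}

#' @export
print.imb_data <- function(x, ...) {
  cat(sprintf("<imb_data> %d rows, %d predictors, %d events (event fraction %.3f)\n",
              nrow(x$x), ncol(x$x), sum(x$y), mean(x$y)))
  if (!is.null(x$pi_true)) cat("  true event probabilities attached\n")
  invisible(x)
}

#' @export
as.data.frame.imb_data <- function(x, ...) {
  df <- as.data.frame(x$x)
  df$y <- x$y
  if (!is.null(x$pi_true)) df$pi_true <- x$pi_true
  df
}

#' @rdname imb_data
#' @param data An `imb_data` object.
#' @param path File path for the headered CSV dialect (columns `x1..xp`,
#'   `y`, optional `pi_true`).
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "imb_data"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname imb_data
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path)
  if (!"y" %in% names(df)) stop("dataset CSV must contain a 'y' column")
  pi_true <- if ("pi_true" %in% names(df)) df$pi_true else NULL
  xcols <- setdiff(names(df), c("y", "pi_true"))
  imb_data(as.matrix(df[xcols]), df$y, pi_true)
}

# number of minority-class rows; minority is the less frequent outcome value
minority_count <- function(data) min(tabulate(data$y + 1L, 2L))
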