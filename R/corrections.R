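#' Imbalance corrections: RUS, ROS and SMOTE
#'
#' Produce an artificially balanced training dataset from an imbalanced one.
#' The minority class is the less frequent outcome value of the dataset at
#' hand (not hard-coded to `y = 1`).
#'
#' * `undersample()` (RUS) discards a random subset of majority-class rows
#'   until both classes have the minority size.
#' * `oversample()` (ROS) resamples minority rows with replacement until the
#'   minority class reaches the majority size; every added row is an exact
#'   duplicate of an original minority row.
#' * `smote()` creates synthetic minority rows: for a minority row `x_i`, one
#'   of its `k` nearest minority neighbors `x_nn` (Euclidean distance, self
#'   excluded, distance ties broken by row index) is chosen uniformly, and the
#'   synthetic row is `x_i + u * (x_nn - x_i)` with `u ~ Uniform(0, 1)`.
#'   Synthetic rows are allocated as evenly as possible over the minority rows
#'   (each gets `floor(needed / minority)`; a random subset gets one more), so
#'   the output is exactly balanced.
#'
#' All three use the current RNG state; call `set.seed()` for reproducibility.
#'
#' @param data An [imb_data] dataset containing both classes.
#' @param k Number of nearest minority neighbors for SMOTE (default 5). If
#'   `k >= minority count`, it is clamped to `minority count - 1` with a
#'   warning.
#' @param round_cols Optional column names/indices whose synthetic SMOTE
#'   values are rounded to the nearest integer within the observed minority
#'   range (for ordinal predictors such as a papillation count).
#' @return A balanced [imb_data] dataset (`pi_true` is dropped: synthetic or
#'   resampled rows no longer carry a meaningful generating probability).
#' @examples
#' set.seed(1)
#' d <- generate_dataset(200, list(b0 = -2, beta = 0.5, p = 2))
#' table(undersample(d)$y)
#' table(oversample(d)$y)
#' table(smote(d)$y)
#' @name corrections
NULL

split_classes <- function(data) {
  n1 <- sum(data$y == 1L)
  n0 <- length(data$y) - n1
  if (n0 == 0L || n1 == 0L) stop("correction failure: dataset has a single class")
  minority <- if (n1 <= n0) 1L else 0L
  list(min_idx = which(data$y == minority),
       maj_idx = which(data$y != minority),
       minority = minority)
}

#' @rdname corrections
#' @export
undersample <- function(data) {
  stopifnot(inherits(data, "imb_data"))
  cl <- split_classes(data)
  keep_maj <- sample(cl$maj_idx, length(cl$min_idx))
  idx <- c(cl$min_idx, keep_maj)
  imb_data(data$x[idx, , drop = FALSE], data$y[idx])
}

#' @rdname corrections
#' @export
oversample <- function(data) {
  stopifnot(inherits(data, "imb_data"))
  cl <- split_classes(data)
  extra <- length(cl$maj_idx) - length(cl$min_idx)
  add <- if (extra > 0) sample(cl$min_idx, extra, replace = TRUE) else integer(0)
  idx <- c(seq_along(data$y), add)
  imb_data(data$x[idx, , drop = FALSE], data$y[idx])
}

#' @rdname corrections
#' @export
smote <- function(data, k = 5, round_cols = NULL) {
  stopifnot(inherits(data, "imb_data"), k >= 1)
  cl <- split_classes(data)
  n_min <- length(cl$min_idx)
  if (n_min < 2) stop("correction failure: SMOTE needs at least 2 minority rows")
  if (k >= n_min) {
    warning(sprintf("k = %d >= minority count %d; clamping k to %d",
                    k, n_min, n_min - 1L))
    k <- n_min - 1L
  }
  needed <- length(cl$maj_idx) - n_min
  if (needed <= 0) return(imb_data(data$x, data$y))

  xmin <- data$x[cl$min_idx, , drop = FALSE]
  # k nearest minority neighbors of each minority row; ties broken by index
  d2 <- as.matrix(stats::dist(xmin))^2
  diag(d2) <- Inf
  nn <- do.call(rbind, lapply(seq_len(n_min),
                              function(i) order(d2[i, ])[seq_len(k)]))

  # even allocation: floor(needed / n_min) per row, one extra for a random subset
  n_each <- rep(needed %/% n_min, n_min)
  rem <- needed %% n_min
  if (rem > 0) {
    extra <- sample.int(n_min, rem)
    n_each[extra] <- n_each[extra] + 1L
  }
  base <- rep.int(seq_len(n_min), n_each)
  pick <- nn[cbind(base, sample.int(k, needed, replace = TRUE))]
  u <- stats::runif(needed)
  synth <- xmin[base, , drop = FALSE] +
    u * (xmin[pick, , drop = FALSE] - xmin[base, , drop = FALSE])
  if (!is.null(round_cols)) {
    for (j in round_cols) {
      rng <- range(xmin[, j])
      synth[, j] <- pmin(pmax(round(synth[, j]), rng[1]), rng[2])
    }
  }
  imb_data(rbind(data$x, synth),
           c(data$y, rep.int(cl$minority, needed)))
}

#' Apply an imbalance correction by name
#'
#' @param data An [imb_data] dataset.
#' @param method One of `"none"`, `"rus"`, `"ros"`, `"smote"`.
#' @param k SMOTE neighbor count.
#' @param round_cols Passed to [smote()].
#' @return The (possibly unchanged) training dataset.
#' @export
rebalance <- function(data, method = c("none", "rus", "ros", "smote"),
                      k = 5, round_cols = NULL) {
  switch(match.arg(method),
         none = data,
         rus = undersample(data),
         ros = oversample(data),
         smote = smote(data, k = k, round_cols = round_cols))
}
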